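test_that("the coefficient transform and its inverse are exact inverses", {
  expect_equal(transform_coefficients(1, -4, 4),
               c(beta0 = 1, beta1 = 4, beta2 = 1))
  expect_equal(transform_coefficients(2.963, -8.228251, 7.685186),
               c(beta0 = 2.963, beta1 = 2.777, beta2 = 0.934),
               tolerance = 1e-6)
  set.seed(60)
  for (i in 1:25) {
    b <- c(runif(1, 0.2, 4), runif(1, 0.1, 5), runif(1, 0.3, 2))
    a <- inverse_transform_coefficients(b[1], b[2], b[3])
    expect_equal(unname(transform_coefficients(a[1], a[2], a[3])),
                 b, tolerance = 1e-12)
  }
  ## undefined components are flagged, not fabricated
  expect_true(is.na(transform_coefficients(0, -1, 1)[["beta1"]]))
  expect_true(is.na(transform_coefficients(1, NA, 1)[["beta2"]]))
})

test_that("binomial surface fits recover the generating landscape", {
  sc <- synth_scenario(d = 300, crosses = c(F2 = 1), family = "binomial",
                       response_scale = 3, seed = 61)
  wd <- attach_fitness(generate_wild_dataset(sc, N = 800), sc)
  tr <- attr(wd, "truth")
  dat <- data.frame(h = tr$h, p12 = tr$p12,
                    fitness = wd$individuals$fitness)
  fit <- fit_surface(dat, "binomial")
  expect_setequal(fit$terms, c("p12", "h", "hh"))
  ## generating values: beta0 = 3, beta1 = 4, beta2 = 1
  ci2 <- profile_ci(fit, "beta2")
  expect_gt(1, ci2[["lower"]] - 0.1)
  expect_lt(abs(fit$betas[["beta2"]] - 1), 0.15)
  expect_lt(abs(fit$betas[["beta1"]] - 4), 1.5)
  expect_gt(fit$betas[["beta0"]], 0)
  expect_true(fit$mcfadden > 0 && fit$mcfadden < 1)
})

test_that("F2-only designs drop the hybrid-index terms", {
  sc <- synth_scenario(d = 100, crosses = c(F2 = 400),
                       family = "binomial", response_scale = 4,
                       seed = 62)
  ds <- attach_fitness(generate_cross_dataset(sc), sc)
  tr <- attr(ds, "truth")
  dat <- data.frame(h = tr$h, p12 = tr$p12,
                    fitness = ds$individuals$fitness)
  fit <- fit_surface(dat, "binomial")
  expect_true("p12" %in% fit$terms)
  expect_false("hh" %in% fit$terms)
})

test_that("a response independent of ancestry usually selects the null model", {
  picks <- integer(12)
  for (s in seq_along(picks)) {
    set.seed(s)
    n <- 300
    h <- runif(n)
    p12 <- runif(n, 0, 2 * pmin(h, 1 - h))
    dat <- data.frame(h = h, p12 = p12, fitness = rnorm(n))
    fit <- fit_surface(dat, "gaussian")
    picks[s] <- length(fit$terms)
    if (length(fit$terms) == 0) expect_true(all(is.na(fit$betas)))
  }
  ## AIC admits a spurious term with bounded probability; the null
  ## model must still be the modal choice
  expect_gte(mean(picks == 0), 0.5)
})

test_that("degenerate designs raise rank-deficiency errors", {
  dat <- data.frame(h = rep(0.5, 40), p12 = rep(1, 40),
                    fitness = rnorm(40))
  expect_error(suppressWarnings(fit_surface(dat, "gaussian")),
               "rank-deficient")
  expect_error(fit_surface(data.frame(h = runif(5), p12 = 0.1,
                                      fitness = 1:5), "gaussian"),
               "at least 10")
})

test_that("profile deviance is zero at the MLE and matches lm algebra", {
  set.seed(64)
  n <- 200
  h <- runif(n)
  p12 <- runif(n, 0, 2 * pmin(h, 1 - h))
  y <- 2 * p12 - 3 * h + 2.5 * h^2 + rnorm(n, sd = 0.3)
  dat <- data.frame(h = h, p12 = p12, fitness = y)
  fit <- fit_surface(dat, "gaussian")
  expect_setequal(fit$terms, c("p12", "h", "hh"))
  for (b in c("beta0", "beta1", "beta2")) {
    expect_equal(fgmhybrid:::profile_loglik(fit, b, fit$betas[[b]]),
                 fit$logLik, tolerance = 1e-6)
  }
  ## closed-form check for the linear component beta0 = a_p12: in a
  ## Gaussian model the profile deviance is n*log(RSS(theta)/RSS_hat);
  ## the constrained refit saves one parameter, so the Delta-AIC = 2
  ## bound sits at deviance 4, i.e. RSS(theta) = RSS_hat*exp(4/n)
  X <- cbind(1, p12, h, h^2)
  bhat <- qr.solve(X, y)
  rss_hat <- sum((y - X %*% bhat)^2)
  ## RSS with a_p12 fixed at t: regress (y - t*p12) on the rest
  rss_at <- function(t) {
    Z <- cbind(1, h, h^2)
    r <- (y - t * p12) - Z %*% qr.solve(Z, y - t * p12)
    sum(r^2)
  }
  target <- rss_hat * exp(4 / n)
  bound <- uniroot(function(t) rss_at(t) - target,
                   c(bhat[2], bhat[2] + 2), tol = 1e-8)$root
  ci <- profile_ci(fit, "beta0", tol = 1e-6)
  expect_equal(ci[["upper"]], bound, tolerance = 1e-4)
})

test_that("profiles can be one-sided when the likelihood is flat", {
  set.seed(65)
  ## tiny information about h-squared: nearly collinear design
  n <- 60
  h <- runif(n, 0.48, 0.52)
  p12 <- runif(n, 0, 0.9)
  y <- rbinom(n, 1, plogis(2 * p12 - 1))
  dat <- data.frame(h = h, p12 = p12, fitness = y)
  full <- fgmhybrid:::fit_one(y, fgmhybrid:::build_design(dat,
                              c("p12", "h", "hh")), "binomial")
  fit <- fit_surface(dat, "binomial")
  ## force the full model so beta2 is profiled despite weak signal
  if (!all(c("h", "hh") %in% fit$terms)) {
    fit$terms <- c("p12", "h", "hh")
    cf <- coef(full)
    fit$coefficients <- c(a_p12 = unname(cf["p12"]),
                          a_h = unname(cf["h"]),
                          a_hh = unname(cf["hh"]))
    fit$betas <- transform_coefficients(cf[["p12"]], cf[["h"]],
                                        cf[["hh"]])
    fit$logLik <- as.numeric(logLik(full))
    fit$model <- full
  }
  ci <- suppressWarnings(profile_ci(fit, "beta2", max_expand = 8))
  expect_true(is.infinite(ci[["lower"]]) || is.infinite(ci[["upper"]]) ||
                diff(ci) > 5)
})

test_that("hX interaction regressions select the true structure", {
  set.seed(66)
  n <- 400
  hx <- rep(c("low", "high"), each = n / 2)
  p12A <- runif(n)
  eta <- ifelse(hx == "low", -3 + 3.7 * p12A, 2.9 - 2 * p12A)
  y <- rbinom(n, 1, plogis(eta))
  res <- hx_interaction_fit(p12A, hx, y)
  expect_equal(res$best, "two_intercepts_two_slopes")
  tab <- res$table[res$table$model == "two_intercepts_two_slopes", ]
  expect_gt(tab$slope_low, 0)
  expect_lt(tab$slope_high, 0)
  ## a single common slope is preferred when the data have one
  eta1 <- ifelse(hx == "low", -1, 0.5) + 2 * p12A
  wins <- 0L
  for (r in 1:20) {
    y1 <- rbinom(n, 1, plogis(eta1))
    r1 <- hx_interaction_fit(p12A, hx, y1)
    if (r1$best == "two_intercepts_one_slope") wins <- wins + 1L
  }
  expect_gte(wins, 12L)
  ## an outcome independent of p12A keeps the two-intercept model as
  ## the modal AIC choice (spurious slopes win only at the AIC rate)
  null_wins <- 0L
  for (r in 1:20) {
    y0 <- rbinom(n, 1, 0.4)
    if (hx_interaction_fit(p12A, hx, y0)$best == "two_intercepts")
      null_wins <- null_wins + 1L
  }
  expect_gte(null_wins, 10L)
  expect_error(hx_interaction_fit(p12A, rep("low", n), rbinom(n, 1, 0.4)),
               "both hX classes")
})

test_that("the signed-rank test matches exact and reference computations", {
  w <- wilcoxon_het(rep(0.5, 10))
  expect_equal(w$p_value, 1)
  expect_true(w$degenerate)
  expect_equal(w$median, 0.5)
  ## all-positive tied shifts: exact tail is 2 * 2^-n
  w20 <- wilcoxon_het(rep(0.6, 20))
  expect_equal(w20$p_value, 2 * 2^-20)
  expect_equal(w20$n_used, 20)
  ## tie-free exact case agrees with the reference implementation
  set.seed(67)
  x <- 0.5 + round(rnorm(15, 0.05, 0.1), 7)
  ref <- wilcox.test(x, mu = 0.5, exact = TRUE)
  ours <- wilcoxon_het(x)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
  ## large-sample path agrees with the reference normal approximation
  y <- 0.5 + round(rnorm(60, 0.02, 0.1), 7)
  refn <- wilcox.test(y, mu = 0.5, exact = FALSE, correct = TRUE)
  oursn <- wilcoxon_het(y)
  expect_equal(oursn$p_value, refn$p.value, tolerance = 1e-10)
  ## type-I error is near nominal under the symmetric null
  rej <- 0L
  for (r in 1:300) {
    z <- 0.5 + rnorm(40, 0, 0.05)
    if (wilcoxon_het(z)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej, 6)   # 0.05 * 300 = 15 expected
  expect_lt(rej, 30)
})

test_that("Wald p-values behave like the normal tail and match LR asymptotics", {
  set.seed(68)
  n <- 3000
  h <- runif(n)
  p12 <- runif(n, 0, 2 * pmin(h, 1 - h))
  y <- rbinom(n, 1, plogis(0.4 * p12))
  fit <- suppressWarnings(fit_surface(
    data.frame(h = h, p12 = p12, fitness = y), "binomial"))
  ## compare against the likelihood-ratio p for the p12 term
  m_full <- glm(y ~ p12, binomial())
  m_null <- glm(y ~ 1, binomial())
  p_wald <- 2 * pnorm(-abs(summary(m_full)$coefficients["p12", 3]))
  p_lr <- anova(m_null, m_full, test = "LRT")$`Pr(>Chi)`[2]
  expect_lt(abs(log(p_wald) - log(p_lr)), 0.2)
  ## direct tail values through the package interface
  m <- glm(y ~ p12, binomial())
  expect_equal(wald_p(m, "p12"), p_wald, tolerance = 1e-12)
  expect_error(wald_p(m, "absent"), "not in fit")
})

test_that("McFadden r2 spans its range and matches hand computation", {
  set.seed(69)
  n <- 200
  h <- runif(n)
  p12 <- ifelse(runif(n) < 0.5, 0.1, 0.7)
  p12 <- pmin(p12, 2 * pmin(h, 1 - h))
  ## response depends only on a two-valued p12: group MLEs are the
  ## group rates and the log-likelihoods have closed form
  grp <- p12 > 0.4
  y <- rbinom(n, 1, ifelse(grp, 0.9, 0.2))
  fit <- fit_surface(data.frame(h = h, p12 = p12, fitness = y),
                     "binomial")
  ll_bin <- function(k, m) {
    p <- k / m
    ifelse(p %in% c(0, 1), 0, k * log(p) + (m - k) * log(1 - p))
  }
  ll0 <- ll_bin(sum(y), n)
  r2_hand <- 1 - fit$logLik / ll0
  expect_equal(fit$mcfadden, r2_hand, tolerance = 1e-9)
  expect_gt(fit$mcfadden, 0.2)
  ## the null fit itself scores zero
  y_null <- rbinom(n, 1, 0.5)
  fit0 <- fit_surface(data.frame(h = h, p12 = p12, fitness = y_null),
                      "binomial")
  if (length(fit0$terms) == 0) expect_equal(fit0$mcfadden, 0,
                                            tolerance = 1e-9)
  ## near-perfect separation approaches 1
  y_sep <- as.numeric(grp)
  fit1 <- suppressWarnings(fit_surface(
    data.frame(h = h, p12 = p12, fitness = y_sep), "binomial"))
  expect_gt(fit1$mcfadden, 0.95)
  expect_true(fit1$separation)
})

test_that("two-level ordinal fits reduce to binomial logit", {
  sc <- synth_scenario(d = 150, crosses = c(F2 = 1), family = "binomial",
                       response_scale = 3, seed = 70)
  wd <- attach_fitness(generate_wild_dataset(sc, N = 500), sc)
  tr <- attr(wd, "truth")
  dat <- data.frame(h = tr$h, p12 = tr$p12,
                    fitness = wd$individuals$fitness)
  fb <- fit_surface(dat, "binomial")
  fo <- fit_surface(dat, "ordinal")
  expect_setequal(fo$terms, fb$terms)
  expect_equal(fo$coefficients, fb$coefficients, tolerance = 1e-3)
  expect_equal(fo$logLik, fb$logLik, tolerance = 1e-5)
  ## an ordinal response with several levels fits and recovers betas
  sc3 <- synth_scenario(d = 150, crosses = c(F2 = 1), family = "ordinal",
                        response_scale = 4, cutpoints = c(-1.5, 0, 1.5),
                        seed = 71)
  wd3 <- attach_fitness(generate_wild_dataset(sc3, N = 600), sc3)
  tr3 <- attr(wd3, "truth")
  f3 <- fit_surface(data.frame(h = tr3$h, p12 = tr3$p12,
                               fitness = wd3$individuals$fitness),
                    "ordinal")
  expect_lt(abs(f3$betas[["beta2"]] - 1), 0.3)
})
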