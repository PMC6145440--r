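#' Reparameterise fitness-scale coefficients as landscape coefficients
#'
#' A GLM of a fitness proxy on \code{p12}, \code{h} and \code{h^2} with
#' fitness-scale coefficients \code{(a_p12, a_h, a_hh)} (higher linear
#' predictor = higher fitness) can be rewritten in landscape form
#' \code{y = const + beta0*(beta1*h*(1 - beta2*h) - p12)} for breakdown
#' \code{y}, with \code{beta0 = a_p12}, \code{beta1 = -a_h / beta0},
#' \code{beta2 = a_hh / (-a_h)}.  \code{beta0 > 0} means selection
#' favours heterozygosity; the geometric model predicts
#' \code{0 <= beta1 <= 4}, with \code{beta1 = 4} and \code{beta2 = 1}
#' for well-adapted parents.
#'
#' @param a_p12,a_h,a_hh fitness-scale coefficients.
#' @return named vector \code{(beta0, beta1, beta2)}; components whose
#'   denominators vanish are NA.
#' @examples
#' transform_coefficients(1, -4, 4)  # c(beta0 = 1, beta1 = 4, beta2 = 1)
#' @export
transform_coefficients <- function(a_p12, a_h = NA, a_hh = NA) {
  a_p12 <- unname(a_p12); a_h <- unname(a_h); a_hh <- unname(a_hh)
  beta0 <- a_p12
  beta1 <- if (!is.na(a_h) && is.finite(beta0) && beta0 != 0)
    -a_h / beta0 else NA_real_
  beta2 <- if (!is.na(a_hh) && !is.na(a_h) && a_h != 0)
    a_hh / (-a_h) else NA_real_
  c(beta0 = beta0, beta1 = beta1, beta2 = beta2)
}

#' @rdname transform_coefficients
#' @param beta0,beta1,beta2 landscape-scale coefficients.
#' @return \code{inverse_transform_coefficients}: named vector
#'   \code{(a_p12, a_h, a_hh)}.
#' @export
inverse_transform_coefficients <- function(beta0, beta1 = NA, beta2 = NA) {
  beta0 <- unname(beta0); beta1 <- unname(beta1); beta2 <- unname(beta2)
  a_p12 <- beta0
  a_h <- if (!is.na(beta1)) -beta1 * beta0 else NA_real_
  a_hh <- if (!is.na(beta2) && !is.na(a_h)) -a_h * beta2 else NA_real_
  c(a_p12 = a_p12, a_h = a_h, a_hh = a_hh)
}

surface_term_sets <- function() {
  list(character(0), "p12", "h", c("p12", "h"), c("h", "hh"),
       c("p12", "h", "hh"))
}

build_design <- function(data, terms) {
  X <- data.frame(row.names = seq_len(nrow(data)))
  if ("p12" %in% terms) X$p12 <- data$p12
  if ("h" %in% terms) X$h <- data$h
  if ("hh" %in% terms) X$hh <- data$h^2
  X
}

fit_one <- function(y, X, family, offset = NULL) {
  df <- cbind(data.frame(.y = y), X)
  rhs <- if (ncol(X)) paste(colnames(X), collapse = " + ") else "1"
  if (!is.null(offset)) {
    df$.off <- offset
    rhs <- paste(rhs, "+ offset(.off)")
  }
  fm <- stats::as.formula(paste(".y ~", rhs))
  if (family == "ordinal") {
    df$.y <- factor(df$.y, ordered = TRUE)
    if (nlevels(df$.y) < 2) stop("ordinal response needs >= 2 levels")
    if (nlevels(df$.y) == 2) {
      ## one cutpoint: the proportional-odds model is logistic
      ## regression on the upper level
      df$.y <- as.numeric(df$.y == levels(df$.y)[2])
      m <- stats::glm(fm, data = df, family = stats::binomial("logit"))
      m$zeta <- c(`1|2` = -unname(stats::coef(m)[["(Intercept)"]]))
      return(m)
    }
    MASS::polr(fm, data = df, Hess = TRUE)
  } else {
    fam <- if (family == "binomial") stats::binomial("logit")
           else stats::gaussian()
    stats::glm(fm, data = df, family = fam)
  }
}

#' Fit the hybrid fitness surface
#'
#' Regresses a fitness proxy on interpopulation heterozygosity and the
#' hybrid index: all subsets of \code{\{p12, h, h^2\}} are fitted
#' (\code{h^2} never enters without \code{h}), the minimum-AIC model is
#' selected (ties within 1e-6 resolved toward fewer parameters), and
#' its coefficients are reported on the fitness scale together with the
#' landscape reparameterisation \code{(beta0, beta1, beta2)} where the
#' required terms were selected.
#'
#' @param data data frame with columns \code{h}, \code{p12} and the
#'   response.
#' @param family \code{"gaussian"}, \code{"binomial"} (logit link) or
#'   \code{"ordinal"} (proportional-odds logistic, via
#'   \code{MASS::polr}).
#' @param response name of the response column (higher = fitter;
#'   binary 0/1 for binomial, an ordered score for ordinal).  A
#'   monotone transform already applied to a Gaussian response can be
#'   recorded via \code{transform_label}.
#' @param transform_label optional note stored in the result.
#' @return object of class \code{"surface_fit"}: selected terms,
#'   fitness-scale coefficients, \code{betas}, AIC table, log
#'   likelihood, McFadden pseudo-r2 (non-Gaussian), and the underlying
#'   model object.
#' @export
fit_surface <- function(data, family = c("gaussian", "binomial", "ordinal"),
                        response = "fitness", transform_label = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), all(c("h", "p12") %in% names(data)))
  if (!response %in% names(data))
    stop(sprintf("response column '%s' not found", response))
  keep <- is.finite(data$h) & is.finite(data$p12) &
    !is.na(data[[response]])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 10)
    stop("surface fitting needs at least 10 complete individuals")
  y <- data[[response]]
  if (family == "binomial" && !all(y %in% 0:1))
    stop("binomial family requires a 0/1 response")
  sets <- surface_term_sets()
  fits <- vector("list", length(sets))
  aics <- numeric(length(sets))
  npar <- integer(length(sets))
  for (i in seq_along(sets)) {
    X <- build_design(data, sets[[i]])
    ## rank check: constant or collinear columns break the fit
    if (ncol(X)) {
      M <- cbind(1, as.matrix(X))
      qrM <- qr(M)
      if (qrM$rank < ncol(M)) {
        dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
        fits[[i]] <- NULL
        aics[i] <- NA
        npar[i] <- NA
        attr(fits, "rank_deficient") <-
          c(attr(fits, "rank_deficient"), dropped)
        next
      }
    }
    m <- fit_one(y, X, family)
    fits[[i]] <- m
    aics[i] <- stats::AIC(m)
    npar[i] <- length(sets[[i]])
  }
  if (anyNA(aics)) {
    bad <- unique(attr(fits, "rank_deficient"))
    stop("rank-deficient design: term(s) ",
         paste(bad, collapse = ", "),
         " are collinear (degenerate sampling of the surface, ",
         "e.g. a single cross class)")
  }
  ok <- which(!is.na(aics))
  ## minimum AIC with ties (within 1e-6) resolved toward fewer terms
  amin <- min(aics[ok])
  cand <- ok[aics[ok] <= amin + 1e-6]
  best <- cand[which.min(npar[cand])]
  terms <- sets[[best]]
  m <- fits[[best]]
  cf <- stats::coef(m)
  a_p12 <- if ("p12" %in% terms) unname(cf[["p12"]]) else NA_real_
  a_h <- if ("h" %in% terms) unname(cf[["h"]]) else NA_real_
  a_hh <- if ("hh" %in% terms) unname(cf[["hh"]]) else NA_real_
  betas <- transform_coefficients(a_p12, a_h, a_hh)
  separation <- FALSE
  if (family == "binomial") {
    eta <- stats::predict(m, type = "link")
    separation <- any(abs(eta) > 12) ||
      any(abs(cf) > 50, na.rm = TRUE)
    if (separation)
      warning("possible complete or quasi-complete separation in the ",
              "binomial fit; coefficients may be unstable")
  }
  ll <- as.numeric(stats::logLik(m))
  aic_tab <- data.frame(
    terms = vapply(sets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept)",
      character(1)),
    n_terms = vapply(sets, length, integer(1)),
    aic = aics)
  res <- structure(list(
    family = family, terms = terms,
    coefficients = c(a_p12 = a_p12, a_h = a_h, a_hh = a_hh),
    intercept = if (family == "ordinal") NA_real_ else
      unname(cf[["(Intercept)"]]),
    cutpoints = if (family == "ordinal") m$zeta else NULL,
    betas = betas, logLik = ll, aic = aics[best], aic_table = aic_tab,
    n = nrow(data), model = m,
    data = data.frame(h = data$h, p12 = data$p12, y = y),
    separation = separation, transform_label = transform_label),
    class = "surface_fit")
  if (family != "gaussian") res$mcfadden <- mcfadden_r2(res)
  res
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("Hybrid fitness surface fit (%s family, n = %d)\n",
              x$family, x$n))
  cat("  selected terms:",
      if (length(x$terms)) paste(x$terms, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("  AIC = %.2f, logLik = %.2f%s\n", x$aic, x$logLik,
              if (!is.null(x$mcfadden))
                sprintf(", McFadden r2 = %.3f", x$mcfadden) else ""))
  b <- x$betas
  cat(sprintf("  beta0 = %s, beta1 = %s, beta2 = %s\n",
              format(b[1], digits = 4), format(b[2], digits = 4),
              format(b[3], digits = 4)))
  invisible(x)
}

## Constrained refit with one landscape component fixed; returns the
## log-likelihood.  Fixing beta0 turns the p12 term into an offset;
## fixing beta1 or beta2 merges two columns into one induced covariate,
## so every profile point is still a plain GLM fit.
profile_loglik <- function(fit, component, value) {
  d <- fit$data
  terms <- fit$terms
  y <- d$y
  if (component == "beta0") {
    X <- data.frame(row.names = seq_len(nrow(d)))
    if ("h" %in% terms) X$h <- d$h
    if ("hh" %in% terms) X$hh <- d$h^2
    m <- fit_one(y, X, fit$family, offset = value * d$p12)
  } else if (component == "beta1") {
    X <- data.frame(pv = d$p12 - value * d$h)
    if ("hh" %in% terms) X$hh <- d$h^2
    m <- fit_one(y, X, fit$family)
  } else {  # beta2
    X <- data.frame(p12 = d$p12, hv = d$h - value * d$h^2)
    m <- fit_one(y, X, fit$family)
  }
  as.numeric(stats::logLik(m))
}

#' Profile confidence interval from a Delta-AIC threshold
#'
#' Confidence bounds on a landscape coefficient are the values at which
#' the constrained refit (the model with that coefficient held fixed,
#' which estimates one parameter fewer) has an AIC \code{delta_aic}
#' units above the full model's.  Because the constrained model saves
#' one parameter, its AIC matches the optimum when the deviance rises
#' by 2, and the default \code{delta_aic = 2} bound sits at a deviance
#' rise of 4 -- approximately a 95 percent interval.  Unbounded
#' profiles yield one-sided intervals with an explicit infinity.
#'
#' @param fit a \code{\link{fit_surface}} result.
#' @param component \code{"beta0"}, \code{"beta1"} or \code{"beta2"}
#'   (the required terms must be in the selected model).
#' @param delta_aic AIC increase defining the bounds.
#' @param tol bisection tolerance on the component.
#' @param max_expand bracketing expansions before declaring the profile
#'   unbounded.
#' @return numeric \code{c(lower, upper)}.
#' @export
profile_ci <- function(fit, component = c("beta0", "beta1", "beta2"),
                       delta_aic = 2, tol = 1e-4, max_expand = 40) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "surface_fit"))
  need <- switch(component, beta0 = "p12", beta1 = c("p12", "h"),
                 beta2 = c("p12", "h", "hh"))
  if (!all(need %in% fit$terms))
    stop(sprintf("component %s is not identified by the selected model",
                 component))
  mle <- unname(fit$betas[[component]])
  if (!is.finite(mle)) stop("component estimate is not finite")
  ll_hat <- fit$logLik
  dev <- function(x) 2 * (ll_hat - profile_loglik(fit, component, x))
  ## dev(mle) = 0; the constrained refit drops one parameter, so its
  ## AIC exceeds the full model's by delta_aic when dev = delta_aic + 2
  thr <- delta_aic + 2
  one_side <- function(dir) {
    step <- 0.25 * max(1, abs(mle))
    lo <- mle
    for (i in seq_len(max_expand)) {
      hi <- mle + dir * step
      if (dev(hi) >= thr) {
        r <- stats::uniroot(function(x) dev(x) - thr,
                            lower = min(lo, hi), upper = max(lo, hi),
                            tol = tol)
        return(r$root)
      }
      lo <- hi
      step <- step * 2
    }
    dir * Inf
  }
  c(lower = one_side(-1), upper = one_side(1))
}

#' Nested regressions of a binary outcome on heterozygosity by X class
#'
#' Fits three nested binomial-logit models of an outcome (e.g. male
#' sterility) on autosomal heterozygosity \code{p12A}, allowing the
#' intercept and then the slope to differ between low- and high-hX
#' individuals: (1) two intercepts; (2) two intercepts + one common
#' slope; (3) two intercepts + two slopes.  The preferred model is the
#' AIC minimum.
#'
#' @param p12A autosomal heterozygosity values.
#' @param hX_class factor or character, \code{"low"} / \code{"high"}.
#' @param outcome binary 0/1 outcome.
#' @return object of class \code{"hx_fit"}: the three fits, a summary
#'   table of coefficients and AICs, and the index of the best model.
#' @export
hx_interaction_fit <- function(p12A, hX_class, outcome) {
  hX_class <- factor(as.character(hX_class), levels = c("low", "high"))
  if (any(is.na(hX_class)))
    stop("hX_class must be 'low' or 'high'")
  if (!all(outcome %in% 0:1)) stop("outcome must be binary 0/1")
  if (any(table(hX_class) == 0))
    stop("both hX classes need at least one individual")
  d <- data.frame(y = outcome, hX = hX_class, p12A = p12A)
  m1 <- stats::glm(y ~ 0 + hX, stats::binomial(), data = d)
  m2 <- stats::glm(y ~ 0 + hX + p12A, stats::binomial(), data = d)
  m3 <- stats::glm(y ~ 0 + hX + hX:p12A, stats::binomial(), data = d)
  fits <- list(two_intercepts = m1,
               two_intercepts_one_slope = m2,
               two_intercepts_two_slopes = m3)
  aic <- vapply(fits, stats::AIC, numeric(1))
  co <- function(m, nm) if (nm %in% names(stats::coef(m)))
    unname(stats::coef(m)[[nm]]) else NA_real_
  tab <- data.frame(
    model = names(fits),
    intercept_low = vapply(fits, co, numeric(1), nm = "hXlow"),
    intercept_high = vapply(fits, co, numeric(1), nm = "hXhigh"),
    slope = vapply(fits, co, numeric(1), nm = "p12A"),
    slope_low = vapply(fits, co, numeric(1), nm = "hXlow:p12A"),
    slope_high = vapply(fits, co, numeric(1), nm = "hXhigh:p12A"),
    aic = aic)
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab,
                 best = names(fits)[which.min(aic)]),
            class = "hx_fit")
}

#' @export
print.hx_fit <- function(x, ...) {
  cat("Nested hX x heterozygosity regressions (binomial logit)\n")
  print(x$table, digits = 4)
  cat("preferred model:", x$best, "\n")
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test for median heterozygosity
#'
#' Tests whether heterozygosities are symmetrically distributed about a
#' null median (0.5, the Mendelian expectation for F2 and first
#' backcrosses); an upward shift indicates selection for heterozygosity
#' among survivors.  Values equal to the null median are dropped
#' (signed-rank convention).  For up to 25 non-zero differences without
#' requiring integer ranks the two-sided p-value is exact, computed by
#' convolution over the 2^n sign assignments (midranks for ties);
#' otherwise a normal approximation with midranks, tie correction and
#' continuity correction is used.
#'
#' @param p12 heterozygosity values.
#' @param null_median null value (default 0.5).
#' @return list with \code{median}, \code{p_value}, \code{statistic}
#'   (positive-rank sum), \code{n_used}, \code{method} and a
#'   \code{degenerate} flag (all values at the null median).
#' @export
wilcoxon_het <- function(p12, null_median = 0.5) {
  stopifnot(length(p12) >= 1)
  x <- p12[!is.na(p12)]
  d <- x - null_median
  d <- d[d != 0]
  n <- length(d)
  med <- stats::median(x)
  if (n == 0)
    return(list(median = med, p_value = 1, statistic = 0, n_used = 0,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    ## exact: distribution of the positive-rank sum over sign flips;
    ## doubled ranks keep midranks integral
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    cnt <- numeric(tot + 1)  # index = sum + 1
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), cnt[seq_len(tot + 1 - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(probs[seq_len(w2 + 1)])
    p_hi <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact (sign-flip convolution)"
  } else {
    E <- n * (n + 1) / 4
    ties <- table(r)
    V <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - E) * 0.5
    z <- (W - E - cc) / sqrt(V)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie and continuity correction"
  }
  list(median = med, p_value = p, statistic = W, n_used = n,
       method = method, degenerate = FALSE)
}

#' Wald p-value for a fitted term
#'
#' Two-sided p-value comparing the coefficient's t-value to the normal
#' distribution.
#'
#' @param fit a \code{\link{fit_surface}} result, or any model with a
#'   \code{summary()} coefficient table.
#' @param term coefficient name (\code{"p12"}, \code{"h"}, \code{"hh"},
#'   ...).
#' @return the p-value.
#' @export
wald_p <- function(fit, term) {
  m <- if (inherits(fit, "surface_fit")) fit$model else fit
  if (inherits(m, "polr")) {
    sm <- summary(m)$coefficients
  } else {
    sm <- summary(m)$coefficients
  }
  if (!term %in% rownames(sm)) stop(sprintf("term '%s' not in fit", term))
  est <- sm[term, 1]
  se <- sm[term, 2]
  if (se == 0) stop("zero standard error; Wald p undefined")
  2 * stats::pnorm(-abs(est / se))
}

#' McFadden pseudo r-squared
#'
#' One minus the ratio of the fitted to the null (intercept- or
#' cutpoint-only) model log-likelihoods; defined for non-Gaussian
#' families.
#'
#' @param fit a \code{\link{fit_surface}} result.
#' @return value in \[0, 1).
#' @export
mcfadden_r2 <- function(fit) {
  stopifnot(inherits(fit, "surface_fit"))
  if (fit$family == "gaussian")
    stop("McFadden r2 is defined for non-Gaussian families")
  null <- fit_one(fit$data$y,
                  data.frame(row.names = seq_len(nrow(fit$data))),
                  fit$family)
  ll0 <- as.numeric(stats::logLik(null))
  if (ll0 == 0) stop("null log-likelihood is zero; r2 undefined")
  1 - fit$logLik / ll0
}
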