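#' Trait space for the geometric model
#'
#' Defines \code{n} quantitative traits under independent optimising
#' selection: trait \code{i} has selection strength \code{lambda[i]} and
#' heterozygous per-trait mutational variance \code{v[i]} (the expected
#' variance a fixed substitution contributes to the trait in heterozygous
#' state).  Substitution effects are additive on each trait, so a
#' homozygous effect is twice the heterozygous effect.
#'
#' @param n number of traits.
#' @param lambda selection strengths (recycled to length \code{n}).
#' @param v heterozygous mutational variances (recycled).
#' @param optimum trait optimum (recycled; default the origin).
#' @return object of class \code{"fgm_traits"}.
#' @export
trait_model <- function(n, lambda = 1, v = 0.01, optimum = 0) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  lambda <- rep_len(as.numeric(lambda), n)
  v <- rep_len(as.numeric(v), n)
  optimum <- rep_len(as.numeric(optimum), n)
  if (any(lambda <= 0)) stop("selection strengths lambda must be positive")
  if (any(v <= 0)) stop("mutational variances v must be positive")
  structure(list(n = n, lambda = lambda, v = v, optimum = optimum),
            class = "fgm_traits")
}

#' Draw the substitutions separating two diverged lineages
#'
#' Samples the heterozygous effect vectors of the \code{d} substitutions
#' (split between the two lineages), under one of three divergence
#' modes:
#' \describe{
#'   \item{\code{"random_walk"}}{effects are free draws, so each parent
#'     performs an unconstrained random walk away from the optimum; the
#'     expected parental breakdown is \code{E(fP) = 2}.}
#'   \item{\code{"coadapted"}}{each lineage's effects are mean-centred so
#'     they sum to zero: both parents sit exactly at the optimum
#'     (\code{fP1 = fP2 = 0}), a discrete analogue of conditioning the
#'     walk to return (a Brownian bridge).}
#'   \item{\code{"asymmetric"}}{lineage 1 is centred (\code{fP1 = 0});
#'     lineage 2 is centred and then given a net displacement scaled so
#'     that its parental breakdown equals \code{fP2_target} exactly.}
#' }
#'
#' @param traits \code{\link{trait_model}}.
#' @param d total number of substitutions across both lineages.
#' @param mode divergence mode.
#' @param fP2_target target parental breakdown for lineage 2
#'   (asymmetric mode only).
#' @param d1 substitutions in lineage 1 (default an equal split; an odd
#'   \code{d} requires an explicit \code{d1}).
#' @param seed optional integer seed.
#' @return object of class \code{"fgm_divergence"}: the trait model, the
#'   lineage assignment and the \code{d x n} matrix of heterozygous
#'   effects, plus realised parental breakdown scores \code{fP1},
#'   \code{fP2}.
#' @export
draw_substitutions <- function(traits, d,
                               mode = c("coadapted", "random_walk",
                                        "asymmetric"),
                               fP2_target = NULL, d1 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(traits, "fgm_traits"), is.numeric(d), length(d) == 1,
            d >= 2)
  d <- as.integer(d)
  if (is.null(d1)) {
    if (d %% 2 != 0)
      stop("d is odd: supply an explicit lineage split d1")
    d1 <- d %/% 2
  }
  d1 <- as.integer(d1)
  if (d1 < 1 || d1 >= d) stop("d1 must satisfy 1 <= d1 < d")
  d2 <- d - d1
  if (mode == "asymmetric" && (is.null(fP2_target) || fP2_target < 0))
    stop("asymmetric mode requires a non-negative fP2_target")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- traits$n
  eff <- matrix(stats::rnorm(d * n, sd = rep(sqrt(traits$v), each = d)),
                d, n)
  lineage <- rep(c(1L, 2L), c(d1, d2))
  center <- function(m) sweep(m, 2, colMeans(m))
  if (mode == "coadapted") {
    eff[lineage == 1L, ] <- center(eff[lineage == 1L, , drop = FALSE])
    eff[lineage == 2L, ] <- center(eff[lineage == 2L, , drop = FALSE])
  } else if (mode == "asymmetric") {
    eff[lineage == 1L, ] <- center(eff[lineage == 1L, , drop = FALSE])
    e2 <- center(eff[lineage == 2L, , drop = FALSE])
    ## displace lineage 2 along trait 1 so that the homozygous parental
    ## phenotype 2 * colSums(e2) has breakdown fP2_target * E(S-dagger)
    target_S <- fP2_target * d * sum(traits$lambda * traits$v)
    z1 <- sqrt(target_S / traits$lambda[1])
    e2[, 1] <- e2[, 1] + (z1 / 2) / d2
    eff[lineage == 2L, ] <- e2
  }
  div <- structure(list(traits = traits, d = d, d1 = d1, d2 = d2,
                        lineage = lineage, effects = eff, mode = mode),
                   class = "fgm_divergence")
  div$fP1 <- breakdown_score(parent_dosage(div, "P1"), div) /
    reference_breakdown(div)
  div$fP2 <- breakdown_score(parent_dosage(div, "P2"), div) /
    reference_breakdown(div)
  div
}

#' @export
print.fgm_divergence <- function(x, ...) {
  cat(sprintf(
    "Divergence model: d = %d substitutions (%d + %d), n = %d traits, %s\n",
    x$d, x$d1, x$d2, x$traits$n, x$mode))
  cat(sprintf("  realised fP1 = %.4g, fP2 = %.4g\n", x$fP1, x$fP2))
  invisible(x)
}

## P2-allele dosage vectors of the pure parental genotypes.
parent_dosage <- function(divergence, line = c("P1", "P2")) {
  line <- match.arg(line)
  if (line == "P1") rep(0L, divergence$d) else rep(2L, divergence$d)
}

#' Breakdown score of a hybrid genotype
#'
#' A genotype is a vector of P2-allele dosages (0, 1, 2) over the
#' \code{d} divergent sites.  Its phenotype is the sum of the carried
#' substitution effects (heterozygous effects counted once, homozygous
#' twice, relative to the lineage in which each substitution arose), and
#' its breakdown score is \code{S = sum(lambda * (z - optimum)^2)}.
#'
#' @param dosage integer vector (length \code{d}) or N x d matrix of
#'   P2-allele dosages.
#' @param divergence \code{\link{draw_substitutions}} output.
#' @return numeric breakdown score(s), one per genotype.
#' @export
breakdown_score <- function(dosage, divergence) {
  stopifnot(inherits(divergence, "fgm_divergence"))
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  if (ncol(dosage) != divergence$d)
    stop("genotype length does not match the divergence model's d")
  if (any(!dosage %in% 0:2))
    stop("dosages must be 0, 1 or 2 copies of the P2 allele")
  ## derived-allele copies: at lineage-1 sites the P1 allele is derived
  copies <- dosage
  l1 <- divergence$lineage == 1L
  copies[, l1] <- 2L - copies[, l1, drop = FALSE]
  z <- copies %*% divergence$effects
  z <- sweep(z, 2, divergence$traits$optimum)
  as.numeric(z^2 %*% divergence$traits$lambda)
}

#' Expected breakdown of the reference (worst) class
#'
#' The normaliser of the scaled breakdown \code{f = S / E(S-dagger)}:
#' the expected breakdown score of the worst hybrid class formed between
#' optimal parents, \code{E(S-dagger) = d * sum(lambda * v)}.
#'
#' @param divergence \code{\link{draw_substitutions}} output, or a
#'   \code{\link{trait_model}} together with \code{d}.
#' @param d number of divergent sites (when \code{divergence} is a trait
#'   model).
#' @return a positive scalar.
#' @export
reference_breakdown <- function(divergence, d = NULL) {
  if (inherits(divergence, "fgm_divergence")) {
    tr <- divergence$traits
    d <- divergence$d
  } else if (inherits(divergence, "fgm_traits")) {
    tr <- divergence
    if (is.null(d)) stop("supply d with a bare trait model")
  } else stop("supply an fgm_divergence or fgm_traits object")
  d * sum(tr$lambda * tr$v)
}

## Deterministic integer site counts for a target class (h, p12):
## n12 het sites, then n2 P2-homozygous sites chosen to match h.
## Rounding is round-half-up (floor(x + 0.5)), applied to p12 first so
## that h is matched as closely as the het count allows -- h is never
## silently truncated.
class_site_counts <- function(h, p12, d) {
  n12 <- as.integer(floor(p12 * d + 0.5))
  n12 <- max(0L, min(d, n12))
  n2 <- as.integer(floor(h * d - n12 / 2 + 0.5))
  n2 <- max(0L, min(d - n12, n2))
  c(n1 = d - n12 - n2, n2 = n2, n12 = n12)
}

#' Monte Carlo breakdown of a fixed ancestry class
#'
#' Draws genotypes with exact integer site counts matching the class
#' \code{(h, p12)} (heterozygous and homozygous sites placed uniformly at
#' random among the \code{d} sites) and returns the Monte Carlo mean and
#' standard error of the scaled breakdown \code{f = S / E(S-dagger)}.
#'
#' @param divergence \code{\link{draw_substitutions}} output.
#' @param h,p12 target ancestry coordinates (attainable).
#' @param reps number of genotype draws.
#' @param seed optional integer seed.
#' @return list with \code{mean}, \code{se}, \code{values}, and the
#'   integer site counts used.
#' @export
simulate_class <- function(divergence, h, p12, reps = 1000, seed = NULL) {
  stopifnot(inherits(divergence, "fgm_divergence"))
  fgm_coords(h, p12)  # validates attainability
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  d <- divergence$d
  cnt <- class_site_counts(h, p12, d)
  ES <- reference_breakdown(divergence)
  base <- rep.int(c(0L, 2L, 1L), cnt)
  dosage <- matrix(0L, reps, d)
  for (r in seq_len(reps)) dosage[r, ] <- base[sample.int(d)]
  f <- breakdown_score(dosage, divergence) / ES
  list(mean = mean(f), se = stats::sd(f) / sqrt(length(f)), values = f,
       counts = cnt)
}

#' Simulate hybrid individuals of a cross in the geometric model
#'
#' Combines per-site Mendelian segregation (free recombination) with the
#' divergence model's substitution effects: returns each individual's
#' ancestry coordinates, breakdown score \code{S} and scaled breakdown
#' \code{f}.
#'
#' @param divergence \code{\link{draw_substitutions}} output.
#' @param cross preset label or \code{\link{cross_spec}}.
#' @param N number of individuals.
#' @param seed optional integer seed.
#' @return data frame with columns \code{h}, \code{p12}, \code{S},
#'   \code{f}; the dosage matrix is attached as attribute
#'   \code{"dosage"}.
#' @export
simulate_cross <- function(divergence, cross, N, seed = NULL) {
  stopifnot(inherits(divergence, "fgm_divergence"))
  sim <- simulate_cross_coords(cross, N = N, d = divergence$d, seed = seed)
  dosage <- attr(sim, "dosage")
  S <- breakdown_score(dosage, divergence)
  out <- data.frame(h = sim$h, p12 = sim$p12, S = S,
                    f = S / reference_breakdown(divergence))
  attr(out, "dosage") <- dosage
  out
}

#' Validate the bridge approximation against simulated classes
#'
#' For each point of a grid of ancestry classes, compares the Monte
#' Carlo mean of the scaled breakdown \code{f} (over genotype draws, and
#' optionally over replicate divergence histories) with the closed-form
#' landscape prediction evaluated at the replicates' mean realised
#' \code{(fP1, fP2)}.
#'
#' @param traits \code{\link{trait_model}}.
#' @param d number of substitutions.
#' @param mode divergence mode (see \code{\link{draw_substitutions}}).
#' @param grid data frame with columns \code{h}, \code{p12}.
#' @param reps genotype draws per grid point and divergence replicate.
#' @param div_reps replicate divergence histories.  With
#'   \code{div_reps > 1} the standard error is taken across replicate
#'   class means, which also captures the genuine between-history
#'   variation of the realised substitution effects; the closed-form
#'   prediction holds in expectation over histories, so several
#'   replicates are recommended for calibrated z-scores.
#' @param fP2_target passed to \code{\link{draw_substitutions}}.
#' @param seed optional integer seed.
#' @return data frame with per-point simulated mean, standard error,
#'   analytic prediction and absolute z-score.
#' @export
bridge_validation_grid <- function(traits, d, mode = "coadapted",
                                   grid = NULL, reps = 1000, div_reps = 6,
                                   fP2_target = NULL, seed = NULL) {
  if (is.null(grid)) {
    grid <- landscape_grid(resolution = 5)[, c("h", "p12")]
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  npt <- nrow(grid)
  rep_means <- matrix(0, div_reps, npt)
  within_var <- matrix(0, div_reps, npt)
  fP <- matrix(0, div_reps, 2)
  for (r in seq_len(div_reps)) {
    div <- draw_substitutions(traits, d, mode = mode,
                              fP2_target = fP2_target)
    fP[r, ] <- c(div$fP1, div$fP2)
    for (i in seq_len(npt)) {
      cl <- simulate_class(div, grid$h[i], grid$p12[i], reps = reps)
      rep_means[r, i] <- cl$mean
      within_var[r, i] <- cl$se^2
    }
  }
  mean_f <- colMeans(rep_means)
  if (div_reps > 1) {
    se_f <- sqrt(apply(rep_means, 2, stats::var) / div_reps)
    ## guard against degenerate classes (e.g. the deterministic F1)
    se_floor <- sqrt(colMeans(within_var) / div_reps)
    se_f <- pmax(se_f, se_floor)
  } else {
    se_f <- sqrt(within_var[1, ])
  }
  params <- landscape_params(mean(fP[, 1]), mean(fP[, 2]))
  pred <- expected_breakdown(fgm_coords(grid$h, grid$p12,
                                        validate = FALSE),
                             params, validate = FALSE)
  ## differences below numerical noise count as exact agreement (the
  ## deterministic classes have breakdown 0 up to rounding error)
  dev <- abs(mean_f - pred)
  z <- ifelse(dev < 1e-9, 0, ifelse(se_f > 0, dev / se_f, Inf))
  data.frame(h = grid$h, p12 = grid$p12, sim_mean = mean_f, sim_se = se_f,
             prediction = pred, abs_z = z)
}
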