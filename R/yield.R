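#' Excess yield of a cross, scaled by the excess yield of the F1
#'
#' A classical fitness proxy for crosses of inbred lines is the excess
#' yield \code{(w - wP) / (wF1 - wP)}: the gain of the cross over the
#' parental lines, relative to the gain of the F1.  To first order
#' (Taylor expansion of the log-fitness map) this equals
#' \deqn{(f_P^{\alpha/2} - E[f^{\alpha/2}]) /
#'       (f_P^{\alpha/2} - f_{F1}^{\alpha/2}),}
#' where \code{fP} is the common breakdown of the (equally maladapted)
#' parental lines and \code{fF1 = fP/2} is the expected F1 breakdown.
#' In the single-locus (Wright) limit \code{fP = 2, alpha = 2} the ratio
#' collapses to the cross's expected heterozygosity \code{p12}, which is
#' the classical prediction of 0.5 for the F2.
#'
#' The expectation over the within-cross distribution of \code{(h, p12)}
#' is taken by Monte Carlo over simulated genotypes
#' (\code{mode = "montecarlo"}, the default), or the class's Mendelian
#' expected coordinates are plugged in directly (\code{mode =
#' "analytic"}, which ignores within-cross variance in \code{f}).
#'
#' @param cross preset label or \code{\link{cross_spec}}; alternatively a
#'   \code{\link{fgm_coords}} object giving a sample of within-cross
#'   coordinates over which to average.
#' @param fP common parental breakdown score (\code{fP1 = fP2 = fP}).
#' @param map \code{\link{fitness_map}} supplying \code{alpha} (the scale
#'   \code{k} cancels from the first-order ratio).
#' @param mode \code{"montecarlo"} or \code{"analytic"}.
#' @param reps Monte Carlo sample size.
#' @param d number of divergent sites used in Monte Carlo genotypes.
#' @param seed optional integer seed.
#' @return the scaled excess yield (dimensionless).
#' @examples
#' excess_yield_ratio("F2", fP = 2, map = fitness_map(alpha = 2),
#'                    mode = "analytic")   # 0.5
#' @export
excess_yield_ratio <- function(cross, fP = 2, map = fitness_map(),
                               mode = c("montecarlo", "analytic"),
                               reps = 1e4, d = 100, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(fP), length(fP) == 1, fP >= 0)
  params <- landscape_params(fP, fP)
  a2 <- map$alpha / 2
  fF1 <- fP / 2  # expected breakdown of the F1 at (h, p12) = (1/2, 1)
  denom <- fP^a2 - fF1^a2
  if (abs(denom) < 1e-12)
    stop("excess yield undefined: parental and F1 expected fitness ",
         "coincide (fP = 0)")
  if (inherits(cross, "fgm_coords")) {
    f <- pmax(expected_breakdown(cross, params), 0)
    mean_fa <- mean(f^a2)
  } else if (mode == "analytic") {
    co <- expected_cross_coords(cross)
    mean_fa <- max(expected_breakdown(co, params), 0)^a2
  } else {
    sim <- simulate_cross_coords(cross, N = reps, d = d, seed = seed)
    f <- pmax(expected_breakdown(fgm_coords(sim$h, sim$p12,
                                            validate = FALSE),
                                 params, validate = FALSE), 0)
    mean_fa <- mean(f^a2)
  }
  (fP^a2 - mean_fa) / denom
}
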