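#' Landscape parameters: parental breakdown and derived coefficients
#'
#' The expected-breakdown landscape is parameterised by the scaled
#' breakdown scores of the two parental lines, \code{fP1} and \code{fP2}
#' (zero for optimally adapted parents; 2 is the expected value when all
#' divergence is maladaptive with no coadaptation).  The derived
#' coefficients are \code{beta1 = 4 - 2*fP1} and
#' \code{beta2 = (4 - fP1 - fP2) / (4 - 2*fP1)}; \code{beta2} is
#' undefined at \code{fP1 = 2} (reported as \code{NA}), but the landscape
#' itself is evaluated in expanded polynomial form and remains finite
#' there.
#'
#' @param fP1,fP2 non-negative parental breakdown scores.
#' @return an object of class \code{"fgm_landscape"} with elements
#'   \code{fP1}, \code{fP2}, \code{beta1}, \code{beta2}.
#' @examples
#' landscape_params(0, 0)     # optimal parents: beta1 = 4, beta2 = 1
#' landscape_params(2, 2)     # Wright limit: beta2 undefined
#' @export
landscape_params <- function(fP1 = 0, fP2 = 0) {
  stopifnot(length(fP1) == 1, length(fP2) == 1, is.finite(fP1),
            is.finite(fP2))
  if (fP1 < 0 || fP2 < 0)
    stop("parental breakdown scores fP1, fP2 must be non-negative")
  beta1 <- 4 - 2 * fP1
  beta2 <- if (fP1 == 2) NA_real_ else (4 - fP1 - fP2) / (4 - 2 * fP1)
  structure(list(fP1 = fP1, fP2 = fP2, beta1 = beta1, beta2 = beta2),
            class = "fgm_landscape")
}

#' @export
print.fgm_landscape <- function(x, ...) {
  cat("Hybrid breakdown landscape parameters\n")
  cat(sprintf("  fP1 = %g, fP2 = %g\n", x$fP1, x$fP2))
  cat(sprintf("  beta1 = %g, beta2 = %s\n", x$beta1,
              if (is.na(x$beta2)) "undefined (fP1 = 2)" else
                format(x$beta2)))
  invisible(x)
}

as_landscape <- function(x) {
  if (inherits(x, "fgm_landscape")) return(x)
  if (is.list(x) && all(c("fP1", "fP2") %in% names(x)))
    return(landscape_params(x$fP1, x$fP2))
  stop("supply landscape_params()")
}

#' Map from breakdown score to relative fitness
#'
#' Relative fitness declines with breakdown as
#' \code{w = exp(-k * f^(alpha/2))}, where \code{alpha} tunes fitness
#' dominance/epistasis and \code{k} sets the overall strength of
#' selection.  The default (\code{alpha = 2}, \code{k = 1}) makes log
#' fitness proportional to breakdown.  The named preset \code{"fig4"}
#' (\code{alpha = 4}, \code{k = 6}, i.e. \code{w = exp(-6 f^2)}) is the
#' strongly epistatic map used for cricket-style cross predictions; its
#' reading of the published plotting formula is interpretation-dependent
#' and it is provided as a convenience only.
#'
#' @param alpha positive exponent, or the string \code{"fig4"}.
#' @param scale positive proportionality constant \code{k}.
#' @return an object of class \code{"fgm_fitness_map"}.
#' @examples
#' fitness_from_breakdown(1, fitness_map())        # exp(-1)
#' fitness_from_breakdown(1, fitness_map("fig4"))  # exp(-6)
#' @export
fitness_map <- function(alpha = 2, scale = 1) {
  if (identical(alpha, "fig4")) {
    alpha <- 4
    scale <- 6
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.numeric(scale),
            length(scale) == 1)
  if (alpha <= 0) stop("alpha must be positive")
  if (scale <= 0) stop("scale k must be positive")
  structure(list(alpha = alpha, scale = scale), class = "fgm_fitness_map")
}

#' @export
print.fgm_fitness_map <- function(x, ...) {
  cat(sprintf("Fitness map: w = exp(-%g * f^%g)\n", x$scale, x$alpha / 2))
  invisible(x)
}

#' Expected breakdown score of a hybrid class
#'
#' Evaluates the Brownian-bridge expectation of the scaled breakdown
#' score \code{f} for a hybrid class at ancestry coordinates
#' \code{(h, p12)}:
#' \deqn{f = f_{P1} + (4 - 2 f_{P1}) h - (4 - f_{P1} - f_{P2}) h^2 - p_{12}.}
#' This is the expanded equivalent of
#' \code{fP1 + beta1*h*(1 - beta2*h) - p12} and is exact at all parameter
#' values, including \code{fP1 = 2} where \code{beta2} is undefined.
#' Internally the algebraically identical symmetric grouping
#' \code{fP1*(1-h)^2 + fP2*h^2 + 4*h*(1-h) - p12} is evaluated, so the
#' parental corner identities \code{f(0,0) = fP1} and \code{f(1,0) = fP2}
#' hold to the last bit.
#' \code{f} runs from 0 (best possible class between optimal parents) to
#' 1 (worst class between optimal parents), and can exceed 1 when the
#' parents are themselves maladapted.
#'
#' @param coords \code{\link{fgm_coords}} (or a data frame with columns
#'   \code{h}, \code{p12}).
#' @param params \code{\link{landscape_params}}.
#' @param validate check the attainability triangle (disable for grids).
#' @return numeric vector of expected breakdown scores.
#' @examples
#' expected_breakdown(fgm_coords(0.5, 0), landscape_params(0, 0))  # 1
#' expected_breakdown(fgm_coords(0.5, 1), landscape_params(0, 0))  # 0
#' @export
expected_breakdown <- function(coords, params = landscape_params(),
                               validate = TRUE) {
  coords <- as_fgm_coords(coords, validate = validate)
  params <- as_landscape(params)
  h <- coords$h
  params$fP1 * (1 - h)^2 + params$fP2 * h^2 + 4 * h * (1 - h) -
    coords$p12
}

#' Is a hybrid class expected to be fitter than parent P1?
#'
#' Heterosis relative to P1 is predicted exactly when the expected
#' breakdown of the class is below the parental breakdown, i.e.
#' \code{f < fP1}, which rearranges to
#' \code{p12 > beta1*h*(1 - beta2*h)}.
#'
#' @inheritParams expected_breakdown
#' @return logical vector.
#' @export
heterosis_condition <- function(coords, params = landscape_params(),
                                validate = TRUE) {
  params <- as_landscape(params)
  expected_breakdown(coords, params, validate = validate) < params$fP1
}

#' Convert breakdown scores to relative fitness
#'
#' @param f non-negative breakdown score(s).
#' @param map a \code{\link{fitness_map}}.
#' @return fitness values in (0, 1].
#' @export
fitness_from_breakdown <- function(f, map = fitness_map()) {
  stopifnot(inherits(map, "fgm_fitness_map"))
  f <- as.numeric(f)
  if (anyNA(f) || any(f < 0))
    stop("breakdown score f must be non-negative")
  exp(-map$scale * f^(map$alpha / 2))
}

#' Mean breakdown of F2 hybrids (directional selection on heterozygosity)
#'
#' In an F2 cross between parents of similar maladaptation \code{fP},
#' \code{4h(1-h)} is close to 1 with little between-individual variation,
#' so the landscape reduces to \code{f = 1 + fP/2 - p12}: heterozygosity
#' is under directional selection.
#'
#' @param p12 interpopulation heterozygosity.
#' @param fP common parental breakdown score.
#' @return numeric breakdown values.
#' @export
f2_mean_breakdown <- function(p12, fP = 0) {
  stopifnot(is.numeric(p12), is.numeric(fP), all(fP >= 0))
  if (any(p12 < 0 | p12 > 1)) stop("p12 must lie in [0, 1]")
  1 + fP / 2 - p12
}

#' Breakdown along a backcross edge (disruptive selection)
#'
#' In a backcross to one parent, all homozygous sites carry that parent's
#' alleles, so \code{4h(1-h) = p12(2 - p12)} and the landscape becomes
#' \code{f = fP + (1 - fP) p12 - (1 - fP/2) p12^2}.  With well-adapted
#' parents this is \code{p12(1 - p12)}: heterozygosity is under
#' symmetrical disruptive selection, worst at intermediate values.
#'
#' @inheritParams f2_mean_breakdown
#' @return numeric breakdown values.
#' @export
backcross_breakdown <- function(p12, fP = 0) {
  stopifnot(is.numeric(p12), is.numeric(fP), all(fP >= 0))
  if (any(p12 < 0 | p12 > 1)) stop("p12 must lie in [0, 1]")
  fP + (1 - fP) * p12 - (1 - fP / 2) * p12^2
}

#' Tabulate the breakdown landscape over the attainable triangle
#'
#' @param params \code{\link{landscape_params}}.
#' @param resolution number of grid points per axis (at least 2).
#' @param map optional \code{\link{fitness_map}}; when supplied a fitness
#'   column \code{w} is added.
#' @return data frame with columns \code{h}, \code{p12}, \code{f} (and
#'   \code{w}), restricted to attainable coordinates and sorted by
#'   \code{(h, p12)}.
#' @export
landscape_grid <- function(params = landscape_params(), resolution = 21,
                           map = NULL) {
  stopifnot(is.numeric(resolution), length(resolution) == 1)
  if (resolution < 2) stop("resolution must be at least 2")
  ax <- seq(0, 1, length.out = resolution)
  g <- expand.grid(p12 = ax, h = ax)[, c("h", "p12")]
  g <- g[g$p12 <= 2 * pmin(g$h, 1 - g$h) + 1e-9, , drop = FALSE]
  g <- g[order(g$h, g$p12), , drop = FALSE]
  rownames(g) <- NULL
  g$f <- expected_breakdown(fgm_coords(g$h, g$p12, validate = FALSE),
                            params, validate = FALSE)
  if (!is.null(map)) g$w <- fitness_from_breakdown(pmax(g$f, 0), map)
  g
}
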