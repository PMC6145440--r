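#' Ancestry coordinates of hybrid classes
#'
#' A hybrid genotype (or the expectation of a hybrid class) is summarised by
#' two numbers: the hybrid index \code{h}, the proportion of alleles at
#' divergent sites that originate from parental population P2, and the
#' interpopulation heterozygosity \code{p12}, the proportion of divergent
#' sites carrying one allele from each parental population.  Writing
#' \code{p1} and \code{p2} for the proportions of sites homozygous for P1
#' and P2 alleles, \code{p1 + p2 + p12 = 1} and \code{h = p2 + p12/2}.
#' Attainable genotypes satisfy \code{p12 <= 2*min(h, 1 - h)}, so all
#' hybrids live in a triangle with the two parents at the lower corners
#' and the fully heterozygous F1 at the apex.
#'
#' @param h hybrid index, in \[0, 1\]; recycled against \code{p12}.
#' @param p12 interpopulation heterozygosity, in \[0, 1\].
#' @param p1,p2 optional homozygous proportions; when supplied they are
#'   checked against \code{p1 + p2 + p12 = 1} and \code{h = p2 + p12/2}.
#' @param validate if \code{FALSE}, skip the triangle checks (useful for
#'   vectorised grid work where rows are filtered afterwards).
#' @param tol numerical tolerance for the constraint checks.
#' @return an object of class \code{"fgm_coords"}: a data frame with
#'   columns \code{h} and \code{p12}.
#' @examples
#' fgm_coords(h = 0.5, p12 = 1)            # the F1
#' fgm_coords(h = c(0, 1), p12 = c(0, 0))  # the two parents
#' @export
fgm_coords <- function(h, p12, p1 = NULL, p2 = NULL, validate = TRUE,
                       tol = 1e-9) {
  n <- max(length(h), length(p12))
  h <- rep_len(as.numeric(h), n)
  p12 <- rep_len(as.numeric(p12), n)
  if (anyNA(h) || anyNA(p12))
    stop("ancestry coordinates must be non-missing")
  if (validate) {
    if (any(h < -tol | h > 1 + tol))
      stop("hybrid index h must lie in [0, 1]")
    if (any(p12 < -tol | p12 > 1 + tol))
      stop("heterozygosity p12 must lie in [0, 1]")
    bad <- p12 > 2 * pmin(h, 1 - h) + tol
    if (any(bad))
      stop(sprintf(paste0(
        "coordinates outside the attainable triangle: p12 <= 2*min(h, 1-h) ",
        "violated at %d point(s), first at (h=%.6g, p12=%.6g)"),
        sum(bad), h[which(bad)[1]], p12[which(bad)[1]]))
    if (!is.null(p1) && !is.null(p2)) {
      p1 <- rep_len(as.numeric(p1), n)
      p2 <- rep_len(as.numeric(p2), n)
      if (any(abs(p1 + p2 + p12 - 1) > tol))
        stop("invalid composition: p1 + p2 + p12 must equal 1")
      if (any(abs(h - (p2 + p12 / 2)) > tol))
        stop("inconsistent coordinates: h must equal p2 + p12/2")
    }
  }
  out <- data.frame(h = h, p12 = p12)
  class(out) <- c("fgm_coords", "data.frame")
  out
}

#' @export
print.fgm_coords <- function(x, ...) {
  cat("Hybrid ancestry coordinates (", nrow(x), " class",
      if (nrow(x) != 1) "es", ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

## Coerce anything with h and p12 (data frame, list, fgm_coords) to
## validated coordinates; numeric length-2 vectors are (h, p12).
as_fgm_coords <- function(x, validate = TRUE) {
  if (inherits(x, "fgm_coords")) {
    if (validate) return(fgm_coords(x$h, x$p12))
    return(x)
  }
  if (is.numeric(x) && length(x) == 2 && is.null(dim(x)))
    return(fgm_coords(x[1], x[2], validate = validate))
  if ((is.list(x) || is.data.frame(x)) && all(c("h", "p12") %in% names(x)))
    return(fgm_coords(x$h, x$p12, validate = validate))
  stop("cannot interpret input as ancestry coordinates; ",
       "supply fgm_coords() or a data frame with columns h and p12")
}
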