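#' Cross specifications
#'
#' Crosses are expressed recursively as a maternal x paternal pair whose
#' elements are themselves cross specifications, bottoming out at the
#' pure lines \code{"P1"} and \code{"P2"}.  A registry of preset labels
#' covers the standard designs: \code{"P1"}, \code{"P2"}, \code{"F1"}
#' (P1 mother x P2 father), \code{"F1r"} (the reciprocal), \code{"F2"}
#' (F1 x F1), and \code{"BCn_P1"} / \code{"BCn_P2"}, the n-th backcross
#' to a parental line (\code{BC1_P1 = F1 x P1},
#' \code{BC2_P1 = (F1 x P1) x P1}, ...), with the hybrid as mother by
#' convention.
#'
#' @param mother,father cross specifications (strings or
#'   \code{cross_spec} objects).
#' @return an object of class \code{"cross_spec"}.
#' @examples
#' cross_spec("F1", "P1")        # first backcross to P1
#' parse_cross("BC2_P1")         # preset: (F1 x P1) x P1
#' @export
cross_spec <- function(mother, father) {
  structure(list(mother = parse_cross(mother), father = parse_cross(father)),
            class = "cross_spec")
}

#' @rdname cross_spec
#' @param x a preset label or a \code{cross_spec}.
#' @export
parse_cross <- function(x) {
  if (inherits(x, "cross_spec")) return(x)
  if (!is.character(x) || length(x) != 1)
    stop("a cross is a preset label or a cross_spec(mother, father)")
  if (x %in% c("P1", "P2")) return(structure(list(line = x),
                                            class = "cross_spec"))
  if (x == "F1") return(cross_spec("P1", "P2"))
  if (x == "F1r") return(cross_spec("P2", "P1"))
  if (x == "F2") return(cross_spec("F1", "F1"))
  m <- regmatches(x, regexec("^BC([0-9]+)_(P[12])$", x))[[1]]
  if (length(m) == 3) {
    k <- as.integer(m[2])
    if (k < 1) stop("backcross generation must be >= 1")
    par <- m[3]
    spec <- parse_cross("F1")
    for (i in seq_len(k)) spec <- cross_spec(spec, par)
    return(spec)
  }
  stop(sprintf("unknown cross label '%s'", x))
}

#' @export
print.cross_spec <- function(x, ...) {
  cat(deparse_cross(x), "\n")
  invisible(x)
}

deparse_cross <- function(x) {
  if (!is.null(x$line)) return(x$line)
  paste0("(", deparse_cross(x$mother), " x ", deparse_cross(x$father), ")")
}

#' Mendelian expected ancestry coordinates of a cross
#'
#' Under independent segregation the expected hybrid index of a cross is
#' the mean of the parental gamete P2-fractions, and the expected
#' heterozygosity is \code{aM(1-aP) + (1-aM)aP}, where \code{aM} and
#' \code{aP} are the probabilities that a maternal or paternal gamete
#' allele originates from P2 (each equal to the parent's expected hybrid
#' index).
#'
#' @param cross a preset label or \code{\link{cross_spec}}.
#' @return \code{\link{fgm_coords}} with one row.
#' @examples
#' expected_cross_coords("F1")      # (0.5, 1)
#' expected_cross_coords("F2")      # (0.5, 0.5)
#' expected_cross_coords("BC1_P1")  # (0.25, 0.5)
#' @export
expected_cross_coords <- function(cross) {
  spec <- parse_cross(cross)
  rec <- function(s) {
    if (!is.null(s$line)) {
      a <- if (s$line == "P1") 0 else 1
      return(list(h = a, p12 = if (a == 0) 0 else 0))
    }
    m <- rec(s$mother)
    p <- rec(s$father)
    list(h = (m$h + p$h) / 2,
         p12 = m$h * (1 - p$h) + (1 - m$h) * p$h)
  }
  e <- rec(spec)
  fgm_coords(e$h, e$p12)
}

## Simulate N diploid genotypes at d unlinked biallelic divergent sites
## for a recursive cross.  Returns a list of two N x d 0/1 matrices
## (maternal and paternal allele: 1 = P2-origin).  Each simulated
## individual has its own independently simulated ancestors, i.e.
## individuals are unrelated members of the cross class.
simulate_cross_haplotypes <- function(cross, N, d) {
  spec <- parse_cross(cross)
  rec <- function(s) {
    if (!is.null(s$line)) {
      a <- if (s$line == "P1") 0L else 1L
      m <- matrix(a, N, d)
      return(list(mat = m, pat = m))
    }
    mo <- rec(s$mother)
    fa <- rec(s$father)
    gamete <- function(ind) {
      pick <- matrix(stats::runif(N * d) < 0.5, N, d)
      ifelse(pick, ind$mat, ind$pat)
    }
    list(mat = gamete(mo), pat = gamete(fa))
  }
  rec(spec)
}

#' Simulate within-cross ancestry coordinates
#'
#' Draws \code{N} unrelated individuals from a cross by per-site
#' Mendelian segregation at \code{d} unlinked divergent sites (free
#' recombination), and returns each individual's realised \code{(h, p12)}.
#'
#' @param cross preset label or \code{\link{cross_spec}}.
#' @param N number of individuals.
#' @param d number of divergent sites.
#' @param seed optional integer seed (local to this call).
#' @return data frame with columns \code{h}, \code{p12} and attribute
#'   \code{"dosage"}, the N x d matrix of P2-allele counts.
#' @export
simulate_cross_coords <- function(cross, N, d = 100, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  hap <- simulate_cross_haplotypes(cross, N, d)
  dosage <- hap$mat + hap$pat
  out <- data.frame(h = rowSums(dosage) / (2 * d),
                    p12 = rowMeans(dosage == 1L))
  attr(out, "dosage") <- dosage
  out
}

## Save/restore the global RNG state so seeded helpers do not disturb
## the caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
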