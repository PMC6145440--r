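#' Multilocus Dobzhansky-Muller incompatibility model
#'
#' An incompatibility involves \code{ell >= 2} divergent loci.  In a
#' hybrid, each locus of an \code{ell}-tuple is homozygous for alleles
#' from one parental line, homozygous for the other, or heterozygous;
#' the severity table \code{s[i, j, k]} gives the expected breakdown
#' contributed by an incompatibility whose tuple contains \code{i} loci
#' homozygous from one parent, \code{j} homozygous from the other and
#' \code{k} heterozygous (\code{i + j + k = ell}).  Severities must be
#' symmetric in \code{i} and \code{j} (neither parental line is
#' privileged) and zero for the pure parental configurations
#' (\code{k = 0} and \code{i = 0} or \code{j = 0}): the parents
#' themselves are fit.
#'
#' @param ell loci per incompatibility.
#' @param severity data frame with columns \code{i}, \code{j}, \code{k},
#'   \code{s}, complete over all compositions of \code{ell}.
#' @return object of class \code{"dmi_model"}.
#' @seealso \code{\link{dmi_severity_preset}}
#' @export
dmi_model <- function(ell, severity) {
  stopifnot(is.numeric(ell), length(ell) == 1, ell >= 2)
  ell <- as.integer(ell)
  need <- dmi_configs(ell)
  severity <- as.data.frame(severity)
  if (!all(c("i", "j", "k", "s") %in% names(severity)))
    stop("severity table needs columns i, j, k, s")
  key <- function(d) paste(d$i, d$j, d$k)
  if (anyDuplicated(key(severity)))
    stop("duplicated configurations in severity table")
  miss <- setdiff(key(need), key(severity))
  if (length(miss))
    stop("incomplete severity table: missing configuration(s) ",
         paste(miss, collapse = "; "))
  severity <- severity[match(key(need), key(severity)), , drop = FALSE]
  rownames(severity) <- NULL
  if (any(severity$s < 0)) stop("severities must be non-negative")
  pure <- severity$k == 0 & (severity$i == 0 | severity$j == 0)
  if (any(severity$s[pure] != 0))
    stop("pure parental configurations must have zero severity")
  swapped <- severity$s[match(paste(severity$j, severity$i, severity$k),
                              key(severity))]
  if (any(abs(severity$s - swapped) > 1e-12))
    stop("severity table must be symmetric under exchange of i and j")
  structure(list(ell = ell, severity = severity), class = "dmi_model")
}

## All compositions i + j + k = ell.
dmi_configs <- function(ell) {
  g <- expand.grid(i = 0:ell, j = 0:ell)
  g <- g[g$i + g$j <= ell, ]
  g <- data.frame(i = g$i, j = g$j, k = ell - g$i - g$j)
  rownames(g) <- NULL
  g
}

#' Shipped severity tables
#'
#' \describe{
#'   \item{\code{"equivalence"}}{\code{s = (4ij + k(i+j)) / (ell(ell-1))}.
#'     This is the unique pairwise-quadratic dominance scheme whose
#'     expected surface equals the optimal-parents landscape
#'     \code{4h(1-h) - p12} exactly, for every \code{ell}.  It embodies
#'     partial recessivity (a heterozygous locus contributes at quarter
#'     strength relative to a homozygous one) and maximal severity when
#'     homozygous alleles from both parents meet.}
#'   \item{\code{"fully_recessive"}}{\code{s = ij}: incompatibilities are
#'     only expressed between homozygous alleles from the two parents.}
#'   \item{\code{"codominant"}}{\code{s = 4(i + k/2)(j + k/2) /
#'     (ell(ell-1))}: heterozygous loci contribute half a dose to each
#'     side, so the F1 is maximally affected.  Violates the recessivity
#'     conditions and serves as a negative control.}
#' }
#'
#' @param preset preset name.
#' @param ell loci per incompatibility.
#' @return a \code{\link{dmi_model}}.
#' @export
dmi_severity_preset <- function(preset = c("equivalence",
                                           "fully_recessive",
                                           "codominant"), ell = 2) {
  preset <- match.arg(preset)
  cfg <- dmi_configs(ell)
  cfg$s <- switch(preset,
    equivalence = (4 * cfg$i * cfg$j + cfg$k * (cfg$i + cfg$j)) /
      (ell * (ell - 1)),
    fully_recessive = cfg$i * cfg$j,
    codominant = 4 * (cfg$i + cfg$k / 2) * (cfg$j + cfg$k / 2) /
      (ell * (ell - 1)))
  ## keep the parental configurations exactly zero for the control
  if (preset == "codominant")
    cfg$s[cfg$k == 0 & (cfg$i == 0 | cfg$j == 0)] <- 0
  dmi_model(ell, cfg)
}

#' Probability of a tuple configuration
#'
#' The probability that an \code{ell}-tuple of divergent sites shows
#' \code{i} P1-homozygous, \code{j} P2-homozygous and \code{k}
#' heterozygous loci, when sites are independent with genotype
#' proportions \code{(p1, p2, p12)}:
#' multinomial coefficient times \code{p1^i p2^j p12^k}.
#'
#' @param p1,p2,p12 genotype proportions (must sum to 1).
#' @param ell loci per incompatibility.
#' @param i,j,k configuration counts with \code{i + j + k = ell}.
#' @return a probability.
#' @export
config_probability <- function(p1, p2, p12, ell, i, j, k) {
  if (i + j + k != ell) stop("configuration must satisfy i + j + k = ell")
  if (min(i, j, k) < 0) stop("configuration counts must be non-negative")
  if (any(c(p1, p2, p12) < -1e-12) || abs(p1 + p2 + p12 - 1) > 1e-9)
    stop("(p1, p2, p12) must be a valid composition summing to 1")
  exp(lgamma(ell + 1) - lgamma(i + 1) - lgamma(j + 1) - lgamma(k + 1)) *
    p1^i * p2^j * p12^k
}

#' Expected incompatibility breakdown of a hybrid class
#'
#' Sums severity over tuple configurations weighted by their
#' probability, giving the expected breakdown per incompatibility-bearing
#' tuple (up to the model's density constant).  With \code{d} supplied,
#' the class proportions are resolved to exact integer site counts and
#' the configuration distribution is multivariate hypergeometric (tuples
#' drawn without replacement from a finite genome); otherwise the
#' infinite-sites multinomial limit is used.
#'
#' @param coords \code{\link{fgm_coords}} (vectorised over rows).
#' @param model \code{\link{dmi_model}}.
#' @param d optional finite number of divergent sites.
#' @return numeric vector of expected breakdown values.
#' @export
expected_dmi_breakdown <- function(coords, model, d = NULL) {
  stopifnot(inherits(model, "dmi_model"))
  coords <- as_fgm_coords(coords)
  sev <- model$severity
  ell <- model$ell
  p12 <- coords$p12
  p2 <- coords$h - p12 / 2
  p1 <- 1 - p2 - p12
  vapply(seq_len(nrow(coords)), function(r) {
    if (is.null(d)) {
      probs <- mapply(config_probability, i = sev$i, j = sev$j, k = sev$k,
                      MoreArgs = list(p1 = max(p1[r], 0),
                                      p2 = max(p2[r], 0),
                                      p12 = p12[r], ell = ell))
    } else {
      cnt <- class_site_counts(coords$h[r], p12[r], d)
      if (ell > d) stop("ell exceeds the number of divergent sites")
      probs <- choose(cnt["n1"], sev$i) * choose(cnt["n2"], sev$j) *
        choose(cnt["n12"], sev$k) / choose(d, ell)
    }
    sum(probs * sev$s)
  }, numeric(1))
}

#' Incompatibility breakdown of an explicit genotype
#'
#' Averages the severity over all \code{choose(d, ell)} tuples of the
#' genotype's divergent sites (per-tuple scale, matching
#' \code{\link{expected_dmi_breakdown}} up to the density constant).
#'
#' @param dosage vector of P2-allele dosages (0, 1, 2) over the sites.
#' @param model \code{\link{dmi_model}}.
#' @return a single breakdown value.
#' @export
genotype_dmi_breakdown <- function(dosage, model) {
  stopifnot(inherits(model, "dmi_model"))
  if (any(!dosage %in% 0:2)) stop("dosages must be 0, 1 or 2")
  d <- length(dosage)
  if (model$ell > d) stop("ell exceeds the number of sites")
  sev <- model$severity
  n1 <- sum(dosage == 0)
  n2 <- sum(dosage == 2)
  n12 <- sum(dosage == 1)
  sum(choose(n1, sev$i) * choose(n2, sev$j) * choose(n12, sev$k) *
        sev$s) / choose(d, model$ell)
}

#' Snowball count of potential incompatibilities
#'
#' The number of \code{ell}-tuples among \code{d} divergent sites,
#' \code{choose(d, ell)}: the incompatibility count grows like
#' \code{d^ell}, so under a fitness map with exponent \code{alpha} the
#' log fitness of hybrids declines like \code{-d^(ell*alpha/2)},
#' compared with \code{-d^(alpha/2)} for the geometric model.
#'
#' @param d number of divergent sites.
#' @param ell loci per incompatibility.
#' @param alpha fitness-map exponent used for the reported scaling
#'   exponent.
#' @return the tuple count, with attribute \code{"log_fitness_exponent"}
#'   equal to \code{ell * alpha / 2}.
#' @export
snowball_count <- function(d, ell, alpha = 2) {
  stopifnot(d >= 1, ell >= 2)
  if (d < ell) stop("d must be at least ell")
  structure(choose(d, ell), log_fitness_exponent = ell * alpha / 2)
}

#' Read or write a severity table as TSV
#'
#' @param path file path.
#' @param ell loci per incompatibility (checked against the table).
#' @return \code{read_severity_table} returns a \code{\link{dmi_model}}.
#' @export
read_severity_table <- function(path, ell = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(ell)) ell <- max(tab$i + tab$j + tab$k)
  dmi_model(ell, tab)
}

#' @rdname read_severity_table
#' @param model a \code{\link{dmi_model}}.
#' @export
write_severity_table <- function(model, path) {
  stopifnot(inherits(model, "dmi_model"))
  utils::write.table(model$severity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
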