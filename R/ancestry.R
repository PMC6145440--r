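#' Marker dataset container
#'
#' Holds a genotype table of hybrid individuals at diagnostic markers.
#' Genotypes are stored as counts of the P2-oriented allele: 0, 1, 2 for
#' diploid calls and 0, 1 (with ploidy 1) for hemizygous calls (the X in
#' heterogametic males).  Marker metadata give the chromosome class and
#' current orientation; individual metadata give sex, cross label,
#' sequencing order and the fitness response.
#'
#' @param geno integer matrix, individuals x markers, of P2-allele
#'   counts (NA = missing).
#' @param ploidy integer matrix of the same shape (1 or 2).
#' @param markers data frame with columns \code{marker_id},
#'   \code{chrom_class} (\code{"A"}, \code{"X"}, \code{"Y"},
#'   \code{"mito"}) and \code{orientation} (\code{1} = P2 allele
#'   counted, \code{-1} = flipped relative to input).
#' @param individuals data frame with columns \code{individual_id},
#'   \code{sex}, \code{cross}, \code{order}, \code{fitness}.
#' @param system sex-determination system for hemizygosity handling.
#' @return object of class \code{"marker_dataset"}.
#' @export
marker_dataset <- function(geno, ploidy = NULL, markers = NULL,
                           individuals = NULL,
                           system = c("none", "XY", "XO", "ZW")) {
  system <- match.arg(system)
  geno <- as.matrix(geno)
  if (is.null(ploidy)) ploidy <- matrix(2L, nrow(geno), ncol(geno))
  if (is.null(markers))
    markers <- data.frame(marker_id = colnames(geno) %||%
                            paste0("m", seq_len(ncol(geno))),
                          chrom_class = "A", orientation = 1L)
  if (is.null(individuals))
    individuals <- data.frame(individual_id = rownames(geno) %||%
                                paste0("ind", seq_len(nrow(geno))),
                              sex = NA_character_, cross = NA_character_,
                              order = seq_len(nrow(geno)),
                              fitness = NA_real_)
  if (anyDuplicated(markers$marker_id))
    stop("duplicated marker ids: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
               collapse = ", "))
  stopifnot(nrow(markers) == ncol(geno), nrow(individuals) == nrow(geno),
            all(dim(ploidy) == dim(geno)))
  ok <- is.na(geno) | (geno >= 0 & geno <= ploidy & geno == round(geno))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid genotype code %s for individual '%s' at marker '%s'",
      format(geno[bad[1], bad[2]]), individuals$individual_id[bad[1]],
      markers$marker_id[bad[2]]))
  }
  dimnames(geno) <- list(individuals$individual_id, markers$marker_id)
  dimnames(ploidy) <- dimnames(geno)
  structure(list(geno = geno, ploidy = ploidy, markers = markers,
                 individuals = individuals, system = system),
            class = "marker_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_dataset <- function(x, ...) {
  cat(sprintf("Marker dataset: %d individuals x %d markers (%s system)\n",
              nrow(x$geno), ncol(x$geno), x$system))
  cat(sprintf("  classes: %s; missing calls: %.1f%%\n",
              paste(names(table(x$markers$chrom_class)), collapse = ", "),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.marker_dataset <- function(x) dim(x$geno)

## subset a dataset by individuals (i) and/or markers (j)
subset_dataset <- function(ds, i = NULL, j = NULL) {
  if (!is.null(i)) {
    ds$geno <- ds$geno[i, , drop = FALSE]
    ds$ploidy <- ds$ploidy[i, , drop = FALSE]
    ds$individuals <- ds$individuals[i, , drop = FALSE]
    rownames(ds$individuals) <- NULL
  }
  if (!is.null(j)) {
    ds$geno <- ds$geno[, j, drop = FALSE]
    ds$ploidy <- ds$ploidy[, j, drop = FALSE]
    ds$markers <- ds$markers[j, , drop = FALSE]
    rownames(ds$markers) <- NULL
  }
  ds
}

#' Read a marker genotype table
#'
#' Reads a TSV with columns \code{individual_id}, \code{sex},
#' \code{cross}, \code{order}, \code{fitness}, followed by one dosage
#' column per marker (codes 0/1/2, empty or NA = missing), together
#' with a marker metadata TSV (\code{marker_id}, \code{chrom_class},
#' optionally \code{orientation}).  Alternatively reads a VCF (via the
#' vcfR package) using the GT field, ignoring phase; the metadata
#' sidecar is required in either case.
#'
#' X-linked calls in heterogametic males are remapped to single-copy
#' states: input 0/2 become allele counts 0/1 with ploidy 1, and a
#' heterozygous call (1) is treated as a genotyping error and set to
#' missing (with \code{strict = TRUE} the individual is dropped
#' instead).
#'
#' @param path genotype table path.
#' @param metadata_path marker metadata path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param system sex-determination system.
#' @param strict drop individuals with heterozygous hemizygous calls.
#' @return a \code{\link{marker_dataset}}.
#' @export
read_marker_table <- function(path, metadata_path, format = c("tsv", "vcf"),
                              system = c("none", "XY", "XO", "ZW"),
                              strict = FALSE) {
  format <- match.arg(format)
  system <- match.arg(system)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "chrom_class") %in% names(meta)))
    stop("marker metadata needs columns marker_id and chrom_class")
  if (is.null(meta$orientation)) meta$orientation <- 1L
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    fixed <- c("individual_id", "sex", "cross", "order", "fitness")
    miss <- setdiff(fixed, names(tab))
    if (length(miss))
      stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
    mcols <- setdiff(names(tab), fixed)
    if (!setequal(mcols, meta$marker_id))
      stop("marker columns do not match the metadata marker_id set")
    mcols <- meta$marker_id
    geno <- as.matrix(tab[, mcols, drop = FALSE])
    storage.mode(geno) <- "numeric"
    bad <- !is.na(geno) & !(geno %in% 0:2)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "invalid genotype code '%s' for individual '%s' at marker '%s'",
        format(geno[w[1], w[2]]), tab$individual_id[w[1]], mcols[w[2]]))
    }
    ind <- tab[, fixed]
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- rownames(gt)
    alleles <- function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
      vapply(a, function(p) {
        p <- suppressWarnings(as.integer(p))
        if (anyNA(p)) NA_real_ else sum(p > 0)
      }, numeric(1))
    }
    geno <- t(apply(gt, 1, alleles))
    geno <- t(geno)  # samples x markers
    colnames(geno) <- ids
    keep <- intersect(meta$marker_id, colnames(geno))
    if (!length(keep)) stop("no metadata markers found in the VCF")
    meta <- meta[match(keep, meta$marker_id), , drop = FALSE]
    geno <- geno[, keep, drop = FALSE]
    ind <- data.frame(individual_id = rownames(geno),
                      sex = NA_character_, cross = NA_character_,
                      order = seq_len(nrow(geno)), fitness = NA_real_)
  }
  ploidy <- matrix(2L, nrow(geno), ncol(geno))
  hetero <- switch(system, XY = "male", XO = "male", ZW = "female",
                   none = NA_character_)
  drop_ind <- logical(nrow(geno))
  if (!is.na(hetero)) {
    hemi_row <- !is.na(ind$sex) & ind$sex == hetero
    hemi_col <- meta$chrom_class %in% c("X", "Y")
    if (any(hemi_row) && any(hemi_col)) {
      sub <- geno[hemi_row, hemi_col, drop = FALSE]
      err <- !is.na(sub) & sub == 1
      if (any(err)) {
        if (strict) {
          drop_ind[hemi_row][rowSums(err) > 0] <- TRUE
        } else {
          warning(sum(err), " heterozygous hemizygous call(s) set to ",
                  "missing (likely genotyping errors)")
          sub[err] <- NA
        }
      }
      sub[!is.na(sub) & sub == 2] <- 1
      geno[hemi_row, hemi_col] <- sub
      ploidy[hemi_row, hemi_col] <- 1L
    }
  }
  ds <- marker_dataset(geno, ploidy, meta, ind, system = system)
  if (any(drop_ind)) ds <- subset_dataset(ds, i = !drop_ind)
  ds
}

#' Keep markers heterozygous in all F1 individuals
#'
#' Diagnostic markers must segregate one allele from each parental line;
#' a marker that is truly diagnostic is heterozygous in every F1 hybrid.
#' Markers with any non-heterozygous or missing call among the listed F1
#' individuals are dropped.
#'
#' @param ds \code{\link{marker_dataset}}.
#' @param f1_ids individual ids of the F1 hybrids.
#' @return the filtered dataset.
#' @export
filter_f1_heterozygous <- function(ds, f1_ids) {
  stopifnot(inherits(ds, "marker_dataset"), length(f1_ids) > 0)
  unknown <- setdiff(f1_ids, ds$individuals$individual_id)
  if (length(unknown))
    stop("unknown F1 id(s): ", paste(unknown, collapse = ", "))
  rows <- match(f1_ids, ds$individuals$individual_id)
  g <- ds$geno[rows, , drop = FALSE]
  keep <- apply(g, 2, function(x) all(!is.na(x)) && all(x == 1))
  subset_dataset(ds, j = keep)
}

#' Keep strongly diagnostic markers and orient them to P2
#'
#' Computes sample allele frequencies of the currently counted allele in
#' two reference panels (missing calls excluded) and keeps markers whose
#' absolute frequency difference exceeds \code{threshold}.  Retained
#' markers are re-oriented so the majority allele of the P2 panel is the
#' counted allele.
#'
#' @param ds \code{\link{marker_dataset}}.
#' @param pop1_ids,pop2_ids individual ids of the P1 and P2 reference
#'   panels.
#' @param threshold minimum absolute allele-frequency difference
#'   (default 0.9).
#' @return the filtered, re-oriented dataset; panel frequencies are
#'   attached as attribute \code{"panel_freqs"}.
#' @export
diagnostic_markers <- function(ds, pop1_ids, pop2_ids, threshold = 0.9) {
  stopifnot(inherits(ds, "marker_dataset"))
  if (!length(pop1_ids) || !length(pop2_ids))
    stop("reference panels must be nonempty")
  unknown <- setdiff(c(pop1_ids, pop2_ids), ds$individuals$individual_id)
  if (length(unknown))
    stop("unknown panel id(s): ", paste(unknown, collapse = ", "))
  freq <- function(ids) {
    rows <- match(ids, ds$individuals$individual_id)
    g <- ds$geno[rows, , drop = FALSE]
    p <- ds$ploidy[rows, , drop = FALSE]
    p[is.na(g)] <- NA
    colSums(g, na.rm = TRUE) / colSums(p, na.rm = TRUE)
  }
  f1 <- freq(pop1_ids)
  f2 <- freq(pop2_ids)
  untyped <- !is.finite(f1) | !is.finite(f2)
  if (any(untyped))
    stop("marker(s) untyped in a reference panel: ",
         paste(ds$markers$marker_id[untyped], collapse = ", "))
  keep <- abs(f1 - f2) > threshold
  out <- subset_dataset(ds, j = keep)
  flip <- f2[keep] < 0.5  # counted allele should be the P2-panel majority
  if (any(flip)) {
    out$geno[, flip] <- out$ploidy[, flip] - out$geno[, flip]
    out$markers$orientation[flip] <- -out$markers$orientation[flip]
  }
  attr(out, "panel_freqs") <- data.frame(
    marker_id = ds$markers$marker_id, freq_pop1 = f1, freq_pop2 = f2,
    kept = keep)
  out
}

#' Per-individual ancestry coordinates from markers
#'
#' Estimates \code{(h, p12)} for each individual, per chromosome class
#' and combined.  Within a class, \code{p12} is the fraction of scored
#' diploid markers that are heterozygous, and \code{h} is the fraction
#' of scored allele copies that are P2-oriented (hemizygous markers
#' contribute a single copy and no heterozygosity).  Classes are
#' combined with the partition weights, or with each individual's
#' scored-copy proportions when no partition is given.
#'
#' @param ds \code{\link{marker_dataset}}.
#' @param partition optional \code{\link{genome_partition}} supplying
#'   class weights.
#' @param min_markers individuals scoring fewer markers (total) are
#'   flagged in the \code{low_coverage} column.
#' @return data frame, one row per individual: \code{h}, \code{p12},
#'   per-class coordinates and counts, missingness and flags.
#' @export
individual_coords <- function(ds, partition = NULL, min_markers = 1) {
  stopifnot(inherits(ds, "marker_dataset"))
  classes <- sort(unique(ds$markers$chrom_class))
  n <- nrow(ds$geno)
  out <- data.frame(individual_id = ds$individuals$individual_id,
                    h = NA_real_, p12 = NA_real_)
  acc <- list()
  for (cl in classes) {
    cols <- ds$markers$chrom_class == cl
    g <- ds$geno[, cols, drop = FALSE]
    p <- ds$ploidy[, cols, drop = FALSE]
    scored <- !is.na(g)
    copies <- rowSums(p * scored)
    h_c <- rowSums(g, na.rm = TRUE) / copies
    dip <- scored & p == 2
    p12_c <- rowSums(g == 1 & dip, na.rm = TRUE) / rowSums(dip)
    acc[[cl]] <- list(h = h_c, p12 = p12_c, copies = copies,
                      n_scored = rowSums(scored))
    out[[paste0("h_", cl)]] <- h_c
    out[[paste0("p12_", cl)]] <- p12_c
    out[[paste0("n_", cl)]] <- rowSums(scored)
  }
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "genome_partition"))
    wmap <- c(A = "A", X = "X", Y = "Y", mito = "mito")
    w <- partition$weights
    used <- names(w)[w > 0]
    missing_cl <- setdiff(used, classes)
    if (length(missing_cl))
      stop("partition weights positive for class(es) with no markers: ",
           paste(missing_cl, collapse = ", "))
    for (i in seq_len(n)) {
      if (any(vapply(used, function(cl) acc[[cl]]$n_scored[i] == 0,
                     logical(1))))
        stop(sprintf(
          "individual '%s' has no scored markers in a weighted class",
          out$individual_id[i]))
    }
    h <- Reduce(`+`, lapply(used, function(cl) w[[cl]] * acc[[cl]]$h))
    p12 <- Reduce(`+`, lapply(used, function(cl) {
      pc <- acc[[cl]]$p12
      pc[!is.finite(pc)] <- 0  # hemizygous-only class carries no p12
      w[[cl]] * pc
    }))
  } else {
    ## default weights: each individual's scored-marker proportions
    tot <- Reduce(`+`, lapply(acc, `[[`, "n_scored"))
    h <- Reduce(`+`, lapply(acc, function(a) {
      ifelse(a$n_scored > 0, a$h, 0) * a$n_scored
    })) / tot
    p12 <- Reduce(`+`, lapply(acc, function(a) {
      pc <- a$p12
      pc[!is.finite(pc)] <- 0  # hemizygous-only class carries no p12
      pc * a$n_scored
    })) / tot
  }
  out$h <- h
  out$p12 <- p12
  tot_scored <- Reduce(`+`, lapply(acc, `[[`, "n_scored"))
  out$missingness <- 1 - tot_scored / ncol(ds$geno)
  out$low_coverage <- tot_scored < min_markers
  out
}

#' Missingness quality control
#'
#' Datasets in which the proportion of missing calls per individual is
#' rank-correlated with heterozygosity or with fitness yield biased
#' selection tests; such datasets should be excluded or repaired before
#' estimating the fitness surface.  Reports Spearman correlations of
#' per-individual missingness against estimated \code{p12} and against
#' the fitness response, with a pass/fail flag at a p-value threshold.
#'
#' @param ds \code{\link{marker_dataset}} (needs >= 3 individuals).
#' @param p_threshold flag threshold on the Spearman p-value.
#' @return data frame with one row per check (\code{heterozygosity},
#'   \code{fitness}): rho, p-value and pass flag.  Undefined
#'   correlations (constant inputs) are reported as NA with a pass.
#' @export
missingness_qc <- function(ds, p_threshold = 0.001) {
  stopifnot(inherits(ds, "marker_dataset"))
  if (nrow(ds$geno) < 3) stop("missingness QC needs at least 3 individuals")
  miss <- rowMeans(is.na(ds$geno))
  co <- individual_coords(ds)
  test <- function(y) {
    ok <- is.finite(y) & is.finite(miss)
    if (sum(ok) < 3 || stats::sd(miss[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(miss[ok], y[ok],
                                           method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  het <- test(co$p12)
  fit <- test(ds$individuals$fitness)
  out <- data.frame(check = c("heterozygosity", "fitness"),
                    rho = c(het["rho"], fit["rho"]),
                    p_value = c(het["p"], fit["p"]))
  out$pass <- is.na(out$p_value) | out$p_value >= p_threshold
  out
}

#' Apply a published-data subsampling rule
#'
#' Rules mirror common hybrid-cross curation steps:
#' \describe{
#'   \item{\code{"drop_missing_any"}}{drop individuals with any missing
#'     call.}
#'   \item{\code{"bc_purge"}}{drop backcross individuals carrying the
#'     non-recurrent parent's allele in homozygous form at any marker
#'     (dosage 0 with the P2-recurrent orientation; set
#'     \code{purge_dosage = 2} for backcrosses to P1).}
#'   \item{\code{"first_n_by_order"}}{keep the \code{n} individuals with
#'     the lowest sequencing order (ties broken by input order).}
#' }
#'
#' @param ds \code{\link{marker_dataset}}.
#' @param rule rule name.
#' @param n sample size for \code{"first_n_by_order"}.
#' @param purge_dosage homozygous dosage that triggers exclusion for
#'   \code{"bc_purge"}.
#' @return the subsampled dataset; excluded individual ids and reasons
#'   are attached as attribute \code{"excluded"}.
#' @export
subsample_rules <- function(ds, rule = c("drop_missing_any", "bc_purge",
                                         "first_n_by_order"),
                            n = NULL, purge_dosage = 0) {
  rule <- match.arg(rule)
  stopifnot(inherits(ds, "marker_dataset"))
  keep <- rep(TRUE, nrow(ds$geno))
  reason <- character(nrow(ds$geno))
  if (rule == "drop_missing_any") {
    keep <- rowSums(is.na(ds$geno)) == 0
    reason[!keep] <- "missing call"
  } else if (rule == "bc_purge") {
    hom <- !is.na(ds$geno) & ds$geno == purge_dosage & ds$ploidy == 2
    keep <- rowSums(hom) == 0
    reason[!keep] <- sprintf("homozygous dosage-%d call", purge_dosage)
  } else {
    if (is.null(n)) stop("first_n_by_order requires n")
    ord <- ds$individuals$order
    if (anyNA(ord)) stop("sequencing-order metadata is missing")
    sel <- order(ord)[seq_len(min(n, length(ord)))]
    keep <- seq_along(ord) %in% sel
    reason[!keep] <- "beyond first n by sequencing order"
  }
  excluded <- data.frame(
    individual_id = ds$individuals$individual_id[!keep],
    reason = reason[!keep])
  out <- subset_dataset(ds, i = keep)
  attr(out, "excluded") <- excluded
  out
}

#' Classify the X ancestry of heterogametic individuals
#'
#' Males (or ZW females) are classified as \code{"low"} hX when every
#' listed X marker carries the P1 allele, \code{"high"} when every
#' marker carries the P2 allele, and \code{"intermediate"} otherwise.
#' Individuals with missing calls at listed markers are classified
#' intermediate and flagged.
#'
#' @param ds \code{\link{marker_dataset}}.
#' @param x_marker_ids marker ids used for the classification.
#' @return data frame with \code{individual_id}, \code{hX_class} and a
#'   \code{missing_x} flag.
#' @export
classify_hX <- function(ds, x_marker_ids) {
  stopifnot(inherits(ds, "marker_dataset"))
  unknown <- setdiff(x_marker_ids, ds$markers$marker_id)
  if (length(unknown))
    stop("unknown X marker(s): ", paste(unknown, collapse = ", "))
  cols <- match(x_marker_ids, ds$markers$marker_id)
  g <- ds$geno[, cols, drop = FALSE]
  p <- ds$ploidy[, cols, drop = FALSE]
  frac <- g / p
  cls <- apply(frac, 1, function(x) {
    if (anyNA(x)) return("intermediate")
    if (all(x == 0)) "low" else if (all(x == 1)) "high" else "intermediate"
  })
  miss <- rowSums(is.na(g)) > 0
  if (any(miss))
    warning(sum(miss), " individual(s) with missing X calls classified ",
            "intermediate")
  data.frame(individual_id = ds$individuals$individual_id,
             hX_class = cls, missing_x = miss)
}
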