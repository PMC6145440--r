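#' Synthetic marker-dataset scenario
#'
#' Describes a marker panel and cross design from which seeded datasets
#' with the Mendelian structure assumed by the inference can be
#' generated: diagnostic markers split between autosomes and the X, a
#' set of crosses with sample sizes, independent missingness, a
#' contamination rate (the probability that a nominally diagnostic
#' marker is in fact shared-polymorphic between the parental panels,
#' with the shared minor allele at a frequency drawn uniformly on
#' \[0, 0.3\]), the breakdown landscape driving fitness, and the
#' response family.
#'
#' @param d number of markers.
#' @param gX fraction of markers on the X (0 for purely autosomal).
#' @param system sex-determination system.
#' @param crosses named integer vector: sample size per cross label.
#' @param missing_rate per-call missing probability.
#' @param contamination_rate per-marker shared-polymorphism probability.
#' @param x_het_error_rate probability that a hemizygous male X call is
#'   mis-scored heterozygous (exercises the QC path).
#' @param params \code{\link{landscape_params}} of the generating
#'   landscape.
#' @param map \code{\link{fitness_map}} used for viability selection
#'   and, by default, the response mean.
#' @param family response family (\code{"gaussian"},
#'   \code{"binomial"}, \code{"ordinal"}, or \code{"viability"}:
#'   individuals survive with probability \code{w} and survivors are
#'   returned).
#' @param noise_sd Gaussian response noise.
#' @param response_scale slope of the linear predictor on breakdown
#'   (binomial/ordinal: logit scale).
#' @param cutpoints latent-scale cutpoints for the ordinal family.
#' @param seed integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return object of class \code{"synth_scenario"}.
#' @export
synth_scenario <- function(d = 43, gX = 0, system = c("none", "XY", "XO"),
                           crosses = c(F2 = 132), missing_rate = 0,
                           contamination_rate = 0,
                           x_het_error_rate = 0,
                           params = landscape_params(),
                           map = fitness_map(),
                           family = c("gaussian", "binomial", "ordinal",
                                      "viability"),
                           noise_sd = 0.1, response_scale = 3,
                           cutpoints = c(-1, 1), seed = 1) {
  system <- match.arg(system)
  family <- match.arg(family)
  stopifnot(d >= 1, gX >= 0, gX <= 1,
            missing_rate >= 0, missing_rate <= 1,
            contamination_rate >= 0, contamination_rate <= 1,
            x_het_error_rate >= 0, x_het_error_rate <= 1,
            length(crosses) >= 1, all(crosses >= 1))
  if (gX > 0 && system == "none")
    stop("X-linked markers require an XY or XO system")
  if (is.null(names(crosses)) || any(names(crosses) == ""))
    stop("crosses must be a named vector of sample sizes")
  structure(list(d = as.integer(d), gX = gX, system = system,
                 crosses = crosses, missing_rate = missing_rate,
                 contamination_rate = contamination_rate,
                 x_het_error_rate = x_het_error_rate,
                 params = params, map = map, family = family,
                 noise_sd = noise_sd, response_scale = response_scale,
                 cutpoints = cutpoints, seed = as.integer(seed)),
            class = "synth_scenario")
}

## Marker classes for a scenario: first round(gX*d) markers X-linked.
scenario_marker_classes <- function(sc) {
  nx <- as.integer(floor(sc$gX * sc$d + 0.5))
  c(rep("X", nx), rep("A", sc$d - nx))
}

## Shared minor-allele frequency per marker (0 = fully diagnostic).
scenario_contamination <- function(sc) {
  contaminated <- stats::runif(sc$d) < sc$contamination_rate
  ifelse(contaminated, stats::runif(sc$d, 0, 0.3), 0)
}

## Simulate one individual's two haplotypes (P2-allele indicator per
## marker) through the recursive pedigree.  Founders of line P1 carry
## the P2-typical allele at the shared frequency u (and conversely for
## P2 founders), which is what makes contaminated markers non-diagnostic.
## Returns list(mat, pat); for males, X entries of pat are NA.
sim_pedigree_ind <- function(spec, sex, classes, u, system) {
  d <- length(classes)
  xcol <- classes == "X"
  hetero_male <- system %in% c("XY", "XO")
  rec <- function(s, sx) {
    if (!is.null(s$line)) {
      base <- if (s$line == "P1") stats::runif(d) < u
              else stats::runif(d) >= u
      hap2 <- if (s$line == "P1") stats::runif(d) < u
              else stats::runif(d) >= u
      out <- list(mat = as.integer(base), pat = as.integer(hap2))
      if (hetero_male && sx == "male") out$pat[xcol] <- NA_integer_
      return(out)
    }
    mo <- rec(s$mother, "female")
    fa <- rec(s$father, "male")
    gam <- function(ind) {
      pick <- stats::runif(d) < 0.5
      g <- ifelse(pick, ind$mat, ind$pat)
      ## a father's X gamete is his single (maternal) X
      na <- is.na(g)
      g[na] <- ind$mat[na]
      g
    }
    child <- list(mat = gam(mo), pat = gam(fa))
    if (hetero_male && sx == "male") child$pat[xcol] <- NA_integer_
    return(child)
  }
  rec(parse_cross(spec), sex)
}

## True coordinates of an individual from its haplotypes, weighting
## markers equally (hemizygous X contributes one copy, no p12).
true_coords_from_haps <- function(mat, pat) {
  hemi <- is.na(pat)
  ## marker-share weighting: a hemizygous marker contributes its single
  ## expressed allele's origin to h at full weight and zero to p12
  hm <- ifelse(hemi, mat, (mat + pat) / 2)
  c(h = mean(hm), p12 = sum(!hemi & mat != pat) / length(mat))
}

#' Generate a marker dataset for a cross design
#'
#' Simulates every individual through its pedigree by independent
#' Mendelian segregation at unlinked markers (X-linked markers follow
#' X inheritance; heterogametic males are hemizygous), applies
#' contamination and missingness, and stores the true generating
#' coordinates alongside the observable genotypes.
#'
#' @param sc a \code{\link{synth_scenario}}.
#' @return a \code{\link{marker_dataset}}; the per-individual true
#'   coordinates are attached as attribute \code{"truth"}.
#' @export
generate_cross_dataset <- function(sc) {
  stopifnot(inherits(sc, "synth_scenario"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(sc$seed)
  classes <- scenario_marker_classes(sc)
  u <- scenario_contamination(sc)
  n_total <- sum(sc$crosses)
  geno <- matrix(NA_integer_, n_total, sc$d)
  ploidy <- matrix(2L, n_total, sc$d)
  ind <- data.frame(individual_id = sprintf("ind%04d", seq_len(n_total)),
                    sex = NA_character_, cross = NA_character_,
                    order = seq_len(n_total), fitness = NA_real_)
  truth <- data.frame(h = numeric(n_total), p12 = numeric(n_total))
  row <- 0L
  sexed <- sc$system %in% c("XY", "XO")
  for (ci in seq_along(sc$crosses)) {
    lab <- names(sc$crosses)[ci]
    for (k in seq_len(sc$crosses[[ci]])) {
      row <- row + 1L
      sex <- if (sexed) sample(c("female", "male"), 1) else "female"
      haps <- sim_pedigree_ind(lab, sex, classes, u, sc$system)
      tc <- true_coords_from_haps(haps$mat, haps$pat)
      truth$h[row] <- tc["h"]
      truth$p12[row] <- tc["p12"]
      hemi <- is.na(haps$pat)
      g <- haps$mat + ifelse(hemi, 0L, haps$pat)
      ploidy[row, hemi] <- 1L
      ## optional mis-scored heterozygous calls on the male X
      if (sc$x_het_error_rate > 0 && any(hemi)) {
        err <- hemi & stats::runif(sc$d) < sc$x_het_error_rate
        g[err] <- 1L
        ploidy[row, err] <- 2L
      }
      geno[row, ] <- g
      ind$sex[row] <- if (sexed) sex else NA_character_
      ind$cross[row] <- lab
    }
  }
  if (sc$missing_rate > 0) {
    miss <- matrix(stats::runif(n_total * sc$d) < sc$missing_rate,
                   n_total, sc$d)
    geno[miss] <- NA_integer_
  }
  markers <- data.frame(marker_id = sprintf("m%03d", seq_len(sc$d)),
                        chrom_class = classes, orientation = 1L)
  markers$shared_freq <- u
  ds <- marker_dataset(geno, ploidy, markers, ind, system = sc$system)
  attr(ds, "truth") <- truth
  ds
}

#' Attach a fitness response driven by the landscape
#'
#' Computes each individual's true breakdown \code{f} from the
#' generating coordinates (not the marker estimates) and draws the
#' response: Gaussian (\code{w + noise} on the linear fitness scale),
#' binomial survival through a logistic link with linear predictor
#' \code{-response_scale * f} (plus a centring constant), ordinal via a
#' logistic latent variable cut at \code{cutpoints}, or viability
#' selection (individuals retained with probability \code{w}).
#'
#' @param ds dataset from \code{\link{generate_cross_dataset}}.
#' @param sc the generating \code{\link{synth_scenario}}.
#' @param seed optional seed for the response draw (defaults to
#'   \code{sc$seed + 1}).
#' @return the dataset with the \code{fitness} column filled (viability
#'   mode: survivors only); generating values are attached in attribute
#'   \code{"truth"} (columns \code{f}, \code{eta}, \code{w}).
#' @export
attach_fitness <- function(ds, sc, seed = NULL) {
  stopifnot(inherits(ds, "marker_dataset"), inherits(sc, "synth_scenario"))
  truth <- attr(ds, "truth")
  if (is.null(truth)) stop("dataset lacks generating coordinates")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(if (is.null(seed)) sc$seed + 1L else as.integer(seed))
  f <- expected_breakdown(fgm_coords(truth$h, truth$p12, validate = FALSE),
                          sc$params, validate = FALSE)
  f <- pmax(f, 0)
  w <- fitness_from_breakdown(f, sc$map)
  eta <- sc$response_scale * (0.5 - f)  # centred fitness-scale predictor
  n <- nrow(truth)
  y <- switch(sc$family,
    gaussian = w + stats::rnorm(n, sd = sc$noise_sd),
    binomial = as.numeric(stats::runif(n) < stats::plogis(eta)),
    ordinal = {
      latent <- eta + stats::rlogis(n)
      findInterval(latent, sort(sc$cutpoints)) + 1
    },
    viability = NA_real_)
  truth$f <- f
  truth$eta <- eta
  truth$w <- w
  if (sc$family == "viability") {
    keep <- stats::runif(n) < w
    ds <- subset_dataset(ds, i = keep)
    truth <- truth[keep, , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    ds$individuals$fitness <- y
  }
  attr(ds, "truth") <- truth
  ds
}

#' Generate wild hybrids scattered over the ancestry triangle
#'
#' Wild hybrid collections cover the fitness surface much more evenly
#' than single crosses.  The default distribution is a mixture of
#' recombinant cross classes (F2 and first/second backcrosses) and
#' individuals at uniformly drawn triangle coordinates (realised by
#' assigning exact marker counts); the result is a
#' \code{\link{marker_dataset}} like any other, so the full
#' estimation pipeline applies.
#'
#' @param sc a \code{\link{synth_scenario}} (its \code{crosses} field is
#'   ignored).
#' @param N number of individuals.
#' @param mixture named weights for components \code{F2}, \code{BC1_P1},
#'   \code{BC1_P2}, \code{BC2_P1}, \code{BC2_P2}, \code{uniform}.
#' @return a \code{\link{marker_dataset}} with attribute \code{"truth"}.
#' @export
generate_wild_dataset <- function(sc, N = 800,
                                  mixture = c(F2 = 0.25, BC1_P1 = 0.15,
                                              BC1_P2 = 0.15, BC2_P1 = 0.1,
                                              BC2_P2 = 0.1,
                                              uniform = 0.25)) {
  stopifnot(inherits(sc, "synth_scenario"), N >= 1)
  if (sc$gX > 0)
    stop("wild-hybrid generation is implemented for autosomal panels")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(sc$seed)
  mixture <- mixture / sum(mixture)
  classes <- scenario_marker_classes(sc)
  u <- scenario_contamination(sc)
  d <- sc$d
  comp <- sample(names(mixture), N, replace = TRUE, prob = mixture)
  geno <- matrix(NA_integer_, N, d)
  truth <- data.frame(h = numeric(N), p12 = numeric(N))
  for (i in seq_len(N)) {
    if (comp[i] == "uniform") {
      h <- stats::runif(1)
      p12 <- stats::runif(1, 0, 2 * min(h, 1 - h))
      cnt <- class_site_counts(h, p12, d)
      dose <- rep.int(c(0L, 2L, 1L), cnt)[sample.int(d)]
      mat <- ifelse(dose == 2L, 1L, ifelse(dose == 1L,
                                           as.integer(stats::runif(d) < 0.5),
                                           0L))
      pat <- dose - mat
    } else {
      haps <- sim_pedigree_ind(comp[i], "female", classes, u, sc$system)
      mat <- haps$mat
      pat <- haps$pat
    }
    tc <- true_coords_from_haps(mat, pat)
    truth$h[i] <- tc["h"]
    truth$p12[i] <- tc["p12"]
    geno[i, ] <- mat + pat
  }
  if (sc$missing_rate > 0) {
    miss <- matrix(stats::runif(N * d) < sc$missing_rate, N, d)
    geno[miss] <- NA_integer_
  }
  markers <- data.frame(marker_id = sprintf("m%03d", seq_len(d)),
                        chrom_class = classes, orientation = 1L)
  markers$shared_freq <- u
  ind <- data.frame(individual_id = sprintf("wh%04d", seq_len(N)),
                    sex = NA_character_, cross = comp,
                    order = seq_len(N), fitness = NA_real_)
  ds <- marker_dataset(geno, matrix(2L, N, d), markers, ind,
                       system = sc$system)
  attr(ds, "truth") <- truth
  ds
}
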