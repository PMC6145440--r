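#' Genome partition into inheritance classes
#'
#' Weights give the share of divergent sites in each expressed class
#' (autosomes, X/Z, Y/W, mitochondria); they must sum to one.  The
#' weight of the X, \code{gX}, is typically estimated as the fraction of
#' coding sequence on the X (see \code{\link{gx_from_annotation}}).
#' Uniparental classes (Y/W, mitochondria) default to weight zero.
#'
#' @param gX weight of the X (or Z) chromosome class.
#' @param gY weight of the Y (or W) class (heterogametic sex only).
#' @param gMito weight of the mitochondrial class.
#' @param system sex-determination system: \code{"XY"}, \code{"XO"},
#'   \code{"ZW"} or \code{"none"}.  In \code{"ZW"} the heterogametic sex
#'   is female and the \code{gX} weight applies to the Z.
#' @return object of class \code{"genome_partition"}.
#' @export
genome_partition <- function(gX = 0, gY = 0, gMito = 0,
                             system = c("XY", "XO", "ZW", "none")) {
  system <- match.arg(system)
  w <- c(A = 1 - gX - gY - gMito, X = gX, Y = gY, mito = gMito)
  if (any(w < -1e-9)) stop("class weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("class weights must sum to 1")
  if (system == "none" && gX > 0)
    stop("an X weight requires a sex-chromosome system")
  structure(list(weights = w, system = system), class = "genome_partition")
}

heterogametic_sex <- function(partition) {
  switch(partition$system, XY = "male", XO = "male", ZW = "female",
         none = NA_character_)
}

#' Paternal X silencing model
#'
#' In the homogametic sex, a fraction \code{pi} of X-linked divergent
#' sites express only the maternally inherited copy (a parent-of-origin
#' dosage-compensation effect).  \code{pi = 0} recovers biparental X
#' expression; \code{pi = 1} makes the female X effectively hemizygous
#' maternal.  In a ZW system the silenced copy is the one inherited from
#' the heterogametic parent.
#'
#' @param pi silenced fraction, in \[0, 1\].
#' @return object of class \code{"silencing_model"}.
#' @export
silencing_model <- function(pi = 0) {
  stopifnot(is.numeric(pi), length(pi) == 1, pi >= 0, pi <= 1)
  structure(list(pi = pi), class = "silencing_model")
}

#' Combine per-class ancestry into effective genome-wide coordinates
#'
#' Weighted combination of per-class coordinates:
#' \code{p12 = sum(g_c * p12_c)} and \code{h = sum(g_c * h_c)}.
#' Hemizygous classes (the X in the heterogametic sex, Y/W,
#' mitochondria) and silenced site fractions are expressed single-copy:
#' they contribute the origin of the expressed allele to \code{h} at
#' full weight and zero to \code{p12}.  With partial silencing
#' \code{pi}, the female X contributes the \code{pi}-weighted mixture of
#' its silenced (maternal single-copy) and biparental values.
#'
#' @param classes named list of per-class coordinates.  Elements:
#'   \code{A = list(h, p12)}; \code{X = list(h, p12, h_maternal)}
#'   (diploid X; \code{h_maternal} is required when silencing acts) or
#'   \code{X = list(h)} for the hemizygous sex; \code{Y = list(h)};
#'   \code{mito = list(h)}.  Classes with zero weight may be omitted.
#' @param partition \code{\link{genome_partition}}.
#' @param silencing \code{\link{silencing_model}} (default: none).
#' @param sex \code{"female"} or \code{"male"}.
#' @return \code{\link{fgm_coords}} with one row; per-class
#'   contributions are attached as attribute \code{"classes"}.
#' @export
effective_coords <- function(classes, partition,
                             silencing = silencing_model(0),
                             sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(inherits(partition, "genome_partition"))
  if (is.null(silencing)) silencing <- silencing_model(0)
  w <- partition$weights
  hemi <- !is.na(heterogametic_sex(partition)) &&
    sex == heterogametic_sex(partition)
  out <- data.frame(class = character(0), weight = numeric(0),
                    h = numeric(0), p12 = numeric(0))
  for (cl in names(w)) {
    if (w[[cl]] == 0) next
    cc <- classes[[cl]]
    if (is.null(cc))
      stop(sprintf("class '%s' has weight %g but no coordinates supplied",
                   cl, w[[cl]]))
    if (cl == "A") {
      hc <- cc$h; pc <- cc$p12
    } else if (cl == "X") {
      if (hemi) {
        hc <- cc$h; pc <- 0      # single expressed copy
      } else {
        pi <- silencing$pi
        if (pi > 0 && is.null(cc$h_maternal))
          stop("paternal X silencing requires h_maternal for the X class")
        hb <- cc$h; pb <- cc$p12
        hm <- if (is.null(cc$h_maternal)) hb else cc$h_maternal
        hc <- pi * hm + (1 - pi) * hb
        pc <- (1 - pi) * pb
      }
    } else {                     # uniparental: Y/W, mito
      hc <- cc$h; pc <- 0
    }
    if (is.null(pc)) stop(sprintf("class '%s' lacks p12", cl))
    out <- rbind(out, data.frame(class = cl, weight = w[[cl]], h = hc,
                                 p12 = pc))
  }
  co <- fgm_coords(sum(out$weight * out$h), sum(out$weight * out$p12))
  attr(co, "classes") <- out
  co
}

## Expected per-class ancestry state of a cross, tracked through the
## pedigree.  State: P2-origin probability of the maternal and paternal
## allele for autosomes and (sex-appropriate) X copies, plus the
## uniparental classes.  Mothers are evaluated as females, fathers as
## males, matching the maternal x paternal cross grammar.
cross_class_state <- function(spec, sex, partition) {
  het <- heterogametic_sex(partition)
  rec <- function(s, sx) {
    if (!is.null(s$line)) {
      a <- if (s$line == "P1") 0 else 1
      return(list(aA_m = a, aA_p = a, aX_m = a, aX_p = a, mito = a,
                  y = a))
    }
    mo <- rec(s$mother, "female")
    fa <- rec(s$father, "male")
    ## gamete P2-probabilities
    gam_A_m <- (mo$aA_m + mo$aA_p) / 2
    gam_A_p <- (fa$aA_m + fa$aA_p) / 2
    if (is.na(het) || het == "male") {
      ## X: mother diploid, father hemizygous (carries maternal X only)
      gam_X_m <- (mo$aX_m + mo$aX_p) / 2
      gam_X_p <- fa$aX_m
    } else {
      ## ZW: father diploid for Z, mother hemizygous (her Z is paternal)
      gam_X_m <- mo$aX_p
      gam_X_p <- (fa$aX_m + fa$aX_p) / 2
    }
    ## Y/W slot: in XY the son's Y is paternal; in ZW the daughter's W
    ## is maternal
    list(aA_m = gam_A_m, aA_p = gam_A_p, aX_m = gam_X_m,
         aX_p = gam_X_p, mito = mo$mito,
         y = if (!is.na(het) && het == "female") mo$y else fa$y)
  }
  rec(parse_cross(spec), sex)
}

## Per-class expected coordinates for one sex of a cross.
cross_class_coords <- function(spec, sex, partition) {
  st <- cross_class_state(spec, sex, partition)
  het <- heterogametic_sex(partition)
  p12 <- function(a, b) a * (1 - b) + (1 - a) * b
  classes <- list(A = list(h = (st$aA_m + st$aA_p) / 2,
                           p12 = p12(st$aA_m, st$aA_p)))
  if (partition$weights[["X"]] > 0) {
    if (!is.na(het) && sex == het) {
      ## single X/Z: maternal in XY/XO males, paternal in ZW females
      classes$X <- list(h = if (het == "male") st$aX_m else st$aX_p)
    } else {
      classes$X <- list(h = (st$aX_m + st$aX_p) / 2,
                        p12 = p12(st$aX_m, st$aX_p),
                        h_maternal = st$aX_m)
    }
  }
  if (partition$weights[["Y"]] > 0) classes$Y <- list(h = st$y)
  if (partition$weights[["mito"]] > 0) classes$mito <- list(h = st$mito)
  classes
}

#' Predicted breakdown gap between F1 sexes (Haldane's rule)
#'
#' Computes the expected breakdown of the heterogametic F1 minus that of
#' the homogametic F1, for a given F1 direction.  A positive gap means
#' the heterogametic sex is the less fit one, i.e. Haldane's rule is
#' predicted.  The gap arises because the heterogametic F1 is
#' hemizygous for one parent's X (or Z) alleles, losing the
#' heterozygosity benefit on that fraction \code{gX} of the genome.
#'
#' @param partition \code{\link{genome_partition}} with a sex-chromosome
#'   system.
#' @param params \code{\link{landscape_params}}.
#' @param silencing \code{\link{silencing_model}} applied to the
#'   homogametic F1.
#' @param maternal which parental line is the mother of the F1
#'   (\code{"P1"} or \code{"P2"}).
#' @return the breakdown difference (heterogametic minus homogametic).
#' @export
haldane_gap <- function(partition, params = landscape_params(),
                        silencing = silencing_model(0), maternal = "P1") {
  stopifnot(inherits(partition, "genome_partition"))
  if (partition$system == "none")
    stop("Haldane's rule requires a sex-chromosome system")
  spec <- if (maternal == "P1") cross_spec("P1", "P2")
          else cross_spec("P2", "P1")
  hetsex <- heterogametic_sex(partition)
  homsex <- if (hetsex == "male") "female" else "male"
  f_het <- expected_breakdown(
    effective_coords(cross_class_coords(spec, hetsex, partition), partition,
                     silencing, sex = hetsex), params)
  f_hom <- expected_breakdown(
    effective_coords(cross_class_coords(spec, homsex, partition), partition,
                     silencing, sex = homsex), params)
  f_het - f_hom
}

#' Selection on autosomal heterozygosity in heterogametic backcross males
#'
#' For backcross males (XY or XO), the direction of selection on
#' autosomal heterozygosity \code{p12,A} depends on the ancestry of the
#' hemizygous X.  On the backcross edge to parent \code{P}, autosomal
#' homozygous sites all carry \code{P} alleles, so
#' \code{hA = p12A/2} (backcross to P1) or \code{1 - p12A/2} (to P2),
#' and the combined coordinates trace a one-parameter path through the
#' landscape as \code{p12A} varies.  This function reports the breakdown
#' along that path, the \code{p12A} minimising it and the sign of
#' \code{df/dp12A} at the class mean \code{p12A = 1/2} (negative means
#' higher heterozygosity is favoured).
#'
#' @param hX_class \code{"low"} (X alleles from P1, \code{hX = 0}) or
#'   \code{"high"} (X alleles from P2, \code{hX = 1}).
#' @param backcross_parent \code{"P1"} or \code{"P2"}.
#' @param partition \code{\link{genome_partition}} (XY or XO).
#' @param params \code{\link{landscape_params}}.
#' @return list with \code{p12A_min} (breakdown-minimising autosomal
#'   heterozygosity), \code{slope_at_mid} (sign of \code{df/dp12A} at
#'   1/2), \code{selection} (\code{"favors_higher"},
#'   \code{"favors_lower"} or \code{"neutral"}) and the breakdown
#'   profile \code{profile} (data frame over \code{p12A}).
#' @export
backcross_male_selection <- function(hX_class = c("low", "high"),
                                     backcross_parent = c("P1", "P2"),
                                     partition, params = landscape_params()) {
  hX_class <- match.arg(hX_class)
  backcross_parent <- match.arg(backcross_parent)
  stopifnot(inherits(partition, "genome_partition"))
  if (!partition$system %in% c("XY", "XO"))
    stop("backcross-male predictions require an XY or XO system")
  gX <- partition$weights[["X"]]
  gA <- partition$weights[["A"]]
  hX <- if (hX_class == "low") 0 else 1
  q <- seq(0, 1, length.out = 201)
  hA <- if (backcross_parent == "P1") q / 2 else 1 - q / 2
  h <- gX * hX + gA * hA
  p12 <- gA * q
  f <- expected_breakdown(fgm_coords(h, p12, validate = FALSE), params,
                          validate = FALSE)
  ## quadratic in q: exact derivative at the class mean q = 1/2
  dq <- 1e-6
  at <- function(qq) {
    hh <- gX * hX + gA * (if (backcross_parent == "P1") qq / 2
                          else 1 - qq / 2)
    expected_breakdown(fgm_coords(hh, gA * qq, validate = FALSE), params,
                       validate = FALSE)
  }
  slope <- (at(0.5 + dq) - at(0.5 - dq)) / (2 * dq)
  sel <- if (abs(slope) < 1e-9) "neutral"
         else if (slope < 0) "favors_higher" else "favors_lower"
  list(p12A_min = q[which.min(f)], slope_at_mid = slope, selection = sel,
       profile = data.frame(p12A = q, f = f))
}

#' Expected breakdown table for a set of crosses, by sex
#'
#' Computes per-class and combined ancestry coordinates, expected
#' breakdown \code{f} and (optionally) fitness \code{w} for each cross
#' and sex, under a genome partition and a paternal-X silencing model.
#' This reproduces the structure of cricket-style cross tables: with
#' complete silencing and an asymmetrically maladapted parent, the
#' reciprocal F1 females differ in predicted fitness even though their
#' chromosomes are identical.
#'
#' @param crosses list (or character vector) of cross specifications.
#' @param partition \code{\link{genome_partition}}.
#' @param silencing \code{\link{silencing_model}}.
#' @param params \code{\link{landscape_params}}.
#' @param map optional \code{\link{fitness_map}} for a fitness column.
#' @param sexes sexes to tabulate.
#' @return data frame with one row per cross and sex.
#' @export
cross_prediction_table <- function(crosses, partition,
                                   silencing = silencing_model(0),
                                   params = landscape_params(),
                                   map = NULL,
                                   sexes = c("female", "male")) {
  stopifnot(inherits(partition, "genome_partition"))
  if (is.character(crosses)) crosses <- as.list(crosses)
  rows <- list()
  for (ci in seq_along(crosses)) {
    spec <- parse_cross(crosses[[ci]])
    label <- if (is.character(crosses[[ci]])) crosses[[ci]]
             else deparse_cross(spec)
    for (sx in sexes) {
      cls <- cross_class_coords(spec, sx, partition)
      co <- effective_coords(cls, partition, silencing, sex = sx)
      f <- expected_breakdown(co, params)
      rows[[length(rows) + 1]] <- data.frame(
        cross = label, sex = sx,
        h_A = cls$A$h, p12_A = cls$A$p12,
        h_X = if (!is.null(cls$X)) cls$X$h else NA_real_,
        p12_X = if (!is.null(cls$X$p12)) cls$X$p12 else
          if (!is.null(cls$X)) 0 else NA_real_,
        h = co$h, p12 = co$p12, f = f,
        w = if (is.null(map)) NA_real_ else
          fitness_from_breakdown(max(f, 0), map))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(map)) out$w <- NULL
  rownames(out) <- NULL
  out
}
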