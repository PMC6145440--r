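test_that("marker tables round-trip with schema validation", {
  geno <- rbind(c(0, 1, 2), c(1, 1, NA), c(2, 0, 1))
  paths <- write_marker_fixture(geno)
  ds <- read_marker_table(paths$geno, paths$meta)
  expect_equal(dim(ds), c(3L, 3L))
  expect_equal(unname(ds$geno[1, ]), c(0, 1, 2))
  expect_true(is.na(ds$geno[2, 3]))
  ## out-of-range dosage names the offending cell
  geno_bad <- geno
  geno_bad[2, 2] <- 3
  paths2 <- write_marker_fixture(geno_bad)
  expect_error(read_marker_table(paths2$geno, paths2$meta),
               "invalid genotype code '3'.*i02.*m02")
  ## duplicated marker ids rejected
  meta <- read.delim(paths$meta)
  meta$marker_id <- c("m01", "m01", "m03")
  dup <- withr::local_tempfile(fileext = ".tsv")
  write.table(meta, dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(marker_dataset(matrix(0, 2, 3),
                              markers = read.delim(dup)), "duplicated")
})

test_that("hemizygous male X calls become single-copy states", {
  geno <- rbind(c(2, 1), c(0, 1), c(1, 1))
  paths <- write_marker_fixture(geno, classes = c("X", "A"),
                                sex = c("male", "male", "male"))
  expect_warning(ds <- read_marker_table(paths$geno, paths$meta,
                                         system = "XO"),
                 "heterozygous hemizygous")
  expect_equal(unname(ds$ploidy[, 1]), c(1L, 1L, 1L))
  expect_equal(unname(ds$geno[, 1]), c(1L, 0L, NA))
  ## strict mode drops the offending individual instead
  expect_silent(ds2 <- read_marker_table(paths$geno, paths$meta,
                                         system = "XO", strict = TRUE))
  expect_equal(nrow(ds2$geno), 2L)
})

test_that("F1-heterozygosity filtering keeps verifiable markers only", {
  ## marker 1: het in both F1; marker 2: het in 1/2; marker 3: missing
  geno <- rbind(c(1, 1, 1), c(1, 0, NA), c(0, 2, 1))
  paths <- write_marker_fixture(geno)
  ds <- read_marker_table(paths$geno, paths$meta)
  kept <- filter_f1_heterozygous(ds, c("i01", "i02"))
  expect_equal(kept$markers$marker_id, "m01")
  expect_error(filter_f1_heterozygous(ds, "nobody"), "unknown F1")
})

test_that("diagnostic filtering applies the frequency threshold and flips", {
  ## panels of 2 diploid individuals each; marker freqs (pop1 vs pop2):
  ## m1: 0.00 vs 1.00 (kept), m2: 0.05-ish 0/0 vs 0.75 (dropped at 0.9),
  ## m3: 1.00 vs 0.00 (kept but needs flipping)
  geno <- rbind(c(0, 0, 2), c(0, 0, 2),   # pop1
                c(2, 2, 0), c(2, 1, 0),   # pop2
                c(1, 1, 1))               # a hybrid
  paths <- write_marker_fixture(geno)
  ds <- read_marker_table(paths$geno, paths$meta)
  out <- diagnostic_markers(ds, c("i01", "i02"), c("i03", "i04"))
  expect_equal(out$markers$marker_id, c("m01", "m03"))
  expect_equal(out$markers$orientation, c(1L, -1L))
  ## after re-orientation the hybrid's dosages count the pop2 allele
  expect_equal(unname(out$geno[5, ]), c(1, 1))
  expect_equal(unname(out$geno[3, ]), c(2, 2))
  ## threshold 0 keeps markers with any difference
  all3 <- diagnostic_markers(ds, c("i01", "i02"), c("i03", "i04"),
                             threshold = 0)
  expect_equal(ncol(all3$geno), 3L)
  expect_error(diagnostic_markers(ds, character(0), "i03"), "nonempty")
  ## an untyped marker in a panel is an error, not a silent drop
  geno_na <- geno
  geno_na[1:2, 2] <- NA
  paths2 <- write_marker_fixture(geno_na)
  ds2 <- read_marker_table(paths2$geno, paths2$meta)
  expect_error(diagnostic_markers(ds2, c("i01", "i02"), c("i03", "i04")),
               "untyped.*m02")
})

test_that("individual coordinates follow the scored-marker conventions", {
  ## 10 markers: 4 het, 3 P2-hom, 3 P1-hom
  geno <- matrix(c(rep(1, 4), rep(2, 3), rep(0, 3)), nrow = 1)
  ds <- marker_dataset(geno)
  co <- individual_coords(ds)
  expect_equal(co$p12, 0.4)
  expect_equal(co$h, 0.5)
  ## missing calls drop out of the denominators
  geno2 <- matrix(c(rep(1, 4), rep(2, 2), rep(0, 2), NA, NA), nrow = 1)
  co2 <- individual_coords(marker_dataset(geno2))
  expect_equal(co2$p12, 0.5)
  expect_equal(co2$h, 0.5)
  expect_equal(co2$missingness, 0.2)
  ## XO male: X markers single-copy P2, autosomes all het, gX = 0.5
  geno3 <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1), nrow = 1)
  ploidy3 <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), nrow = 1)
  markers3 <- data.frame(marker_id = paste0("m", 1:8),
                         chrom_class = rep(c("X", "A"), each = 4),
                         orientation = 1L)
  ds3 <- marker_dataset(geno3, ploidy3, markers3, system = "XO")
  co3 <- individual_coords(ds3, genome_partition(gX = 0.5,
                                                 system = "XO"))
  expect_equal(co3$h, 0.75)
  expect_equal(co3$p12, 0.5)
  expect_equal(co3$h_X, 1)
  expect_equal(co3$h_A, 0.5)
  ## an individual with nothing scored in a weighted class errors
  geno4 <- geno3
  geno4[1, 1:4] <- NA
  ds4 <- marker_dataset(geno4, ploidy3, markers3, system = "XO")
  expect_error(individual_coords(ds4, genome_partition(gX = 0.5,
                                                       system = "XO")),
               "no scored markers")
})

test_that("estimates are invariant to marker order and re-orientation", {
  set.seed(40)
  geno <- matrix(sample(0:2, 200, replace = TRUE), nrow = 10)
  ds <- marker_dataset(geno)
  co <- individual_coords(ds)
  perm <- sample(ncol(geno))
  co_perm <- individual_coords(fgmhybrid:::subset_dataset(ds, j = perm))
  expect_equal(co_perm$h, co$h)
  expect_equal(co_perm$p12, co$p12)
  ## flipping a marker's input coding is undone by panel re-orientation,
  ## so downstream coordinates do not depend on the input allele coding
  panel <- rbind(matrix(0, 3, 4), matrix(2, 3, 4),
                 matrix(sample(0:2, 20, replace = TRUE), 5, 4))
  ds_a <- marker_dataset(panel)
  panel_b <- panel
  panel_b[, 2] <- 2 - panel_b[, 2]
  ds_b <- marker_dataset(panel_b)
  ids <- ds_a$individuals$individual_id
  out_a <- diagnostic_markers(ds_a, ids[1:3], ids[4:6], threshold = 0.5)
  out_b <- diagnostic_markers(ds_b, ids[1:3], ids[4:6], threshold = 0.5)
  expect_equal(individual_coords(out_b)$h, individual_coords(out_a)$h)
  expect_equal(individual_coords(out_b)$p12, individual_coords(out_a)$p12)
})

test_that("missingness QC flags informative missingness only", {
  set.seed(41)
  n <- 20
  geno <- matrix(sample(0:2, n * 30, replace = TRUE), nrow = n)
  ds <- marker_dataset(geno)
  ds$individuals$fitness <- rnorm(n)
  qc <- missingness_qc(ds)
  expect_true(all(qc$pass))  # zero missingness: undefined, pass
  expect_true(all(is.na(qc$rho)))
  ## missingness tracking heterozygosity is flagged
  het <- rowMeans(geno == 1)
  ds2 <- ds
  for (i in seq_len(n)) {
    k <- round(rank(het)[i])
    if (k > 1) ds2$geno[i, seq_len(k - 1)] <- NA
  }
  qc2 <- missingness_qc(ds2)
  het_row <- qc2[qc2$check == "heterozygosity", ]
  expect_false(het_row$pass)
  expect_gt(het_row$rho, 0.5)
  ## independent missingness passes at roughly the nominal rate
  fails <- 0L
  for (r in 1:100) {
    g <- matrix(sample(0:2, 15 * 20, replace = TRUE), nrow = 15)
    g[matrix(runif(300) < 0.15, 15, 20)] <- NA
    dsr <- marker_dataset(g)
    dsr$individuals$fitness <- rnorm(15)
    if (any(!missingness_qc(dsr)$pass)) fails <- fails + 1L
  }
  expect_lte(fails, 3L)  # ~0.2% nominal across 200 tests
})

test_that("subsampling rules act exactly and log exclusions", {
  geno <- rbind(c(1, 1, 1), c(0, 1, 2), c(1, NA, 1), c(2, 2, 2))
  ds <- marker_dataset(geno)
  ds$individuals$order <- c(3, 1, 4, 2)
  dm <- subsample_rules(ds, "drop_missing_any")
  expect_equal(nrow(dm$geno), 3L)
  expect_equal(attr(dm, "excluded")$individual_id, "ind3")
  ## complete data: identity
  full <- fgmhybrid:::subset_dataset(ds, i = c(1, 2, 4))
  expect_equal(nrow(subsample_rules(full, "drop_missing_any")$geno), 3L)
  ## purge backcrosses carrying the non-recurrent parent's homozygote
  bp <- subsample_rules(ds, "bc_purge", purge_dosage = 0)
  expect_equal(bp$individuals$individual_id, c("ind1", "ind3", "ind4"))
  expect_match(attr(bp, "excluded")$reason, "dosage-0")
  ## first n by sequencing order, ties by input order
  fn <- subsample_rules(ds, "first_n_by_order", n = 2)
  expect_setequal(fn$individuals$individual_id, c("ind2", "ind4"))
  ds$individuals$order <- rep(NA_real_, 4)
  expect_error(subsample_rules(ds, "first_n_by_order", n = 2),
               "order metadata")
})

test_that("hX classification needs unanimous X markers", {
  geno <- rbind(c(0, 0, 1), c(1, 1, 0), c(0, 1, 2), c(NA, 0, 1))
  ploidy <- cbind(matrix(1L, 4, 2), matrix(2L, 4, 1))
  markers <- data.frame(marker_id = c("x1", "x2", "a1"),
                        chrom_class = c("X", "X", "A"), orientation = 1L)
  ds <- marker_dataset(geno, ploidy, markers, system = "XY")
  expect_warning(cls <- classify_hX(ds, c("x1", "x2")), "missing X")
  expect_equal(cls$hX_class, c("low", "high", "intermediate",
                               "intermediate"))
  expect_equal(cls$missing_x, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(classify_hX(ds, "x9"), "unknown X marker")
})

test_that("coordinates recovered from simulated crosses are Mendelian", {
  sc <- synth_scenario(d = 200, crosses = c(F2 = 150, BC1_P1 = 150),
                       seed = 50)
  ds <- generate_cross_dataset(sc)
  co <- individual_coords(ds)
  f2 <- ds$individuals$cross == "F2"
  expect_lt(abs(mean(co$p12[f2]) - 0.5), 0.02)
  expect_lt(abs(mean(co$h[f2]) - 0.5), 0.02)
  expect_lt(abs(mean(co$h[!f2]) - 0.25), 0.02)
  expect_lt(abs(mean(co$p12[!f2]) - 0.5), 0.02)
})
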