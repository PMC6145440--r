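## Independent oracles and tiny fixture builders used across tests.

## All 3^d diploid genotypes at d divergent sites, as dosage rows.
enumerate_genotypes <- function(d) {
  as.matrix(expand.grid(rep(list(0:2), d)))
}

## Brute-force breakdown of one genotype: sum the carried effect
## vectors term by term (heterozygous once, homozygous twice, with the
## P1 allele derived at lineage-1 sites) and apply S = sum(lambda z^2).
## Written independently of breakdown_score's matrix algebra.
oracle_breakdown <- function(dosage, div) {
  z <- rep(0, div$traits$n)
  for (s in seq_len(div$d)) {
    copies <- if (div$lineage[s] == 1L) 2 - dosage[s] else dosage[s]
    z <- z + copies * div$effects[s, ]
  }
  sum(div$traits$lambda * (z - div$traits$optimum)^2)
}

## Class-conditional mean of f over the exhaustive genotype set.
oracle_class_mean_f <- function(div, n1, n2, n12) {
  G <- enumerate_genotypes(div$d)
  sel <- rowSums(G == 0) == n1 & rowSums(G == 2) == n2 &
    rowSums(G == 1) == n12
  vals <- apply(G[sel, , drop = FALSE], 1, oracle_breakdown, div = div)
  mean(vals) / (div$d * sum(div$traits$lambda * div$traits$v))
}

## Per-genotype DMI breakdown by literal tuple enumeration (ell = 2):
## loop over all site pairs and look up the severity of each pair's
## configuration.
oracle_dmi_pairs <- function(dosage, severity) {
  d <- length(dosage)
  tot <- 0
  npair <- 0
  for (s in seq_len(d - 1)) for (t in (s + 1):d) {
    i <- sum(dosage[c(s, t)] == 0)
    j <- sum(dosage[c(s, t)] == 2)
    k <- sum(dosage[c(s, t)] == 1)
    row <- severity$i == i & severity$j == j & severity$k == k
    tot <- tot + severity$s[row]
    npair <- npair + 1
  }
  tot / npair
}

## Minimal marker-table fixture written to temp files; returns paths.
write_marker_fixture <- function(geno, classes = NULL, sex = NULL,
                                 cross = NULL, fitness = NULL,
                                 dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  n <- nrow(geno)
  m <- ncol(geno)
  ids <- sprintf("i%02d", seq_len(n))
  mids <- sprintf("m%02d", seq_len(m))
  tab <- data.frame(individual_id = ids,
                    sex = sex %||% rep(NA, n),
                    cross = cross %||% rep("F2", n),
                    order = seq_len(n),
                    fitness = fitness %||% rep(NA, n))
  gtab <- as.data.frame(geno)
  names(gtab) <- mids
  path <- file.path(dir, "geno.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  utils::write.table(cbind(tab, gtab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(marker_id = mids,
               chrom_class = classes %||% rep("A", m)),
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(geno = path, meta = meta_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Toy GFF3 with two genes: an X-linked gene whose longest isoform has
## summed CDS 370 (two exons 300 + 70, with a shorter 200 nt isoform),
## and an autosomal gene with a single 630 nt CDS, plus a Y gene that
## must be excluded.  gX = 370 / 1000 = 0.37.
write_toy_gff <- function(path) {
  lines <- c(
    "##gff-version 3",
    "X\ttoy\tgene\t1\t5000\t.\t+\t.\tID=gene1",
    "X\ttoy\tmRNA\t1\t5000\t.\t+\t.\tID=tx1a;Parent=gene1",
    "X\ttoy\tCDS\t101\t400\t.\t+\t0\tID=cds1a;Parent=tx1a",
    "X\ttoy\tCDS\t1001\t1070\t.\t+\t0\tID=cds1b;Parent=tx1a",
    "X\ttoy\tmRNA\t1\t5000\t.\t+\t.\tID=tx1b;Parent=gene1",
    "X\ttoy\tCDS\t101\t300\t.\t+\t0\tID=cds1c;Parent=tx1b",
    "2\ttoy\tgene\t1\t9000\t.\t-\t.\tID=gene2",
    "2\ttoy\tmRNA\t1\t9000\t.\t-\t.\tID=tx2;Parent=gene2",
    "2\ttoy\tCDS\t501\t1130\t.\t-\t0\tID=cds2;Parent=tx2",
    "Y\ttoy\tgene\t1\t2000\t.\t+\t.\tID=gene3",
    "Y\ttoy\tmRNA\t1\t2000\t.\t+\t.\tID=tx3;Parent=gene3",
    "Y\ttoy\tCDS\t1\t900\t.\t+\t0\tID=cds3;Parent=tx3")
  writeLines(lines, path)
  path
}
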