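#' Estimate chromosome-class weights from an annotated genome
#'
#' The weight of the X, \code{gX}, is estimated as the total length of
#' X-linked coding sequence divided by the total coding-sequence length,
#' counting one isoform per gene (the one with the longest summed CDS)
#' and excluding the listed chromosomes (Y and mitochondrion by
#' default).  Lengths are summed in nucleotides; the ratio is identical
#' whether protein or nucleotide lengths are used.
#'
#' Annotation is read with \pkg{rtracklayer} from GFF3 or GTF.  CDS
#' features are assigned to transcripts via \code{Parent} (GFF3) or
#' \code{transcript_id} (GTF), and transcripts to genes via the
#' \code{mRNA}/\code{transcript} features' \code{Parent} or the
#' \code{gene_id} attribute; CDS features with no gene assignment are
#' grouped by their own ID and counted per chromosome (their number is
#' reported).
#'
#' @param gff_path path to a GFF3 or GTF file.
#' @param x_chromosomes chromosome (seqid) names counted as X-linked.
#' @param excluded_chromosomes seqids excluded from the totals.
#' @return a \code{\link{genome_partition}} (system \code{"XY"}) with
#'   attributes \code{"cds_by_chrom"} (named lengths) and
#'   \code{"unassigned_genes"}.
#' @export
gx_from_annotation <- function(gff_path, x_chromosomes = "X",
                               excluded_chromosomes = c("Y", "MT")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("gx_from_annotation requires the rtracklayer package")
  gr <- rtracklayer::import(gff_path)
  meta <- as.data.frame(gr)
  if (!"type" %in% names(meta)) stop("annotation lacks feature types")
  cds <- meta[meta$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features in annotation")
  first_chr <- function(x) as.character(x)[1]

  ## transcript id of each CDS row
  tx_of_cds <- if ("Parent" %in% names(cds) &&
                   any(lengths(cds$Parent) > 0)) {
    vapply(cds$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
  } else if ("transcript_id" %in% names(cds)) {
    as.character(cds$transcript_id)
  } else NA_character_
  tx_of_cds[is.na(tx_of_cds)] <-
    paste0(".orphan", seq_len(sum(is.na(tx_of_cds))))

  ## gene id of each transcript
  tx_meta <- meta[meta$type %in% c("mRNA", "transcript"), , drop = FALSE]
  gene_of_tx <- character(0)
  if (nrow(tx_meta)) {
    ids <- if ("ID" %in% names(tx_meta)) as.character(tx_meta$ID)
           else as.character(tx_meta$transcript_id)
    parents <- if ("Parent" %in% names(tx_meta) &&
                   any(lengths(tx_meta$Parent) > 0)) {
      vapply(tx_meta$Parent, function(p)
        if (length(p)) as.character(p)[1] else NA_character_, character(1))
    } else if ("gene_id" %in% names(tx_meta)) {
      as.character(tx_meta$gene_id)
    } else rep(NA_character_, nrow(tx_meta))
    gene_of_tx <- stats::setNames(parents, ids)
  }
  gene_id <- gene_of_tx[tx_of_cds]
  if ("gene_id" %in% names(cds)) {
    fill <- is.na(gene_id) & !is.na(cds$gene_id)
    gene_id[fill] <- as.character(cds$gene_id)[fill]
  }
  unassigned <- sum(is.na(gene_id))
  gene_id[is.na(gene_id)] <- tx_of_cds[is.na(gene_id)]

  cds_len <- tapply(cds$width, tx_of_cds, sum)
  tx_chrom <- tapply(as.character(cds$seqnames), tx_of_cds, first_chr)
  tx_gene <- tapply(gene_id, tx_of_cds, first_chr)

  ## longest summed-CDS isoform per gene
  by_gene <- split(seq_along(cds_len), tx_gene)
  pick <- vapply(by_gene, function(ix) ix[which.max(cds_len[ix])],
                 integer(1))
  gene_len <- cds_len[pick]
  gene_chrom <- tx_chrom[pick]

  keep <- !(gene_chrom %in% excluded_chromosomes)
  totals <- tapply(gene_len[keep], gene_chrom[keep], sum)
  grand <- sum(totals)
  if (grand == 0) stop("no CDS length outside the excluded chromosomes")
  gX <- sum(totals[names(totals) %in% x_chromosomes]) / grand
  part <- genome_partition(gX = gX, system = "XY")
  attr(part, "cds_by_chrom") <- totals
  attr(part, "unassigned_genes") <- unassigned
  part
}
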