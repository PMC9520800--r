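# Fixtures are built in code at test time; nothing binary is stored.

# one-gene plus-strand frame covering [utr_start, search_end)
fixture_frame <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                          utr_start = 100, utr_end = 2100,
                          search_end = NULL, mode = "default") {
  if (is.null(search_end)) {
    search_end <- if (strand == "+") utr_end else utr_start
  }
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    utr_start = utr_start, utr_end = utr_end,
    search_end = search_end, mode = mode
  )
}

# transcripts tibble for build_utr_frames tests
fixture_transcripts <- function(gene_id = "g1", strand = "+",
                                tx_start = 100, tx_ends = c(500, 800),
                                cds_end_3p = 300, chrom = "chr1") {
  tibble::tibble(
    gene_id = gene_id,
    transcript_id = paste0(gene_id, ".", seq_along(tx_ends)),
    chrom = chrom, strand = strand,
    tx_start = tx_start, tx_end = tx_ends,
    cds_end_3p = cds_end_3p,
    exons = lapply(tx_ends, function(e) cbind(start = tx_start, end = e))
  )
}

# write a tiny SAM and convert to a sorted, indexed BAM
fixture_bam <- function(reads, chrom = "chr1", chrom_len = 1000,
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)
  )
  body <- vapply(seq_len(nrow(reads)), function(i) {
    len <- reads$end[i] - reads$start[i]
    sprintf(
      "r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
      i, chrom, reads$start[i] + 1, len,
      strrep("A", len), strrep("I", len)
    )
  }, character(1))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE)
  bam
}

# independent Pearson chi-square oracle (stats::chisq.test)
oracle_chi2 <- function(a, b, c, d) {
  ct <- suppressWarnings(stats::chisq.test(matrix(c(a, c, b, d), 2), correct = FALSE))
  list(stat = unname(ct$statistic), p = unname(ct$p.value))
}

# independent AUC oracle: pairwise concordance (Mann-Whitney)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
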