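test_that("refFlat lines map onto transcripts with 0-based half-open coordinates", {
  rf <- withr::local_tempfile(fileext = ".refFlat")
  writeLines("g1\ttx1\tchr1\t+\t100\t500\t150\t300\t1\t100,\t500,", rf)
  tx <- load_annotation(rf, "refflat")
  expect_equal(nrow(tx), 1)
  expect_equal(tx$tx_start, 100)
  expect_equal(tx$tx_end, 500)
  expect_equal(tx$cds_end_3p, 300)
  expect_equal(tx$exons[[1]], cbind(start = 100, end = 500))

  # minus strand: the CDS 3' boundary is cdsStart
  rf2 <- withr::local_tempfile(fileext = ".refFlat")
  writeLines("g2\ttx2\tchr1\t-\t100\t500\t150\t300\t1\t100,\t500,", rf2)
  expect_equal(load_annotation(rf2, "refflat")$cds_end_3p, 150)
})

test_that("empty annotation yields an empty transcript table", {
  rf <- withr::local_tempfile(fileext = ".refFlat")
  writeLines(character(), rf)
  expect_equal(nrow(load_annotation(rf, "refflat")), 0)
})

test_that("parse errors name the offending line; unknown dialect errors", {
  rf <- withr::local_tempfile(fileext = ".refFlat")
  writeLines(c(
    "g1\ttx1\tchr1\t+\t100\t500\t150\t300\t1\t100,\t500,",
    "truncated\tline"
  ), rf)
  expect_error(load_annotation(rf, "refflat"), "line 2")
  expect_error(load_annotation(rf, "bed"), "dialect")
})

test_that("GTF 1-based coordinates convert to 0-based on load", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0(
      "chr1\ttest\texon\t101\t500\t.\t+\t.\t",
      'gene_id "g1"; transcript_id "t1";'
    ),
    paste0(
      "chr1\ttest\tCDS\t101\t300\t.\t+\t0\t",
      'gene_id "g1"; transcript_id "t1";'
    )
  ), gtf)
  tx <- load_annotation(gtf, "gtf")
  expect_equal(tx$tx_start, 100)
  expect_equal(tx$tx_end, 500)
  expect_equal(tx$cds_end_3p, 300)
})

test_that("default frames run from the stop codon to the 3'-most transcript end", {
  tx <- fixture_transcripts(tx_ends = c(500, 800), cds_end_3p = 300)
  fr <- build_utr_frames(tx)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$utr_start, 300)
  expect_equal(fr$utr_end, 800)
  expect_equal(fr$search_end, 800)

  ext <- build_utr_frames(tx, mode = "extended")
  expect_equal(ext$search_end, 10800)
})

test_that("minus-strand frames mirror the extension and clip at zero", {
  tx <- tibble::tibble(
    gene_id = "gm", transcript_id = "gm.1", chrom = "chr1", strand = "-",
    tx_start = 400, tx_end = 1200, cds_end_3p = 900,
    exons = list(cbind(start = 400, end = 1200))
  )
  fr <- build_utr_frames(tx, mode = "extended")
  expect_equal(fr$utr_start, 400)
  expect_equal(fr$utr_end, 900)
  expect_equal(fr$search_end, 0) # 400 - 10000, clipped
})

test_that("degenerate genes are skipped with a warning", {
  both <- dplyr::bind_rows(
    fixture_transcripts("gx", strand = "+"),
    fixture_transcripts("gx", strand = "-")
  )
  expect_warning(f1 <- build_utr_frames(both), "both strands")
  expect_equal(nrow(f1), 0)

  nc <- fixture_transcripts("gy")
  nc$cds_end_3p <- NA_real_
  expect_warning(f2 <- build_utr_frames(nc), "no coding")
  expect_equal(nrow(f2), 0)

  short <- fixture_transcripts("gz", tx_ends = 330, cds_end_3p = 300)
  expect_warning(f3 <- build_utr_frames(short), "shorter")
  expect_equal(nrow(f3), 0)
})

test_that("default search end equals the strand-aware 3'-most end; extended contains default", {
  set.seed(11)
  for (i in 1:20) {
    strand <- sample(c("+", "-"), 1)
    ends <- sort(sample(1000:5000, 3))
    if (strand == "+") {
      tx <- fixture_transcripts("g", strand = "+", tx_start = 500,
        tx_ends = ends, cds_end_3p = 800)
    } else {
      tx <- tibble::tibble(
        gene_id = "g", transcript_id = paste0("t", 1:3), chrom = "chr1",
        strand = "-", tx_start = ends, tx_end = 6000, cds_end_3p = 5500,
        exons = lapply(ends, function(s) cbind(start = s, end = 6000))
      )
    }
    def <- build_utr_frames(tx)
    ext <- build_utr_frames(tx, mode = "extended")
    if (strand == "+") {
      expect_equal(def$search_end, max(ends))
      expect_gte(ext$search_end, def$search_end)
    } else {
      expect_equal(def$search_end, min(ends))
      expect_lte(ext$search_end, def$search_end)
    }
    expect_equal(def$utr_start, ext$utr_start)
    expect_equal(def$utr_end, ext$utr_end)
  }
})

test_that("frames round-trip through BED", {
  tx <- dplyr::bind_rows(
    fixture_transcripts("g1", tx_ends = c(500, 900), cds_end_3p = 300),
    fixture_transcripts("g2", strand = "-", tx_start = 2000,
      tx_ends = 4000, cds_end_3p = 3500)
  )
  fr <- build_utr_frames(tx, mode = "extended")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_frames_bed(fr, bed)
  back <- read_frames_bed(bed)
  cols <- c("gene_id", "chrom", "strand", "utr_start", "utr_end", "search_end", "mode")
  expect_equal(
    as.data.frame(back[cols]),
    as.data.frame(fr[order(fr$gene_id), cols]),
    ignore_attr = TRUE
  )
})

test_that("extended frames overlapping a downstream gene are flagged, not trimmed", {
  tx <- dplyr::bind_rows(
    fixture_transcripts("g1", tx_ends = 800, cds_end_3p = 300),
    fixture_transcripts("g2", tx_start = 5000, tx_ends = 6000, cds_end_3p = 5300)
  )
  ext <- build_utr_frames(tx, mode = "extended")
  g1 <- ext[ext$gene_id == "g1", ]
  expect_true(g1$flag_overlap)
  expect_equal(g1$search_end, 10800) # untouched by the overlap
  expect_false(ext$flag_overlap[ext$gene_id == "g2"])
})
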