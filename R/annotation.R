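# Gene-model parsing and 3'-UTR frame construction.
#
# All coordinates inside the package are 0-based half-open (BED convention).
# refFlat is already in that convention; GTF (1-based closed) is converted on
# load. A "frame" is the genomic interval searched for cleavage sites: the
# 3'-UTR of the transcript whose annotated end is 3'-most, optionally pushed
# a further 10 kb downstream (extended mode) to pick up de novo distal sites.

#' Read transcript models from refFlat or GTF
#'
#' Parses a gene annotation into one row per transcript with coordinates
#' normalised to 0-based half-open intervals. The strand-aware 3' end of the
#' coding sequence (`cds_end_3p`, the boundary just past the stop codon) is
#' recorded per transcript; non-coding transcripts carry `NA` there.
#'
#' @param path Path to the annotation file.
#' @param dialect `"refflat"` (11-column UCSC refFlat) or `"gtf"`.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `cds_end_3p` and a list-column `exons`
#'   of two-column matrices (start, end), sorted and non-overlapping.
#' @examples
#' rf <- tempfile(fileext = ".refFlat")
#' writeLines("g1\ttx1\tchr1\t+\t100\t500\t150\t300\t1\t100,\t500,", rf)
#' load_annotation(rf, "refflat")
#' @export
load_annotation <- function(path, dialect = c("refflat", "gtf")) {
  dialect <- tryCatch(match.arg(dialect),
    error = function(e) abort(paste0("unknown annotation dialect: ", dialect[1]))
  )
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  tx <- switch(dialect,
    refflat = read_refflat(path),
    gtf = read_gtf_transcripts(path)
  )
  validate_transcripts(tx)
  tx
}

read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_transcripts())
  }
  rows <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      abort(sprintf("refFlat parse error at line %d: expected 11 tab-separated fields, got %d", i, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(5, 6, 7, 8, 9)]))
    if (any(is.na(num))) {
      abort(sprintf("refFlat parse error at line %d: non-numeric coordinate field", i))
    }
    starts <- suppressWarnings(as.numeric(strsplit(f[10], ",", fixed = TRUE)[[1]]))
    ends <- suppressWarnings(as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]]))
    if (any(is.na(starts)) || any(is.na(ends)) || length(starts) != length(ends)) {
      abort(sprintf("refFlat parse error at line %d: malformed exon lists", i))
    }
    cds_start <- num[3]
    cds_end <- num[4]
    coding <- cds_end > cds_start
    tibble(
      gene_id = f[1], transcript_id = f[2], chrom = f[3], strand = f[4],
      tx_start = num[1], tx_end = num[2],
      cds_end_3p = if (!coding) NA_real_ else if (f[4] == "+") cds_end else cds_start,
      exons = list(cbind(start = starts, end = ends))
    )
  })
  bind_rows(rows)
}

read_gtf_transcripts <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(paste0("GTF parse error in ", path, ": ", conditionMessage(e)))
  )
  if (length(gr) == 0) {
    return(empty_transcripts())
  }
  df <- as_tibble(as.data.frame(gr))
  need <- c("type", "transcript_id", "gene_id")
  if (!all(need %in% names(df))) {
    abort("GTF lacks required attributes (gene_id, transcript_id)")
  }
  ex <- df |> filter(.data$type == "exon", !is.na(.data$transcript_id))
  if (nrow(ex) == 0) abort("GTF contains no exon features")
  # 1-based closed -> 0-based half-open: start-1, end unchanged
  ex <- ex |> mutate(start0 = .data$start - 1, end0 = .data$end)
  cds <- df |>
    filter(.data$type %in% c("CDS", "stop_codon"), !is.na(.data$transcript_id)) |>
    mutate(start0 = .data$start - 1, end0 = .data$end) |>
    group_by(.data$transcript_id) |>
    summarise(cds_min = min(.data$start0), cds_max = max(.data$end0), .groups = "drop")
  ex |>
    group_by(.data$gene_id, .data$transcript_id, .data$seqnames, .data$strand) |>
    summarise(
      tx_start = min(.data$start0), tx_end = max(.data$end0),
      exons = list(cbind(
        start = sort(.data$start0),
        end = .data$end0[order(.data$start0)]
      )),
      .groups = "drop"
    ) |>
    left_join(cds, by = "transcript_id") |>
    mutate(
      chrom = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      cds_end_3p = dplyr::if_else(.data$strand == "+", .data$cds_max, .data$cds_min)
    ) |>
    select("gene_id", "transcript_id", "chrom", "strand",
      "tx_start", "tx_end", "cds_end_3p", "exons")
}

empty_transcripts <- function() {
  tibble(
    gene_id = character(), transcript_id = character(), chrom = character(),
    strand = character(), tx_start = numeric(), tx_end = numeric(),
    cds_end_3p = numeric(), exons = list()
  )
}

validate_transcripts <- function(tx) {
  if (nrow(tx) == 0) {
    return(invisible(tx))
  }
  bad <- tx$tx_end <= tx$tx_start
  if (any(bad)) abort(paste0("transcript with tx_end <= tx_start: ", tx$transcript_id[bad][1]))
  ok_exons <- purrr::pmap_lgl(
    list(tx$exons, tx$tx_start, tx$tx_end),
    function(e, s, t) {
      all(e[, "start"] < e[, "end"]) && all(e[, "start"] >= s) && all(e[, "end"] <= t) &&
        (nrow(e) < 2 || all(e[-1, "start"] >= e[-nrow(e), "end"]))
    }
  )
  if (!all(ok_exons)) {
    abort(paste0("malformed exon structure in transcript ", tx$transcript_id[!ok_exons][1]))
  }
  cds_in <- is.na(tx$cds_end_3p) | (tx$cds_end_3p >= tx$tx_start & tx$cds_end_3p <= tx$tx_end)
  if (!all(cds_in)) {
    abort(paste0("CDS 3' end outside transcript span: ", tx$transcript_id[!cds_in][1]))
  }
  invisible(tx)
}

#' Build one 3'-UTR search frame per gene
#'
#' For each gene the defining transcript is the coding transcript whose
#' annotated end is 3'-most (rightmost on `+`, leftmost on `-`): the frame
#' runs from that transcript's stop-codon boundary to the 3'-most annotated
#' transcript end of the gene. In extended mode the searched region continues
#' `extension_bp` further downstream (clipped at position 0) so that
#' unannotated distal polyadenylation sites can be found.
#'
#' Genes whose transcripts disagree on strand, genes without a coding
#' transcript, and genes whose UTR is shorter than `min_utr_length` are
#' skipped with a warning.
#'
#' @param transcripts Tibble from [load_annotation()].
#' @param mode `"default"` (search the annotated 3'-UTR) or `"extended"`
#'   (search a further `extension_bp` downstream).
#' @param extension_bp Downstream extension in bp for extended mode.
#' @param min_utr_length Minimum UTR length (bp) for a gene to be kept.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `utr_start`, `utr_end` (the annotated UTR, 0-based half-open),
#'   `search_end` (the downstream search boundary; equals the 3' UTR boundary
#'   in default mode), `mode`, and `flag_overlap` (`TRUE` when an extended
#'   frame runs into another gene's annotated span; the frame is kept).
#' @examples
#' tx <- tibble::tibble(
#'   gene_id = "g1", transcript_id = c("a", "b"), chrom = "chr1",
#'   strand = "+", tx_start = 100, tx_end = c(500, 800), cds_end_3p = 300,
#'   exons = list(cbind(start = 100, end = 500), cbind(start = 100, end = 800))
#' )
#' build_utr_frames(tx)
#' build_utr_frames(tx, mode = "extended")
#' @export
build_utr_frames <- function(transcripts, mode = c("default", "extended"),
                             extension_bp = 10000, min_utr_length = 50) {
  mode <- match.arg(mode)
  stopifnot(is_tibble(transcripts) || is.data.frame(transcripts))
  frames <- transcripts |>
    group_by(.data$gene_id) |>
    dplyr::group_map(function(g, key) {
      gene <- key$gene_id
      if (length(unique(g$strand)) != 1) {
        warn(paste0("gene ", gene, ": transcripts on both strands; skipped"))
        return(NULL)
      }
      strand <- g$strand[1]
      coding <- g[!is.na(g$cds_end_3p), ]
      if (nrow(coding) == 0) {
        warn(paste0("gene ", gene, ": no coding transcript; skipped"))
        return(NULL)
      }
      if (strand == "+") {
        utr_end <- max(g$tx_end)
        utr_start <- coding$cds_end_3p[which.max(coding$tx_end)]
        search_end <- if (mode == "extended") utr_end + extension_bp else utr_end
      } else {
        utr_start <- min(g$tx_start)
        utr_end <- coding$cds_end_3p[which.min(coding$tx_start)]
        search_end <- if (mode == "extended") max(0, utr_start - extension_bp) else utr_start
      }
      if (utr_end - utr_start < min_utr_length) {
        warn(paste0("gene ", gene, ": 3'-UTR shorter than ", min_utr_length, " bp; skipped"))
        return(NULL)
      }
      tibble(
        gene_id = gene, chrom = g$chrom[1], strand = strand,
        utr_start = utr_start, utr_end = utr_end,
        search_end = search_end, mode = mode
      )
    }) |>
    purrr::compact() |>
    bind_rows()
  if (nrow(frames) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      utr_start = numeric(), utr_end = numeric(), search_end = numeric(),
      mode = character(), flag_overlap = logical()
    ))
  }
  # flag (never trim) extended frames that run into another gene's span
  spans <- transcripts |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(s = min(.data$tx_start), e = max(.data$tx_end), .groups = "drop")
  frames$flag_overlap <- purrr::pmap_lgl(
    frames[c("gene_id", "chrom", "strand", "utr_start", "utr_end", "search_end")],
    function(gene_id, chrom, strand, utr_start, utr_end, search_end) {
      ext <- if (strand == "+") c(utr_end, search_end) else c(search_end, utr_start)
      if (ext[2] <= ext[1]) {
        return(FALSE)
      }
      other <- spans[spans$gene_id != gene_id & spans$chrom == chrom, ]
      any(other$s < ext[2] & other$e > ext[1])
    }
  )
  arrange(frames, .data$chrom, .data$utr_start)
}

# genomic interval actually scanned/covered for a frame row
frame_region <- function(frame) {
  if (frame$strand == "+") {
    c(start = frame$utr_start, end = frame$search_end)
  } else {
    c(start = frame$search_end, end = frame$utr_end)
  }
}

#' Write / read UTR frames as BED
#'
#' Frames are stored as BED6 over the searched region plus two extra columns
#' (`utr_start`, `utr_end`) so that a written file round-trips exactly.
#'
#' @param frames Tibble from [build_utr_frames()].
#' @param path Output path.
#' @return `write_frames_bed()` returns `path` invisibly; `read_frames_bed()`
#'   returns the frames tibble.
#' @export
write_frames_bed <- function(frames, path) {
  reg <- purrr::map(seq_len(nrow(frames)), function(i) frame_region(frames[i, ]))
  out <- tibble(
    chrom = frames$chrom,
    start = purrr::map_dbl(reg, "start"),
    end = purrr::map_dbl(reg, "end"),
    name = paste(frames$gene_id, frames$mode, sep = "|"),
    score = 0L,
    strand = frames$strand,
    utr_start = frames$utr_start,
    utr_end = frames$utr_end
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_frames_bed
#' @export
read_frames_bed <- function(path) {
  bed <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
      "utr_start", "utr_end"),
    col_types = "cddcicdd", progress = FALSE
  )
  name <- stringr::str_split_fixed(bed$name, stringr::fixed("|"), 2)
  tibble(
    gene_id = name[, 1], chrom = bed$chrom, strand = bed$strand,
    utr_start = bed$utr_start, utr_end = bed$utr_end,
    search_end = dplyr::if_else(bed$strand == "+", bed$end, bed$start),
    mode = name[, 2]
  )
}
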