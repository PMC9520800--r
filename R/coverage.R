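# Per-base read-depth tracks.
#
# A coverage track is deliberately minimal: a contig name, a 0-based start,
# and one non-negative depth value per base. Tracks live in list-columns of
# tibbles elsewhere in the package; keeping them as plain vectors (rather
# than per-base rows) keeps a 1000-gene simulation in tens of MB.

#' Construct a coverage track
#'
#' @param chrom Contig name.
#' @param start 0-based start of the covered interval.
#' @param values Non-negative per-base depths; the track covers
#'   `[start, start + length(values))`.
#' @return An object of class `cov_track`.
#' @export
cov_track <- function(chrom, start, values) {
  stopifnot(is.character(chrom), length(chrom) == 1)
  if (length(values) < 1) abort("cov_track: empty value vector")
  if (any(is.na(values)) || any(values < 0)) abort("cov_track: depths must be non-negative")
  structure(
    list(chrom = chrom, start = as.numeric(start), values = as.numeric(values)),
    class = "cov_track"
  )
}

#' @export
print.cov_track <- function(x, ...) {
  cat(sprintf(
    "<cov_track> %s:%d-%d (%d bp), mean depth %.2f\n",
    x$chrom, as.integer(x$start), as.integer(x$start + length(x$values)),
    length(x$values), mean(x$values)
  ))
  invisible(x)
}

#' @export
length.cov_track <- function(x) length(x$values)

track_end <- function(x) x$start + length(x$values)

#' Per-base depth over an interval from a BAM or bedGraph source
#'
#' For BAM input, depth at a base is the number of aligned reads overlapping
#' it; unmapped, secondary, supplementary and duplicate-flagged records are
#' skipped, with an optional mapping-quality floor. For bedGraph input the
#' file's value is used and positions absent from the file are 0.
#'
#' @param source Path to a coordinate-sorted indexed BAM (`.bam`) or a
#'   position-sorted bedGraph (`.bedgraph`/`.bg`/`.bedGraph`).
#' @param chrom,start,end Interval to extract (0-based half-open).
#' @param min_mapq Minimum mapping quality for BAM records (default 0: keep
#'   all mapped primary records).
#' @return A [cov_track()] of length `end - start`.
#' @export
coverage_for_interval <- function(source, chrom, start, end, min_mapq = 0) {
  check_interval(start, end, "coverage interval")
  if (grepl("\\.bam$", source, ignore.case = TRUE)) {
    coverage_from_bam(source, chrom, start, end, min_mapq)
  } else {
    coverage_from_bedgraph(source, chrom, start, end)
  }
}

coverage_from_bam <- function(path, chrom, start, end, min_mapq = 0) {
  bf <- Rsamtools::BamFile(path)
  hdr <- Rsamtools::scanBamHeader(bf)
  if (!chrom %in% names(hdr$targets)) {
    abort(paste0("contig ", chrom, " not present in BAM ", path))
  }
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  sbp <- Rsamtools::ScanBamParam(
    which = which,
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE
    ),
    mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_
  )
  pp <- Rsamtools::PileupParam(
    max_depth = 1e6L, min_base_quality = 0L, min_mapq = as.integer(min_mapq),
    min_nucleotide_depth = 1L, distinguish_strands = FALSE,
    distinguish_nucleotides = FALSE, include_deletions = FALSE,
    include_insertions = FALSE
  )
  p <- Rsamtools::pileup(bf, scanBamParam = sbp, pileupParam = pp)
  values <- numeric(end - start)
  if (nrow(p) > 0) {
    idx <- p$pos - start # pileup pos is 1-based -> offset+1 into values
    keep <- idx >= 1 & idx <= length(values)
    values[idx[keep]] <- p$count[keep]
  }
  cov_track(chrom, start, values)
}

coverage_from_bedgraph <- function(path, chrom, start, end) {
  bg <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = "cddd", comment = "track", progress = FALSE
  )
  if (!chrom %in% bg$chrom) {
    abort(paste0("contig ", chrom, " not present in bedGraph ", path))
  }
  rows <- bg[bg$chrom == chrom, ]
  if (is.unsorted(rows$start) || any(rows$end[-nrow(rows)] > rows$start[-1])) {
    abort(paste0("bedGraph ", path, " is not position-sorted on ", chrom))
  }
  values <- numeric(end - start)
  hit <- rows[rows$end > start & rows$start < end, ]
  for (i in seq_len(nrow(hit))) {
    s <- max(hit$start[i], start) - start + 1
    e <- min(hit$end[i], end) - start
    values[s:e] <- hit$value[i]
  }
  cov_track(chrom, start, values)
}

#' Pool replicate tracks by position-wise sum
#'
#' Replicates within a condition (and pooled 3'-end-seq samples) are combined
#' by summing depth at every base.
#'
#' @param tracks List of [cov_track()] objects over identical intervals.
#' @return A single [cov_track()].
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t1 <- tracks[[1]]
  for (t in tracks[-1]) {
    if (t$chrom != t1$chrom || t$start != t1$start ||
        length(t$values) != length(t1$values)) {
      abort("pool_tracks: tracks cover mismatched intervals")
    }
  }
  vals <- Reduce(`+`, lapply(tracks, `[[`, "values"))
  cov_track(t1$chrom, t1$start, vals)
}

#' Regional depth sum, length and mean
#'
#' The "reads mapped to" a region is taken as its summed per-base depth `r`;
#' dividing by the region length `l` gives the mean coverage used by the
#' ratio statistic.
#'
#' @param track A [cov_track()].
#' @param start,end Sub-interval (0-based half-open), within the track.
#' @return A tibble with columns `r` (summed depth), `l` (length) and
#'   `mean` (`r/l`).
#' @export
region_stats <- function(track, start, end) {
  check_interval(start, end, "region_stats interval")
  if (start < track$start || end > track_end(track)) {
    abort("region_stats: sub-interval outside track extent")
  }
  idx <- (start - track$start + 1):(end - track$start)
  r <- sum(track$values[idx])
  l <- end - start
  tibble(r = r, l = l, mean = r / l)
}

#' Write one or more tracks as bedGraph
#'
#' Runs of equal depth are collapsed; zero-depth runs are omitted, matching
#' the usual sparse bedGraph convention.
#'
#' @param tracks A [cov_track()] or list of them (distinct contigs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "cov_track")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in tracks) {
    r <- rle(t$values)
    ends <- t$start + cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    if (!any(keep)) next
    writeLines(
      sprintf("%s\t%d\t%d\t%g", t$chrom, as.integer(starts[keep]),
        as.integer(ends[keep]), r$values[keep]),
      con
    )
  }
  invisible(path)
}
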