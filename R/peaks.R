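# Peak calling on pooled 3'-end-seq coverage.
#
# A "hill" is a maximal run of strictly positive depth between two
# zero-coverage positions; the position of maximal depth inside the hill is
# the peak, and the peak position is taken as the putative cleavage site
# (the 3'-most position among tied maxima). The alternative reading — the
# hill's 3' boundary — is available via `cleavage = "hill_end"`.

#' Call peaks on a coverage track
#'
#' @param track Pooled 3'-end-seq [cov_track()] over a gene's search region.
#' @param min_height Minimum peak depth for a hill to be reported.
#' @param strand Strand of the gene the track covers; decides which of the
#'   tied maximum positions (and which hill boundary) is 3'-most.
#' @param cleavage `"argmax"` (default): the cleavage position is the peak
#'   position; `"hill_end"`: the hill's 3' boundary (the position just past
#'   the last positive base on `+`, the first positive base on `-`).
#' @return Tibble with one row per hill: `chrom`, `hill_start`, `hill_end`
#'   (half-open), `peak_pos`, `peak_height`, `cleavage_pos`, sorted by
#'   coordinate. An all-zero track yields zero rows.
#' @examples
#' call_peaks(cov_track("chr1", 100, c(0, 1, 3, 5, 2, 0)))
#' @export
call_peaks <- function(track, min_height = 1, strand = c("+", "-"),
                       cleavage = c("argmax", "hill_end")) {
  strand <- match.arg(strand)
  cleavage <- match.arg(cleavage)
  v <- track$values
  r <- rle(v > 0)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  pos_runs <- which(r$values)
  rows <- purrr::map(pos_runs, function(k) {
    i0 <- run_start[k]
    i1 <- run_end[k]
    seg <- v[i0:i1]
    mx <- max(seg)
    if (mx < min_height) {
      return(NULL)
    }
    tied <- i0 - 1 + which(seg == mx) # 1-based track indices of tied maxima
    pk <- if (strand == "+") max(tied) else min(tied)
    hill_start <- track$start + i0 - 1
    hill_end <- track$start + i1
    peak_pos <- track$start + pk - 1
    tibble(
      chrom = track$chrom,
      hill_start = hill_start, hill_end = hill_end,
      peak_pos = peak_pos, peak_height = mx,
      cleavage_pos = switch(cleavage,
        argmax = peak_pos,
        hill_end = if (strand == "+") hill_end else hill_start
      )
    )
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(
      chrom = character(), hill_start = numeric(), hill_end = numeric(),
      peak_pos = numeric(), peak_height = numeric(), cleavage_pos = numeric()
    ))
  }
  arrange(out, .data$hill_start)
}

#' Convert peak calls to cleavage candidates
#'
#' One candidate per peak with `source = "peak"` and the peak height as
#' support. Peaks too close to the frame boundaries (closer than
#' `edge_margin` bp, so that one side of the split would be degenerate) are
#' dropped.
#'
#' @param peaks Tibble from [call_peaks()].
#' @param frame One frame row from [build_utr_frames()].
#' @param edge_margin Minimum distance (bp) from either frame boundary.
#' @return Candidate tibble as in [pas_candidates()].
#' @export
peaks_to_candidates <- function(peaks, frame, edge_margin = 50) {
  if (nrow(peaks) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      position = numeric(), source = character(), motif = character(),
      support = numeric()
    ))
  }
  reg <- frame_region(frame)
  tibble(
    gene_id = frame$gene_id, chrom = peaks$chrom, strand = frame$strand,
    position = peaks$cleavage_pos, source = "peak", motif = NA_character_,
    support = peaks$peak_height
  ) |>
    filter(
      .data$position - reg["start"] >= edge_margin,
      reg["end"] - .data$position >= edge_margin
    )
}

#' Write peak calls as BED
#'
#' Score column carries the peak height.
#' @param peaks Tibble from [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$hill_start, end = peaks$hill_end,
    name = paste0("peak@", peaks$peak_pos), score = peaks$peak_height,
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
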