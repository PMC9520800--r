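# Pipeline wiring: configuration, the detect/simulate/evaluate/plot runners
# used both programmatically and by the inst/cli entry point.

#' Build and validate a run configuration
#'
#' Collects paths, mode switches and thresholds for a detection run. The
#' candidate source resolves automatically: when any 3'-end-seq sample is
#' given the peaks path is used, otherwise PAS hexamers scanned in the
#' genome (which is then required).
#'
#' @param annotation Annotation path.
#' @param annotation_format `"refflat"` or `"gtf"`.
#' @param cond1,cond2 Character vectors of coverage sources (BAM or
#'   bedGraph) for the two conditions.
#' @param genome FASTA path (required for the PAS path).
#' @param endseq1,endseq2 Optional 3'-end-seq sources per condition.
#' @param mode Frame mode, `"default"` or `"extended"`.
#' @param report `"default"` (best site per gene) or `"all"`.
#' @param motifs PAS hexamer set.
#' @param ratio_threshold,alpha Decision thresholds.
#' @param out Output directory.
#' @param seed Seed recorded in outputs (used by the simulator path).
#' @return A validated list of class `apa_config` with a `source` element
#'   (`"peak"` or `"pas"`).
#' @export
apa_config <- function(annotation, annotation_format = c("refflat", "gtf"),
                       cond1, cond2, genome = NULL,
                       endseq1 = NULL, endseq2 = NULL,
                       mode = c("default", "extended"),
                       report = c("all", "default"),
                       motifs = c("AATAAA", "ATTAAA"),
                       ratio_threshold = 0.1, alpha = 0.05,
                       out = ".", seed = 1L) {
  mode <- match.arg(mode)
  report <- match.arg(report)
  annotation_format <- match.arg(annotation_format)
  for (p in c(annotation, cond1, cond2, genome, endseq1, endseq2)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  if (length(cond1) < 1 || length(cond2) < 1) {
    abort("need at least one coverage sample per condition")
  }
  source <- if (length(c(endseq1, endseq2)) > 0) "peak" else "pas"
  if (source == "pas" && is.null(genome)) {
    abort("PAS path requires a genome FASTA (no 3'-end-seq input given)")
  }
  structure(
    list(
      annotation = annotation, annotation_format = annotation_format,
      cond1 = cond1, cond2 = cond2, genome = genome,
      endseq1 = endseq1, endseq2 = endseq2,
      mode = mode, report = report, motifs = motifs,
      ratio_threshold = ratio_threshold, alpha = alpha,
      out = out, seed = as.integer(seed), source = source
    ),
    class = "apa_config"
  )
}

pooled_condition_tracks <- function(sources, frames) {
  tracks <- list()
  for (i in seq_len(nrow(frames))) {
    fr <- frames[i, ]
    reg <- frame_region(fr)
    per_sample <- purrr::map(sources, function(src) {
      coverage_for_interval(src, fr$chrom, reg["start"], reg["end"])
    })
    tracks[[fr$gene_id]] <- pool_tracks(per_sample)
  }
  tracks
}

#' Run the full detection pipeline
#'
#' Frames -> coverage -> candidate sites (peaks or PAS) -> per-site tests ->
#' report files (`report.tsv`, `report.csv`, `candidates.bed`,
#' `frames.bed`). Per-gene stage counts are logged via `message()`.
#'
#' @param config An [apa_config()].
#' @return The `apa_result`, invisibly; report files under `config$out`.
#' @export
run_detect <- function(config) {
  stopifnot(inherits(config, "apa_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  tx <- load_annotation(config$annotation, config$annotation_format)
  frames <- build_utr_frames(tx, mode = config$mode)
  inform(sprintf("frames: %d genes", nrow(frames)))

  if (config$source == "peak") {
    endseq <- c(config$endseq1, config$endseq2)
    cand <- purrr::map(seq_len(nrow(frames)), function(i) {
      fr <- frames[i, ]
      reg <- frame_region(fr)
      pooled <- pool_tracks(purrr::map(endseq, function(src) {
        coverage_for_interval(src, fr$chrom, reg["start"], reg["end"])
      }))
      peaks_to_candidates(call_peaks(pooled, strand = fr$strand), fr)
    }) |> bind_rows()
  } else {
    cand <- pas_candidates(frames, config$genome, motifs = config$motifs)
  }
  cand <- merge_candidates(cand)
  inform(sprintf("candidates: %d sites (%s)", nrow(cand), config$source))

  tracks1 <- pooled_condition_tracks(config$cond1, frames)
  tracks2 <- pooled_condition_tracks(config$cond2, frames)
  res <- detect_events(frames, cand, tracks1, tracks2,
    report = config$report, ratio_threshold = config$ratio_threshold,
    alpha = config$alpha
  )
  inform(sprintf(
    "tested: %d sites, significant: %d", nrow(res), sum(res$significant)
  ))
  write_report(res, file.path(config$out, "report.tsv"))
  write_report(res, file.path(config$out, "report.csv"))
  write_candidates_bed(cand, file.path(config$out, "candidates.bed"))
  write_frames_bed(frames, file.path(config$out, "frames.bed"))
  invisible(res)
}

#' Simulate a dataset and write its fileset
#'
#' @param out Output directory.
#' @param n_genes,n_events,depth,replicates,seed Simulation parameters;
#'   `depth` is a [depth_preset()] label.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the written paths.
#' @export
run_simulate <- function(out, n_genes = 1000, n_events = 500, depth = "30M",
                         replicates = 3, seed, overwrite = FALSE) {
  sim <- simulate_dataset(
    n_genes = n_genes, n_events = n_events,
    depth_scale = depth_preset(depth), replicates = replicates, seed = seed
  )
  write_simulated_dataset(sim, out, overwrite = overwrite)
}

#' Detect events on a simulated dataset and score against its truth
#'
#' In-memory composition of the simulator and detector used by the
#' benchmark: candidate sites are the simulated proximal positions, coverage
#' is pooled per condition, and the detector's calls are scored against the
#' ground-truth labels.
#'
#' @param sim An `apa_sim`.
#' @param candidates Candidate tibble; defaults to [truth_candidates()].
#' @param report Report mode for [detect_events()].
#' @param ... Passed to [detect_events()].
#' @return List with `results` (`apa_result`) and `evaluation` (`apa_eval`).
#' @export
run_benchmark <- function(sim, candidates = truth_candidates(sim),
                          report = "all", ...) {
  frames <- sim_frames(sim)
  res <- detect_events(
    frames, candidates,
    sim_pooled_tracks(sim, "cond1"), sim_pooled_tracks(sim, "cond2"),
    report = report, ...
  )
  truth <- setNames(sim$genes$is_event, sim$genes$gene_id)
  ev <- if (any(truth) && !all(truth)) {
    evaluate_detection(res, truth)
  } else {
    inform("single-class truth: ROC evaluation not applicable")
    NULL
  }
  list(results = res, evaluation = ev)
}

#' Render an event plot for a region string
#'
#' @param config An [apa_config()].
#' @param region `"chrom:start-end"` string.
#' @param out Image path (PNG/PDF).
#' @return The ggplot object, invisibly.
#' @export
run_plot <- function(config, region, out) {
  m <- stringr::str_match(region, "^([^:]+):(\\d+)-(\\d+)$")
  if (is.na(m[1, 1])) {
    abort(paste0("malformed region (expected chrom:start-end): ", region))
  }
  chrom <- m[1, 2]
  start <- as.numeric(m[1, 3])
  end <- as.numeric(m[1, 4])
  tx <- load_annotation(config$annotation, config$annotation_format)
  frames <- build_utr_frames(tx, mode = config$mode)
  frames <- frames[frames$chrom == chrom, ]
  hit <- which(purrr::map_lgl(seq_len(nrow(frames)), function(i) {
    reg <- frame_region(frames[i, ])
    start < reg["end"] && end > reg["start"]
  }))
  if (length(hit) == 0) {
    abort(paste0("region ", region, " overlaps no 3'-UTR frame"))
  }
  fr <- frames[hit[1], ]
  reg <- frame_region(fr)
  s <- max(start, reg["start"])
  e <- min(end, reg["end"])
  rnaseq <- c(
    setNames(
      purrr::map(config$cond1, coverage_for_interval, chrom = chrom, start = s, end = e),
      paste0("cond1.", seq_along(config$cond1))
    ),
    setNames(
      purrr::map(config$cond2, coverage_for_interval, chrom = chrom, start = s, end = e),
      paste0("cond2.", seq_along(config$cond2))
    )
  )
  endseq <- NULL
  if (config$source == "peak") {
    es <- c(config$endseq1, config$endseq2)
    endseq <- setNames(
      purrr::map(es, coverage_for_interval, chrom = chrom, start = s, end = e),
      paste0("endseq.", seq_along(es))
    )
  }
  plot_event(c(s, e), rnaseq, fr, endseq = endseq, out = out)
}
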