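# Two-condition coverage simulator with ground-truth APA events.
#
# The generator works at the depth level: for each gene, replicate and
# condition a transcript count T is drawn from Poisson(mean_expression); a
# fraction p_short of those transcripts ends at the gene's proximal
# polyadenylation site, the rest at the distal (annotated) end. Per-base
# depth is then drawn independently as Poisson(depth_scale * copies), with
# all transcripts covering the UTR upstream of the proximal site and only
# long isoforms covering it downstream. Event genes differ in p_short
# between conditions by more than 0.10; null genes carry only a small
# proportion jitter. Each simulated gene lives on its own contig.

#' Sequencing-depth presets
#'
#' Named mapping from a library-size label to the `depth_scale` parameter
#' (expected per-base depth contributed by one transcript copy). The label is
#' a paired-end library size in read pairs; with the default expression mean
#' of 50 transcript copies, an M-million-pair library of 2 x 76 bp reads
#' spread over a ~100 Mbp expressed transcriptome leaves roughly M/3 x
#' per-base depth on a typical 3'-UTR per replicate, i.e. depth_scale =
#' M/150 per transcript copy. Detection accuracy saturates from the 10M
#' preset upward and degrades below it, reproducing the method's
#' depth-dependence regime.
#'
#' @param preset One of `"2M"`, `"5M"`, `"10M"`, `"30M"`, `"50M"`.
#' @return The `depth_scale` value.
#' @export
depth_preset <- function(preset = c("30M", "2M", "5M", "10M", "50M")) {
  preset <- match.arg(preset)
  c(`2M` = 2, `5M` = 5, `10M` = 10, `30M` = 30, `50M` = 50)[[preset]] / 150
}

#' Simulate a two-condition APA dataset
#'
#' Generates `n_genes` genes, each with one proximal polyadenylation site
#' inside its 3'-UTR, and RNA-seq-like coverage tracks for two conditions
#' with `replicates` technical replicates each. `n_events` genes are true
#' APA events: their short-isoform proportions differ between conditions by
#' an amount drawn uniformly from (0.10, 0.5]. The remaining genes differ by
#' at most `null_jitter`. Expression is Poisson with mean `mean_expression`
#' transcripts per replicate; per-base depth adds independent Poisson noise.
#'
#' @param n_genes Number of genes.
#' @param n_events Number of true APA events (`<= n_genes`).
#' @param mean_expression Poisson mean of the per-replicate transcript count.
#' @param depth_scale Expected per-base depth per transcript copy; see
#'   [depth_preset()].
#' @param replicates Technical replicates per condition.
#' @param seed Integer seed; mandatory, the dataset regenerates
#'   bit-identically from (parameters, seed).
#' @param utr_range Range (bp) from which UTR lengths are drawn uniformly.
#' @param p_short_range Range of baseline short-isoform proportions.
#' @param null_jitter Maximum absolute proportion difference of non-event
#'   genes (must be `<= 0.05`).
#' @return An object of class `apa_sim`: list with `genes` (tibble of
#'   per-gene truth: `gene_id`, `chrom`, `strand`, `utr_length`,
#'   `proximal_offset`, `proximal_pos` (genomic), `expression_rate`,
#'   `p_short_cond1`, `p_short_cond2`, `is_event`), `transcripts` (synthetic
#'   annotation in [load_annotation()] layout), `tracks` (tibble with
#'   `gene_id`, `condition`, `replicate` and a `track` list-column of
#'   [cov_track()]s over the gene's UTR frame), `params`, `seed`.
#' @examples
#' sim <- simulate_dataset(n_genes = 4, n_events = 2, seed = 1)
#' sim$genes
#' @export
simulate_dataset <- function(n_genes, n_events,
                             mean_expression = 50, depth_scale = depth_preset("30M"),
                             replicates = 3, seed,
                             utr_range = c(800, 2000),
                             p_short_range = c(0.10, 0.50),
                             null_jitter = 0.025) {
  if (missing(seed) || is.null(seed)) {
    abort("simulate_dataset: a seed is mandatory (reproducibility)")
  }
  if (n_events > n_genes) abort("simulate_dataset: n_events exceeds n_genes")
  stopifnot(
    n_genes >= 1, mean_expression > 0, depth_scale > 0, replicates >= 1,
    null_jitter <= 0.05, null_jitter >= 0
  )
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  utr_length <- floor(runif(n_genes, utr_range[1], utr_range[2] + 1))
  # proximal site well inside the UTR: room for both flanks and for the
  # distal 3'-end-seq hill to stay separate from the proximal one
  proximal_offset <- floor(runif(n_genes, 0.25 * utr_length, 0.60 * utr_length))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  is_event <- rep(FALSE, n_genes)
  if (n_events > 0) is_event[sample.int(n_genes, n_events)] <- TRUE

  p1 <- numeric(n_genes)
  p2 <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    if (is_event[i]) {
      delta <- runif(1, 0.10, 0.50)
      base <- runif(1, p_short_range[1], p_short_range[2])
      hi <- min(base + delta, 0.95)
      lo <- hi - delta
      if (runif(1) < 0.5) {
        p1[i] <- lo; p2[i] <- hi
      } else {
        p1[i] <- hi; p2[i] <- lo
      }
    } else {
      p1[i] <- runif(1, p_short_range[1], p_short_range[2])
      p2[i] <- min(max(p1[i] + runif(1, -null_jitter, null_jitter), 0), 1)
    }
  }

  pad <- 100 # CDS stub upstream of the stop codon on each synthetic contig
  genes <- tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = sprintf("chr_g%04d", seq_len(n_genes)),
    strand = strand,
    utr_length = utr_length,
    proximal_offset = proximal_offset,
    expression_rate = mean_expression,
    p_short_cond1 = p1,
    p_short_cond2 = p2,
    is_event = is_event
  ) |>
    mutate(
      # UTR occupies [pad, pad + utr_length) on both strands; the CDS stub
      # sits 5' of the stop codon (left on +, right on -)
      tx_start = dplyr::if_else(.data$strand == "+", 0, pad),
      tx_end = dplyr::if_else(.data$strand == "+",
        pad + .data$utr_length, pad + .data$utr_length + pad),
      cds_end_3p = dplyr::if_else(.data$strand == "+", pad,
        pad + .data$utr_length),
      utr_start = pad,
      utr_end = pad + .data$utr_length,
      proximal_pos = dplyr::if_else(.data$strand == "+",
        .data$utr_start + .data$proximal_offset,
        .data$utr_end - .data$proximal_offset
      )
    )

  grid <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    condition = c("cond1", "cond2"),
    replicate = seq_len(replicates)
  )
  gidx <- match(grid$gene_id, genes$gene_id)
  tracks <- purrr::pmap(list(gidx, grid$condition), function(i, cond) {
    g <- genes[i, ]
    p_short <- if (cond == "cond1") g$p_short_cond1 else g$p_short_cond2
    t_total <- rpois(1, mean_expression)
    copies_long <- t_total * (1 - p_short)
    len <- g$utr_length
    off <- g$proximal_offset
    # transcript-orientation lambda: all copies up to the proximal site,
    # long copies beyond it
    lam <- c(
      rep(depth_scale * t_total, off),
      rep(depth_scale * copies_long, len - off)
    )
    if (g$strand == "-") lam <- rev(lam)
    cov_track(g$chrom, g$utr_start, rpois(len, lam))
  })
  grid$track <- tracks

  transcripts <- tibble(
    gene_id = genes$gene_id,
    transcript_id = paste0(genes$gene_id, ".t1"),
    chrom = genes$chrom, strand = genes$strand,
    tx_start = genes$tx_start, tx_end = genes$tx_end,
    cds_end_3p = genes$cds_end_3p,
    exons = purrr::map2(genes$tx_start, genes$tx_end, function(s, e) {
      cbind(start = s, end = e)
    })
  )

  structure(
    list(
      genes = genes, transcripts = transcripts, tracks = grid,
      params = list(
        n_genes = n_genes, n_events = n_events,
        mean_expression = mean_expression, depth_scale = depth_scale,
        replicates = replicates, utr_range = utr_range,
        p_short_range = p_short_range, null_jitter = null_jitter
      ),
      seed = seed
    ),
    class = "apa_sim"
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.apa_sim <- function(x, ...) {
  cat(sprintf(
    "<apa_sim> %d genes (%d events), %d replicates x 2 conditions, depth_scale %.3g, seed %d\n",
    nrow(x$genes), sum(x$genes$is_event), x$params$replicates,
    x$params$depth_scale, x$seed
  ))
  invisible(x)
}

#' Ground-truth candidate sites of a simulated dataset
#'
#' The simulated proximal polyadenylation sites as a candidate tibble, for
#' running the detector against known split points.
#'
#' @param sim An `apa_sim`.
#' @return Candidate tibble as in [pas_candidates()] with `source = "truth"`.
#' @export
truth_candidates <- function(sim) {
  tibble(
    gene_id = sim$genes$gene_id, chrom = sim$genes$chrom,
    strand = sim$genes$strand, position = sim$genes$proximal_pos,
    source = "truth", motif = NA_character_, support = NA_real_
  )
}

#' UTR frames of a simulated dataset
#' @param sim An `apa_sim`.
#' @param mode Frame mode, see [build_utr_frames()].
#' @return Frames tibble.
#' @export
sim_frames <- function(sim, mode = "default") {
  build_utr_frames(sim$transcripts, mode = mode)
}

#' Pooled per-condition coverage of a simulated dataset
#' @param sim An `apa_sim`.
#' @param condition `"cond1"` or `"cond2"`.
#' @return Named list (by gene) of pooled [cov_track()]s.
#' @export
sim_pooled_tracks <- function(sim, condition) {
  tr <- sim$tracks[sim$tracks$condition == condition, ]
  split(tr$track, tr$gene_id) |>
    purrr::map(pool_tracks)
}

#' Simulate 3'-end-seq coverage for a dataset
#'
#' Places one coverage hill per used polyadenylation site: a triangular bump
#' of width `peak_width` centred on the site (the distal hill is shifted
#' inside the UTR), with peak height proportional to the total number of
#' transcripts using that site across conditions and replicates. The centre
#' jitters by up to 2 bp (seeded) to emulate imprecise cleavage.
#'
#' @param sim An `apa_sim`.
#' @param peak_width Hill width in bp.
#' @param seed Integer seed for the positional jitter.
#' @return Tibble with `gene_id` and a `track` list-column of pooled
#'   3'-end-seq [cov_track()]s over the gene's UTR.
#' @export
simulate_end_seq <- function(sim, peak_width = 50, seed = sim$seed + 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  n_rep <- sim$params$replicates
  lam <- sim$params$mean_expression
  rows <- purrr::map(seq_len(nrow(sim$genes)), function(i) {
    g <- sim$genes[i, ]
    len <- g$utr_length
    vals <- numeric(len)
    usage_short <- lam * n_rep * (g$p_short_cond1 + g$p_short_cond2)
    usage_long <- lam * n_rep * (2 - g$p_short_cond1 - g$p_short_cond2)
    half <- floor(peak_width / 2)
    add_hill <- function(vals, centre, height) {
      if (height <= 0) {
        return(vals)
      }
      idx <- (centre - half):(centre + half)
      keep <- idx >= 1 & idx <= len
      bump <- height * (1 - abs(idx - centre) / (half + 1))
      vals[idx[keep]] <- vals[idx[keep]] + pmax(bump[keep], 0)
      vals
    }
    # transcript-orientation centres, then mirror for minus strand
    prox_centre <- g$proximal_offset + sample(-2:2, 1)
    dist_centre <- len - half
    vals <- add_hill(vals, prox_centre, usage_short)
    vals <- add_hill(vals, dist_centre, usage_long)
    if (g$strand == "-") vals <- rev(vals)
    tibble(gene_id = g$gene_id, track = list(cov_track(g$chrom, g$utr_start, round(vals, 6))))
  })
  bind_rows(rows)
}

#' Write a simulated dataset to disk
#'
#' Emits the synthetic annotation as refFlat, one bedGraph per condition and
#' replicate (all contigs in one file), a ground-truth TSV, and optionally a
#' synthetic genome FASTA with the canonical AATAAA hexamer planted just
#' upstream of each proximal site (so the PAS path rediscovers the truth).
#'
#' @param sim An `apa_sim`.
#' @param dir Output directory (created; refuses to overwrite unless
#'   `overwrite = TRUE`).
#' @param genome Also write `genome.fa`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a named list of the written paths.
#' @export
write_simulated_dataset <- function(sim, dir, genome = TRUE, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    abort(paste0("output directory ", dir, " exists and is not empty (set overwrite = TRUE)"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  rf <- sim$transcripts
  refflat <- sprintf(
    "%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t1\t%d,\t%d,",
    rf$gene_id, rf$transcript_id, rf$chrom, rf$strand,
    as.integer(rf$tx_start), as.integer(rf$tx_end),
    as.integer(ifelse(rf$strand == "+", rf$tx_start, rf$cds_end_3p)),
    as.integer(ifelse(rf$strand == "+", rf$cds_end_3p, rf$tx_end)),
    as.integer(rf$tx_start), as.integer(rf$tx_end)
  )
  paths$annotation <- file.path(dir, "annotation.refFlat")
  writeLines(refflat, paths$annotation)

  combos <- distinct(sim$tracks, .data$condition, .data$replicate)
  paths$coverage <- purrr::pmap_chr(combos, function(condition, replicate) {
    p <- file.path(dir, sprintf("%s_rep%d.bedgraph", condition, replicate))
    tr <- sim$tracks[sim$tracks$condition == condition &
      sim$tracks$replicate == replicate, ]
    write_bedgraph(tr$track, p)
    p
  })

  paths$truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(
    select(sim$genes, "gene_id", "chrom", "strand", "utr_length",
      "proximal_offset", "proximal_pos", "p_short_cond1", "p_short_cond2",
      "is_event"),
    paths$truth
  )

  if (genome) {
    paths$genome <- file.path(dir, "genome.fa")
    writeLines(unlist(purrr::map(seq_len(nrow(sim$genes)), function(i) {
      g <- sim$genes[i, ]
      seq <- sim_gene_sequence(g, seed = sim$seed + i)
      c(paste0(">", g$chrom), substring(seq, seq(1, nchar(seq), 70),
        pmin(seq(70, nchar(seq) + 69, 70), nchar(seq))))
    })), paths$genome)
  }

  seed_file <- file.path(dir, "params.json")
  jsonlite::write_json(c(sim$params, list(seed = sim$seed)), seed_file,
    auto_unbox = TRUE)
  paths$params <- seed_file
  invisible(paths)
}

# random contig with an AATAAA planted so that the PAS scan yields a
# candidate exactly at the simulated proximal split point
sim_gene_sequence <- function(g, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  n <- g$tx_end - g$tx_start
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (g$strand == "+") {
    # candidate = motif end: motif occupies [pos-6, pos)
    idx <- (g$proximal_pos - 6 + 1):g$proximal_pos
    base[idx] <- c("A", "A", "T", "A", "A", "A")
  } else {
    # candidate = match start of the reverse complement: motif at [pos, pos+6)
    idx <- (g$proximal_pos + 1):(g$proximal_pos + 6)
    base[idx] <- c("T", "T", "T", "A", "T", "T")
  }
  paste(base, collapse = "")
}
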