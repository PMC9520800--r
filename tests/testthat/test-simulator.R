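test_that("the requested number of event genes is constructed exactly", {
  sim <- simulate_dataset(n_genes = 4, n_events = 2, seed = 12)
  expect_equal(sum(sim$genes$is_event), 2)
  expect_equal(nrow(sim$genes), 4)
  # event definition: proportion difference > 0.10, nulls small
  d <- abs(sim$genes$p_short_cond1 - sim$genes$p_short_cond2)
  expect_true(all(d[sim$genes$is_event] > 0.10))
  expect_true(all(d[!sim$genes$is_event] <= 0.05))
  # proximal sites leave >= 50 bp on both flanks
  expect_true(all(sim$genes$proximal_offset >= 50))
  expect_true(all(sim$genes$proximal_offset <= sim$genes$utr_length - 50))
  expect_error(simulate_dataset(n_genes = 2, n_events = 3, seed = 1), "n_events")
  expect_error(simulate_dataset(n_genes = 2, n_events = 1), "seed")
})

test_that("the same parameters and seed regenerate the dataset bit-identically", {
  a <- simulate_dataset(n_genes = 6, n_events = 3, seed = 99)
  b <- simulate_dataset(n_genes = 6, n_events = 3, seed = 99)
  expect_identical(a$genes, b$genes)
  expect_identical(a$tracks$track, b$tracks$track)
  c <- simulate_dataset(n_genes = 6, n_events = 3, seed = 100)
  expect_false(identical(a$tracks$track, c$tracks$track))
})

test_that("equal isoform proportions give near-zero ratio differences", {
  sim <- simulate_dataset(n_genes = 60, n_events = 0, null_jitter = 0, seed = 5)
  expect_true(all(sim$genes$p_short_cond1 == sim$genes$p_short_cond2))
  b <- suppressMessages(run_benchmark(sim, report = "all"))
  rd <- b$results$ratio_diff
  expect_lt(mean(abs(rd), na.rm = TRUE), 0.05)
})

test_that("doubling depth_scale doubles regional depth sums within Poisson noise", {
  tot_r <- function(scale) {
    sim <- simulate_dataset(
      n_genes = 40, n_events = 0, depth_scale = scale, seed = 77
    )
    sum(purrr::map_dbl(sim$tracks$track, function(t) sum(t$values)))
  }
  r1 <- tot_r(0.4)
  r2 <- tot_r(0.8)
  expect_equal(r2 / r1, 2, tolerance = 0.05)
})

test_that("the detected ratio difference carries the sign of the proportion shift", {
  sim <- simulate_dataset(n_genes = 200, n_events = 200, seed = 41)
  b <- suppressMessages(run_benchmark(sim, report = "all"))
  joined <- dplyr::inner_join(
    tibble::as_tibble(b$results)[c("gene_id", "ratio_diff", "status")],
    sim$genes[c("gene_id", "p_short_cond1", "p_short_cond2")],
    by = "gene_id"
  )
  testable <- joined[joined$status != "untestable", ]
  agree <- sign(testable$ratio_diff) ==
    sign(testable$p_short_cond1 - testable$p_short_cond2)
  expect_gte(mean(agree), 0.95)
})

test_that("simulated 3'-end-seq places one hill per used polyadenylation site", {
  sim <- simulate_dataset(n_genes = 20, n_events = 10, seed = 13)
  es <- simulate_end_seq(sim)
  for (i in 1:5) {
    g <- sim$genes[i, ]
    pk <- call_peaks(es$track[[which(es$gene_id == g$gene_id)]], strand = g$strand)
    expect_equal(nrow(pk), 2) # both isoforms used on this parameter range
    expect_lte(min(abs(pk$peak_pos - g$proximal_pos)), 5)
  }

  # a gene using only the distal site gets a single distal hill
  sim$genes$p_short_cond1[1] <- 0
  sim$genes$p_short_cond2[1] <- 0
  es0 <- simulate_end_seq(sim)
  pk0 <- call_peaks(es0$track[[which(es0$gene_id == sim$genes$gene_id[1])]],
    strand = sim$genes$strand[1])
  expect_equal(nrow(pk0), 1)
  expect_gt(min(abs(pk0$peak_pos - sim$genes$proximal_pos[1])), 100)
})

test_that("end-seq peak heights reflect short:long isoform usage", {
  sim <- simulate_dataset(n_genes = 100, n_events = 0, seed = 29)
  es <- simulate_end_seq(sim)
  ratios <- purrr::map_dbl(seq_len(nrow(sim$genes)), function(i) {
    g <- sim$genes[i, ]
    pk <- call_peaks(es$track[[which(es$gene_id == g$gene_id)]], strand = g$strand)
    prox <- pk[which.min(abs(pk$peak_pos - g$proximal_pos)), ]
    dist <- pk[which.max(abs(pk$peak_pos - g$proximal_pos)), ]
    prox$peak_height / (prox$peak_height + dist$peak_height)
  })
  p <- (sim$genes$p_short_cond1 + sim$genes$p_short_cond2) / 2
  expect_equal(mean(ratios - p), 0, tolerance = 0.02)
})

test_that("a written fileset reloads through the normal file interfaces", {
  sim <- simulate_dataset(n_genes = 5, n_events = 2, seed = 50)
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir, overwrite = TRUE)
  tx <- load_annotation(paths$annotation, "refflat")
  expect_equal(sort(tx$gene_id), sort(sim$genes$gene_id))
  fr <- build_utr_frames(tx)
  expect_equal(nrow(fr), 5)
  # coverage re-read from bedGraph equals the in-memory track
  g <- sim$genes[1, ]
  tr_mem <- sim$tracks$track[[which(
    sim$tracks$gene_id == g$gene_id & sim$tracks$condition == "cond1" &
      sim$tracks$replicate == 1
  )]]
  tr_file <- coverage_for_interval(
    grep("cond1_rep1", paths$coverage, value = TRUE),
    g$chrom, g$utr_start, g$utr_end
  )
  expect_equal(tr_file$values, tr_mem$values)
  truth <- readr::read_tsv(paths$truth, show_col_types = FALSE)
  expect_equal(truth$is_event, sim$genes$is_event)
  expect_error(write_simulated_dataset(sim, dir), "overwrite")
})

test_that("the planted genome hexamer recovers the true proximal site via PAS scan", {
  sim <- simulate_dataset(n_genes = 8, n_events = 4, seed = 61)
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir, overwrite = TRUE)
  fr <- sim_frames(sim)
  cand <- pas_candidates(fr, paths$genome)
  hit <- dplyr::inner_join(cand, sim$genes[c("gene_id", "proximal_pos")], by = "gene_id")
  exact <- hit[hit$position == hit$proximal_pos, ]
  expect_equal(sort(unique(exact$gene_id)), sort(sim$genes$gene_id))
})
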