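test_that("ratio difference arithmetic and antisymmetry under condition swap", {
  expect_equal(ratio_difference(5, 10, 5, 10), 0)
  expect_equal(ratio_difference(8, 10, 2, 10), 0.6)
  expect_equal(ratio_difference(2, 10, 8, 10), -0.6)
  set.seed(3)
  for (i in 1:25) {
    x <- runif(4, 0.1, 20)
    expect_equal(
      ratio_difference(x[1], x[2], x[3], x[4]),
      -ratio_difference(x[3], x[4], x[1], x[2])
    )
  }
  expect_true(is.na(ratio_difference(5, 0, 5, 10)))
})

test_that("2x2 chi-square matches the closed form and known values", {
  flat <- chi2_2x2(10, 10, 10, 10)
  expect_equal(flat$stat, 0)
  expect_equal(flat$p, 1)

  # closed form N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 72 for [[20,80],[80,20]]
  skewed <- chi2_2x2(20, 80, 80, 20)
  expect_equal(skewed$stat, 72)
  expect_lt(skewed$p, 1e-15)

  # row swap leaves the test unchanged
  expect_equal(chi2_2x2(7, 3, 11, 13), chi2_2x2(11, 13, 7, 3))

  # zero marginal -> untestable
  expect_true(is.na(chi2_2x2(0, 0, 5, 5)$p))
  expect_true(is.na(chi2_2x2(0, 5, 0, 5)$p))
})

test_that("chi-square agrees with an independent Pearson computation to 1e-9", {
  set.seed(17)
  for (i in 1:200) {
    t <- sample(1:500, 4, replace = TRUE)
    mine <- chi2_2x2(t[1], t[2], t[3], t[4])
    ref <- oracle_chi2(t[1], t[2], t[3], t[4])
    expect_equal(mine$stat, ref$stat, tolerance = 1e-9)
    expect_equal(mine$p, ref$p, tolerance = 1e-9)
  }
})

test_that("Yates correction is available and shrinks the statistic", {
  plain <- chi2_2x2(12, 5, 6, 14)
  yates <- chi2_2x2(12, 5, 6, 14, correct = TRUE)
  ref <- suppressWarnings(stats::chisq.test(matrix(c(12, 6, 5, 14), 2)))
  expect_lt(yates$stat, plain$stat)
  expect_equal(yates$stat, unname(ref$statistic), tolerance = 1e-9)
})

test_that("non-integer tables are accepted", {
  res <- chi2_2x2(10.5, 3.25, 2.75, 9.5)
  expect_gt(res$stat, 0)
  expect_true(res$p > 0 && res$p < 1)
})

test_that("uniform coverage yields a zero ratio difference and a filtered site", {
  fr <- fixture_frame(utr_start = 0, utr_end = 2000)
  t1 <- cov_track("chr1", 0, rep(10, 2000))
  t2 <- cov_track("chr1", 0, rep(7, 2000))
  res <- evaluate_site(t1, t2, fr, 1000)
  expect_equal(res$ratio_diff, 0)
  expect_false(res$significant)
  expect_equal(res$status, "filtered")
  expect_equal(res$p_value, 1)
})

test_that("a coverage drop in one condition is caught at the split", {
  fr <- fixture_frame(utr_start = 0, utr_end = 2000)
  t1 <- cov_track("chr1", 0, rep(10, 2000))
  t2 <- cov_track("chr1", 0, c(rep(10, 1000), rep(1, 1000)))
  res <- evaluate_site(t1, t2, fr, 1000)
  expect_equal(res$ratio_diff, 1 - 10)
  expect_equal(c(res$r_u1, res$r_d1, res$r_u2, res$r_d2), c(10000, 10000, 10000, 1000))
  ref <- oracle_chi2(10000, 10000, 10000, 1000)
  expect_equal(res$chi2_stat, ref$stat, tolerance = 1e-9)
  expect_true(res$significant)
})

test_that("zero downstream coverage in both conditions is untestable, not dropped", {
  fr <- fixture_frame(utr_start = 0, utr_end = 2000)
  t1 <- cov_track("chr1", 0, c(rep(10, 1000), rep(0, 1000)))
  t2 <- cov_track("chr1", 0, c(rep(8, 1000), rep(0, 1000)))
  res <- evaluate_site(t1, t2, fr, 1000)
  expect_equal(res$status, "untestable")
  expect_false(res$significant)
  expect_true(is.na(res$p_value))
})

test_that("minus-strand sites split with upstream at higher coordinates", {
  fr <- fixture_frame(strand = "-", utr_start = 0, utr_end = 2000, search_end = 0)
  # upstream of the stop codon (transcript 5') is the right half on minus
  t1 <- cov_track("chr1", 0, c(rep(1, 1000), rep(10, 1000)))
  t2 <- cov_track("chr1", 0, rep(10, 2000))
  res <- evaluate_site(t1, t2, fr, 1000)
  expect_equal(res$n1, 10)
  expect_equal(res$N1, 1)
  expect_equal(res$ratio_diff, 10 - 1)
})

test_that("condition swap negates the ratio difference and preserves the p-value", {
  set.seed(31)
  fr <- fixture_frame(utr_start = 0, utr_end = 400, search_end = 400)
  for (i in 1:10) {
    t1 <- cov_track("chr1", 0, rpois(400, 8))
    t2 <- cov_track("chr1", 0, c(rpois(200, 8), rpois(200, 2)))
    a <- evaluate_site(t1, t2, fr, 200)
    b <- evaluate_site(t2, t1, fr, 200)
    expect_equal(a$ratio_diff, -b$ratio_diff)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$chi2_stat, b$chi2_stat)
  }
})

test_that("scaling both conditions by k preserves the ratio and scales the statistic", {
  fr <- fixture_frame(utr_start = 0, utr_end = 400, search_end = 400)
  set.seed(8)
  base1 <- c(rpois(200, 20), rpois(200, 5))
  base2 <- rpois(400, 12)
  k <- 3
  a <- evaluate_site(cov_track("c", 0, base1), cov_track("c", 0, base2), fr, 200)
  b <- evaluate_site(cov_track("c", 0, k * base1), cov_track("c", 0, k * base2), fr, 200)
  expect_equal(b$ratio_diff, a$ratio_diff)
  expect_equal(b$chi2_stat, k * a$chi2_stat, tolerance = 1e-12)
})

test_that("the chi-square table can alternatively be filled with means", {
  fr <- fixture_frame(utr_start = 0, utr_end = 2000)
  t1 <- cov_track("chr1", 0, rep(10, 2000))
  t2 <- cov_track("chr1", 0, c(rep(10, 1000), rep(1, 1000)))
  sums <- evaluate_site(t1, t2, fr, 1000)
  means <- evaluate_site(t1, t2, fr, 1000, table_scale = "means")
  expect_equal(means$ratio_diff, sums$ratio_diff)
  expect_equal(means$chi2_stat, sums$chi2_stat / 1000) # lengths 1000 here
})

test_that("default report keeps the best site per gene with documented tie-breaks", {
  fr <- fixture_frame(utr_start = 0, utr_end = 2000)
  t1 <- cov_track("chr1", 0, rep(10, 2000))
  t2 <- cov_track("chr1", 0, c(rep(10, 600), rep(3, 1400)))
  cand <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    position = c(600, 1500), source = "pas", motif = NA, support = NA_real_
  )
  all_res <- suppressMessages(detect_events(
    fr, cand, list(g1 = t1), list(g1 = t2), report = "all"
  ))
  expect_equal(nrow(all_res), 2)
  def <- suppressMessages(detect_events(
    fr, cand, list(g1 = t1), list(g1 = t2), report = "default"
  ))
  expect_equal(nrow(def), 1)
  expect_equal(def$site_position, all_res$site_position[which.min(all_res$p_value)])

  # tied p-values broken by larger |ratio_diff|
  sym2 <- cov_track("chr1", 0, c(rep(10, 500), rep(2, 1000), rep(10, 500)))
  symc <- dplyr::mutate(cand, position = c(1500, 500))
  tie <- suppressMessages(detect_events(
    fr, symc, list(g1 = t1), list(g1 = sym2), report = "default"
  ))
  both <- suppressMessages(detect_events(
    fr, symc, list(g1 = t1), list(g1 = sym2), report = "all"
  ))
  expect_equal(
    tie$site_position,
    both$site_position[order(both$p_value, -abs(both$ratio_diff))][1]
  )

  # exact tie in p and |ratio_diff| (both sites filtered) -> 5'-most wins
  flat_tie <- suppressMessages(detect_events(
    fr, symc, list(g1 = t1), list(g1 = t1), report = "default"
  ))
  expect_equal(flat_tie$site_position, 500)
})

test_that("reports round-trip through TSV and CSV with significance thresholds intact", {
  fr <- fixture_frame(utr_start = 0, utr_end = 2000)
  t1 <- cov_track("chr1", 0, rep(10, 2000))
  t2 <- cov_track("chr1", 0, c(rep(10, 1000), rep(1, 1000)))
  cand <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", position = 1000,
    source = "pas", motif = NA, support = NA_real_
  )
  res <- suppressMessages(detect_events(fr, cand, list(g1 = t1), list(g1 = t2)))
  for (ext in c(".tsv", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_report(res, f)
    back <- read_report(f)
    expect_equal(back$p_value, res$p_value)
    expect_equal(back$ratio_diff, res$ratio_diff)
    expect_equal(back$significant, abs(back$ratio_diff) > 0.1 & back$p_value < 0.05)
  }
})

test_that("tidy and glance summarise detection output", {
  fr <- fixture_frame(utr_start = 0, utr_end = 2000)
  t1 <- cov_track("chr1", 0, rep(10, 2000))
  t2 <- cov_track("chr1", 0, c(rep(10, 1000), rep(1, 1000)))
  cand <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", position = 1000,
    source = "pas", motif = NA, support = NA_real_
  )
  res <- suppressMessages(detect_events(fr, cand, list(g1 = t1), list(g1 = t2)))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "apa_result"))
  gl <- glance(res)
  expect_equal(gl$n_sites, 1)
  expect_equal(gl$n_significant, 1)
  expect_equal(gl$alpha, 0.05)
})
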