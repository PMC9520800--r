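# Site scoring: coverage-ratio difference and the 2x2 chi-square test.
#
# For a candidate cleavage site the UTR is split strand-aware into an
# upstream region (stop codon to site) and a downstream region (site to the
# search boundary). With r = summed depth and l = length of a region, the
# mean coverages are n = r_u/l_u (upstream) and N = r_d/l_d (downstream),
# and the statistic contrasting two conditions is the ratio difference
# n1/N1 - n2/N2. Sites with |ratio difference| <= 0.1 are filtered out;
# surviving sites get a Pearson 2x2 chi-square p-value on the depth sums
# [[r_u1, r_d1], [r_u2, r_d2]]. A site is significant when the filter passes
# and p < 0.05.

#' Ratio difference between two conditions
#'
#' @param n1,N1 Mean upstream/downstream coverage in condition 1.
#' @param n2,N2 Same for condition 2.
#' @return `n1/N1 - n2/N2`; `NA` when either downstream mean is 0 (the site
#'   is untestable, which is distinct from insignificant).
#' @examples
#' ratio_difference(8, 10, 2, 10) # 0.6
#' @export
ratio_difference <- function(n1, N1, n2, N2) {
  ifelse(N1 > 0 & N2 > 0, n1 / N1 - n2 / N2, NA_real_)
}

#' Pearson 2x2 chi-square test
#'
#' Plain Pearson statistic on the table `[[a, b], [c, d]]` with 1 degree of
#' freedom, by default without continuity correction. Entries may be
#' non-integer (pooled depths scaled upstream are accepted as reals).
#'
#' @param a,b,c,d Non-negative table entries.
#' @param correct Apply the Yates continuity correction.
#' @return Tibble with columns `stat` and `p`; both `NA` when a row or
#'   column marginal is zero (untestable).
#' @examples
#' chi2_2x2(20, 80, 80, 20)
#' @export
chi2_2x2 <- function(a, b, c, d, correct = FALSE) {
  if (any(c(a, b, c, d) < 0)) abort("chi2_2x2: negative table entry")
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  m1 <- (a + b) * (c + d) * (a + c) * (b + d)
  if (n == 0 || m1 == 0) {
    return(tibble(stat = NA_real_, p = NA_real_))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / m1
  tibble(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# strand-aware up/down split of a frame at a site position
split_regions <- function(frame, site) {
  reg <- frame_region(frame)
  if (site <= reg["start"] || site >= reg["end"]) {
    abort(sprintf("site %d not interior to frame of gene %s", site, frame$gene_id))
  }
  if (frame$strand == "+") {
    list(up = c(frame$utr_start, site), down = c(site, frame$search_end))
  } else {
    list(up = c(site, frame$utr_end), down = c(frame$search_end, site))
  }
}

#' Score one candidate site
#'
#' Computes regional depth sums and means for both conditions, the ratio
#' difference, and — only when `|ratio difference| >` `ratio_threshold` —
#' the chi-square p-value on the depth sums. Filtered sites keep `p = 1`;
#' sites with a zero downstream mean or a zero chi-square marginal are
#' flagged untestable rather than dropped.
#'
#' @param track1,track2 Pooled [cov_track()] per condition covering the
#'   frame's search region.
#' @param frame One frame row from [build_utr_frames()].
#' @param site Candidate row (needs `position`, optionally `source`).
#' @param ratio_threshold Minimum absolute ratio difference (default 0.1).
#' @param alpha Significance cutoff on the raw p-value (default 0.05).
#' @param table_scale Fill the chi-square table with regional depth sums
#'   (`"sums"`, default: count-scale input) or with the per-bp means
#'   (`"means"`).
#' @param correct Continuity correction, passed to [chi2_2x2()].
#' @return One-row tibble: identities, `n1`, `N1`, `n2`, `N2`, the four
#'   regional sums, `ratio_diff`, `chi2_stat`, `p_value`, `significant`,
#'   `status` (`"ok"`/`"filtered"`/`"untestable"`), `source`, `mode`.
#' @export
evaluate_site <- function(track1, track2, frame, site,
                          ratio_threshold = 0.1, alpha = 0.05,
                          table_scale = c("sums", "means"), correct = FALSE) {
  table_scale <- match.arg(table_scale)
  pos <- if (is.data.frame(site)) site$position[1] else site
  src <- if (is.data.frame(site) && "source" %in% names(site)) site$source[1] else NA_character_
  regs <- split_regions(frame, pos)
  u1 <- region_stats(track1, regs$up[1], regs$up[2])
  d1 <- region_stats(track1, regs$down[1], regs$down[2])
  u2 <- region_stats(track2, regs$up[1], regs$up[2])
  d2 <- region_stats(track2, regs$down[1], regs$down[2])
  rd <- ratio_difference(u1$mean, d1$mean, u2$mean, d2$mean)
  res <- tibble(
    gene_id = frame$gene_id, chrom = frame$chrom, strand = frame$strand,
    site_position = pos,
    n1 = u1$mean, N1 = d1$mean, n2 = u2$mean, N2 = d2$mean,
    r_u1 = u1$r, r_d1 = d1$r, r_u2 = u2$r, r_d2 = d2$r,
    ratio_diff = rd, chi2_stat = NA_real_, p_value = NA_real_,
    significant = FALSE, status = "ok", source = src, mode = frame$mode
  )
  if (is.na(rd)) {
    res$status <- "untestable"
    return(res)
  }
  if (abs(rd) <= ratio_threshold) {
    res$p_value <- 1
    res$status <- "filtered"
    return(res)
  }
  tab <- if (table_scale == "sums") {
    c(u1$r, d1$r, u2$r, d2$r)
  } else {
    c(u1$mean, d1$mean, u2$mean, d2$mean)
  }
  ct <- chi2_2x2(tab[1], tab[2], tab[3], tab[4], correct = correct)
  if (is.na(ct$p)) {
    res$status <- "untestable"
    return(res)
  }
  res$chi2_stat <- ct$stat
  res$p_value <- ct$p
  res$significant <- abs(rd) > ratio_threshold && ct$p < alpha
  res
}

#' Score all candidates and assemble the event report
#'
#' Evaluates every candidate site of every gene against the pooled
#' per-condition coverage. Benjamini-Hochberg q-values are added across all
#' evaluated sites as an extra column; they do not gate the `significant`
#' flag, which follows the raw `p < alpha` rule. With `report = "default"`
#' only the most significant site per gene is kept (smallest p; ties broken
#' by larger absolute ratio difference, then by the 5'-most position);
#' `report = "all"` keeps every candidate. Insignificant sites are reported,
#' not dropped.
#'
#' @param frames Frames tibble ([build_utr_frames()]).
#' @param candidates Candidate tibble ([pas_candidates()],
#'   [peaks_to_candidates()], [merge_candidates()]).
#' @param tracks1,tracks2 Named lists (by `gene_id`) of pooled
#'   [cov_track()]s, one per condition.
#' @param report `"default"` or `"all"` (see above).
#' @inheritParams evaluate_site
#' @return An `apa_result` tibble (one row per reported site) with the
#'   columns of [evaluate_site()] plus `q_value`.
#' @export
detect_events <- function(frames, candidates, tracks1, tracks2,
                          report = c("default", "all"),
                          ratio_threshold = 0.1, alpha = 0.05,
                          table_scale = c("sums", "means"), correct = FALSE) {
  report <- match.arg(report)
  table_scale <- match.arg(table_scale)
  rows <- purrr::map(seq_len(nrow(frames)), function(i) {
    fr <- frames[i, ]
    cand <- candidates[candidates$gene_id == fr$gene_id, ]
    if (nrow(cand) == 0) {
      inform(paste0("gene ", fr$gene_id, ": no candidate sites; omitted"))
      return(NULL)
    }
    t1 <- tracks1[[fr$gene_id]]
    t2 <- tracks2[[fr$gene_id]]
    if (is.null(t1) || is.null(t2)) {
      warn(paste0("gene ", fr$gene_id, ": missing coverage track; omitted"))
      return(NULL)
    }
    purrr::map(seq_len(nrow(cand)), function(j) {
      evaluate_site(t1, t2, fr, cand[j, ],
        ratio_threshold = ratio_threshold, alpha = alpha,
        table_scale = table_scale, correct = correct
      )
    }) |> bind_rows()
  })
  res <- bind_rows(purrr::compact(rows))
  if (nrow(res) == 0) {
    abort("detect_events: no testable gene/candidate combinations")
  }
  res$q_value <- p.adjust(res$p_value, method = "BH")
  if (report == "default") {
    res <- res |>
      group_by(.data$gene_id) |>
      dplyr::group_modify(function(g, key) {
        # untestable sites sort last; 5'-most = min position on +, max on -
        ord <- order(
          dplyr::coalesce(g$p_value, Inf),
          -abs(dplyr::coalesce(g$ratio_diff, 0)),
          if (g$strand[1] == "+") g$site_position else -g$site_position
        )
        g[ord[1], ]
      }) |>
      ungroup()
  }
  res <- arrange(res, .data$gene_id, .data$site_position)
  new_apa_result(res, report = report, ratio_threshold = ratio_threshold,
    alpha = alpha, table_scale = table_scale)
}

new_apa_result <- function(x, ...) {
  structure(x,
    class = c("apa_result", class(tibble())),
    apa_params = list(...)
  )
}

#' Write the event report
#'
#' Writes the per-site report with the standard header (gene, chrom, strand,
#' site, n1, N1, n2, N2, ratio_diff, chi2, p_value, q_value, significant,
#' source, mode) as tab-separated text, and as CSV when `path` ends in
#' `.csv` (a spreadsheet-readable copy of the same table).
#'
#' @param results An `apa_result` from [detect_events()].
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  out <- tibble(
    gene = results$gene_id, chrom = results$chrom, strand = results$strand,
    site = results$site_position,
    n1 = results$n1, N1 = results$N1, n2 = results$n2, N2 = results$N2,
    ratio_diff = results$ratio_diff, chi2 = results$chi2_stat,
    p_value = results$p_value, q_value = results$q_value,
    significant = results$significant, source = results$source,
    mode = results$mode
  )
  if (grepl("\\.csv$", path)) readr::write_csv(out, path) else readr::write_tsv(out, path)
  invisible(path)
}

#' Re-read an event report written by [write_report()]
#' @param path Report path.
#' @return A tibble with the report columns.
#' @export
read_report <- function(path) {
  if (grepl("\\.csv$", path)) {
    readr::read_csv(path, col_types = "cccdddddddddlcc", progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = "cccdddddddddlcc", progress = FALSE)
  }
}
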