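# Benchmarking against ground truth and 3'-end-seq validation.

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the distinct score values (ties grouped
#' into one step) and computes the trapezoidal area under the ROC curve.
#' The conventional ranking score for detector output is `1 - p` with sites
#' failing the ratio-difference filter forced to score 0 (see
#' [result_scores()]).
#'
#' @param scores Named numeric vector of per-gene scores (higher = more
#'   event-like).
#' @param truth Named logical vector of ground-truth labels, aligned by name
#'   with `scores` (or positionally when unnamed).
#' @return An object of class `apa_roc`: list with `auc`, `roc_points`
#'   (tibble `fpr`, `tpr`), `n_true`, `n_false`.
#' @export
roc_auc <- function(scores, truth) {
  if (!is.null(names(scores)) && !is.null(names(truth))) {
    truth <- truth[names(scores)]
  }
  stopifnot(length(scores) == length(truth), !any(is.na(scores)), !any(is.na(truth)))
  n_true <- sum(truth)
  n_false <- sum(!truth)
  if (n_true == 0 || n_false == 0) {
    abort("roc_auc: need at least one positive and one negative gene")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  # group tied scores into single steps
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(!y)[grp_last]
  tpr <- c(0, tp / n_true)
  fpr <- c(0, fp / n_false)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(
      auc = auc,
      roc_points = tibble(fpr = fpr, tpr = tpr),
      n_true = n_true, n_false = n_false
    ),
    class = "apa_roc"
  )
}

#' @export
print.apa_roc <- function(x, ...) {
  cat(sprintf(
    "<apa_roc> AUC %.4f (%d true, %d false genes, %d ROC points)\n",
    x$auc, x$n_true, x$n_false, nrow(x$roc_points)
  ))
  invisible(x)
}

#' Per-gene ranking scores from detector output
#'
#' Scores each gene as `1 - p` of its reported site (best site per gene for
#' an `"all"`-mode report), with filtered and untestable sites forced to
#' score 0: sites that fail the ratio-difference filter must rank below
#' every tested site, otherwise specificity would be overstated.
#'
#' @param results An `apa_result` from [detect_events()].
#' @return Named numeric vector of scores, one per gene.
#' @export
result_scores <- function(results) {
  df <- as_tibble(results) |>
    mutate(score = dplyr::if_else(.data$status == "ok", 1 - .data$p_value, 0)) |>
    group_by(.data$gene_id) |>
    summarise(score = max(.data$score), .groups = "drop")
  setNames(df$score, df$gene_id)
}

#' Sensitivity and specificity at the fixed decision rule
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) with the detector's
#' significance calls (p < alpha and |ratio difference| > threshold) as the
#' decision. Genes present in `truth` but absent from `significant` (e.g.
#' untestable) count as negative calls.
#'
#' @param significant Named logical vector of per-gene calls.
#' @param truth Named logical vector of ground-truth labels.
#' @return Tibble with `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
sens_spec <- function(significant, truth) {
  nm <- names(truth)
  if (!is.null(nm) && !is.null(names(significant))) {
    significant <- setNames(
      ifelse(is.na(significant[nm]), FALSE, significant[nm]), nm
    )
  }
  stopifnot(length(significant) == length(truth))
  if (!any(truth) || all(truth)) {
    abort("sens_spec: need both true and false genes")
  }
  tp <- sum(significant & truth)
  fn <- sum(!significant & truth)
  tn <- sum(!significant & !truth)
  fp <- sum(significant & !truth)
  tibble(
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Evaluate detector output against simulation truth
#'
#' Convenience wrapper: ROC/AUC on the `1 - p` scores and
#' sensitivity/specificity of the significance calls, with untestable or
#' unreported true events counted as misses.
#'
#' @param results An `apa_result` from [detect_events()].
#' @param truth Named logical vector (gene -> is_event), e.g.
#'   `setNames(sim$genes$is_event, sim$genes$gene_id)`.
#' @return An object of class `apa_eval`: list with `auc`, `sensitivity`,
#'   `specificity`, `roc` (`apa_roc`), `counts`.
#' @export
evaluate_detection <- function(results, truth) {
  scores <- result_scores(results)
  missing_genes <- setdiff(names(truth), names(scores))
  if (length(missing_genes) > 0) {
    scores <- c(scores, setNames(rep(0, length(missing_genes)), missing_genes))
  }
  scores <- scores[names(truth)]
  roc <- roc_auc(scores, truth)
  calls <- as_tibble(results) |>
    group_by(.data$gene_id) |>
    summarise(sig = any(.data$significant), .groups = "drop")
  ss <- sens_spec(setNames(calls$sig, calls$gene_id), truth)
  structure(
    list(
      auc = roc$auc, sensitivity = ss$sensitivity, specificity = ss$specificity,
      roc = roc, counts = select(ss, "tp", "fp", "tn", "fn")
    ),
    class = "apa_eval"
  )
}

#' @export
print.apa_eval <- function(x, ...) {
  cat(sprintf(
    "<apa_eval> AUC %.3f, sensitivity %.3f, specificity %.3f (TP %d FP %d TN %d FN %d)\n",
    x$auc, x$sensitivity, x$specificity,
    x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn
  ))
  invisible(x)
}

#' Validate detected events against 3'-end-seq peaks
#'
#' An event is validated when some peak's cleavage position on the same
#' contig lies within `window` bp (inclusive) of the event's site.
#'
#' @param events An `apa_result` or any tibble with `chrom` and
#'   `site_position`.
#' @param peaks Tibble from [call_peaks()] (needs `chrom`, `cleavage_pos`).
#' @param window Half-width of the validation window in bp.
#' @return Tibble with `n_detected`, `n_validated` and `ratio` (percent
#'   validated); `ratio` is `NA` when no events are supplied.
#' @export
validate_against_end_seq <- function(events, peaks, window = 50) {
  n_det <- nrow(events)
  if (n_det == 0) {
    return(tibble(n_detected = 0L, n_validated = 0L, ratio = NA_real_))
  }
  validated <- purrr::map_lgl(seq_len(n_det), function(i) {
    pk <- peaks[peaks$chrom == events$chrom[i], ]
    any(abs(pk$cleavage_pos - events$site_position[i]) <= window)
  })
  tibble(
    n_detected = n_det, n_validated = sum(validated),
    ratio = 100 * sum(validated) / n_det
  )
}

#' Write ROC points as TSV / evaluation report as JSON
#'
#' @param eval_or_roc An `apa_eval` or `apa_roc`.
#' @param path Output path (`.tsv` writes ROC points, `.json` writes the
#'   scalar summary).
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(eval_or_roc, path) {
  if (grepl("\\.json$", path)) {
    x <- if (inherits(eval_or_roc, "apa_eval")) {
      list(
        auc = eval_or_roc$auc, sensitivity = eval_or_roc$sensitivity,
        specificity = eval_or_roc$specificity,
        counts = as.list(eval_or_roc$counts)
      )
    } else {
      list(auc = eval_or_roc$auc)
    }
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    roc <- if (inherits(eval_or_roc, "apa_eval")) eval_or_roc$roc else eval_or_roc
    readr::write_tsv(roc$roc_points, path)
  }
  invisible(path)
}
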