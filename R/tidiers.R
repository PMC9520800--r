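# broom-style accessors for the package's result objects.

#' Tidy an event report
#'
#' @param x An `apa_result` from [detect_events()].
#' @param ... Unused.
#' @return A plain tibble, one row per reported site.
#' @method tidy apa_result
#' @export
tidy.apa_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of an event report
#'
#' @param x An `apa_result` from [detect_events()].
#' @param ... Unused.
#' @return A one-row tibble: numbers of sites, genes, significant and
#'   untestable sites, and the run parameters.
#' @method glance apa_result
#' @export
glance.apa_result <- function(x, ...) {
  p <- attr(x, "apa_params")
  df <- unclass_result(x)
  tibble(
    n_sites = nrow(df),
    n_genes = dplyr::n_distinct(df$gene_id),
    n_significant = sum(df$significant),
    n_untestable = sum(df$status == "untestable"),
    report = p$report %||% NA_character_,
    ratio_threshold = p$ratio_threshold %||% NA_real_,
    alpha = p$alpha %||% NA_real_
  )
}

#' @rdname evaluate_detection
#' @param x An `apa_eval`.
#' @param ... Unused.
#' @method glance apa_eval
#' @export
glance.apa_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(auc = x$auc, sensitivity = x$sensitivity, specificity = x$specificity),
    x$counts
  )
}

#' @rdname roc_auc
#' @param x An `apa_roc`.
#' @method tidy apa_roc
#' @export
tidy.apa_roc <- function(x, ...) x$roc_points

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), "apa_result")
  x
}
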