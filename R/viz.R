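# Coverage plots with UTR annotation, and nucleotide composition profiles
# around predicted polyadenylation sites.

#' Read-coverage plot of an APA event
#'
#' Stacked per-sample coverage panels over a region, with the 3'-UTR drawn
#' as an annotation bar and vertical red markers at the cleavage sites.
#' Panels are scaled per sample (libraries differ in depth). The plot is
#' returned as a ggplot object; when `out` is given it is also written to
#' file (PNG or PDF by extension).
#'
#' @param region Numeric `c(start, end)` to display (0-based half-open).
#' @param rnaseq Named list of [cov_track()]s (panel label -> track), e.g.
#'   one per condition.
#' @param frame One frame row from [build_utr_frames()].
#' @param sites Numeric vector of cleavage-site positions to mark.
#' @param endseq Optional named list of 3'-end-seq [cov_track()]s, drawn as
#'   extra panels.
#' @param out Optional output file path.
#' @param width,height Device size in inches when writing to file.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_event <- function(region, rnaseq, frame, sites = numeric(),
                       endseq = NULL, out = NULL, width = 7, height = 5) {
  check_interval(region[1], region[2], "plot region")
  freg <- frame_region(frame)
  if (region[2] <= freg["start"] || region[1] >= freg["end"]) {
    abort(sprintf(
      "region %d-%d does not overlap the frame of gene %s",
      region[1], region[2], frame$gene_id
    ))
  }
  panel_df <- function(tracks, kind) {
    purrr::imap(tracks, function(t, label) {
      s <- max(region[1], t$start)
      e <- min(region[2], track_end(t))
      if (e <= s) {
        return(NULL)
      }
      idx <- (s - t$start + 1):(e - t$start)
      tibble(
        pos = s:(e - 1), depth = t$values[idx],
        sample = label, kind = kind
      )
    }) |>
      purrr::compact() |>
      bind_rows()
  }
  df <- bind_rows(
    panel_df(rnaseq, "RNA-seq"),
    if (!is.null(endseq)) panel_df(endseq, "3'-end-seq")
  )
  if (nrow(df) == 0) abort("no coverage overlaps the requested region")
  df$sample <- factor(df$sample, levels = unique(df$sample))
  utr_bar <- tibble(
    xmin = max(frame$utr_start, region[1]),
    xmax = min(frame$utr_end, region[2])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey35") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$sample), scales = "free_y") +
    ggplot2::geom_vline(xintercept = sites, colour = "red", linewidth = 0.4) +
    ggplot2::geom_rect(
      data = utr_bar,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = 0, fill = "steelblue", inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = paste0(frame$chrom, " position"), y = "read depth",
      title = paste0(frame$gene_id, " 3'-UTR (", frame$strand, ")")
    ) +
    ggplot2::theme_bw()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Nucleotide composition around polyadenylation sites
#'
#' Tallies the A/C/G/T fractions at every offset in a `[-flank, +flank]`
#' window centred on each site (offset 0 = the site). Windows of `-` strand
#' sites are reverse-complemented before tallying so all sites are read in
#' transcript orientation. `N` bases are excluded from the tally; at each
#' offset with at least one informative base the four fractions sum to 1.
#'
#' @param sites Tibble with `chrom`, `position`, `strand`.
#' @param genome A [Biostrings::DNAStringSet] named by contig, or FASTA path.
#' @param flank Window half-width in bp.
#' @return An object of class `apa_composition`: tibble with `offset`
#'   (-flank..flank), `base` (A/C/G/T) and `fraction`.
#' @export
composition_profile <- function(sites, genome, flank = 50) {
  if (nrow(sites) == 0) abort("composition_profile: empty site list")
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  win <- 2 * flank + 1
  counts <- matrix(0, nrow = win, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    pos <- sites$position[i]
    if (!chrom %in% names(genome)) abort(paste0("contig ", chrom, " absent from genome"))
    clen <- Biostrings::width(genome[chrom])
    s <- pos - flank
    e <- pos + flank
    if (s < 0 || e >= clen) {
      warn(sprintf("site %s:%d within %d bp of contig edge; trimmed", chrom, pos, flank))
      s <- max(s, 0)
      e <- min(e, clen - 1)
    }
    seq <- Biostrings::subseq(genome[[chrom]], s + 1, e + 1)
    offs <- (s:e) - pos
    if (sites$strand[i] == "-") {
      seq <- Biostrings::reverseComplement(seq)
      offs <- rev(-offs)
    }
    ch <- strsplit(as.character(seq), "")[[1]]
    for (k in seq_along(ch)) {
      if (ch[k] %in% colnames(counts)) {
        row <- offs[k] + flank + 1
        counts[row, ch[k]] <- counts[row, ch[k]] + 1
      }
    }
  }
  tot <- rowSums(counts)
  frac <- counts / ifelse(tot == 0, NA, tot)
  out <- as_tibble(frac) |>
    mutate(offset = -flank:flank) |>
    tidyr::pivot_longer(c("A", "C", "G", "T"),
      names_to = "base", values_to = "fraction"
    ) |>
    select("offset", "base", "fraction")
  structure(out, class = c("apa_composition", class(tibble())))
}

#' @rdname composition_profile
#' @param object An `apa_composition`.
#' @param ... Unused.
#' @method autoplot apa_composition
#' @export
autoplot.apa_composition <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$offset, y = .data$fraction, colour = .data$base)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "position relative to polyadenylation site (bp)",
      y = "nucleotide fraction", colour = NULL
    ) +
    ggplot2::theme_bw()
}

#' @rdname roc_auc
#' @param object An `apa_roc`.
#' @param ... Unused.
#' @method autoplot apa_roc
#' @export
autoplot.apa_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_bw()
}
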