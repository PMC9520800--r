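# Candidate cleavage sites from polyadenylation-signal (PAS) hexamers.
#
# The PAS path applies when no 3'-end-seq data is available: occurrences of
# the canonical hexamers (AATAAA, ATTAAA by default) inside a gene's search
# frame are taken as putative cleavage positions. The candidate is placed at
# the motif's 3' boundary in transcript orientation, so the hexamer sits
# upstream of the assumed cleavage point on either strand.

#' Scan a sequence for PAS hexamer candidates
#'
#' On the `+` strand every verbatim motif match (overlaps allowed) yields a
#' candidate at the motif end (0-based offset just past the hexamer). On the
#' `-` strand the reverse complement of each motif is matched against the
#' given forward-strand sequence and the candidate is the match's leftmost
#' offset — the motif's 3' boundary read in transcript orientation. `N`
#' bases never match.
#'
#' @param sequence Forward-strand nucleotide string (A/C/G/T/N; case
#'   insensitive).
#' @param strand `"+"` or `"-"`.
#' @param motifs Character vector of hexamers (default the two canonical
#'   polyadenylation signals). Longer lists, e.g. the twelve common PAS
#'   variants, are accepted.
#' @return Tibble with columns `offset` (0-based candidate position relative
#'   to the sequence start) and `motif`.
#' @examples
#' scan_pas("CCAATAAAGG", "+") # candidate at offset 8
#' @export
scan_pas <- function(sequence, strand = c("+", "-"),
                     motifs = c("AATAAA", "ATTAAA")) {
  strand <- match.arg(strand)
  motifs <- toupper(motifs)
  bad <- nchar(motifs) != 6 | grepl("[^ACGT]", motifs)
  if (any(bad)) {
    abort(paste0("invalid PAS motif (must be 6 bp over ACGT): ", motifs[bad][1]))
  }
  seq <- Biostrings::DNAString(toupper(sequence))
  hits <- purrr::map(motifs, function(m) {
    pat <- if (strand == "+") m else as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    mt <- Biostrings::matchPattern(pat, seq, fixed = TRUE) # fixed: N never matches
    if (length(mt) == 0) {
      return(tibble(offset = numeric(), motif = character()))
    }
    off <- if (strand == "+") BiocGenerics::end(mt) else BiocGenerics::start(mt) - 1
    tibble(offset = as.numeric(off), motif = m)
  })
  bind_rows(hits) |> arrange(.data$offset)
}

#' Enumerate PAS candidates over UTR frames
#'
#' Extracts each frame's search-region sequence from the genome, scans it
#' with [scan_pas()], converts offsets to genomic positions and drops
#' candidates closer than `edge_margin` bp to either frame boundary (both
#' flanks of the chi-square split must be non-degenerate).
#'
#' @param frames Tibble from [build_utr_frames()].
#' @param genome A [Biostrings::DNAStringSet] named by contig, or a path to
#'   a FASTA file (read with an index when present).
#' @param motifs Hexamer set, see [scan_pas()].
#' @param edge_margin Minimum distance (bp) from either frame boundary.
#' @return Candidate tibble: `gene_id`, `chrom`, `strand`, `position`
#'   (0-based split point), `source = "pas"`, `motif`, `support = NA`.
#' @export
pas_candidates <- function(frames, genome, motifs = c("AATAAA", "ATTAAA"),
                           edge_margin = 50) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  out <- purrr::map(seq_len(nrow(frames)), function(i) {
    fr <- frames[i, ]
    reg <- frame_region(fr)
    if (!fr$chrom %in% names(genome)) {
      abort(paste0("contig ", fr$chrom, " absent from genome"))
    }
    clen <- Biostrings::width(genome[fr$chrom])
    s <- max(reg["start"], 0)
    e <- min(reg["end"], clen)
    if (e - s < 2 * edge_margin) {
      return(NULL)
    }
    seq <- as.character(Biostrings::subseq(genome[[fr$chrom]], s + 1, e))
    hits <- scan_pas(seq, fr$strand, motifs)
    if (nrow(hits) == 0) {
      return(NULL)
    }
    tibble(
      gene_id = fr$gene_id, chrom = fr$chrom, strand = fr$strand,
      position = s + hits$offset, source = "pas", motif = hits$motif,
      support = NA_real_
    ) |>
      filter(.data$position - s >= edge_margin, e - .data$position >= edge_margin)
  })
  bind_rows(purrr::compact(out))
}

#' Merge candidate lists across samples
#'
#' Takes the union of candidate positions per gene. Duplicate positions are
#' collapsed keeping the maximum support; with `window > 0`, positions within
#' `window` bp of a higher-support candidate collapse onto it
#' (greedy, highest support first; ties favour the 5'-most position).
#'
#' @param candidates Candidate tibble (rows from one or more samples).
#' @param window Collapse radius in bp (0 = exact-duplicate collapse only).
#' @return Merged candidate tibble, sorted by gene and position.
#' @export
merge_candidates <- function(candidates, window = 0) {
  if (nrow(candidates) == 0) {
    return(candidates)
  }
  merged <- candidates |>
    group_by(.data$gene_id, .data$position) |>
    arrange(dplyr::desc(dplyr::coalesce(.data$support, -Inf)), .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  if (window > 0) {
    merged <- merged |>
      group_by(.data$gene_id) |>
      dplyr::group_modify(function(g, key) {
        g <- arrange(g, dplyr::desc(dplyr::coalesce(.data$support, -Inf)), .data$position)
        kept <- g[0, ]
        while (nrow(g) > 0) {
          kept <- bind_rows(kept, g[1, ])
          g <- g[abs(g$position - g$position[1]) > window, ]
        }
        kept
      }) |>
      ungroup()
  }
  arrange(merged, .data$gene_id, .data$position)
}

#' Write candidates as BED
#'
#' Name field carries `gene|source|motif`; score carries peak support where
#' available.
#' @param candidates Candidate tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  out <- tibble(
    chrom = candidates$chrom,
    start = candidates$position,
    end = candidates$position + 1,
    name = paste(candidates$gene_id, candidates$source,
      dplyr::coalesce(candidates$motif, "."), sep = "|"),
    score = dplyr::coalesce(candidates$support, 0),
    strand = candidates$strand
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
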