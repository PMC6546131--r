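#' Read a chromatin-state segmentation
#'
#' Headerless BED4 (chrom, start, end, state label), 0-based half-open.
#' Overlapping segments are allowed in the file but resolved first-wins at
#' assignment time; a warning is emitted here when any overlap exists.
#'
#' @param path File path.
#' @param cell_type Optional cell-type name stored as an attribute.
#' @return Tibble with `chrom`, `start`, `end`, `state`.
#' @export
read_state_segments <- function(path, cell_type = NULL) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(bed) < 4) abort("state BED needs 4 columns (chrom, start, end, state)")
  seg <- tibble(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
                end = as.integer(bed[[3]]), state = as.character(bed[[4]]))
  stopifnot(all(seg$start < seg$end))
  gr <- segments_granges(seg)
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(self) > 0) {
    warn(sprintf("%d overlapping segment pair(s); first segment in file wins",
                 length(self)))
  }
  attr(seg, "cell_type") <- cell_type
  seg
}

segments_granges <- function(segments) {
  GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1L, end = segments$end)
  )
}

#' Assign a chromatin state to each probe
#'
#' A probe's state is the label of the segment containing its CpG position
#' (0-based half-open containment); probes covered by no segment get
#' `"none"`. When segments overlap, the first one in the file wins.
#'
#' @param probe_set Probe ids to annotate.
#' @param probe_annot Probe annotation tibble (`probe`, `chrom`, `pos`).
#' @param segments Segmentation tibble from [read_state_segments()].
#' @return Tibble with `probe` and `state`.
#' @export
assign_states <- function(probe_set, probe_annot, segments) {
  pa <- probe_annot[match(probe_set, probe_annot$probe), ]
  if (any(is.na(pa$probe))) abort("unknown probe id in probe_set")
  pts <- GenomicRanges::GRanges(
    pa$chrom, IRanges::IRanges(start = pa$pos + 1L, width = 1L)
  )
  first <- GenomicRanges::findOverlaps(pts, segments_granges(segments),
                                       select = "first")
  tibble(probe = pa$probe,
         state = ifelse(is.na(first), "none", segments$state[first]))
}

#' Chromatin-state enrichment against a sampled distal background
#'
#' Compares the state composition of the selected probes with a background
#' sampled uniformly without replacement from the remaining distal probes.
#' Uncovered probes count as the pseudo-state `"none"`. Each state observed
#' in either set gets a one-sided Fisher's exact test with odds ratio and
#' 95% CI, BH-adjusted across states.
#'
#' @param selected_probes Result probe ids.
#' @param distal_pool All distal probe ids (the selection pool).
#' @param probe_annot Probe annotation tibble.
#' @param segments Segmentation tibble from [read_state_segments()].
#' @param n_background Background size (default `10 * length(selected_probes)`,
#'   capped at the pool size).
#' @param seed Integer seed making the background draw reproducible.
#' @return Tibble of class `ml_state_enrichment`: `state`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `ci_low`, `ci_high`, `pvalue`, `padj`, sorted by
#'   `ci_low` descending.
#' @export
enrich_states <- function(selected_probes, distal_pool, probe_annot, segments,
                          n_background = NULL, seed = 1) {
  selected_probes <- unique(selected_probes)
  rest <- setdiff(distal_pool, selected_probes)
  n_background <- min(n_background %||% (10L * length(selected_probes)),
                      length(rest))
  if (n_background < 1) abort("distal pool too small for a background sample")
  background <- with_seed(seed, sample(rest, n_background))
  sel_states <- assign_states(selected_probes, probe_annot, segments)$state
  bg_states <- assign_states(background, probe_annot, segments)$state
  states <- sort(unique(c(sel_states, bg_states)))
  out <- bind_rows(purrr::map(states, function(s) {
    a <- sum(sel_states == s)
    cc <- sum(bg_states == s)
    fisher_exact_enrichment(a, length(sel_states) - a,
                            cc, length(bg_states) - cc, "greater")
  }))
  out <- dplyr::bind_cols(tibble(state = states), out)
  out$padj <- bh_adjust(out$pvalue)
  out <- arrange(out, desc(.data$ci_low), .data$state)
  attr(out, "cell_type") <- attr(segments, "cell_type")
  class(out) <- c("ml_state_enrichment", class(out))
  out
}
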