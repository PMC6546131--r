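#' Read motif instances from BED
#'
#' Headerless BED with at least 4 columns; column 4 is the motif name.
#' Coordinates are 0-based half-open.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `motif`.
#' @export
read_motif_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(bed) < 4) abort("motif BED needs at least 4 columns")
  tibble(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
         end = as.integer(bed[[3]]), motif = as.character(bed[[4]]))
}

#' Assign motif instances to probes within a window
#'
#' Probe `p` carries motif `m` if at least one instance interval of `m`
#' overlaps the half-open window `[pos(p) - w, pos(p) + w + 1)` around the
#' CpG position; strand is ignored and multiple instances count once.
#' Instances on chromosomes absent from the probe annotation are skipped
#' with a warning. When the probe annotation carries an `is_distal` flag,
#' only distal probes are mapped.
#'
#' @param motif_intervals Tibble from [read_motif_bed()] (columns `chrom`,
#'   `start`, `end`, `motif`).
#' @param probe_annot Probe annotation tibble (`probe`, `chrom`, `pos`,
#'   optional `is_distal`).
#' @param w Window half-width in bp (default 250).
#' @return Tibble of class `ml_motif_map` with one row per (motif, probe)
#'   assignment.
#' @export
build_motif_probe_map <- function(motif_intervals, probe_annot, w = 250) {
  stopifnot(w > 0, all(motif_intervals$start < motif_intervals$end))
  if ("is_distal" %in% names(probe_annot) &&
      any(probe_annot$is_distal %in% c(TRUE, FALSE))) {
    probe_annot <- probe_annot[probe_annot$is_distal %in% TRUE, ]
  }
  known <- motif_intervals$chrom %in% unique(probe_annot$chrom)
  if (any(!known)) {
    warn(sprintf("skipping %d motif instance(s) on unknown chromosome(s): %s",
                 sum(!known),
                 paste(unique(motif_intervals$chrom[!known]), collapse = ", ")))
    motif_intervals <- motif_intervals[known, ]
  }
  if (nrow(motif_intervals) == 0 || nrow(probe_annot) == 0) {
    out <- tibble(motif = character(), probe = character())
    class(out) <- c("ml_motif_map", class(out))
    return(out)
  }
  # 0-based half-open [s, e) maps to the 1-based closed IRanges (s + 1, e)
  windows <- GenomicRanges::GRanges(
    probe_annot$chrom,
    IRanges::IRanges(start = probe_annot$pos - w + 1L,
                     end = probe_annot$pos + w + 1L)
  )
  inst <- GenomicRanges::GRanges(
    motif_intervals$chrom,
    IRanges::IRanges(start = motif_intervals$start + 1L,
                     end = motif_intervals$end)
  )
  hits <- GenomicRanges::findOverlaps(inst, windows, ignore.strand = TRUE)
  out <- tibble(
    motif = motif_intervals$motif[S4Vectors::queryHits(hits)],
    probe = probe_annot$probe[S4Vectors::subjectHits(hits)]
  )
  out <- dplyr::distinct(arrange(out, .data$motif, .data$probe))
  class(out) <- c("ml_motif_map", class(out))
  out
}

#' Motif enrichment among paired probes
#'
#' Tests each motif for over-representation among the foreground probes
#' (probes of significant probe-gene pairs) against the distal-probe
#' background, with a one-sided Fisher's exact test on the disjoint 2x2
#' contrast `a = |fg with motif|`, `b = |fg without|`, `c = |bg-minus-fg
#' with motif|`, `d = rest`, Benjamini-Hochberg adjustment across motifs,
#' and the sample odds ratio with its Woolf 95% CI. A motif is `enriched`
#' when `ci_low > config$or_ci_lower_cut` and `a >= config$motif_min_probes`.
#' Records are sorted by `ci_low` descending (ties by motif name).
#'
#' @param fg_probes Foreground probe ids (must be a subset of `bg_probes`).
#' @param bg_probes Background probe ids (all distal probes).
#' @param motif_map An `ml_motif_map` from [build_motif_probe_map()].
#' @param config An [analysis_config()].
#' @return Tibble of class `ml_motif_enrichment` with columns `motif`, `a`,
#'   `b`, `c`, `d`, `n_fg_probes`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `pvalue`, `padj`, `enriched`.
#' @export
enrich_motifs <- function(fg_probes, bg_probes, motif_map, config) {
  fg_probes <- unique(fg_probes)
  bg_probes <- unique(bg_probes)
  if (length(fg_probes) == 0) abort("empty foreground probe set")
  if (!all(fg_probes %in% bg_probes)) {
    abort("foreground probes must be a subset of the background")
  }
  if (nrow(motif_map) == 0) abort("empty motif-probe map")
  rest <- setdiff(bg_probes, fg_probes)
  motifs <- sort(unique(motif_map$motif))
  tabs <- purrr::map(motifs, function(m) {
    set <- motif_map$probe[motif_map$motif == m]
    a <- sum(fg_probes %in% set)
    cc <- sum(rest %in% set)
    fisher_exact_enrichment(a, length(fg_probes) - a,
                            cc, length(rest) - cc, "greater")
  })
  out <- bind_rows(tabs)
  out <- dplyr::bind_cols(tibble(motif = motifs), out)
  out$padj <- bh_adjust(out$pvalue)
  out$n_fg_probes <- out$a
  out$enriched <- out$ci_low > config$or_ci_lower_cut &
    out$a >= config$motif_min_probes
  out <- arrange(out, desc(.data$ci_low), .data$motif)
  class(out) <- c("ml_motif_enrichment", class(out))
  out
}
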