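#' Analysis configuration
#'
#' Collects every tunable of the linking pipeline in one validated object.
#' Defaults follow the conventions of methylation/expression linking of
#' distal regulatory elements: the 20% extreme-sample quantile, a +/-250 bp
#' motif window around the CpG, and a 2 kb transcription-start-site cutoff
#' defining "distal".
#'
#' @param mode `"unsupervised"` (per-locus extreme-quantile groups) or
#'   `"supervised"` (two predefined sample groups covering all samples).
#' @param extreme_fraction Fraction of samples taken at each methylation
#'   extreme in unsupervised selection (default 0.20, must be in (0, 0.5]).
#' @param direction `"hypo"` (group 1 / case loses methylation) or
#'   `"hyper"`. A two-direction study is two runs.
#' @param dm_pvalue_cut BH-adjusted p-value cutoff for differentially
#'   methylated CpGs (default 0.01).
#' @param dm_min_diff Minimum absolute beta-value difference between group
#'   means for a DMC (default 0.3).
#' @param num_nearest_genes Candidate genes per probe, split half upstream
#'   and half downstream by TSS position (default 20).
#' @param n_permutations Random distal probes drawn for each probe-gene
#'   empirical p-value (default 10000).
#' @param pe_cut Empirical p-value cutoff declaring a probe-gene pair
#'   significant (default 0.001).
#' @param motif_window Half-width in bp of the window around each CpG used
#'   to assign motif instances to probes (default 250).
#' @param or_ci_lower_cut A motif is enriched only if the lower bound of the
#'   95% CI of its odds ratio exceeds this value (default 1.1).
#' @param motif_min_probes Minimum foreground probes carrying the motif
#'   (default 10).
#' @param mr_top_fraction Fraction of ranked TFs flagged as candidate master
#'   regulators (default 0.05).
#' @param tss_distal_cut Minimum distance in bp from every annotated TSS for
#'   a probe to count as distal (default 2000).
#' @param group1,group2 Group labels compared in supervised mode (and used
#'   for within-group extreme selection in unsupervised mode when labels are
#'   present). Defaults to the two labels in lexicographic order. In a
#'   `"hypo"` run, `group1` is the group expected to lose methylation.
#' @param min_group_samples Minimum usable samples per comparison group at a
#'   probe (default 5); probes below it are skipped.
#' @param rng_seed Integer seed governing every stochastic step.
#'
#' @return An object of class `ml_config` (a validated named list).
#' @examples
#' cfg <- analysis_config(mode = "supervised", n_permutations = 100, rng_seed = 1)
#' cfg$extreme_fraction
#' @export
analysis_config <- function(mode = c("unsupervised", "supervised"),
                            extreme_fraction = 0.2,
                            direction = c("hypo", "hyper"),
                            dm_pvalue_cut = 0.01,
                            dm_min_diff = 0.3,
                            num_nearest_genes = 20L,
                            n_permutations = 10000L,
                            pe_cut = 0.001,
                            motif_window = 250L,
                            or_ci_lower_cut = 1.1,
                            motif_min_probes = 10L,
                            mr_top_fraction = 0.05,
                            tss_distal_cut = 2000L,
                            group1 = NULL,
                            group2 = NULL,
                            min_group_samples = 5L,
                            rng_seed = 1L) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  cfg <- list(
    mode = mode,
    extreme_fraction = extreme_fraction,
    direction = direction,
    dm_pvalue_cut = dm_pvalue_cut,
    dm_min_diff = dm_min_diff,
    num_nearest_genes = as.integer(num_nearest_genes),
    n_permutations = as.integer(n_permutations),
    pe_cut = pe_cut,
    motif_window = as.integer(motif_window),
    or_ci_lower_cut = or_ci_lower_cut,
    motif_min_probes = as.integer(motif_min_probes),
    mr_top_fraction = mr_top_fraction,
    tss_distal_cut = as.integer(tss_distal_cut),
    group1 = group1,
    group2 = group2,
    min_group_samples = as.integer(min_group_samples),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "ml_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$extreme_fraction > 0, cfg$extreme_fraction <= 0.5,
    cfg$motif_window > 0,
    cfg$n_permutations >= 1,
    cfg$tss_distal_cut >= 0,
    cfg$num_nearest_genes >= 1,
    cfg$mr_top_fraction > 0, cfg$mr_top_fraction <= 1
  )
  for (p in c("dm_pvalue_cut", "pe_cut")) {
    if (cfg[[p]] <= 0 || cfg[[p]] > 1) {
      abort(sprintf("`%s` must lie in (0, 1], got %g", p, cfg[[p]]))
    }
  }
  if (cfg$dm_min_diff < 0 || cfg$dm_min_diff > 1) {
    abort("`dm_min_diff` must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.ml_config <- function(x, ...) {
  cat("<methlink analysis config>\n")
  cat(sprintf("  mode: %s   direction: %s\n", x$mode, x$direction))
  cat(sprintf("  extreme fraction: %g   distal cutoff: %d bp\n",
              x$extreme_fraction, x$tss_distal_cut))
  cat(sprintf("  DMC: padj < %g, |diff| >= %g\n", x$dm_pvalue_cut, x$dm_min_diff))
  cat(sprintf("  pairing: %d candidates, R = %d, Pe < %g\n",
              x$num_nearest_genes, x$n_permutations, x$pe_cut))
  cat(sprintf("  motifs: window +/-%d bp, CI low > %g, >= %d probes\n",
              x$motif_window, x$or_ci_lower_cut, x$motif_min_probes))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}
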