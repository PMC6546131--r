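# resolve the two comparison group label sets (supervised / labeled cohorts)
group_sample_ids <- function(dataset, config) {
  if (is.null(dataset$groups)) return(NULL)
  labels <- sort(unique(dataset$groups))
  g1 <- config$group1 %||% labels[1]
  g2 <- config$group2 %||% setdiff(labels, g1)[1]
  if (!all(c(g1, g2) %in% labels)) {
    abort(sprintf("group labels '%s'/'%s' not found in the sample sheet", g1, g2))
  }
  list(g1 = dataset$samples[dataset$groups == g1],
       g2 = dataset$samples[dataset$groups == g2],
       labels = c(g1, g2))
}

#' Samples compared at one probe
#'
#' In supervised mode this is all samples of each predefined group. In
#' unsupervised mode it is, within each group, the `ceiling(n * group size)`
#' samples with the most extreme methylation at this probe in the configured
#' direction (lowest for `"hypo"`, highest for `"hyper"`); the selected
#' subset therefore changes from probe to probe. When no group labels exist,
#' unsupervised mode falls back to comparing the lowest versus highest n% of
#' all samples. Boundary ties are broken by sample id for determinism;
#' missing beta values are unusable.
#'
#' @param probe_id Probe identifier.
#' @param dataset A [paired_omics] object.
#' @param config An [analysis_config()].
#' @return List with character vectors `g1` and `g2`, or `NULL` when either
#'   group has fewer than `config$min_group_samples` usable samples.
#' @export
select_comparison_samples <- function(probe_id, dataset, config) {
  row <- dataset$meth[probe_id, ]
  gs <- group_sample_ids(dataset, config)
  take_extreme <- function(ids) {
    v <- row[ids]
    ids <- ids[!is.na(v)]
    v <- v[!is.na(v)]
    m <- extreme_count(length(ids), config$extreme_fraction)
    o <- if (config$direction == "hypo") order(v, ids) else order(-v, ids)
    ids[o][seq_len(min(m, length(ids)))]
  }
  if (config$mode == "supervised") {
    if (is.null(gs)) abort("supervised mode needs group labels")
    g1 <- gs$g1[!is.na(row[gs$g1])]
    g2 <- gs$g2[!is.na(row[gs$g2])]
  } else if (!is.null(gs)) {
    g1 <- take_extreme(gs$g1)
    g2 <- take_extreme(gs$g2)
  } else {
    ids <- dataset$samples[!is.na(row)]
    v <- row[ids]
    m <- extreme_count(length(ids), config$extreme_fraction)
    low <- ids[order(v, ids)][seq_len(min(m, length(ids)))]
    high <- ids[order(-v, ids)][seq_len(min(m, length(ids)))]
    if (config$direction == "hypo") { g1 <- low; g2 <- high }
    else { g1 <- high; g2 <- low }
  }
  if (length(g1) < config$min_group_samples ||
      length(g2) < config$min_group_samples) {
    return(NULL)
  }
  list(g1 = g1, g2 = g2)
}

#' Call differentially methylated CpGs among distal probes
#'
#' For every distal probe, compares methylation of the two sample sets from
#' [select_comparison_samples()] with a one-sided Welch t test in the
#' configured direction (`"hypo"`: group 1 lower), then applies
#' Benjamini-Hochberg adjustment across all tested probes. A probe is a
#' significant DMC when `padj <= dm_pvalue_cut`, `|diff| >= dm_min_diff`,
#' and the sign of `diff = mean_g1 - mean_g2` matches the direction.
#'
#' @inheritParams select_comparison_samples
#' @param verbose Emit filter counts.
#' @return Tibble of class `ml_dmc` with columns `probe`, `mean_g1`,
#'   `mean_g2`, `diff`, `statistic`, `pvalue`, `padj`, `significant`,
#'   `direction`. Probes skipped for insufficient usable samples are listed
#'   in `attr(, "skipped")`.
#' @export
call_dmcs <- function(dataset, config, verbose = FALSE) {
  probes <- distal_probes(dataset)
  if (length(probes) == 0) abort("no distal probes to test")
  meth <- dataset$meth[probes, , drop = FALSE]

  moments <- function(ids_list) {
    # ids_list: per-probe character vectors of sample ids
    t(vapply(seq_along(ids_list), function(i) {
      v <- meth[i, ids_list[[i]]]
      c(mean(v), stats::var(v), length(v))
    }, numeric(3)))
  }

  sel <- lapply(probes, function(p) select_comparison_samples(p, dataset, config))
  ok <- !vapply(sel, is.null, logical(1))
  skipped <- tibble(probe = probes[!ok],
                    reason = "fewer than min_group_samples usable values in a group")
  if (!any(ok)) abort("zero testable distal probes")
  meth <- meth[ok, , drop = FALSE]
  probes <- probes[ok]
  sel <- sel[ok]

  s1 <- moments(lapply(sel, `[[`, "g1"))
  s2 <- moments(lapply(sel, `[[`, "g2"))
  alternative <- if (config$direction == "hypo") "less" else "greater"
  res <- welch_from_moments(s1[, 1], s1[, 2], s1[, 3],
                            s2[, 1], s2[, 2], s2[, 3], alternative)
  padj <- bh_adjust(res$pvalue)
  diff <- s1[, 1] - s2[, 1]
  sign_ok <- if (config$direction == "hypo") diff < 0 else diff > 0
  out <- tibble(
    probe = probes,
    mean_g1 = s1[, 1], mean_g2 = s2[, 1], diff = diff,
    statistic = res$statistic, pvalue = res$pvalue, padj = padj,
    significant = !is.na(padj) & padj <= config$dm_pvalue_cut &
      abs(diff) >= config$dm_min_diff & sign_ok,
    direction = config$direction
  )
  ml_log("tested %d distal probes, %d significant DMCs, %d skipped",
         nrow(out), sum(out$significant), nrow(skipped), verbose = verbose)
  attr(out, "skipped") <- skipped
  attr(out, "mode") <- config$mode
  class(out) <- c("ml_dmc", class(out))
  out
}
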