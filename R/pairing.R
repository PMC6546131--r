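#' Methylated / unmethylated sample groups at a probe
#'
#' In unsupervised mode, `M` is the `ceiling(n * N)` samples with the
#' highest methylation at the probe and `U` the same number with the
#' lowest (ties broken by sample id). In supervised mode, `M` and `U` are
#' the two predefined groups, oriented so that mean methylation of `M` is at
#' least that of `U` at this probe. Samples with missing beta values are
#' excluded.
#'
#' @inheritParams select_comparison_samples
#' @return List with character vectors `M` and `U`, or `NULL` when the
#'   methylation row is degenerate (constant) or fewer than 10 usable
#'   samples remain.
#' @export
define_mu_groups <- function(probe_id, dataset, config) {
  row <- dataset$meth[probe_id, ]
  ids <- dataset$samples[!is.na(row)]
  v <- row[ids]
  if (length(ids) < 10 || length(unique(v)) == 1L) return(NULL)
  if (config$mode == "supervised") {
    gs <- group_sample_ids(dataset, config)
    if (is.null(gs)) abort("supervised mode needs group labels")
    a <- gs$g1[!is.na(row[gs$g1])]
    b <- gs$g2[!is.na(row[gs$g2])]
    if (mean(row[a]) >= mean(row[b])) list(M = a, U = b) else list(M = b, U = a)
  } else {
    m <- extreme_count(length(ids), config$extreme_fraction)
    list(M = ids[order(-v, ids)][seq_len(m)],
         U = ids[order(v, ids)][seq_len(m)])
  }
}

#' Raw probe-gene association p-value
#'
#' One-sided Mann-Whitney test on the gene's expression between the `U` and
#' `M` sample groups of a probe. For a `"hypo"` run the alternative is
#' "U expresses more than M" (anti-correlation of methylation and
#' expression); for `"hyper"` the reverse.
#'
#' @param probe_id,gene_id Identifiers.
#' @param M_ids,U_ids Sample id vectors from [define_mu_groups()].
#' @param dataset A [paired_omics] object.
#' @param direction `"hypo"` or `"hyper"`.
#' @return The raw p-value (NA when expression is all-missing).
#' @export
score_pair <- function(probe_id, gene_id, M_ids, U_ids, dataset,
                       direction = "hypo") {
  xu <- dataset$expr[gene_id, U_ids]
  xm <- dataset$expr[gene_id, M_ids]
  alt <- if (direction == "hypo") "greater" else "less"
  mann_whitney_one_sided(xu, xm, alt)$pvalue
}

# per-distal-probe extreme M/U sample column indices used by the
# permutation null; returns index matrices when group sizes are uniform
# (the fast path), else index lists
mu_extreme_index <- function(dataset, config, probes = distal_probes(dataset)) {
  n <- length(dataset$samples)
  sets <- lapply(probes, function(p) {
    row <- dataset$meth[p, ]
    usable <- which(!is.na(row))
    if (length(usable) < 10 || length(unique(row[usable])) == 1L) return(NULL)
    m <- extreme_count(length(usable), config$extreme_fraction)
    o_lo <- usable[order(row[usable], dataset$samples[usable])]
    o_hi <- usable[order(-row[usable], dataset$samples[usable])]
    list(M = o_hi[seq_len(m)], U = o_lo[seq_len(m)])
  })
  names(sets) <- probes
  sets
}

#' Empirical permutation p-value for one probe-gene pair
#'
#' Draws `config$n_permutations` random distal probes (excluding the probe
#' itself), scores the same gene against the methylation-extreme M/U groups
#' of each random probe, and returns the add-one empirical p-value of the
#' observed association within that null. The draw is reproducible from
#' `config$rng_seed` and a stable hash of (probe, gene), so results do not
#' depend on evaluation order.
#'
#' @inheritParams score_pair
#' @param config An [analysis_config()].
#' @param mu_sets Optional precomputed [mu_extreme_index] result (internal
#'   cache used by [find_pairs()]).
#' @param obs_groups Optional observed M/U groups (defaults to
#'   [define_mu_groups()] for the probe).
#' @return List with `pe` and `effective_R`.
#' @export
permutation_null <- function(probe_id, gene_id, dataset, config,
                             mu_sets = NULL, obs_groups = NULL) {
  pool <- setdiff(distal_probes(dataset), probe_id)
  if (length(pool) < 1) abort("no eligible distal probes for the null")
  if (is.null(mu_sets)) mu_sets <- mu_extreme_index(dataset, config, pool)
  obs_groups <- obs_groups %||% define_mu_groups(probe_id, dataset, config)
  if (is.null(obs_groups)) return(list(pe = NA_real_, effective_R = 0L))

  seed_pg <- (config$rng_seed + hash32(probe_id, gene_id)) %% 2147483647
  null_probes <- with_seed(seed_pg, {
    if (length(pool) >= config$n_permutations) {
      sample(pool, config$n_permutations)
    } else {
      pool
    }
  })
  sets <- mu_sets[null_probes]
  sets <- sets[!vapply(sets, is.null, logical(1))]
  r_eff <- length(sets)
  if (r_eff == 0) return(list(pe = NA_real_, effective_R = 0L))

  gx <- dataset$expr[gene_id, ]
  has_ties <- anyDuplicated(gx[!is.na(gx)]) > 0L
  alt <- if (config$direction == "hypo") "greater" else "less"
  sizes_u <- lengths(lapply(sets, `[[`, "U"))
  sizes_m <- lengths(lapply(sets, `[[`, "M"))
  if (length(unique(sizes_u)) == 1L && length(unique(sizes_m)) == 1L) {
    xu <- matrix(gx[t(vapply(sets, `[[`, integer(sizes_u[1]), "U"))],
                 nrow = r_eff)
    xm <- matrix(gx[t(vapply(sets, `[[`, integer(sizes_m[1]), "M"))],
                 nrow = r_eff)
    null_p <- mw_batch_p(xu, xm, alt, ties = has_ties)
  } else {
    null_p <- vapply(sets, function(s) {
      mw_batch_p(matrix(gx[s$U], nrow = 1), matrix(gx[s$M], nrow = 1), alt,
                 ties = has_ties)
    }, numeric(1))
  }
  obs_p <- mw_batch_p(matrix(gx[obs_groups$U], nrow = 1),
                      matrix(gx[obs_groups$M], nrow = 1), alt,
                      ties = has_ties)
  list(pe = empirical_p(obs_p, null_p, smaller_is_better = TRUE),
       effective_R = r_eff)
}

#' Link significant DMCs to putative target genes
#'
#' For every significant DMC and each of its nearest candidate genes,
#' computes the raw Mann-Whitney association p-value and the permutation
#' empirical p-value `pe`; a pair is significant when `pe < config$pe_cut`.
#' All tested pairs are returned with their flags.
#'
#' @param dataset A [paired_omics] object with distal probes selected.
#' @param dmcs An `ml_dmc` tibble from [call_dmcs()] (only rows with
#'   `significant == TRUE` are paired).
#' @param config An [analysis_config()].
#' @param verbose Emit progress messages.
#' @return Tibble of class `ml_pairs` with columns `probe`, `gene`, `side`,
#'   `rank`, `distance`, `raw_pvalue`, `pe`, `significant`.
#' @export
find_pairs <- function(dataset, dmcs, config, verbose = FALSE) {
  stopifnot(nrow(dmcs) > 0)
  sig <- dmcs$probe[dmcs$significant]
  empty <- tibble(probe = character(), gene = character(), side = character(),
                  rank = integer(), distance = integer(),
                  raw_pvalue = numeric(), pe = numeric(),
                  significant = logical())
  if (length(sig) == 0) {
    ml_log("no significant DMCs: no pairs to test", verbose = verbose)
    class(empty) <- c("ml_pairs", class(empty))
    return(empty)
  }
  pool <- distal_probes(dataset)
  mu_sets <- mu_extreme_index(dataset, config, pool)
  usable <- !vapply(mu_sets, is.null, logical(1))
  # uniform extreme-group sizes (the usual case: no missing betas) allow a
  # matrix fast path for the permutation scoring
  sizes <- lengths(lapply(mu_sets[usable], `[[`, "U"))
  mats <- NULL
  if (length(unique(sizes)) == 1L) {
    m <- sizes[1]
    mats <- list(
      U = t(vapply(mu_sets[usable], `[[`, integer(m), "U")),
      M = t(vapply(mu_sets[usable], `[[`, integer(m), "M")),
      probes = pool[usable]
    )
  }
  alt <- if (config$direction == "hypo") "greater" else "less"
  r <- config$n_permutations

  cand_list <- lapply(sig, function(p) {
    cand <- nearest_genes(p, dataset, config$num_nearest_genes)
    cand[cand$gene %in% rownames(dataset$expr), ]
  })
  n_total <- sum(vapply(cand_list, nrow, integer(1)))
  probe_v <- character(n_total); gene_v <- character(n_total)
  side_v <- character(n_total); rank_v <- integer(n_total)
  dist_v <- integer(n_total); raw_v <- numeric(n_total); pe_v <- numeric(n_total)
  k <- 0L
  for (i in seq_along(sig)) {
    p <- sig[i]
    cand <- cand_list[[i]]
    if (nrow(cand) == 0) next
    obs <- define_mu_groups(p, dataset, config)
    if (is.null(obs)) next
    for (j in seq_len(nrow(cand))) {
      g <- cand$gene[j]
      raw <- score_pair(p, g, obs$M, obs$U, dataset, config$direction)
      if (is.na(raw)) next
      gx <- dataset$expr[g, ]
      has_ties <- anyDuplicated(gx[!is.na(gx)]) > 0L
      if (!is.null(mats)) {
        eligible <- which(mats$probes != p)
        null_rows <- if (length(eligible) >= r) {
          seed_pg <- (config$rng_seed + hash32(p, g)) %% 2147483647
          with_seed(seed_pg, eligible[sample.int(length(eligible), r)])
        } else eligible
        xu <- matrix(gx[mats$U[null_rows, , drop = FALSE]],
                     nrow = length(null_rows))
        xm <- matrix(gx[mats$M[null_rows, , drop = FALSE]],
                     nrow = length(null_rows))
        null_p <- mw_batch_p(xu, xm, alt, ties = has_ties)
        obs_p <- mw_batch_p(matrix(gx[obs$U], nrow = 1),
                            matrix(gx[obs$M], nrow = 1), alt, ties = has_ties)
        pe <- empirical_p(obs_p, null_p, smaller_is_better = TRUE)
      } else {
        pe <- permutation_null(p, g, dataset, config,
                               mu_sets = mu_sets, obs_groups = obs)$pe
      }
      k <- k + 1L
      probe_v[k] <- p; gene_v[k] <- g; side_v[k] <- cand$side[j]
      rank_v[k] <- cand$rank[j]; dist_v[k] <- cand$distance[j]
      raw_v[k] <- raw; pe_v[k] <- pe
    }
  }
  out <- if (k > 0) {
    idx <- seq_len(k)
    tibble(probe = probe_v[idx], gene = gene_v[idx], side = side_v[idx],
           rank = rank_v[idx], distance = dist_v[idx],
           raw_pvalue = raw_v[idx], pe = pe_v[idx],
           significant = !is.na(pe_v[idx]) & pe_v[idx] < config$pe_cut)
  } else empty
  ml_log("tested %d probe-gene pairs, %d significant",
         nrow(out), sum(out$significant), verbose = verbose)
  attr(out, "n_dmcs_paired") <- length(sig)
  class(out) <- c("ml_pairs", class(out))
  out
}
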