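#' Read chromatin-interaction loops from BEDPE
#'
#' Headerless BEDPE: chrom1, start1, end1, chrom2, start2, end2 (extra
#' columns ignored), 0-based half-open anchors.
#'
#' @param path File path.
#' @return Tibble with the six anchor columns and a `loop` id.
#' @export
read_bedpe <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(bed) < 6) abort("BEDPE needs at least 6 columns")
  tibble(chrom1 = as.character(bed[[1]]), start1 = as.integer(bed[[2]]),
         end1 = as.integer(bed[[3]]), chrom2 = as.character(bed[[4]]),
         start2 = as.integer(bed[[5]]), end2 = as.integer(bed[[6]]),
         loop = seq_len(nrow(bed)))
}

# which (pos1, pos2) point pairs fall inside a loop's two anchors (either
# orientation); returns a logical matrix pairs x loops
loop_support_matrix <- function(chrom_p, pos_p, chrom_t, pos_t, loops) {
  n <- length(pos_p)
  vapply(seq_len(nrow(loops)), function(i) {
    l <- loops[i, ]
    in1_p <- chrom_p == l$chrom1 & pos_p >= l$start1 & pos_p < l$end1
    in2_p <- chrom_p == l$chrom2 & pos_p >= l$start2 & pos_p < l$end2
    in1_t <- chrom_t == l$chrom1 & pos_t >= l$start1 & pos_t < l$end1
    in2_t <- chrom_t == l$chrom2 & pos_t >= l$start2 & pos_t < l$end2
    (in1_p & in2_t) | (in2_p & in1_t)
  }, logical(n))
}

#' Evaluate predicted pairs against chromatin loops
#'
#' A predicted (significant) probe-gene pair is loop-supported when the
#' probe position falls inside one anchor of a loop and the gene TSS inside
#' the other, in either orientation. Precision is the supported fraction of
#' predicted pairs; recall is the fraction of evaluable loops (loops with at
#' least one *tested* probe-gene combination spanning their anchors) hit by
#' at least one predicted pair. The enrichment ratio compares the observed
#' precision with the mean precision after re-drawing each predicted pair's
#' gene uniformly from that probe's candidate gene list.
#'
#' @param pair_records An `ml_pairs` tibble from [find_pairs()] (all tested
#'   pairs; the `significant` flag marks predictions).
#' @param loops Tibble from [read_bedpe()].
#' @param dataset The [paired_omics] object the pairs came from.
#' @param config The [analysis_config()] used (for the candidate list size).
#' @param n_randomizations Gene re-draws (default 100).
#' @param seed Integer seed for the randomization.
#' @return One-row tibble: `n_predicted`, `n_supported`, `precision`,
#'   `n_loops_evaluable`, `n_loops_hit`, `recall`, `random_precision_mean`,
#'   `random_precision_se`, `enrichment_ratio`.
#' @export
evaluate_against_loops <- function(pair_records, loops, dataset, config,
                                   n_randomizations = 100, seed = 1) {
  if (nrow(loops) == 0) abort("empty loop set")
  pred <- pair_records[pair_records$significant, ]
  if (nrow(pred) == 0) abort("no significant pairs to evaluate")
  pa <- dataset$probe_annot
  ga <- dataset$gene_annot
  locate <- function(df) {
    pi <- match(df$probe, pa$probe)
    gi <- match(df$gene, ga$gene)
    list(chrom_p = pa$chrom[pi], pos_p = pa$pos[pi],
         chrom_t = ga$chrom[gi], pos_t = ga$tss[gi])
  }
  lp <- locate(pred)
  sup_pred <- loop_support_matrix(lp$chrom_p, lp$pos_p, lp$chrom_t, lp$pos_t,
                                  loops)
  sup_pred <- matrix(sup_pred, nrow = nrow(pred))
  lt <- locate(pair_records)
  sup_tested <- matrix(
    loop_support_matrix(lt$chrom_p, lt$pos_p, lt$chrom_t, lt$pos_t, loops),
    nrow = nrow(pair_records)
  )
  evaluable <- colSums(sup_tested) > 0
  hit <- colSums(sup_pred) > 0
  precision <- mean(rowSums(sup_pred) > 0)
  recall <- if (any(evaluable)) sum(hit & evaluable) / sum(evaluable) else NA_real_

  # null: keep each predicted probe, re-draw its gene from the candidates
  cand <- lapply(unique(pred$probe), function(p) {
    nearest_genes(p, dataset, config$num_nearest_genes)$gene
  })
  names(cand) <- unique(pred$probe)
  rand_prec <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(i) {
      genes <- vapply(pred$probe, function(p) {
        g <- cand[[p]]
        g[sample.int(length(g), 1)]
      }, character(1))
      lr <- locate(tibble(probe = pred$probe, gene = genes))
      m <- matrix(loop_support_matrix(lr$chrom_p, lr$pos_p, lr$chrom_t,
                                      lr$pos_t, loops), nrow = nrow(pred))
      mean(rowSums(m) > 0)
    }, numeric(1))
  })
  rp_mean <- mean(rand_prec)
  ratio <- if (is.na(rp_mean) || rp_mean == 0) NA_real_ else precision / rp_mean
  if (all(colSums(sup_tested) == 0) && precision == 0) ratio <- NA_real_
  tibble(
    n_predicted = nrow(pred), n_supported = sum(rowSums(sup_pred) > 0),
    precision = precision,
    n_loops_evaluable = sum(evaluable), n_loops_hit = sum(hit & evaluable),
    recall = recall,
    random_precision_mean = rp_mean,
    random_precision_se = stats::sd(rand_prec) / sqrt(length(rand_prec)),
    enrichment_ratio = ratio
  )
}
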