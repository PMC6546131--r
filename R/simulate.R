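#' Simulate a paired methylation/expression cohort with planted signal
#'
#' Generates a desk-scale two-subtype cohort in which a chosen set of distal
#' enhancer probes loses methylation in the case subtype, each planted probe
#' drives elevated expression of one nearby target gene, a planted motif
#' flanks every planted probe (plus a ~5% background of other probes), and a
#' planted transcription factor's expression is a negative affine transform
#' of the mean planted-probe methylation. Everything else is noise: null
#' probe beta values are logit-normal around per-probe baselines and null
#' gene expression is Gaussian on the log2 scale.
#'
#' The genome layout is a single chromosome with uniformly spaced gene TSSs
#' (50 kb apart), so every probe has at least 10 genes on each side; each
#' planted probe sits 2.5-25 kb downstream of its target's TSS, making the
#' target its nearest upstream candidate gene. All probes are distal (> 2 kb
#' from every TSS).
#'
#' @param n_samples,n_probes,n_genes Cohort dimensions.
#' @param n_planted_pairs Number of planted probe-gene pairs (must be at
#'   most `n_probes / 4` and fit the gene layout).
#' @param beta_shift Methylation loss (beta scale) of planted probes in case
#'   samples; values are clipped to \[0, 1\] and the clip rate is reported.
#' @param expr_log2fc Expression gain (log2) of planted target genes in case
#'   samples.
#' @param case_fraction Fraction of samples labeled `case`.
#' @param noise_sd Expression noise standard deviation (log2 units).
#' @param logit_sd Methylation noise standard deviation on the logit scale.
#' @param n_decoy_motifs Number of unplanted motifs scattered at background
#'   rate.
#' @param motif_background_rate Per-probe probability of carrying any given
#'   motif by chance.
#' @param n_tfs Number of annotated transcription factors (including the
#'   planted one).
#' @param seed Integer seed; the output is bit-identical across calls with
#'   the same arguments.
#' @param verbose Emit the clipping-rate message.
#' @return A list of class `ml_simulation` with elements `dataset`
#'   ([paired_omics]), `truth` (planted pairs/DMCs/motif/TF and subtype
#'   labels), `motif_intervals` (tibble: chrom, start, end, motif),
#'   `tf_annotation` (tibble: tf, motifs, family, subfamily), and `params`.
#' @examples
#' sim <- simulate_cohort(n_samples = 20, n_probes = 100, n_genes = 60,
#'                        n_planted_pairs = 5, seed = 7)
#' sim$truth$planted_pairs
#' @export
simulate_cohort <- function(n_samples = 100, n_probes = 2000, n_genes = 300,
                            n_planted_pairs = 50, beta_shift = 0.4,
                            expr_log2fc = 2, case_fraction = 0.5,
                            noise_sd = 1, logit_sd = 0.5,
                            n_decoy_motifs = 20, motif_background_rate = 0.05,
                            n_tfs = 30, seed = 1, verbose = FALSE) {
  stopifnot(n_planted_pairs <= n_probes / 4, n_samples >= 4,
            beta_shift >= 0, expr_log2fc >= 0, noise_sd > 0, logit_sd > 0,
            case_fraction > 0, case_fraction < 1)
  gene_spacing <- 50000L
  edge <- 10L
  eligible <- seq.int(edge + 1L, n_genes - edge)
  if (length(eligible) < n_planted_pairs + 1) {
    abort("infeasible layout: too few interior genes for the planted pairs and TF")
  }
  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    n_case <- max(1L, round(case_fraction * n_samples))
    subtype <- setNames(c(rep("case", n_case), rep("control", n_samples - n_case)),
                        samples)

    genes <- sprintf("G%04d", seq_len(n_genes))
    gene_annot <- tibble(gene = genes, chrom = "chr1",
                         tss = as.integer(seq_len(n_genes)) * gene_spacing,
                         strand = rep(c("+", "-"), length.out = n_genes))

    planted_slots <- sort(sample(eligible, n_planted_pairs + 1))
    tf_slot <- planted_slots[length(planted_slots)]
    planted_slots <- planted_slots[-length(planted_slots)]
    planted_genes <- genes[planted_slots]
    planted_tf <- genes[tf_slot]

    probes <- sprintf("cg%05d", seq_len(n_probes))
    planted_probes <- probes[seq_len(n_planted_pairs)]
    # planted probes 2.5-25 kb downstream of their target's TSS
    pos <- integer(n_probes)
    pos[seq_len(n_planted_pairs)] <-
      gene_annot$tss[planted_slots] +
      sample(2500:25000, n_planted_pairs, replace = TRUE)
    # remaining probes anywhere in the interior, > 2 kb from every TSS
    lo <- gene_annot$tss[edge + 1L]
    hi <- gene_annot$tss[n_genes - edge]
    n_rest <- n_probes - n_planted_pairs
    rest <- integer(0)
    while (length(rest) < n_rest) {
      cand <- sample(lo:hi, n_rest - length(rest), replace = TRUE)
      off <- cand %% gene_spacing
      rest <- c(rest, cand[off > 2000 & off < gene_spacing - 2000])
    }
    pos[(n_planted_pairs + 1):n_probes] <- rest
    probe_annot <- tibble(probe = probes, chrom = "chr1", pos = pos)

    # methylation: logit-normal around per-probe baselines; planted probes
    # start methylated and lose beta_shift in case samples
    baseline <- runif(n_probes, 0.1, 0.9)
    baseline[seq_len(n_planted_pairs)] <- runif(n_planted_pairs, 0.65, 0.9)
    meth <- matrix(
      plogis(rnorm(n_probes * n_samples,
                   mean = rep(qlogis(baseline), n_samples), sd = logit_sd)),
      nrow = n_probes, ncol = n_samples, dimnames = list(probes, samples)
    )
    is_case <- subtype[samples] == "case"
    raw <- meth[seq_len(n_planted_pairs), is_case, drop = FALSE] - beta_shift
    clipped <- sum(raw < 0)
    meth[seq_len(n_planted_pairs), is_case] <- pmax(raw, 0)
    clip_rate <- clipped / length(meth)
    ml_log("clipped %d beta value(s) (%.3f%% of matrix)", clipped,
           100 * clip_rate, verbose = verbose)

    # expression: Gaussian log2 values; planted targets gain expr_log2fc in
    # case samples; planted TF tracks mean planted-probe methylation
    mu_g <- runif(n_genes, 4, 8)
    expr <- matrix(
      rnorm(n_genes * n_samples, mean = rep(mu_g, n_samples), sd = noise_sd),
      nrow = n_genes, ncol = n_samples, dimnames = list(genes, samples)
    )
    expr[planted_slots, is_case] <- expr[planted_slots, is_case] + expr_log2fc
    mm <- colMeans(meth[seq_len(n_planted_pairs), , drop = FALSE])
    slope <- expr_log2fc / max(beta_shift, 0.2)
    expr[tf_slot, ] <- mu_g[tf_slot] + slope * (mean(mm) - mm) +
      rnorm(n_samples, sd = noise_sd / 2)

    # motif instances: planted motif flanks every planted probe within the
    # scoring window; every motif also appears at background rate
    planted_motif <- "M_PLANTED"
    motifs <- c(planted_motif, sprintf("M_D%02d", seq_len(n_decoy_motifs)))
    inst <- list(tibble(chrom = "chr1",
                        start = pos[seq_len(n_planted_pairs)] +
                          sample(-240:230, n_planted_pairs, replace = TRUE),
                        end = NA_integer_, motif = planted_motif))
    for (m in motifs) {
      hit <- which(runif(n_probes) < motif_background_rate)
      if (m == planted_motif) hit <- setdiff(hit, seq_len(n_planted_pairs))
      if (length(hit) > 0) {
        inst[[length(inst) + 1]] <-
          tibble(chrom = "chr1",
                 start = pos[hit] + sample(-240:230, length(hit), replace = TRUE),
                 end = NA_integer_, motif = m)
      }
    }
    motif_intervals <- bind_rows(inst)
    motif_intervals$start <- pmax(motif_intervals$start, 0L)
    motif_intervals$end <- motif_intervals$start + 10L
    motif_intervals <- arrange(motif_intervals, .data$chrom, .data$start,
                               .data$motif)

    # TF annotation: planted TF and one same-family sibling share the
    # planted motif; decoy motifs are spread over null-gene TFs
    non_planted <- setdiff(setdiff(genes, planted_genes), planted_tf)
    other_tfs <- sample(non_planted, n_tfs - 1)
    tf_ids <- c(planted_tf, other_tfs)
    fams <- sprintf("F%02d", 1 + (seq_len(n_tfs) - 1) %% 8)
    tf_annotation <- tibble(
      tf = tf_ids, family = fams,
      subfamily = sprintf("%s.%d", fams, 1 + (seq_len(n_tfs) - 1) %% 2),
      motifs = ""
    )
    tf_annotation$family[1] <- "F01"
    sibling <- which(tf_annotation$family == "F01" & tf_annotation$tf != planted_tf)[1]
    tf_annotation$motifs[1] <- planted_motif
    if (!is.na(sibling)) tf_annotation$motifs[sibling] <- planted_motif
    decoys <- setdiff(motifs, planted_motif)
    owner <- 2 + (seq_along(decoys) - 1) %% (n_tfs - 1)
    for (i in seq_along(decoys)) {
      cur <- tf_annotation$motifs[owner[i]]
      tf_annotation$motifs[owner[i]] <-
        if (nzchar(cur)) paste(cur, decoys[i], sep = ",") else decoys[i]
    }
    tf_annotation <- tf_annotation[, c("tf", "motifs", "family", "subfamily")]

    dataset <- paired_omics(meth, expr, probe_annot, gene_annot,
                            groups = subtype)
    dataset <- select_distal_probes(dataset, 2000)
    truth <- list(
      planted_pairs = tibble(probe = planted_probes, gene = planted_genes),
      planted_dmcs = planted_probes,
      planted_motif = planted_motif,
      planted_tf = planted_tf,
      subtype_of_sample = subtype,
      beta_shift = beta_shift,
      expr_log2fc = expr_log2fc,
      clip_rate = clip_rate
    )
    params <- list(n_samples = n_samples, n_probes = n_probes,
                   n_genes = n_genes, n_planted_pairs = n_planted_pairs,
                   beta_shift = beta_shift, expr_log2fc = expr_log2fc,
                   case_fraction = case_fraction, noise_sd = noise_sd,
                   logit_sd = logit_sd, n_decoy_motifs = n_decoy_motifs,
                   motif_background_rate = motif_background_rate,
                   n_tfs = n_tfs, seed = seed)
    structure(list(dataset = dataset, truth = truth,
                   motif_intervals = motif_intervals,
                   tf_annotation = tf_annotation, params = params),
              class = "ml_simulation")
  })
}

#' Write a simulated cohort as a pipeline-ready fixture
#'
#' Emits every file format the loaders consume: the matrix/annotation TSVs
#' of [write_dataset()], the motif instances as BED (name column = motif
#' id), the TF annotation TSV, the simulation truth as TSV, and the full
#' parameter set as YAML.
#'
#' @param sim An `ml_simulation` from [simulate_cohort()].
#' @param out_dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "ml_simulation"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_dataset(sim$dataset, out_dir)
  paths[["motifs"]] <- file.path(out_dir, "motif_instances.bed")
  bed <- sim$motif_intervals[, c("chrom", "start", "end", "motif")]
  readr::write_tsv(bed, paths[["motifs"]], col_names = FALSE, progress = FALSE)
  paths[["tf_annotation"]] <- file.path(out_dir, "tf_annotation.tsv")
  readr::write_tsv(sim$tf_annotation, paths[["tf_annotation"]], progress = FALSE)
  paths[["truth_pairs"]] <- file.path(out_dir, "truth_pairs.tsv")
  readr::write_tsv(sim$truth$planted_pairs, paths[["truth_pairs"]],
                   progress = FALSE)
  paths[["truth_samples"]] <- file.path(out_dir, "truth_samples.tsv")
  readr::write_tsv(tibble(sample = names(sim$truth$subtype_of_sample),
                          subtype = unname(sim$truth$subtype_of_sample)),
                   paths[["truth_samples"]], progress = FALSE)
  paths[["params"]] <- file.path(out_dir, "params.yaml")
  writeLines(yaml::as.yaml(c(sim$params,
                             list(planted_motif = sim$truth$planted_motif,
                                  planted_tf = sim$truth$planted_tf))),
             paths[["params"]])
  invisible(paths)
}
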