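# shared fixtures built in code

# small planted cohort for fast module tests
small_sim <- function(seed = 42, ...) {
  simulate_cohort(n_samples = 60, n_probes = 400, n_genes = 120,
                  n_planted_pairs = 15, beta_shift = 0.4, expr_log2fc = 2,
                  seed = seed, ...)
}

supervised_config <- function(...) {
  analysis_config(mode = "supervised", group1 = "case", group2 = "control",
                  ...)
}

# hand-built dataset with a known layout: one chromosome, genes every 10 kb
toy_dataset <- function(n_probes = 6, n_genes = 8, n_samples = 10,
                        groups = NULL, seed = 1) {
  set.seed(seed)
  probes <- paste0("p", seq_len(n_probes))
  genes <- paste0("g", seq_len(n_genes))
  samples <- paste0("s", sprintf("%03d", seq_len(n_samples)))
  meth <- matrix(runif(n_probes * n_samples), n_probes,
                 dimnames = list(probes, samples))
  expr <- matrix(rnorm(n_genes * n_samples, 6), n_genes,
                 dimnames = list(genes, samples))
  pa <- tibble::tibble(probe = probes, chrom = "chr1",
                       pos = as.integer(seq_len(n_probes)) * 9000L + 4500L)
  ga <- tibble::tibble(gene = genes, chrom = "chr1",
                       tss = as.integer(seq_len(n_genes)) * 10000L,
                       strand = "+")
  paired_omics(meth, expr, pa, ga, groups = groups)
}

# exact Mann-Whitney tail by enumeration over all rank assignments
mw_enum_p <- function(x, y, alternative) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  if (alternative == "less") mean(all_u <= u_obs) else mean(all_u >= u_obs)
}

# hypergeometric tail by explicit binomial-coefficient enumeration
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  j <- max(0, k - r2):min(r1, k)
  probs <- choose(r1, j) * choose(r2, k - j) / choose(r1 + r2, k)
  sum(probs[j >= a])
}
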