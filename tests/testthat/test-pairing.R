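test_that("M/U group construction is disjoint, oriented and order-invariant", {
  groups <- setNames(rep(c("case", "control"), each = 50),
                     paste0("s", sprintf("%03d", 1:100)))
  ds <- toy_dataset(n_probes = 3, n_genes = 8, n_samples = 100,
                    groups = groups, seed = 4)
  cfg <- analysis_config(mode = "unsupervised", extreme_fraction = 0.2)
  mu <- define_mu_groups("p1", ds, cfg)
  expect_length(mu$M, 20)
  expect_length(mu$U, 20)
  expect_length(intersect(mu$M, mu$U), 0)
  v <- ds$meth["p1", ]
  expect_true(min(v[mu$M]) >= max(v[setdiff(names(v), c(mu$M, mu$U))]))

  # supervised orientation: the hypomethylated group becomes U
  ds$meth["p2", groups == "case"] <- ds$meth["p2", groups == "case"] * 0.2
  mu <- define_mu_groups("p2", ds, supervised_config())
  expect_setequal(mu$U, names(groups)[groups == "case"])
  expect_setequal(mu$M, names(groups)[groups == "control"])

  # permuting the sample columns does not change the selected sets
  perm <- sample(ncol(ds$meth))
  ds_perm <- paired_omics(ds$meth[, perm], ds$expr[, perm],
                          ds$probe_annot, ds$gene_annot,
                          groups = ds$groups[perm])
  expect_setequal(define_mu_groups("p1", ds_perm, cfg)$M,
                  define_mu_groups("p1", ds, cfg)$M)

  # degenerate rows are skipped
  ds$meth["p3", ] <- 0.5
  expect_null(define_mu_groups("p3", ds, cfg))
})

test_that("pair scoring is directional and handles flat expression", {
  sim <- small_sim(seed = 5)
  ds <- sim$dataset
  cfg <- supervised_config(rng_seed = 5)
  pair <- sim$truth$planted_pairs[1, ]
  mu <- define_mu_groups(pair$probe, ds, cfg)
  expect_lt(score_pair(pair$probe, pair$gene, mu$M, mu$U, ds, "hypo"), 0.001)

  ds$expr[pair$gene, ] <- 3.14
  expect_gte(score_pair(pair$probe, pair$gene, mu$M, mu$U, ds, "hypo"), 0.5)
})

test_that("permutation p-values hit the add-one floor for planted pairs", {
  sim <- small_sim(seed = 8)
  cfg <- supervised_config(n_permutations = 200, rng_seed = 8)
  pair <- sim$truth$planted_pairs[2, ]
  pn <- permutation_null(pair$probe, pair$gene, sim$dataset, cfg)
  expect_equal(pn$effective_R, 200)
  expect_equal(pn$pe, 1 / 201)

  # a probe paired with an unrelated gene is not extreme in its null
  null_gene <- setdiff(rownames(sim$dataset$expr),
                       c(sim$truth$planted_pairs$gene, sim$truth$planted_tf))[1]
  pn0 <- permutation_null(pair$probe, null_gene, sim$dataset, cfg)
  expect_gte(pn0$pe, 0.05)

  # R = 1 gives pe in {1/2, 1}
  cfg1 <- supervised_config(n_permutations = 1, rng_seed = 8)
  pn1 <- permutation_null(pair$probe, pair$gene, sim$dataset, cfg1)
  expect_true(pn1$pe %in% c(0.5, 1))

  # fewer eligible probes than R: all are used and logged in effective_R
  cfg_big <- supervised_config(n_permutations = 10000, rng_seed = 8)
  pn_big <- permutation_null(pair$probe, pair$gene, sim$dataset, cfg_big)
  expect_equal(pn_big$effective_R, length(distal_probes(sim$dataset)) - 1)
})

test_that("find_pairs links planted probes to their targets deterministically", {
  sim <- small_sim(seed = 12)
  cfg <- supervised_config(n_permutations = 300, pe_cut = 0.005, rng_seed = 12)
  dm <- call_dmcs(sim$dataset, cfg)
  pr <- find_pairs(sim$dataset, dm, cfg)

  truth_keys <- paste(sim$truth$planted_pairs$probe, sim$truth$planted_pairs$gene)
  got_keys <- paste(pr$probe, pr$gene)[pr$significant]
  expect_gte(mean(truth_keys %in% got_keys), 0.9)

  # every significant pair's probe is a significant DMC within the window
  sig <- pr[pr$significant, ]
  expect_true(all(sig$probe %in% dm$probe[dm$significant]))
  expect_true(all(sig$rank <= cfg$num_nearest_genes / 2))
  expect_true(all(pr$pe >= 1 / (cfg$n_permutations + 1) & pr$pe <= 1))

  # bit-identical rerun with the same seed
  pr2 <- find_pairs(sim$dataset, dm, cfg)
  expect_identical(pr$pe, pr2$pe)

  # a different RNG seed leaves the planted significant set stable
  cfg_b <- supervised_config(n_permutations = 300, pe_cut = 0.005,
                             rng_seed = 4242)
  pr3 <- find_pairs(sim$dataset, dm, cfg_b)
  expect_setequal(intersect(got_keys, truth_keys),
                  intersect(paste(pr3$probe, pr3$gene)[pr3$significant],
                            truth_keys))

  # no significant DMCs: empty pair table
  dm0 <- dm
  dm0$significant <- FALSE
  expect_equal(nrow(find_pairs(sim$dataset, dm0, cfg)), 0)
})

test_that("null-gene association p-values are calibrated", {
  # expression of a gene unrelated to the probe: raw p approximately uniform
  sim <- simulate_cohort(n_samples = 60, n_probes = 300, n_genes = 120,
                         n_planted_pairs = 10, beta_shift = 0, expr_log2fc = 0,
                         seed = 33)
  ds <- sim$dataset
  cfg <- analysis_config(mode = "unsupervised", rng_seed = 33)
  set.seed(1)
  probes <- sample(distal_probes(ds), 500, replace = TRUE)
  genes <- sample(rownames(ds$expr), 500, replace = TRUE)
  raw <- vapply(seq_len(500), function(i) {
    mu <- define_mu_groups(probes[i], ds, cfg)
    score_pair(probes[i], genes[i], mu$M, mu$U, ds, "hypo")
  }, numeric(1))
  ks <- suppressWarnings(ks.test(raw, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical p-values under the global null are conservative", {
  # >= 10,000 null pairs: fraction with pe < 0.001 must stay below 0.002
  sim <- simulate_cohort(n_samples = 100, n_probes = 2000, n_genes = 300,
                         n_planted_pairs = 50, beta_shift = 0, expr_log2fc = 0,
                         seed = 44)
  cfg <- supervised_config(n_permutations = 1000, rng_seed = 44)
  dm <- call_dmcs(sim$dataset, cfg)
  forced <- dm
  set.seed(2)
  forced$significant <- forced$probe %in% sample(forced$probe, 500)
  pr <- find_pairs(sim$dataset, forced, cfg)
  expect_gte(nrow(pr), 10000)
  expect_lte(mean(pr$pe < 0.001), 0.002)
})
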