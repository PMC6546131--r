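test_that("signature computation matches explicit averaging", {
  sim <- small_sim(seed = 16)
  ds <- sim$dataset
  one <- motif_mean_methylation(ds, "cg00003")
  expect_equal(unname(one), unname(ds$meth["cg00003", ]))

  ds2 <- ds
  ds2$meth["cg00001", ] <- 0.2
  ds2$meth["cg00002", ] <- 0.6
  expect_true(all(abs(motif_mean_methylation(ds2, c("cg00001", "cg00002")) - 0.4)
                  < 1e-12))

  set.seed(1)
  probes <- sample(rownames(ds$meth), 20)
  got <- motif_mean_methylation(ds, probes)
  naive <- vapply(ds$samples, function(s) {
    acc <- 0
    for (p in probes) acc <- acc + ds$meth[p, s]
    acc / length(probes)
  }, numeric(1))
  expect_equal(got, naive, tolerance = 1e-12)

  # missing values are excluded per sample
  ds2$meth["cg00001", 1] <- NA
  mm <- motif_mean_methylation(ds2, c("cg00001", "cg00002"))
  expect_equal(unname(mm[1]), 0.6)
  expect_error(motif_mean_methylation(ds, character(0)), "empty")
})

test_that("the planted TF ranks first for the planted motif", {
  sim <- small_sim(seed = 18)
  ds <- sim$dataset
  cfg <- supervised_config(rng_seed = 18)
  mm <- motif_mean_methylation(ds, sim$truth$planted_dmcs)
  rk <- rank_tfs(ds, mm, sim$tf_annotation, cfg)
  expect_equal(rk$tf[rk$rank == 1], sim$truth$planted_tf)
  expect_lt(rk$rho[rk$rank == 1], 0)

  # ranks are a gapless permutation; top fraction is exact
  expect_setequal(rk$rank, seq_len(nrow(rk)))
  expect_equal(sum(rk$is_top_fraction),
               ceiling(cfg$mr_top_fraction * nrow(rk)))

  # constant signature is fatal
  expect_error(rank_tfs(ds, setNames(rep(0.5, length(ds$samples)), ds$samples),
                        sim$tf_annotation, cfg), "constant")
})

test_that("identical TF expression rows get adjacent ranks in id order", {
  sim <- small_sim(seed = 20)
  ds <- sim$dataset
  tfa <- sim$tf_annotation
  twins <- tfa$tf[tfa$tf != sim$truth$planted_tf][1:2]
  ds$expr[twins[2], ] <- ds$expr[twins[1], ]
  mm <- motif_mean_methylation(ds, sim$truth$planted_dmcs)
  rk <- rank_tfs(ds, mm, tfa, supervised_config(rng_seed = 20))
  r <- sort(rk$rank[rk$tf %in% twins])
  expect_equal(diff(r), 1)
  expect_equal(rk$tf[rk$rank == r[1]], sort(twins)[1])
})

test_that("family flags equal a brute-force annotation lookup", {
  tfa <- tibble::tibble(
    tf = paste0("T", 1:10),
    motifs = c("mA", "", "mB", "", "", "mA,mB", "", "", "mC", ""),
    family = rep(c("F1", "F2", "F3"), length.out = 10),
    subfamily = rep(c("F1.1", "F2.1", "F3.1"), length.out = 10)
  )
  ranking <- tibble::tibble(tf = tfa$tf, pvalue = seq(0.01, 0.1, length.out = 10),
                            rho = -seq(0.1, 1, length.out = 10),
                            rank = 1:10,
                            is_top_fraction = c(TRUE, rep(FALSE, 9)))
  got <- classify_mrs(ranking, tfa, "mA")
  anchor_fams <- unique(tfa$family[c(1, 6)])
  for (i in 1:10) {
    expect_equal(got$same_family[i], tfa$family[i] %in% anchor_fams)
  }
  # motif's own TF at rank 1: top and same-family
  expect_true(got$is_mr_candidate[got$tf == "T1"])
  expect_warning(out <- classify_mrs(ranking, tfa, "mZ"), "absent")
  expect_false(any(out$same_family))
})

test_that("Jaccard clustering recovers block structure and is a metric", {
  m <- rbind(
    a1 = c(1, 1, 1, 0, 0, 0), a2 = c(1, 1, 1, 0, 0, 0),
    a3 = c(1, 1, 0, 0, 0, 0), a4 = c(1, 0, 1, 0, 0, 0),
    b1 = c(0, 0, 0, 1, 1, 1), b2 = c(0, 0, 0, 1, 1, 1),
    b3 = c(0, 0, 0, 1, 1, 0), b4 = c(0, 0, 0, 0, 1, 1)
  )
  cl <- cross_analysis_cluster(m, n_clusters = 2)
  expect_length(unique(cl$cluster[1:4]), 1)
  expect_length(unique(cl$cluster[5:8]), 1)
  expect_false(cl$cluster[1] == cl$cluster[5])

  d <- attr(cl, "dissim")
  expect_equal(d["a1", "a2"], 0)  # identical rows
  expect_equal(d["a1", "b1"], 1)  # disjoint rows
  # brute-force set computation
  for (i in rownames(m)) {
    for (j in rownames(m)) {
      si <- which(m[i, ] == 1)
      sj <- which(m[j, ] == 1)
      expect_equal(d[i, j],
                   1 - length(intersect(si, sj)) / length(union(si, sj)))
    }
  }
  # metric properties on random binary rows
  set.seed(8)
  rm <- matrix(rbinom(60, 1, 0.5), 10)
  rm[rowSums(rm) == 0, 1] <- 1
  rownames(rm) <- paste0("t", 1:10)
  dd <- attr(cross_analysis_cluster(rm, 3), "dissim")
  expect_equal(dd, t(dd))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  }

  expect_error(cross_analysis_cluster(m, 9), "more clusters")
  m0 <- m
  m0[1, ] <- 0
  expect_error(cross_analysis_cluster(m0, 2), "nonzero")
})

test_that("the annotation converter joins models to classified TFs", {
  dir <- withr::local_tempdir()
  models <- tibble::tibble(
    model = c("TF1.M1", "TF1.M2", "TF2.M1", "TF3.M1"),
    tf = c("TF1", "TF1", "TF2", "TF3")
  )
  klass <- tibble::tibble(
    tf = c("TF1", "TF2", "TF3", "TF4"),
    family = c("bHLH", "bHLH", "Forkhead", "Forkhead"),
    subfamily = c("bHLH.1", "bHLH.2", "FOX.1", "FOX.1")
  )
  readr::write_tsv(models, file.path(dir, "models.tsv"))
  readr::write_tsv(klass, file.path(dir, "class.tsv"))
  out <- convert_tf_annotation(file.path(dir, "models.tsv"),
                               file.path(dir, "class.tsv"),
                               out_path = file.path(dir, "tf.tsv"))
  expect_equal(out$n_models, 4)
  expect_equal(out$n_tfs, 4)
  expect_equal(out$n_families, 2)
  expect_equal(out$n_subfamilies, 3)
  ann <- read_tf_annotation(file.path(dir, "tf.tsv"))
  expect_equal(ann$motifs[ann$tf == "TF1"], "TF1.M1,TF1.M2")
  expect_equal(ann$motifs[ann$tf == "TF4"], "")
})
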