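test_that("dataset write/load round-trips bit-identically", {
  sim <- small_sim(seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim$dataset, dir)
  ds2 <- suppressMessages(load_dataset(paths[["meth"]], paths[["expr"]],
                                       paths[["samples"]], paths[["probes"]],
                                       paths[["genes"]]))
  expect_identical(ds2$meth, sim$dataset$meth)
  expect_identical(ds2$expr, sim$dataset$expr)
  expect_identical(ds2$samples, sim$dataset$samples)
  expect_identical(ds2$groups, sim$dataset$groups)
})

test_that("loader intersects samples and validates inputs", {
  dir <- withr::local_tempdir()
  write_mat <- function(m, id, path) {
    df <- tibble::as_tibble(m)
    df <- dplyr::bind_cols(tibble::tibble(!!id := rownames(m)), df)
    readr::write_tsv(df, path)
  }
  meth <- matrix(runif(15), 5, 3, dimnames = list(paste0("p", 1:5), c("A", "B", "C")))
  expr <- matrix(rnorm(9, 6), 3, 3, dimnames = list(paste0("g", 1:3), c("B", "C", "D")))
  write_mat(meth, "probe", file.path(dir, "m.tsv"))
  write_mat(expr, "gene", file.path(dir, "e.tsv"))
  readr::write_tsv(tibble::tibble(sample = c("A", "B", "C", "D")),
                   file.path(dir, "s.tsv"))
  readr::write_tsv(tibble::tibble(probe = paste0("p", 1:5), chrom = "chr1",
                                  pos = 1:5 * 1000L),
                   file.path(dir, "pa.tsv"))
  readr::write_tsv(tibble::tibble(gene = paste0("g", 1:3), chrom = "chr1",
                                  tss = 1:3 * 10000L, strand = "+"),
                   file.path(dir, "ga.tsv"))
  expect_warning(
    ds <- load_dataset(file.path(dir, "m.tsv"), file.path(dir, "e.tsv"),
                       file.path(dir, "s.tsv"), file.path(dir, "pa.tsv"),
                       file.path(dir, "ga.tsv"), verbose = FALSE),
    "dropped"
  )
  expect_identical(ds$samples, c("B", "C"))

  # out-of-range beta is fatal and names the offending cell
  meth_bad <- meth
  meth_bad["p2", "B"] <- 1.3
  write_mat(meth_bad, "probe", file.path(dir, "mbad.tsv"))
  expect_error(
    suppressWarnings(load_dataset(file.path(dir, "mbad.tsv"), file.path(dir, "e.tsv"),
                                  file.path(dir, "s.tsv"), file.path(dir, "pa.tsv"),
                                  file.path(dir, "ga.tsv"), verbose = FALSE)),
    "p2.*B"
  )

  # fewer than 2 shared samples is fatal
  readr::write_tsv(tibble::tibble(sample = "B"), file.path(dir, "s1.tsv"))
  expect_error(
    suppressWarnings(load_dataset(file.path(dir, "m.tsv"), file.path(dir, "e.tsv"),
                                  file.path(dir, "s1.tsv"), file.path(dir, "pa.tsv"),
                                  file.path(dir, "ga.tsv"), verbose = FALSE)),
    "fewer than 2"
  )
})

test_that("duplicated ids are fatal", {
  m <- matrix(runif(4), 2, 2, dimnames = list(c("p1", "p1"), c("A", "B")))
  e <- matrix(rnorm(4), 2, 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  pa <- tibble::tibble(probe = "p1", chrom = "chr1", pos = 100L)
  ga <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                       tss = c(1L, 2L), strand = "+")
  expect_error(paired_omics(m, e, pa, ga), "duplicated probe")
})

test_that("distal probe selection equals the brute-force distance check", {
  set.seed(21)
  n_probes <- 10
  pos <- sort(sample(1:60000, n_probes))
  tss <- c(10500L, 30000L, 52000L)
  meth <- matrix(runif(n_probes * 10), n_probes,
                 dimnames = list(paste0("p", 1:n_probes), paste0("s", 1:10)))
  expr <- matrix(rnorm(30, 6), 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  ds <- paired_omics(
    meth, expr,
    tibble::tibble(probe = rownames(meth), chrom = "chr1", pos = as.integer(pos)),
    tibble::tibble(gene = rownames(expr), chrom = "chr1", tss = tss, strand = "+")
  )
  for (cut in c(500, 2000, 8000)) {
    got <- tryCatch(distal_probes(select_distal_probes(ds, cut)),
                    error = function(e) character(0))
    brute <- rownames(meth)[vapply(pos, function(p) {
      all(abs(p - tss) > cut)
    }, logical(1))]
    expect_setequal(got, brute)
  }
  # monotone: larger cutoff never adds probes
  d1 <- distal_probes(select_distal_probes(ds, 500))
  d2 <- distal_probes(select_distal_probes(ds, 2000))
  expect_true(all(d2 %in% d1))

  # boundary: distance exactly equal to the cutoff is not distal
  ds_edge <- paired_omics(
    meth[1, , drop = FALSE], expr[1, , drop = FALSE],
    tibble::tibble(probe = "p1", chrom = "chr1", pos = 10000L),
    tibble::tibble(gene = "g1", chrom = "chr1", tss = 10500L, strand = "+")
  )
  expect_error(select_distal_probes(ds_edge, 500), "no distal probe")
})

test_that("nearest gene lookup matches a brute-force sort by distance", {
  ds <- toy_dataset(n_probes = 1, n_genes = 20)
  ds$probe_annot$pos <- 105000L # between gene 10 (100 kb) and 11 (110 kb)
  nn <- nearest_genes("p1", ds, k = 20)
  expect_equal(nrow(nn), 20)
  expect_equal(sum(nn$side == "upstream"), 10)
  expect_equal(sum(nn$side == "downstream"), 10)

  # probe before every TSS: only downstream genes
  ds$probe_annot$pos <- 100L
  nn <- nearest_genes("p1", ds, k = 20)
  expect_equal(unique(nn$side), "downstream")
  expect_equal(nn$gene, paste0("g", 1:10))

  # random annotation vs brute force
  set.seed(31)
  n <- 50
  meth <- matrix(runif(5), 1, 5, dimnames = list("p1", paste0("s", 1:5)))
  expr <- matrix(rnorm(n * 5, 6), n,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:5)))
  tss <- sample(1:1000000, n)
  ds2 <- paired_omics(
    meth, expr,
    tibble::tibble(probe = "p1", chrom = "chr1", pos = 431287L),
    tibble::tibble(gene = paste0("g", 1:n), chrom = "chr1",
                   tss = as.integer(tss), strand = "+")
  )
  nn <- nearest_genes("p1", ds2, k = 20)
  pos <- 431287
  brute_up <- paste0("g", seq_len(n))[tss < pos]
  brute_up <- brute_up[order(pos - tss[tss < pos])][1:10]
  brute_dn <- paste0("g", seq_len(n))[tss >= pos]
  brute_dn <- brute_dn[order(tss[tss >= pos] - pos)][1:10]
  expect_equal(nn$gene[nn$side == "upstream"], brute_up)
  expect_equal(nn$gene[nn$side == "downstream"], brute_dn)

  # every omitted gene is farther than every included gene on its side
  omitted <- setdiff(paste0("g", 1:n), nn$gene)
  om_tss <- tss[match(omitted, paste0("g", 1:n))]
  om_up <- om_tss[om_tss < pos]
  om_dn <- om_tss[om_tss >= pos]
  expect_true(min(pos - om_up) >=
                max(nn$distance[nn$side == "upstream"]))
  expect_true(min(om_dn - pos) >=
                max(-nn$distance[nn$side == "downstream"]))

  # unknown chromosome: empty with a warning
  ds2$probe_annot$chrom <- "chrX"
  expect_warning(out <- nearest_genes("p1", ds2, k = 20), "no annotated gene")
  expect_equal(nrow(out), 0)
})

test_that("GFF3 gene records convert to the TSS table", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\tID=geneA",
    "chr1\tsrc\tgene\t9001\t12000\t.\t-\t.\tID=geneB",
    "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tID=exon1"
  ), gff)
  ann <- gff_to_gene_annotation(gff)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$tss[ann$gene == "geneA"], 1000L)  # 0-based start
  expect_equal(ann$tss[ann$gene == "geneB"], 11999L) # 0-based end - 1
  expect_equal(ann$strand, c("+", "-"))
})
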