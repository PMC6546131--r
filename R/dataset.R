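#' Paired methylation/expression dataset
#'
#' Container for matched DNA methylation (beta values in \[0, 1\], probes x
#' samples) and gene expression (log2 scale, genes x samples) matrices,
#' together with sample group labels and probe/gene annotations. Both
#' matrices must carry the identical ordered sample set.
#'
#' @param meth Numeric matrix of beta values, probe rownames, sample
#'   colnames.
#' @param expr Numeric matrix of log2 expression, gene rownames, same sample
#'   colnames in the same order.
#' @param probe_annot Tibble with columns `probe`, `chrom`, `pos` (0-based
#'   CpG coordinate); an `is_distal` column is added by
#'   [select_distal_probes()].
#' @param gene_annot Tibble with columns `gene`, `chrom`, `tss` (0-based),
#'   `strand` (`"+"` or `"-"`).
#' @param groups Optional named character vector mapping sample id to group
#'   label; when present every sample must be labeled and exactly two labels
#'   must occur.
#' @return An object of class `paired_omics`.
#' @export
paired_omics <- function(meth, expr, probe_annot, gene_annot, groups = NULL) {
  stopifnot(is.matrix(meth), is.matrix(expr))
  samples <- colnames(meth)
  if (is.null(samples) || is.null(rownames(meth)) || is.null(rownames(expr))) {
    abort("matrices need probe/gene rownames and sample colnames")
  }
  if (!identical(samples, colnames(expr))) {
    abort("methylation and expression matrices must share the identical ordered sample set")
  }
  if (anyDuplicated(rownames(meth))) abort("duplicated probe ids")
  if (anyDuplicated(rownames(expr))) abort("duplicated gene ids")
  bad <- which(!is.na(meth) & (meth < 0 | meth > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("beta value %.4g outside [0, 1] at probe '%s', sample '%s'",
                  meth[bad[1, 1], bad[1, 2]],
                  rownames(meth)[bad[1, 1]], samples[bad[1, 2]]))
  }
  probe_annot <- as_tibble(probe_annot)
  gene_annot <- as_tibble(gene_annot)
  stopifnot(all(c("probe", "chrom", "pos") %in% names(probe_annot)),
            all(c("gene", "chrom", "tss", "strand") %in% names(gene_annot)))
  if (!all(rownames(meth) %in% probe_annot$probe)) {
    abort("every probe row needs an annotation entry")
  }
  if (!all(rownames(expr) %in% gene_annot$gene)) {
    abort("every gene row needs an annotation entry")
  }
  probe_annot <- probe_annot[match(rownames(meth), probe_annot$probe), ]
  gene_annot <- gene_annot[match(rownames(expr), gene_annot$gene), ]
  if (!"is_distal" %in% names(probe_annot)) probe_annot$is_distal <- NA
  if (!is.null(groups)) {
    groups <- groups[samples]
    if (any(is.na(groups))) abort("every sample must carry a group label")
    if (length(unique(groups)) != 2) {
      abort("exactly two distinct group labels are required")
    }
    names(groups) <- samples
  }
  structure(
    list(meth = meth, expr = expr, samples = samples, groups = groups,
         probe_annot = probe_annot, gene_annot = gene_annot),
    class = "paired_omics"
  )
}

#' @export
print.paired_omics <- function(x, ...) {
  cat("<paired_omics>\n")
  cat(sprintf("  %d probes x %d samples (methylation), %d genes (expression)\n",
              nrow(x$meth), length(x$samples), nrow(x$expr)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  }
  nd <- sum(x$probe_annot$is_distal %in% TRUE)
  if (nd > 0) cat(sprintf("  distal probes: %d\n", nd))
  invisible(x)
}

read_matrix_tsv <- function(path) {
  # base parser: correctly rounded doubles, so written matrices reload
  # bit-identically
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated row ids in %s (e.g. '%s')",
                  path, ids[duplicated(ids)][1]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read probe annotation (TSV or BED)
#'
#' Accepts either a headered TSV with columns `probe`, `chrom`, `pos`
#' (0-based CpG coordinate) or a headerless BED file (chrom, start, end,
#' name) where the CpG position is the interval start.
#'
#' @param path File path.
#' @return Tibble with `probe`, `chrom`, `pos`.
#' @export
read_probe_annotation <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^probe\t", first)) {
    ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    ann <- ann[, c("probe", "chrom", "pos")]
  } else {
    bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(bed) < 4) abort("probe BED needs at least 4 columns (chrom, start, end, name)")
    ann <- tibble(probe = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
                  pos = as.integer(bed[[2]]))
  }
  ann$pos <- as.integer(ann$pos)
  as_tibble(ann)
}

#' Read gene annotation TSV
#'
#' Headered TSV with columns `gene`, `chrom`, `tss` (0-based), `strand`.
#' @param path File path.
#' @return Tibble.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(ann)))
  ann$tss <- as.integer(ann$tss)
  as_tibble(ann[, c("gene", "chrom", "tss", "strand")])
}

#' Convert GFF3 gene records to the gene annotation table
#'
#' Extracts `gene`-type records from a GFF3 file and derives the 0-based
#' transcription start site from the strand (interval start for `+`,
#' interval end minus one for `-`).
#'
#' @param gff_path Path to a GFF3 file.
#' @param id_attribute Attribute holding the gene identifier (default
#'   `"ID"`).
#' @return Tibble with `gene`, `chrom`, `tss`, `strand`.
#' @export
gff_to_gene_annotation <- function(gff_path, id_attribute = "ID") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("the GFF converter needs the 'rtracklayer' package")
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- as.character(S4Vectors::mcols(gr)[[id_attribute]])
  strand <- as.character(GenomicRanges::strand(gr))
  start1 <- GenomicRanges::start(gr) # 1-based inclusive
  end1 <- GenomicRanges::end(gr)
  tss0 <- ifelse(strand == "-", end1 - 1L, start1 - 1L)
  tibble(gene = ids,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         tss = as.integer(tss0),
         strand = ifelse(strand == "-", "-", "+"))
}

#' Load a paired dataset from TSV files
#'
#' Reads the methylation and expression matrices, the sample sheet and both
#' annotations, restricts everything to the samples present in all three,
#' and drops unannotated probes/genes with a logged count. Sample order
#' follows the methylation matrix.
#'
#' @param meth_path,expr_path Matrix TSVs: first column probe/gene id,
#'   remaining columns one per sample with sample ids in the header.
#' @param sample_sheet_path TSV with column `sample` and optional `group`.
#' @param probe_annot_path See [read_probe_annotation()].
#' @param gene_annot_path See [read_gene_annotation()].
#' @param verbose Emit progress messages.
#' @return A [paired_omics] object.
#' @export
load_dataset <- function(meth_path, expr_path, sample_sheet_path,
                         probe_annot_path, gene_annot_path, verbose = TRUE) {
  meth <- read_matrix_tsv(meth_path)
  expr <- read_matrix_tsv(expr_path)
  sheet <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE,
                           progress = FALSE)
  stopifnot("sample" %in% names(sheet))
  shared <- colnames(meth)[colnames(meth) %in% colnames(expr) &
                             colnames(meth) %in% as.character(sheet$sample)]
  dropped <- setdiff(unique(c(colnames(meth), colnames(expr))), shared)
  if (length(dropped) > 0) {
    warn(sprintf("%d sample(s) absent from some input were dropped: %s",
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  if (length(shared) < 2) abort("fewer than 2 samples shared across inputs")
  meth <- meth[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]

  probe_annot <- read_probe_annotation(probe_annot_path)
  gene_annot <- read_gene_annotation(gene_annot_path)
  keep_p <- rownames(meth) %in% probe_annot$probe
  keep_g <- rownames(expr) %in% gene_annot$gene
  if (any(!keep_p)) {
    ml_log("dropping %d probe(s) lacking annotation", sum(!keep_p),
           verbose = verbose)
  }
  if (any(!keep_g)) {
    ml_log("dropping %d gene(s) lacking annotation", sum(!keep_g),
           verbose = verbose)
  }
  meth <- meth[keep_p, , drop = FALSE]
  expr <- expr[keep_g, , drop = FALSE]

  groups <- NULL
  if ("group" %in% names(sheet) && !all(is.na(sheet$group))) {
    groups <- setNames(as.character(sheet$group), as.character(sheet$sample))
    groups <- groups[shared]
  }
  paired_omics(meth, expr, probe_annot, gene_annot, groups = groups)
}

#' Write a paired dataset to TSV files
#'
#' Emits the same file layout [load_dataset()] consumes. Reloading
#' reproduces the matrices bit-identically (values are written with
#' shortest-round-trip formatting).
#'
#' @param dataset A [paired_omics] object.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(meth = file.path(out_dir, "meth.tsv"),
             expr = file.path(out_dir, "expr.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             probes = file.path(out_dir, "probe_annot.tsv"),
             genes = file.path(out_dir, "gene_annot.tsv"))
  write_matrix_tsv(dataset$meth, "probe", paths[["meth"]])
  write_matrix_tsv(dataset$expr, "gene", paths[["expr"]])
  sheet <- tibble(sample = dataset$samples)
  if (!is.null(dataset$groups)) sheet$group <- unname(dataset$groups)
  readr::write_tsv(sheet, paths[["samples"]], progress = FALSE)
  readr::write_tsv(dataset$probe_annot[, c("probe", "chrom", "pos")],
                   paths[["probes"]], progress = FALSE)
  readr::write_tsv(dataset$gene_annot, paths[["genes"]], progress = FALSE)
  invisible(paths)
}

write_matrix_tsv <- function(m, id_name, path) {
  # 17 significant digits so doubles survive the text round trip bit-exactly
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m),
                dimnames = dimnames(m))
  df <- as_tibble(chr)
  df <- dplyr::bind_cols(tibble(!!id_name := rownames(m)), df)
  readr::write_tsv(df, path, progress = FALSE)
}

#' Flag distal probes
#'
#' A probe is distal when its CpG position lies strictly more than
#' `tss_distal_cut` bp from every annotated transcription start site
#' (absolute genomic distance, strand ignored). Probes on chromosomes with
#' no annotated gene are distal by definition.
#'
#' @param dataset A [paired_omics] object.
#' @param tss_distal_cut Distance cutoff in bp (default 2000).
#' @return The dataset with `probe_annot$is_distal` filled in.
#' @seealso [distal_probes()]
#' @export
select_distal_probes <- function(dataset, tss_distal_cut = 2000) {
  pa <- dataset$probe_annot
  ga <- dataset$gene_annot
  if (nrow(ga) == 0) abort("gene annotation is empty")
  dist <- rep(Inf, nrow(pa))
  for (chr in unique(pa$chrom)) {
    tss <- sort(ga$tss[ga$chrom == chr])
    if (length(tss) == 0) next
    idx <- which(pa$chrom == chr)
    pos <- pa$pos[idx]
    right <- findInterval(pos, tss)
    d_left <- ifelse(right >= 1, pos - tss[pmax(right, 1)], Inf)
    d_right <- ifelse(right < length(tss), tss[pmin(right + 1, length(tss))] - pos, Inf)
    dist[idx] <- pmin(d_left, d_right)
  }
  pa$is_distal <- dist > tss_distal_cut
  if (!any(pa$is_distal)) {
    abort(paste("no distal probe found; check that probe/gene annotations share",
                "chromosome names and that `tss_distal_cut` is not too large"))
  }
  dataset$probe_annot <- pa
  dataset
}

#' Distal probe ids of a dataset
#' @param dataset A [paired_omics] object after [select_distal_probes()].
#' @return Character vector of probe ids.
#' @export
distal_probes <- function(dataset) {
  if (all(is.na(dataset$probe_annot$is_distal))) {
    abort("run select_distal_probes() first")
  }
  dataset$probe_annot$probe[dataset$probe_annot$is_distal %in% TRUE]
}

#' Nearest candidate genes of a probe
#'
#' Returns up to `k/2` genes whose TSS lies before the probe position and
#' `k/2` at or after it, nearest first within each side, restricted to the
#' probe's chromosome. Near a chromosome end fewer genes are returned.
#'
#' @param probe_id Probe identifier.
#' @param dataset A [paired_omics] object.
#' @param k Total candidate count (default 20, i.e. 10 per side).
#' @return Tibble with `gene`, `side` (`"upstream"`/`"downstream"` by TSS
#'   relative to the probe), `rank` (1 = nearest within side), and signed
#'   `distance` (probe position minus TSS).
#' @export
nearest_genes <- function(probe_id, dataset, k = 20) {
  pa <- dataset$probe_annot
  i <- match(probe_id, pa$probe)
  if (is.na(i)) abort(sprintf("unknown probe '%s'", probe_id))
  ga <- dataset$gene_annot[dataset$gene_annot$chrom == pa$chrom[i], ]
  if (nrow(ga) == 0) {
    warn(sprintf("probe '%s': chromosome '%s' has no annotated gene",
                 probe_id, pa$chrom[i]))
    return(tibble(gene = character(), side = character(),
                  rank = integer(), distance = integer()))
  }
  pos <- pa$pos[i]
  per_side <- k %/% 2
  up <- ga[ga$tss < pos, ]
  dn <- ga[ga$tss >= pos, ]
  up <- up[order(pos - up$tss, up$gene), ][seq_len(min(per_side, nrow(up))), ]
  dn <- dn[order(dn$tss - pos, dn$gene), ][seq_len(min(k - per_side, nrow(dn))), ]
  bind_rows(
    tibble(gene = up$gene, side = "upstream",
           rank = seq_len(nrow(up)), distance = pos - up$tss),
    tibble(gene = dn$gene, side = "downstream",
           rank = seq_len(nrow(dn)), distance = pos - dn$tss)
  )
}
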