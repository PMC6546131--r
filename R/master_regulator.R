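#' Mean methylation signature of a probe set
#'
#' Per-sample mean beta value over the probes carrying an enriched motif,
#' ignoring missing values (samples with all values missing get `NA`).
#'
#' @param dataset A [paired_omics] object.
#' @param probe_set Non-empty character vector of probe ids.
#' @return Named numeric vector, one value per sample.
#' @export
motif_mean_methylation <- function(dataset, probe_set) {
  if (length(probe_set) == 0) abort("empty probe set")
  missing_p <- setdiff(probe_set, rownames(dataset$meth))
  if (length(missing_p) > 0) {
    abort(sprintf("unknown probe(s): %s", paste(head(missing_p, 3), collapse = ", ")))
  }
  m <- dataset$meth[probe_set, , drop = FALSE]
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Read a TF annotation table
#'
#' Headered TSV with columns `tf`, `motifs` (comma-joined motif ids),
#' `family`, `subfamily`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_tf_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("tf", "motifs", "family") %in% names(ann)))
  if (!"subfamily" %in% names(ann)) ann$subfamily <- NA_character_
  ann$motifs <- ann$motifs %|na|% "" # motif-less TFs
  as_tibble(ann[, c("tf", "motifs", "family", "subfamily")])
}

# TFs annotated to a motif
motif_tfs <- function(tf_annotation, motif) {
  hit <- vapply(strsplit(tf_annotation$motifs %|na|% "", ","),
                function(m) motif %in% trimws(m), logical(1))
  tf_annotation$tf[hit]
}

#' Rank transcription factors against a methylation signature
#'
#' Splits the samples into methylated/unmethylated groups on the signature
#' (extreme `ceiling(n * N)` samples in unsupervised mode; the predefined
#' groups, oriented by mean signature, in supervised mode), then tests each
#' annotated TF's expression with a one-sided Mann-Whitney test
#' (alternative "U expresses more" for `"hypo"` runs). Spearman's rho of TF
#' expression versus the signature is recorded for plotting. TFs are ranked
#' by ascending p-value, ties broken by ascending rho (most anti-correlated
#' first), then by TF id.
#'
#' @param dataset A [paired_omics] object.
#' @param mean_meth Signature from [motif_mean_methylation()].
#' @param tf_annotation Tibble from [read_tf_annotation()].
#' @param config An [analysis_config()].
#' @return Tibble of class `ml_tf_ranking` with columns `tf`, `pvalue`,
#'   `rho`, `rank`, `is_top_fraction`. TFs missing from the expression
#'   matrix are skipped.
#' @export
rank_tfs <- function(dataset, mean_meth, tf_annotation, config) {
  usable <- !is.na(mean_meth)
  if (sum(usable) < 10) abort("fewer than 10 samples with signature values")
  if (length(unique(mean_meth[usable])) == 1L) {
    abort("constant methylation signature: cannot rank TFs")
  }
  ids <- dataset$samples[usable]
  sig <- mean_meth[ids]
  if (config$mode == "supervised") {
    gs <- group_sample_ids(dataset, config)
    a <- intersect(gs$g1, ids)
    b <- intersect(gs$g2, ids)
    if (mean(sig[a]) >= mean(sig[b])) { M <- a; U <- b } else { M <- b; U <- a }
  } else {
    m <- extreme_count(length(ids), config$extreme_fraction)
    M <- ids[order(-sig, ids)][seq_len(m)]
    U <- ids[order(sig, ids)][seq_len(m)]
  }
  alt <- if (config$direction == "hypo") "greater" else "less"
  tfs <- unique(tf_annotation$tf)
  present <- tfs %in% rownames(dataset$expr)
  if (any(!present)) {
    warn(sprintf("%d TF(s) missing from the expression matrix were skipped",
                 sum(!present)))
  }
  tfs <- tfs[present]
  if (length(tfs) == 0) abort("no annotated TF present in the expression matrix")
  res <- purrr::map(tfs, function(tf) {
    x <- dataset$expr[tf, ]
    tibble(tf = tf,
           pvalue = mann_whitney_one_sided(x[U], x[M], alt)$pvalue,
           rho = suppressWarnings(
             cor(x[ids], sig, method = "spearman", use = "pairwise")))
  })
  out <- bind_rows(res)
  out <- out[order(out$pvalue, out$rho, out$tf), ]
  out$rank <- seq_len(nrow(out))
  out$is_top_fraction <- out$rank <= ceiling(config$mr_top_fraction * nrow(out))
  class(out) <- c("ml_tf_ranking", class(out))
  out
}

#' Annotate a TF ranking with family concordance and MR flags
#'
#' Marks each ranked TF as belonging to the same binding-domain family or
#' sub-family as the TF(s) the motif is annotated to. This is what resolves
#' which family member likely drives a shared motif: family members of the
#' motif's nominal TF that rank near the top are the prime master-regulator
#' candidates.
#'
#' @param rank_records An `ml_tf_ranking` from [rank_tfs()].
#' @param tf_annotation Tibble from [read_tf_annotation()].
#' @param motif Motif identifier.
#' @return The ranking with added columns `motif`, `same_family`,
#'   `same_subfamily`, and `is_mr_candidate`
#'   (`is_top_fraction & same_family`).
#' @export
classify_mrs <- function(rank_records, tf_annotation, motif) {
  anchors <- motif_tfs(tf_annotation, motif)
  if (length(anchors) == 0) {
    warn(sprintf("motif '%s' absent from the TF annotation; family flags all FALSE",
                 motif))
    fams <- character(0)
    subs <- character(0)
  } else {
    idx <- tf_annotation$tf %in% anchors
    fams <- unique(tf_annotation$family[idx])
    subs <- unique(tf_annotation$subfamily[idx])
    subs <- subs[!is.na(subs)]
  }
  ann <- tf_annotation[match(rank_records$tf, tf_annotation$tf), ]
  out <- rank_records
  out$motif <- motif
  out$same_family <- ann$family %in% fams
  out$same_subfamily <- ann$subfamily %in% subs
  out$is_mr_candidate <- out$is_top_fraction & out$same_family
  out
}

#' Cluster master regulators across analyses
#'
#' Given a binary TF-by-analysis membership matrix (1 when the TF was called
#' a master regulator in that analysis), computes pairwise Jaccard
#' dissimilarity `1 - |A and B| / |A or B|` on the row support sets and cuts
#' an average-linkage hierarchical clustering into `n_clusters` groups.
#'
#' @param mr_matrix Binary matrix with TF rownames, or a data frame whose
#'   first column `tf` holds the TF ids and remaining columns the analyses.
#' @param n_clusters Number of clusters to cut.
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Tibble with `tf` and `cluster`; the `hclust` tree and the
#'   dissimilarity matrix are attached as attributes `tree` and `dissim`.
#' @export
cross_analysis_cluster <- function(mr_matrix, n_clusters, linkage = "average") {
  if (is.data.frame(mr_matrix)) {
    tf <- as.character(mr_matrix[[1]])
    mr_matrix <- as.matrix(mr_matrix[, -1, drop = FALSE])
    rownames(mr_matrix) <- tf
  }
  m <- (mr_matrix != 0) * 1
  if (nrow(m) == 0) abort("empty master-regulator matrix")
  if (any(rowSums(m) == 0)) abort("every TF row needs at least one nonzero entry")
  if (n_clusters > nrow(m)) abort("more clusters requested than TFs")
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  tree <- hclust(as.dist(d), method = linkage)
  assignment <- cutree(tree, k = n_clusters)
  out <- tibble(tf = rownames(m), cluster = unname(assignment))
  attr(out, "tree") <- tree
  attr(out, "dissim") <- d
  class(out) <- c("ml_mr_clusters", class(out))
  out
}

#' Build a TF annotation table from motif-model and TF-class tables
#'
#' One-time converter joining (i) a motif-model annotation table mapping
#' each binding model to its transcription factor (columns `model`, `tf`)
#' with (ii) a TF classification table assigning each TF a binding-domain
#' family and sub-family (columns `tf`, `family`, optional `subfamily`).
#' Emits the comma-joined per-TF motif table that [read_tf_annotation()]
#' consumes and reports the table's summary counts.
#'
#' @param model_annotation_path TSV with columns `model`, `tf`.
#' @param tf_class_path TSV with columns `tf`, `family`, optional
#'   `subfamily`.
#' @param out_path Optional path for the emitted TF annotation TSV.
#' @return List with `tf_annotation` (tibble), `n_models`, `n_tfs`,
#'   `n_families`, `n_subfamilies`.
#' @export
convert_tf_annotation <- function(model_annotation_path, tf_class_path,
                                  out_path = NULL) {
  models <- readr::read_tsv(model_annotation_path, show_col_types = FALSE,
                            progress = FALSE)
  stopifnot(all(c("model", "tf") %in% names(models)))
  klass <- readr::read_tsv(tf_class_path, show_col_types = FALSE,
                           progress = FALSE)
  stopifnot(all(c("tf", "family") %in% names(klass)))
  if (!"subfamily" %in% names(klass)) klass$subfamily <- NA_character_
  per_tf <- models |>
    group_by(.data$tf) |>
    summarise(motifs = paste(sort(unique(.data$model)), collapse = ","),
              .groups = "drop")
  ann <- left_join(klass[, c("tf", "family", "subfamily")], per_tf, by = "tf")
  ann$motifs <- ann$motifs %|na|% ""
  ann <- ann[, c("tf", "motifs", "family", "subfamily")]
  if (!is.null(out_path)) readr::write_tsv(ann, out_path, progress = FALSE)
  list(tf_annotation = as_tibble(ann),
       n_models = length(unique(models$model)),
       n_tfs = length(unique(klass$tf)),
       n_families = length(unique(klass$family)),
       n_subfamilies = length(unique(klass$subfamily[!is.na(klass$subfamily)])))
}
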