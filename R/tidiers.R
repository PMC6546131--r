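#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.ml_dmc <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.ml_dmc <- function(x, ...) {
  tibble(n_tested = nrow(x), n_significant = sum(x$significant),
         n_skipped = nrow(attr(x, "skipped") %||% tibble()),
         mode = attr(x, "mode") %||% NA_character_,
         direction = x$direction[1] %||% NA_character_)
}

#' @export
tidy.ml_pairs <- function(x, ...) as_tibble(unclass_result(x))

#' @export
glance.ml_pairs <- function(x, ...) {
  tibble(n_tested = nrow(x), n_significant = sum(x$significant),
         n_probes = length(unique(x$probe)),
         n_genes = length(unique(x$gene)))
}

#' @export
tidy.ml_motif_enrichment <- function(x, ...) as_tibble(unclass_result(x))

#' @export
glance.ml_motif_enrichment <- function(x, ...) {
  tibble(n_motifs = nrow(x), n_enriched = sum(x$enriched),
         top_motif = if (nrow(x) > 0) x$motif[1] else NA_character_)
}

#' @export
tidy.ml_tf_ranking <- function(x, ...) as_tibble(unclass_result(x))

#' @export
glance.ml_tf_ranking <- function(x, ...) {
  tibble(n_tfs = nrow(x), n_top = sum(x$is_top_fraction),
         top_tf = x$tf[x$rank == 1][1])
}

#' @export
tidy.paired_omics <- function(x, ...) {
  meth <- as_tibble(x$meth, rownames = "probe") |>
    tidyr::pivot_longer(-"probe", names_to = "sample", values_to = "beta")
  if (!is.null(x$groups)) meth$group <- unname(x$groups[meth$sample])
  meth
}

#' @export
glance.paired_omics <- function(x, ...) {
  tibble(n_probes = nrow(x$meth), n_genes = nrow(x$expr),
         n_samples = length(x$samples),
         n_groups = if (is.null(x$groups)) 0L else length(unique(x$groups)),
         n_distal = sum(x$probe_annot$is_distal %in% TRUE))
}

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[cls %in% c("tbl_df", "tbl", "data.frame")]
  for (a in c("skipped", "mode", "tree", "dissim", "cell_type",
              "n_dmcs_paired")) {
    attr(x, a) <- NULL
  }
  x
}
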