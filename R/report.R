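html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 25) {
  if (is.null(df) || nrow(df) == 0) return("<p><em>no rows</em></p>")
  shown <- head(df, max_rows)
  fmt <- function(v) {
    if (is.numeric(v)) signif(v, 4) else v
  }
  shown <- as.data.frame(lapply(shown, fmt))
  header <- paste0("<tr>", paste0("<th>", html_escape(names(shown)), "</th>",
                                  collapse = ""), "</tr>")
  body <- apply(shown, 1, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  note <- if (nrow(df) > max_rows) {
    sprintf("<p>showing %d of %d rows</p>", max_rows, nrow(df))
  } else ""
  paste0("<table border='1' cellpadding='3' cellspacing='0'>", header,
         paste(body, collapse = "\n"), "</table>", note)
}

section <- function(title, content) {
  paste0("<h2>", html_escape(title), "</h2>\n",
         content %||% "<p><em>not run</em></p>")
}

# per-sample scatter data (methylation vs expression) for one pair
pair_scatter_data <- function(dataset, probe_id, gene_id) {
  tibble(sample = dataset$samples,
         group = if (is.null(dataset$groups)) NA_character_
                 else unname(dataset$groups),
         meth = dataset$meth[probe_id, ],
         expr = dataset$expr[gene_id, ])
}

#' Write a static HTML summary report
#'
#' Renders the run manifest and the DMC, pair, motif-enrichment,
#' master-regulator and chromatin-state tables into one self-contained HTML
#' file. Sections for stages that did not run are marked "not run". The top
#' significant pair's per-sample methylation/expression values and the top
#' ranked TF's expression-versus-signature values are embedded as scatter
#' data tables. Regeneration from the same inputs is byte-identical.
#'
#' @param run An `ml_run` list from [run_pipeline()].
#' @param out_path Output HTML path.
#' @return `out_path`, invisibly.
#' @export
write_report <- function(run, out_path) {
  cfg <- run$config
  manifest <- tibble(parameter = names(unclass(cfg)),
                     value = vapply(unclass(cfg), function(v) {
                       if (is.null(v)) "NULL" else paste(v, collapse = ",")
                     }, character(1)))
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>methlink report: %s</title></head><body>",
            html_escape(run$label)),
    sprintf("<h1>methlink report &mdash; %s</h1>", html_escape(run$label)),
    section("Parameters", html_table(manifest, max_rows = 50)),
    section("Differentially methylated CpGs",
            if (!is.null(run$dmcs)) paste0(
              sprintf("<p>%d significant of %d tested</p>",
                      sum(run$dmcs$significant), nrow(run$dmcs)),
              html_table(dplyr::arrange(as_tibble(run$dmcs), .data$padj)))),
    section("Probe-gene pairs",
            if (!is.null(run$pairs)) paste0(
              sprintf("<p>%d significant of %d tested</p>",
                      sum(run$pairs$significant), nrow(run$pairs)),
              html_table(dplyr::arrange(as_tibble(run$pairs), .data$pe)))),
    section("Motif enrichment",
            if (!is.null(run$motif_enrichment))
              html_table(as_tibble(run$motif_enrichment))),
    section("Master regulators",
            if (!is.null(run$mr_summary)) html_table(as_tibble(run$mr_summary))),
    section("Chromatin states",
            if (!is.null(run$state_enrichment)) paste(
              vapply(names(run$state_enrichment), function(ct) {
                paste0("<h3>", html_escape(ct), "</h3>",
                       html_table(as_tibble(run$state_enrichment[[ct]])))
              }, character(1)), collapse = "\n"))
  )
  if (!is.null(run$pairs) && any(run$pairs$significant) &&
      !is.null(run$dataset)) {
    top <- run$pairs[run$pairs$significant, ]
    top <- top[order(top$pe, top$raw_pvalue, top$probe, top$gene), ][1, ]
    parts <- c(parts, section(
      sprintf("Scatter data: %s vs %s", top$probe, top$gene),
      html_table(pair_scatter_data(run$dataset, top$probe, top$gene),
                 max_rows = 500)))
  }
  if (!is.null(run$tf_ranking) && !is.null(run$dataset)) {
    top_tf <- run$tf_ranking[run$tf_ranking$rank == 1, ][1, ]
    probes_m <- intersect(unique(run$pairs$probe[run$pairs$significant]),
                          run$motif_map$probe[run$motif_map$motif == top_tf$motif])
    if (length(probes_m) > 0) {
      mm <- motif_mean_methylation(run$dataset, probes_m)
      parts <- c(parts, section(
        sprintf("Scatter data: TF %s vs motif %s signature",
                top_tf$tf, top_tf$motif),
        html_table(tibble(sample = run$dataset$samples,
                          signature = mm,
                          tf_expr = run$dataset$expr[top_tf$tf, ]),
                   max_rows = 500)))
    }
  }
  parts <- c(parts, "</body></html>")
  writeLines(paste(parts, collapse = "\n"), out_path)
  invisible(out_path)
}
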