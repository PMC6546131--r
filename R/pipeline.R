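#' Run the full linking pipeline
#'
#' Executes, in order: distal-probe selection, differential methylation
#' (DMC calling), probe-gene pairing with permutation empirical p-values,
#' motif enrichment around the paired probes, master-regulator TF ranking
#' per enriched motif, and (optionally) chromatin-state enrichment per cell
#' type. Each stage's table is written as `<label>.<stage>.tsv` under
#' `out_dir`, together with a YAML run manifest (all parameters, seed and
#' input checksums), a plain-text log, and a static HTML report. A stage
#' failure halts the run with a stage-named error; outputs of completed
#' stages are retained.
#'
#' @param meth_path,expr_path,sample_sheet_path,probe_annot_path,gene_annot_path
#'   Input files, see [load_dataset()].
#' @param motif_bed_path Motif instances BED (needed for the `motifs` stage).
#' @param tf_annotation_path TF annotation TSV (needed for the `mr` stage).
#' @param state_manifest Optional tibble or TSV path with columns
#'   `cell_type`, `path` pointing at per-cell-type state BEDs.
#' @param out_dir Output directory.
#' @param label Filesystem-safe analysis label used as the file prefix.
#' @param config An [analysis_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("dmc", "pairs", "motifs", "mr", "states")`. Later stages require the
#'   earlier ones.
#' @param n_background Background size for the state enrichment (default 10x
#'   the selected set).
#' @param verbose Emit progress messages.
#' @return A list of class `ml_run` with the dataset, every stage result and
#'   the output paths, invisibly.
#' @export
run_pipeline <- function(meth_path, expr_path, sample_sheet_path,
                         probe_annot_path, gene_annot_path,
                         motif_bed_path = NULL, tf_annotation_path = NULL,
                         state_manifest = NULL, out_dir, label = "analysis",
                         config = analysis_config(),
                         stages = c("dmc", "pairs", "motifs", "mr", "states"),
                         n_background = NULL, verbose = TRUE) {
  if (!grepl("^[A-Za-z0-9._-]+$", label)) {
    abort("`label` must be filesystem-safe ([A-Za-z0-9._-])")
  }
  known <- c("dmc", "pairs", "motifs", "mr", "states")
  stages <- match.arg(stages, known, several.ok = TRUE)
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages) {
      abort(sprintf("stage '%s' requires stage '%s' to be enabled", stage, dep))
    }
  }
  need("pairs", "dmc"); need("motifs", "pairs"); need("mr", "motifs")
  if ("states" %in% stages) need("states", "pairs")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, paste0(label, ".log"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
    ml_log("%s", line, verbose = verbose)
  }
  stage_run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  inputs <- c(meth = meth_path, expr = expr_path,
              sample_sheet = sample_sheet_path,
              probe_annot = probe_annot_path, gene_annot = gene_annot_path,
              motif_bed = motif_bed_path %||% NA_character_,
              tf_annotation = tf_annotation_path %||% NA_character_)
  res <- list(label = label, out_dir = out_dir, config = config,
              paths = character(0))
  out_file <- function(stage) file.path(out_dir, sprintf("%s.%s.tsv", label, stage))

  dataset <- stage_run("load", {
    ds <- load_dataset(meth_path, expr_path, sample_sheet_path,
                       probe_annot_path, gene_annot_path, verbose = verbose)
    select_distal_probes(ds, config$tss_distal_cut)
  })
  res$dataset <- dataset
  say("loaded %d probes x %d samples, %d genes; %d distal probes",
      nrow(dataset$meth), length(dataset$samples), nrow(dataset$expr),
      length(distal_probes(dataset)))

  if ("dmc" %in% stages) {
    res$dmcs <- stage_run("dmc", call_dmcs(dataset, config))
    p <- out_file("dmc")
    readr::write_tsv(as_tibble(res$dmcs), p, progress = FALSE)
    res$paths["dmc"] <- p
    say("dmc: %d tested, %d significant", nrow(res$dmcs),
        sum(res$dmcs$significant))
  }
  if ("pairs" %in% stages) {
    res$pairs <- stage_run("pairs", find_pairs(dataset, res$dmcs, config))
    p <- out_file("pairs")
    readr::write_tsv(as_tibble(res$pairs), p, progress = FALSE)
    res$paths["pairs"] <- p
    sig <- res$pairs[res$pairs$significant, , drop = FALSE]
    if (nrow(sig) > 0) {
      bp <- file.path(out_dir, paste0(label, ".links.bedpe"))
      write_pairs_bedpe(sig, dataset, bp)
      res$paths["links"] <- bp
    }
    say("pairs: %d tested, %d significant", nrow(res$pairs), nrow(sig))
  }
  fg <- if (!is.null(res$pairs)) unique(res$pairs$probe[res$pairs$significant])
        else character(0)
  if ("motifs" %in% stages) {
    if (is.null(motif_bed_path)) abort("stage 'motifs' needs `motif_bed_path`")
    res$motif_map <- stage_run("motifs", build_motif_probe_map(
      read_motif_bed(motif_bed_path), dataset$probe_annot, config$motif_window))
    if (length(fg) == 0) {
      say("motifs: no significant pairs, enrichment skipped")
    } else {
      res$motif_enrichment <- stage_run("motifs", enrich_motifs(
        fg, distal_probes(dataset), res$motif_map, config))
      p <- out_file("motif_enrichment")
      readr::write_tsv(as_tibble(res$motif_enrichment), p, progress = FALSE)
      res$paths["motif_enrichment"] <- p
      say("motifs: %d tested, %d enriched", nrow(res$motif_enrichment),
          sum(res$motif_enrichment$enriched))
    }
  }
  if ("mr" %in% stages && !is.null(res$motif_enrichment)) {
    if (is.null(tf_annotation_path)) abort("stage 'mr' needs `tf_annotation_path`")
    tf_ann <- read_tf_annotation(tf_annotation_path)
    enriched <- res$motif_enrichment$motif[res$motif_enrichment$enriched]
    rankings <- list()
    for (m in enriched) {
      probes_m <- intersect(fg, res$motif_map$probe[res$motif_map$motif == m])
      if (length(probes_m) == 0) next
      mm <- motif_mean_methylation(dataset, probes_m)
      rk <- stage_run("mr", classify_mrs(
        rank_tfs(dataset, mm, tf_ann, config), tf_ann, m))
      rankings[[m]] <- rk
    }
    if (length(rankings) > 0) {
      res$tf_ranking <- bind_rows(rankings)
      p <- out_file("tf_ranking")
      readr::write_tsv(as_tibble(res$tf_ranking), p, progress = FALSE)
      res$paths["tf_ranking"] <- p
      res$mr_summary <- res$tf_ranking |>
        filter(.data$is_top_fraction) |>
        arrange(.data$motif, .data$rank)
      p <- out_file("mr_summary")
      readr::write_tsv(as_tibble(res$mr_summary), p, progress = FALSE)
      res$paths["mr_summary"] <- p
      say("mr: ranked TFs for %d enriched motif(s)", length(rankings))
    } else {
      say("mr: no enriched motif with paired probes, skipped")
    }
  }
  if ("states" %in% stages && !is.null(state_manifest)) {
    manifest <- if (is.character(state_manifest)) {
      readr::read_tsv(state_manifest, show_col_types = FALSE, progress = FALSE)
    } else state_manifest
    stopifnot(all(c("cell_type", "path") %in% names(manifest)))
    if (length(fg) == 0) {
      say("states: no significant pairs, enrichment skipped")
    } else {
      res$state_enrichment <- list()
      for (i in seq_len(nrow(manifest))) {
        ct <- manifest$cell_type[i]
        seg <- read_state_segments(manifest$path[i], cell_type = ct)
        se <- stage_run("states", enrich_states(
          fg, distal_probes(dataset), dataset$probe_annot, seg,
          n_background = n_background, seed = config$rng_seed))
        res$state_enrichment[[ct]] <- se
        p <- file.path(out_dir, sprintf("%s.states.%s.tsv", label, ct))
        readr::write_tsv(as_tibble(se), p, progress = FALSE)
        res$paths[paste0("states_", ct)] <- p
        say("states (%s): %d states tested", ct, nrow(se))
      }
    }
  }

  manifest_path <- file.path(out_dir, paste0(label, ".manifest.yaml"))
  checksums <- vapply(inputs, function(f) {
    if (is.na(f)) NA_character_ else unname(tools::md5sum(f))
  }, character(1))
  yaml::write_yaml(list(
    label = label,
    package_version = as.character(utils::packageVersion("methlink")),
    stages = stages,
    config = unclass(config),
    inputs = as.list(inputs),
    input_md5 = as.list(checksums)
  ), manifest_path)
  res$paths["manifest"] <- manifest_path
  res$paths["log"] <- log_path

  report_path <- file.path(out_dir, paste0(label, ".report.html"))
  write_report(res, report_path)
  res$paths["report"] <- report_path
  say("report written to %s", report_path)

  class(res) <- "ml_run"
  invisible(res)
}

#' @export
print.ml_run <- function(x, ...) {
  cat(sprintf("<methlink run '%s'>\n  outputs in %s\n", x$label, x$out_dir))
  if (!is.null(x$dmcs)) cat(sprintf("  DMCs: %d significant of %d tested\n",
                                    sum(x$dmcs$significant), nrow(x$dmcs)))
  if (!is.null(x$pairs)) cat(sprintf("  pairs: %d significant of %d tested\n",
                                     sum(x$pairs$significant), nrow(x$pairs)))
  if (!is.null(x$motif_enrichment)) {
    cat(sprintf("  motifs: %d enriched of %d tested\n",
                sum(x$motif_enrichment$enriched), nrow(x$motif_enrichment)))
  }
  invisible(x)
}

#' Write significant probe-gene links as BEDPE
#'
#' One record per significant pair: anchor 1 is the CpG position, anchor 2
#' the target gene's TSS (both one-bp half-open intervals).
#'
#' @param pairs An `ml_pairs` tibble (typically already filtered to
#'   significant rows).
#' @param dataset The [paired_omics] object.
#' @param path Output path.
#' @export
write_pairs_bedpe <- function(pairs, dataset, path) {
  pa <- dataset$probe_annot
  ga <- dataset$gene_annot
  pi <- match(pairs$probe, pa$probe)
  gi <- match(pairs$gene, ga$gene)
  df <- tibble(
    chrom1 = pa$chrom[pi], start1 = pa$pos[pi], end1 = pa$pos[pi] + 1L,
    chrom2 = ga$chrom[gi], start2 = ga$tss[gi], end2 = ga$tss[gi] + 1L,
    name = paste(pairs$probe, pairs$gene, sep = "|"),
    score = -log10(pairs$pe)
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain any argument of [run_pipeline()]; entries under
#' the `config:` key are passed to [analysis_config()].
#'
#' @param path YAML file path.
#' @return A named list of arguments for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$config)) y$config <- do.call(analysis_config, y$config)
  y
}
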