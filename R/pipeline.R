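#' End-to-end run configuration
#'
#' Collects every input path and parameter of the staged pipeline. All of
#' the analysis thresholds live here in one place: the QC gene/mito/platelet
#' rules, the clonotype key mode, the expansion fold and minimum-cell
#' thresholds, the module clustering K range, and the DE significance
#' conjunction.
#'
#' @param counts_dir Directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @param contigs_path Contig CSV (10x dialect) path.
#' @param meta_path Cell metadata CSV path.
#' @param panel_path Gene-panel file path.
#' @param outdir Output directory.
#' @param qc [qc_params()].
#' @param key_mode Clonotype key mode (see [call_clonotypes()]).
#' @param expansion [expansion_params()].
#' @param cd8_types Cell-type labels treated as CD8 T cells for repertoire
#'   and expansion analyses.
#' @param k_range Candidate K values for module clustering.
#' @param top_n Top-clonotype count for dominance summaries (default 10).
#' @param seed Seed propagated to every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts_dir, contigs_path, meta_path, panel_path,
                       outdir,
                       qc = qc_params(),
                       key_mode = "genes_plus_cdr3aa",
                       expansion = expansion_params(),
                       cd8_types = c("CD8 naive", "CD8 GZMK", "CD8 Tem", "CD8 cycling"),
                       k_range = 2:8, top_n = 10L, seed = 1L) {
  structure(list(counts_dir = counts_dir, contigs_path = contigs_path,
                 meta_path = meta_path, panel_path = panel_path,
                 outdir = outdir, qc = qc, key_mode = key_mode,
                 expansion = expansion, cd8_types = cd8_types,
                 k_range = k_range, top_n = as.integer(top_n),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `qc` and `expansion`
#' may be nested maps of their parameter names.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    counts_dir = y$counts_dir, contigs_path = y$contigs_path,
    meta_path = y$meta_path, panel_path = y$panel_path, outdir = y$outdir,
    qc = do.call(qc_params, y$qc %||% list()),
    key_mode = y$key_mode %||% "genes_plus_cdr3aa",
    expansion = do.call(expansion_params, y$expansion %||% list()),
    cd8_types = y$cd8_types %||% c("CD8 naive", "CD8 GZMK", "CD8 Tem", "CD8 cycling"),
    k_range = y$k_range %||% 2:8, top_n = y$top_n %||% 10L,
    seed = y$seed %||% 1L)
}

validate_run_config <- function(config) {
  need <- c(file.path(config$counts_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv")),
            config$contigs_path, config$meta_path, config$panel_path)
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort(paste0("missing input files: ", paste(missing, collapse = ", ")),
          class = "clonodyn_validation_error")
  }
  invisible(TRUE)
}

write_tsv_artifact <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE, na = "")
  path
}

#' Run the full staged pipeline
#'
#' Executes QC, clonotype calling, repertoire statistics, expansion
#' classification, module discovery/scoring and DE/composition statistics,
#' writing every intermediate artifact into `config$outdir` and a
#' reproducibility manifest (`manifest.json`) echoing all parameters, the
#' seed and per-stage record counts. A stage failure aborts with the stage
#' name; artifacts of the failed stage keep a `.partial` suffix.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "clonodyn",
    version = as.character(utils::packageVersion("clonodyn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    parameters = list(qc = unclass(config$qc),
                      key_mode = config$key_mode,
                      expansion = unclass(config$expansion),
                      cd8_types = config$cd8_types,
                      k_range = config$k_range, top_n = config$top_n),
    stages = list())

  run_stage <- function(name, artifacts, fun) {
    paths <- file.path(config$outdir, artifacts)
    partial <- paste0(paths, ".partial")
    res <- tryCatch(fun(partial),
                    error = function(e) {
                      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                            class = "clonodyn_stage_error")
                    })
    file.rename(partial[file.exists(partial)], paths[file.exists(partial)])
    manifest$stages[[name]] <<- res
    invisible(res)
  }

  # ---- load ----
  counts <- read_mtx_counts(file.path(config$counts_dir, "matrix.mtx"),
                            file.path(config$counts_dir, "genes.tsv"),
                            file.path(config$counts_dir, "barcodes.tsv"))
  meta <- read_cell_meta(config$meta_path)
  contigs <- read_contigs(config$contigs_path, dialect = "tenx_csv")
  panel <- read_gene_panel(config$panel_path)
  manifest$stages$load <- list(n_genes = nrow(counts), n_cells = ncol(counts),
                               n_contigs = nrow(contigs),
                               n_panel_genes = length(panel))

  # ---- qc ----
  qc_res <- NULL
  run_stage("qc", "qc_report.json", function(p) {
    qc_res <<- suppressWarnings(filter_cells(counts, config$qc))
    jsonlite::write_json(qc_res$report, p[1], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(n_in = qc_res$report$n_input, n_out = qc_res$report$n_retained)
  })
  counts <- qc_res$counts
  meta <- dplyr::filter(meta, .data$barcode %in% colnames(counts))

  # ---- clonotypes ----
  calls <- NULL
  run_stage("clonotypes", c("clonotype_calls.tsv", "clonotype_report.json"),
            function(p) {
    calls <<- call_clonotypes(contigs, mode = config$key_mode)
    # restrict to QC-passing cells
    calls$calls <<- dplyr::filter(calls$calls, .data$barcode %in% meta$barcode)
    write_tsv_artifact(calls$calls, p[1])
    jsonlite::write_json(calls$report, p[2], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(n_in = calls$report$n_barcodes_in, n_out = nrow(calls$calls))
  })

  # ---- repertoire ----
  cd8_meta <- dplyr::filter(meta, .data$cell_type %in% config$cd8_types)
  run_stage("repertoire", c("repertoire_metrics.tsv", "similarity_matrix.tsv"),
            function(p) {
    prof <- repertoire_from_calls(calls, cd8_meta, stratify_by = "sample_id")
    metrics <- repertoire_metrics(prof, top_n = config$top_n)
    write_tsv_artifact(metrics, p[1])
    n_prof <- length(unique(prof$sample_id))
    if (n_prof >= 2) {
      sim <- similarity_matrix(prof, stratify_by = "sample_id")
      write_tsv_artifact(tibble::as_tibble(sim, rownames = "sample_id"), p[2])
    }
    list(n_in = nrow(prof), n_out = nrow(metrics))
  })

  # ---- expansion ----
  expn <- NULL
  run_stage("expansion", c("expansion_calls.tsv", "fate_table.tsv"), function(p) {
    expn <<- classify_expansion_cohort(calls, meta, params = config$expansion,
                                       cell_types = config$cd8_types)
    write_tsv_artifact(expn, p[1])
    fate <- fate_table(calls, cd8_meta, expn)
    write_tsv_artifact(fate, p[2])
    list(n_in = nrow(expn), n_out = sum(expn$expanded))
  })

  # ---- ifn modules ----
  scores <- NULL
  run_stage("ifn_modules",
            c("fc_profile.tsv", "module_partition.tsv", "silhouette_by_k.tsv",
              "module_scores.tsv"), function(p) {
    profile <- log2fc_profile(counts, meta, panel)
    write_tsv_artifact(tibble::as_tibble(profile), p[1])
    part <- cluster_panel(profile, k_range = config$k_range, seed = config$seed)
    write_tsv_artifact(part$assignment, p[2])
    write_tsv_artifact(part$silhouette_by_k, p[3])
    sets <- split(part$assignment$gene, part$assignment$module)
    scores <<- module_scores(counts, sets, seed = config$seed)
    write_tsv_artifact(scores, p[4])
    list(n_in = length(panel), n_out = part$k)
  })

  # ---- de and composition ----
  run_stage("de_and_composition",
            c("de_results.tsv", "composition_fractions.tsv",
              "composition_tests.tsv"), function(p) {
    de <- de_test(counts, meta, group_field = "group")
    write_tsv_artifact(tibble::as_tibble(de), p[1])
    comp <- composition_compare(meta)
    write_tsv_artifact(comp$fractions, p[2])
    write_tsv_artifact(comp$tests, p[3])
    list(n_in = nrow(de), n_out = sum(de$significant))
  })

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
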