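#' Quality-control parameters
#'
#' Cell-level filters applied to the raw UMI matrix. Thresholds follow the
#' strict-inequality convention: a cell is kept when it expresses *more than*
#' `min_genes_per_cell` genes and its mitochondrial UMI fraction is *below*
#' `max_mito_fraction`. Platelets are flagged by any non-zero count of a
#' platelet marker gene.
#'
#' @param min_genes_per_cell Minimum detected genes, exclusive (default 500:
#'   a 500-gene cell is rejected, a 501-gene cell kept). A gene counts as
#'   detected when it has at least one UMI.
#' @param max_mito_fraction Maximum mitochondrial UMI fraction, exclusive
#'   (default 0.05).
#' @param platelet_markers Marker genes whose expression flags a platelet.
#' @param platelet_min_count Count above which a marker flags the cell
#'   (default 0, i.e. any expression).
#' @param mito_prefix Regex identifying mitochondrial genes by symbol
#'   (default `"^MT-"`, case-insensitive, GRCh38 convention).
#' @param blacklist_patterns Regexes for variable-feature exclusion, used by
#'   [blacklist_genes()]: TCR variable segments, immunoglobulin variable
#'   segments, ribosomal proteins, mitochondrial genes and a
#'   dissociation-stress set.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 500L,
                      max_mito_fraction = 0.05,
                      platelet_markers = c("PPBP", "PF4", "NRGN"),
                      platelet_min_count = 0L,
                      mito_prefix = "^MT-",
                      blacklist_patterns = default_blacklist_patterns()) {
  stopifnot(min_genes_per_cell >= 0,
            max_mito_fraction > 0, max_mito_fraction < 1)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_mito_fraction = max_mito_fraction,
                 platelet_markers = platelet_markers,
                 platelet_min_count = platelet_min_count,
                 mito_prefix = mito_prefix,
                 blacklist_patterns = blacklist_patterns),
            class = "qc_params")
}

#' Default variable-feature blacklist patterns
#'
#' Categories: alpha/beta TCR variable segments, immunoglobulin variable
#' segments, ribosomal proteins, mitochondrial genes, and a dissociation
#' stress signature. The stress set is a packaged stand-in core
#' (immediate-early and heat-shock genes); supply your own list to match a
#' specific published signature.
#'
#' @return Named character vector of regexes.
#' @export
default_blacklist_patterns <- function() {
  stress <- c("FOS", "FOSB", "JUN", "JUNB", "JUND", "EGR1", "IER2", "IER3",
              "HSPA1A", "HSPA1B", "HSPA8", "HSPB1", "HSP90AA1", "HSP90AB1",
              "DNAJA1", "DNAJB1", "ZFP36", "SOCS3", "ATF3", "DUSP1")
  c(tcr_variable = "^TR[AB][VDJ]",
    ig_variable = "^IG[HKL][VDJ]",
    ribosomal = "^RP[SL]",
    mitochondrial = "^MT-",
    dissociation_stress = paste0("^(", paste(stress, collapse = "|"), ")$"))
}

#' Filter cells on QC rules
#'
#' Applies the three cell filters (detected genes, mitochondrial fraction,
#' platelet markers) to the *original* matrix — rules are evaluated
#' independently, not sequentially — and returns the retained submatrix plus
#' a report. A cell failing several rules is attributed to the first failing
#' rule in the order genes, mito, platelet.
#'
#' @param counts Genes-by-cells sparse count matrix (rownames = symbols).
#' @param params A [qc_params()] object.
#' @return A list of class `qc_result`: `counts` (filtered matrix), `report`
#'   (list with per-rule rejection counts, retained/input totals, the
#'   detection rule used, and whether the mito rule was skipped), and
#'   `cell_flags` (tibble of per-cell rule outcomes).
#' @export
filter_cells <- function(counts, params = qc_params()) {
  stopifnot(is(counts, "Matrix") || is.matrix(counts))
  genes_detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)

  mito_genes <- grep(params$mito_prefix, rownames(counts), ignore.case = TRUE, value = TRUE)
  mito_skipped <- length(mito_genes) == 0L
  if (mito_skipped) {
    warn("no mitochondrial genes found; mitochondrial fraction rule skipped")
    mito_frac <- rep(0, ncol(counts))
  } else {
    mito_frac <- Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(total, 1)
  }

  plt <- intersect(params$platelet_markers, rownames(counts))
  plt_count <- if (length(plt)) Matrix::colSums(counts[plt, , drop = FALSE]) else rep(0, ncol(counts))

  fail_genes <- genes_detected <= params$min_genes_per_cell
  fail_mito <- if (mito_skipped) rep(FALSE, ncol(counts)) else mito_frac >= params$max_mito_fraction
  fail_platelet <- plt_count > params$platelet_min_count

  keep <- !(fail_genes | fail_mito | fail_platelet)
  # first-failing-rule attribution for the report
  attributed <- dplyr::case_when(fail_genes ~ "low_genes",
                                 fail_mito ~ "high_mito",
                                 fail_platelet ~ "platelet",
                                 .default = "retained")
  flags <- tibble::tibble(barcode = colnames(counts),
                          genes_detected = as.integer(genes_detected),
                          mito_fraction = as.numeric(mito_frac),
                          platelet_count = as.numeric(plt_count),
                          fail_genes = fail_genes, fail_mito = fail_mito,
                          fail_platelet = fail_platelet, retained = keep,
                          attributed_rule = attributed)
  report <- list(
    n_input = ncol(counts),
    n_retained = sum(keep),
    rejected_low_genes = sum(attributed == "low_genes"),
    rejected_high_mito = sum(attributed == "high_mito"),
    rejected_platelet = sum(attributed == "platelet"),
    detection_rule = "gene detected when UMI count >= 1",
    mito_rule_skipped = mito_skipped,
    params = params[c("min_genes_per_cell", "max_mito_fraction",
                      "platelet_markers", "platelet_min_count", "mito_prefix")]
  )
  structure(list(counts = counts[, keep, drop = FALSE],
                 report = report, cell_flags = flags),
            class = "qc_result")
}

#' Remove blacklisted genes from a gene list
#'
#' Returns the genes that match *none* of the blacklist patterns, in input
#' order. Used to exclude TCR/immunoglobulin variable segments, ribosomal,
#' mitochondrial and dissociation-stress genes from variable-feature
#' selection.
#'
#' @param gene_ids Character vector of gene symbols.
#' @param patterns Character vector of regexes
#'   (default [default_blacklist_patterns()]).
#' @return Character subset of `gene_ids`.
#' @export
blacklist_genes <- function(gene_ids, patterns = default_blacklist_patterns()) {
  stopifnot(length(patterns) > 0)
  if (!length(gene_ids)) return(character(0))
  bad <- Reduce(`|`, lapply(patterns, function(p) grepl(p, gene_ids)))
  gene_ids[!bad]
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("Cell QC:", r$n_retained, "of", r$n_input, "cells retained\n")
  cat("  rejected: low genes", r$rejected_low_genes,
      "| high mito", r$rejected_high_mito,
      "| platelet", r$rejected_platelet, "\n")
  if (r$mito_rule_skipped) cat("  (mitochondrial rule skipped: no MT genes)\n")
  invisible(x)
}
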