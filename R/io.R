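#' Read a 10x-style sparse UMI count matrix
#'
#' Reads a MatrixMarket coordinate file together with its `genes.tsv` and
#' `barcodes.tsv` sidecars into a genes-by-cells sparse integer matrix.
#' Entries are UMI counts, so the file must contain non-negative integers,
#' and the sidecar lengths must match the matrix dimensions.
#'
#' @param matrix_path Path to the `.mtx` coordinate file (1-based on disk).
#' @param genes_path Path to a one-gene-per-line TSV; the first column is the
#'   gene identifier used as a row name.
#' @param barcodes_path Path to a one-barcode-per-line file used as column
#'   names.
#'
#' @return A [Matrix::dgCMatrix-class] with `rownames` = gene ids and
#'   `colnames` = barcodes.
#' @export
read_mtx_counts <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p), class = "clonodyn_format_error")
  }
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    abort(paste0("invalid MatrixMarket file '", matrix_path, "': ", conditionMessage(e)),
          class = "clonodyn_format_error")
  })
  genes <- read_first_column(genes_path)
  barcodes <- read_first_column(barcodes_path)
  if (length(genes) != nrow(m)) {
    abort(paste0("gene sidecar '", genes_path, "' has ", length(genes),
                 " entries but matrix has ", nrow(m), " rows"),
          class = "clonodyn_format_error")
  }
  if (length(barcodes) != ncol(m)) {
    abort(paste0("barcode sidecar '", barcodes_path, "' has ", length(barcodes),
                 " entries but matrix has ", ncol(m), " columns"),
          class = "clonodyn_format_error")
  }
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  vals <- m@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    abort(paste0("matrix '", matrix_path, "' contains negative or non-integer values; ",
                 "UMI counts must be non-negative integers"),
          class = "clonodyn_format_error")
  }
  if (anyDuplicated(genes)) abort("duplicated gene ids in sidecar", class = "clonodyn_format_error")
  if (anyDuplicated(barcodes)) abort("duplicated barcodes in sidecar", class = "clonodyn_format_error")
  dimnames(m) <- list(genes, barcodes)
  m
}

read_first_column <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  stringr::str_trim(vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L))
}

#' Write a count matrix as MatrixMarket + sidecars
#'
#' Inverse of [read_mtx_counts()]; writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` into `dir`.
#'
#' @param counts Sparse genes-by-cells matrix with dimnames.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the three file paths.
#' @export
write_mtx_counts <- function(counts, dir) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                  paths[[1]])
  readr::write_lines(rownames(counts), paths[[2]])
  readr::write_lines(colnames(counts), paths[[3]])
  invisible(paths)
}

# column requirements per contig dialect
.tenx_cols <- c("barcode", "chain", "v_gene", "d_gene", "j_gene",
                "cdr3", "cdr3_nt", "umis", "high_confidence", "productive")
# AIRR rearrangement mapping: locus->chain, v_call/d_call/j_call->genes,
# junction_aa->cdr3_aa, junction->cdr3_nt, duplicate_count->umis; AIRR encodes
# logicals as "T"/"F"/"TRUE"/"FALSE"/empty (empty -> NA, treated as TRUE for
# productive per AIRR's "unset means unknown", FALSE for high_confidence guard
# is not applied because the column is optional in AIRR).
.airr_cols <- c("cell_id", "locus", "v_call", "j_call", "junction_aa",
                "junction", "duplicate_count", "productive")

#' Read TCR contig annotations
#'
#' Parses per-cell V(D)J contig tables in either the 10x
#' `filtered_contig_annotations.csv` dialect or the AIRR rearrangement TSV
#' dialect into one canonical tibble with one row per contig. Chains other
#' than TRA/TRB (e.g. IGH, TRG) are mapped to `"other"`.
#'
#' @param path Path to the contig table.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return A tibble with columns `barcode`, `chain` (`TRA`/`TRB`/`other`),
#'   `v_gene`, `d_gene`, `j_gene`, `cdr3_aa`, `cdr3_nt`, `umis`,
#'   `high_confidence`, `productive`.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "clonodyn_format_error")
  if (dialect == "tenx_csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    missing <- setdiff(.tenx_cols, names(df))
    if (length(missing)) {
      abort(paste0("contig file missing required columns: ", paste(missing, collapse = ", ")),
            class = "clonodyn_format_error")
    }
    out <- tibble::tibble(
      barcode = df$barcode,
      chain = normalize_chain(df$chain),
      v_gene = df$v_gene %||% "",
      d_gene = dplyr::coalesce(df$d_gene, ""),
      j_gene = df$j_gene,
      cdr3_aa = df$cdr3,
      cdr3_nt = df$cdr3_nt,
      umis = as.integer(df$umis),
      high_confidence = parse_tenx_bool(df$high_confidence),
      productive = parse_tenx_bool(df$productive)
    )
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    missing <- setdiff(setdiff(.airr_cols, "productive"), names(df))
    if (length(missing)) {
      abort(paste0("AIRR file missing required columns: ", paste(missing, collapse = ", ")),
            class = "clonodyn_format_error")
    }
    out <- tibble::tibble(
      barcode = df$cell_id,
      chain = normalize_chain(df$locus),
      v_gene = df$v_call,
      d_gene = dplyr::coalesce(df[["d_call"]] %||% rep(NA_character_, nrow(df)), ""),
      j_gene = df$j_call,
      cdr3_aa = df$junction_aa,
      cdr3_nt = df$junction,
      umis = as.integer(df$duplicate_count),
      high_confidence = parse_airr_bool(df[["high_confidence"]] %||% rep("T", nrow(df)),
                                        default = TRUE),
      productive = parse_airr_bool(df[["productive"]] %||% rep("T", nrow(df)),
                                   default = TRUE)
    )
  }
  if (any(out$umis < 0, na.rm = TRUE)) {
    abort("negative UMI counts in contig table", class = "clonodyn_format_error")
  }
  out
}

normalize_chain <- function(x) {
  x <- toupper(stringr::str_trim(x))
  dplyr::if_else(x %in% c("TRA", "TRB"), x, "other")
}

parse_tenx_bool <- function(x) {
  toupper(stringr::str_trim(x)) %in% c("TRUE", "T")
}

parse_airr_bool <- function(x, default = TRUE) {
  x <- toupper(stringr::str_trim(x))
  dplyr::case_when(x %in% c("T", "TRUE") ~ TRUE,
                   x %in% c("F", "FALSE") ~ FALSE,
                   .default = default)
}

#' Write contigs in the 10x CSV dialect
#' @param contigs Tibble as returned by [read_contigs()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_contigs <- function(contigs, path) {
  out <- tibble::tibble(
    barcode = contigs$barcode,
    chain = contigs$chain,
    v_gene = contigs$v_gene,
    d_gene = contigs$d_gene,
    j_gene = contigs$j_gene,
    cdr3 = contigs$cdr3_aa,
    cdr3_nt = contigs$cdr3_nt,
    umis = contigs$umis,
    high_confidence = ifelse(contigs$high_confidence, "True", "False"),
    productive = ifelse(contigs$productive, "True", "False")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gene panel file
#'
#' One gene symbol per line, or a CSV with a `gene` column. Symbols are
#' whitespace-trimmed and matched case-sensitively downstream. Duplicates are
#' dropped (order preserved) with a warning.
#'
#' @param path Path to the panel file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "clonodyn_format_error")
  first <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  if (length(first) && grepl(",", first) ) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (!"gene" %in% names(df)) {
      abort("panel CSV must have a 'gene' column", class = "clonodyn_format_error")
    }
    genes <- df$gene
  } else {
    genes <- readr::read_lines(path, progress = FALSE)
  }
  genes <- stringr::str_trim(genes)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) abort("gene panel file is empty", class = "clonodyn_format_error")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn(paste0("gene panel contains duplicated symbols (kept first occurrence): ",
                paste(dup, collapse = ", ")))
    genes <- genes[!duplicated(genes)]
  }
  genes
}

#' Read per-cell metadata
#'
#' @param path CSV with columns `barcode`, `sample_id`, `patient_id`,
#'   `timepoint` (`BF`/`FL` or empty), `group` (`SLE`/`CTL`), `cell_type`.
#' @return Tibble with those columns; `timepoint` is `NA` where empty.
#' @export
read_cell_meta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "clonodyn_format_error")
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("barcode", "sample_id", "patient_id", "timepoint", "group", "cell_type")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(paste0("metadata missing required columns: ", paste(missing, collapse = ", ")),
          class = "clonodyn_format_error")
  }
  df$timepoint[!is.na(df$timepoint) & !nzchar(df$timepoint)] <- NA_character_
  bad <- setdiff(unique(df$timepoint[!is.na(df$timepoint)]), c("BF", "FL"))
  if (length(bad)) {
    abort(paste0("invalid timepoint labels: ", paste(bad, collapse = ", ")),
          class = "clonodyn_format_error")
  }
  if (anyDuplicated(df$barcode)) {
    abort("duplicated barcodes in metadata", class = "clonodyn_format_error")
  }
  tibble::as_tibble(df[req])
}
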