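#' Call paired alpha/beta clonotypes from contigs
#'
#' Applies the four-step contig filter and keying rule:
#' \enumerate{
#'   \item drop contigs not flagged high-confidence (and, by default,
#'     non-productive ones — the 10x filtered-contig convention; turn off
#'     with `require_productive = FALSE` to apply the literal four rules);
#'   \item per barcode and chain, keep the contig with the highest UMI count
#'     (ties broken lexicographically by `(cdr3_nt, v_gene)` so results do
#'     not depend on row order);
#'   \item drop barcodes lacking a TRA or a TRB;
#'   \item assign a clonotype key from the V(D)J genes of both chains,
#'     optionally including both CDR3 amino-acid sequences.
#' }
#'
#' @param contigs Contig tibble as returned by [read_contigs()].
#' @param mode Clonotype key mode: `"genes_plus_cdr3aa"` (default,
#'   field-standard definition) or `"genes_only"` (V/D/J genes alone).
#' @param require_productive Require `productive == TRUE` in rule 1
#'   (default `TRUE`).
#' @return A list of class `clonotype_calls`: `calls`, a tibble with one row
#'   per retained cell (`barcode`, `tra_v`, `tra_j`, `tra_cdr3_aa`,
#'   `tra_umis`, `trb_v`, `trb_d`, `trb_j`, `trb_cdr3_aa`, `trb_umis`,
#'   `clonotype_id`), and `report`, contig- and barcode-level removal counts
#'   plus the key mode used.
#' @export
call_clonotypes <- function(contigs,
                            mode = c("genes_plus_cdr3aa", "genes_only"),
                            require_productive = TRUE) {
  mode <- match.arg(mode)
  empty_calls <- tibble::tibble(
    barcode = character(), tra_v = character(), tra_j = character(),
    tra_cdr3_aa = character(), tra_umis = integer(),
    trb_v = character(), trb_d = character(), trb_j = character(),
    trb_cdr3_aa = character(), trb_umis = integer(),
    clonotype_id = character())

  n_contigs_in <- nrow(contigs)
  barcodes_in <- unique(contigs$barcode)

  if (n_contigs_in == 0L) {
    report <- list(mode = mode, require_productive = require_productive,
                   n_contigs_in = 0L, n_barcodes_in = 0L,
                   n_removed_low_confidence = 0L, n_removed_nonproductive = 0L,
                   n_removed_other_chain = 0L, n_removed_secondary_chain = 0L,
                   n_ties_broken = 0L, n_barcodes_unpaired = 0L, n_calls = 0L)
    return(structure(list(calls = empty_calls, report = report),
                     class = "clonotype_calls"))
  }

  # rule 1: confidence (and productivity under the 10x convention)
  keep1 <- contigs$high_confidence
  n_lowconf <- sum(!keep1)
  n_nonprod <- 0L
  if (require_productive) {
    keep_prod <- contigs$productive
    n_nonprod <- sum(keep1 & !keep_prod)
    keep1 <- keep1 & keep_prod
  }
  step1 <- contigs[keep1, , drop = FALSE]

  is_ab <- step1$chain %in% c("TRA", "TRB")
  n_other <- sum(!is_ab)
  step1 <- step1[is_ab, , drop = FALSE]

  # rule 2: max-UMI contig per barcode x chain, deterministic tie-break
  step2 <- step1 |>
    dplyr::group_by(.data$barcode, .data$chain) |>
    dplyr::arrange(dplyr::desc(.data$umis), .data$cdr3_nt, .data$v_gene,
                   .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number(),
                  # after the sort, umis[1] is the group maximum
                  .tied = dplyr::n() > 1 & .data$umis == .data$umis[1] & .data$.rank > 1) |>
    dplyr::ungroup()
  n_ties <- sum(step2$.tied)
  n_secondary <- sum(step2$.rank > 1)
  step2 <- step2[step2$.rank == 1L, , drop = FALSE]

  # rule 3: require both chains
  wide <- step2 |>
    dplyr::select("barcode", "chain", "v_gene", "d_gene", "j_gene",
                  "cdr3_aa", "umis") |>
    tidyr::pivot_wider(names_from = "chain",
                       values_from = c("v_gene", "d_gene", "j_gene", "cdr3_aa", "umis"))
  chr_cols <- c("v_gene_TRA", "j_gene_TRA", "cdr3_aa_TRA",
                "v_gene_TRB", "d_gene_TRB", "j_gene_TRB", "cdr3_aa_TRB")
  for (col in chr_cols) if (!col %in% names(wide)) wide[[col]] <- NA_character_
  for (col in c("umis_TRA", "umis_TRB")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
  }
  paired <- !is.na(wide$v_gene_TRA) & !is.na(wide$v_gene_TRB)
  n_unpaired <- length(barcodes_in) - sum(paired)
  wide <- wide[paired, , drop = FALSE]

  calls <- tibble::tibble(
    barcode = wide$barcode,
    tra_v = wide$v_gene_TRA, tra_j = wide$j_gene_TRA,
    tra_cdr3_aa = wide$cdr3_aa_TRA, tra_umis = as.integer(wide$umis_TRA),
    trb_v = wide$v_gene_TRB, trb_d = dplyr::coalesce(wide$d_gene_TRB, ""),
    trb_j = wide$j_gene_TRB,
    trb_cdr3_aa = wide$cdr3_aa_TRB, trb_umis = as.integer(wide$umis_TRB))
  calls$clonotype_id <- clonotype_key(calls, mode)
  calls <- dplyr::arrange(calls, .data$barcode)

  report <- list(mode = mode, require_productive = require_productive,
                 n_contigs_in = n_contigs_in,
                 n_barcodes_in = length(barcodes_in),
                 n_removed_low_confidence = n_lowconf,
                 n_removed_nonproductive = n_nonprod,
                 n_removed_other_chain = n_other,
                 n_removed_secondary_chain = n_secondary,
                 n_ties_broken = n_ties,
                 n_barcodes_unpaired = n_unpaired,
                 n_calls = nrow(calls))
  structure(list(calls = calls, report = report), class = "clonotype_calls")
}

# canonical clonotype key: pure function of the two retained chains
clonotype_key <- function(calls, mode) {
  tra <- paste(calls$tra_v, calls$tra_j, sep = ".")
  trb <- paste(calls$trb_v, calls$trb_d, calls$trb_j, sep = ".")
  if (mode == "genes_plus_cdr3aa") {
    tra <- paste(tra, calls$tra_cdr3_aa, sep = ".")
    trb <- paste(trb, calls$trb_cdr3_aa, sep = ".")
  }
  paste(tra, trb, sep = "_")
}

#' @export
print.clonotype_calls <- function(x, ...) {
  r <- x$report
  cat("Clonotype calls:", r$n_calls, "cells from", r$n_barcodes_in,
      "barcodes (key mode:", r$mode, ")\n")
  cat("  removed contigs: low confidence", r$n_removed_low_confidence,
      "| non-productive", r$n_removed_nonproductive,
      "| non-alpha/beta", r$n_removed_other_chain,
      "| secondary chain", r$n_removed_secondary_chain, "\n")
  cat("  unpaired barcodes dropped:", r$n_barcodes_unpaired, "\n")
  invisible(x)
}

#' @export
tidy.clonotype_calls <- function(x, ...) x$calls

#' @export
glance.clonotype_calls <- function(x, ...) {
  tibble::as_tibble(x$report[c("n_contigs_in", "n_barcodes_in", "n_calls",
                               "n_barcodes_unpaired", "mode")])
}

#' Build per-stratum repertoire profiles from clonotype calls
#'
#' Joins calls with cell metadata and tabulates cells per clonotype within
#' each stratum (sample, optionally crossed with cell type or any other
#' metadata fields).
#'
#' @param calls A `clonotype_calls` object or its `calls` tibble.
#' @param meta Cell metadata tibble ([read_cell_meta()] layout).
#' @param stratify_by Metadata fields defining strata
#'   (default `"sample_id"`).
#' @return A tibble with the stratum columns plus `clonotype_id`, `n` (cells)
#'   and `p` (within-stratum proportion; sums to 1 per stratum). Barcodes
#'   absent from `meta` are dropped and reported via the
#'   `n_unmatched_barcodes` attribute.
#' @export
repertoire_from_calls <- function(calls, meta, stratify_by = "sample_id") {
  if (inherits(calls, "clonotype_calls")) calls <- calls$calls
  stopifnot(all(stratify_by %in% names(meta)))
  joined <- dplyr::inner_join(calls["barcode"] |> dplyr::mutate(clonotype_id = calls$clonotype_id),
                              meta, by = "barcode")
  n_unmatched <- nrow(calls) - nrow(joined)
  if (n_unmatched > 0) {
    warn(paste0(n_unmatched, " call barcodes missing from metadata; excluded"))
  }
  prof <- joined |>
    dplyr::count(dplyr::across(dplyr::all_of(stratify_by)), .data$clonotype_id, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratify_by))) |>
    dplyr::mutate(p = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  attr(prof, "n_unmatched_barcodes") <- n_unmatched
  prof
}
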