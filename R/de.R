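# counts-per-10k then log1p; the normalization used before averaging,
# scoring and rank tests throughout the package
normalize_log1p <- function(counts, scale = 1e4) {
  libsize <- Matrix::colSums(counts)
  libsize[libsize == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(x = scale / libsize)
  colnames(norm) <- colnames(counts)
  log1p(norm)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement,
#' mapped back to the input order (a validated front-end to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) abort("p values must be numeric")
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p, method = "BH")
}

#' Two-group differential expression
#'
#' Per-gene Mann-Whitney (Wilcoxon rank-sum) test on normalized log1p
#' expression between two groups of cells, with fold change computed on
#' linear-scale normalized group means (pseudocount `eps` on both sides) and
#' Benjamini-Hochberg correction over all tested genes. A gene is flagged
#' significant when `fold_change > fc_threshold` **and**
#' `p_adj < p_threshold`, both strict. The rank-sum test is a
#' distribution-free substitute for model-based single-cell DE; the test
#' name is recorded in the result attributes.
#'
#' @param counts Genes-by-cells count matrix.
#' @param meta Cell metadata (must cover the cells of `counts`).
#' @param group_field Metadata column with exactly two levels among the
#'   selected cells.
#' @param cells_subset Optional barcodes restricting the test (e.g. one cell
#'   type).
#' @param fc_threshold Linear fold-change cutoff, strict (default 1.25).
#' @param p_threshold Adjusted-p cutoff, strict (default 1e-6).
#' @param eps Pseudocount on linear means (default 0.01).
#' @return Tibble of class `de_result`: `gene`, `mean_<level>` for both
#'   levels, `fold_change`, `log2fc`, `p_raw`, `p_adj`, `significant`.
#'   Genes with all-zero counts in both groups are skipped (recorded in the
#'   `n_skipped_zero` attribute). Fold change is level2/level1 with levels
#'   sorted alphabetically unless `group_levels` is given.
#' @param group_levels Optional length-2 character: reference level first.
#' @export
de_test <- function(counts, meta, group_field = "group", cells_subset = NULL,
                    fc_threshold = 1.25, p_threshold = 1e-6, eps = 0.01,
                    group_levels = NULL) {
  meta <- dplyr::filter(meta, .data$barcode %in% colnames(counts))
  if (!is.null(cells_subset)) meta <- dplyr::filter(meta, .data$barcode %in% cells_subset)
  grp <- meta[[group_field]]
  levels <- group_levels %||% sort(unique(grp))
  if (length(levels) != 2) abort("de_test requires exactly two groups")
  g1 <- meta$barcode[grp == levels[1]]
  g2 <- meta$barcode[grp == levels[2]]
  if (length(g1) < 3 || length(g2) < 3) abort("each group needs at least 3 cells")

  sub <- counts[, c(g1, g2), drop = FALSE]
  norm_lin <- sub %*% Matrix::Diagonal(x = 1e4 / pmax(Matrix::colSums(sub), 1))
  colnames(norm_lin) <- colnames(sub)
  logn <- log1p(norm_lin)

  i1 <- seq_along(g1); i2 <- length(g1) + seq_along(g2)
  nonzero <- Matrix::rowSums(sub) > 0
  n_skipped <- sum(!nonzero)
  genes <- rownames(sub)[nonzero]

  m1 <- Matrix::rowMeans(norm_lin[genes, i1, drop = FALSE])
  m2 <- Matrix::rowMeans(norm_lin[genes, i2, drop = FALSE])
  fc <- (m2 + eps) / (m1 + eps)
  lm_ <- as.matrix(logn[genes, , drop = FALSE])
  p_raw <- vapply(seq_along(genes), function(i) {
    suppressWarnings(wilcox.test(lm_[i, i2], lm_[i, i1], exact = FALSE)$p.value)
  }, numeric(1))
  p_raw[is.na(p_raw)] <- 1  # constant genes
  p_adj <- benjamini_hochberg(p_raw)

  out <- tibble::tibble(gene = genes,
                        mean_ref = unname(m1), mean_alt = unname(m2),
                        fold_change = unname(fc), log2fc = log2(unname(fc)),
                        p_raw = p_raw, p_adj = p_adj,
                        significant = fc > fc_threshold & p_adj < p_threshold)
  names(out)[2:3] <- paste0("mean_", levels)
  attr(out, "test") <- "Mann-Whitney (Wilcoxon rank-sum), normal approximation"
  attr(out, "levels") <- levels
  attr(out, "n_skipped_zero") <- n_skipped
  attr(out, "thresholds") <- c(fold_change = fc_threshold, p_adj = p_threshold)
  class(out) <- c("de_result", class(out))
  out
}

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(n_genes_tested = nrow(x),
                 n_significant = sum(x$significant),
                 n_skipped_zero = attr(x, "n_skipped_zero"),
                 test = attr(x, "test"))
}

#' Cell-type composition comparison between groups
#'
#' Computes per-sample cell-type fractions and compares them between two
#' groups with a per-type Mann-Whitney test on the sample fractions
#' (samples — not cells — are the independent units), BH-adjusted across
#' cell types. Types absent from a sample contribute fraction 0.
#'
#' @param meta Cell metadata.
#' @param group_field Metadata column with the two groups (default
#'   `"group"`).
#' @param type_field Cell-type column (default `"cell_type"`).
#' @return List of class `composition_result`: `fractions` (sample x type
#'   tibble; fractions sum to 1 per sample), `tests` (per type: group
#'   medians, direction, p, p_adj).
#' @export
composition_compare <- function(meta, group_field = "group",
                                type_field = "cell_type") {
  samples <- meta |>
    dplyr::distinct(.data$sample_id, grp = .data[[group_field]])
  levels <- sort(unique(samples$grp))
  if (length(levels) != 2) abort("composition_compare requires exactly two groups")
  if (any(table(samples$grp) < 2)) abort("need at least two samples per group")

  fr <- meta |>
    dplyr::count(.data$sample_id, type = .data[[type_field]]) |>
    tidyr::complete(.data$sample_id, .data$type, fill = list(n = 0L)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::left_join(samples, by = "sample_id")

  tests <- fr |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      median_1 = stats::median(.data$fraction[.data$grp == levels[1]]),
      median_2 = stats::median(.data$fraction[.data$grp == levels[2]]),
      p_value = suppressWarnings(
        wilcox.test(.data$fraction[.data$grp == levels[2]],
                    .data$fraction[.data$grp == levels[1]], exact = FALSE)$p.value),
      .groups = "drop") |>
    dplyr::mutate(p_value = ifelse(is.na(.data$p_value), 1, .data$p_value),
                  p_adj = benjamini_hochberg(.data$p_value),
                  direction = dplyr::case_when(
                    .data$median_2 > .data$median_1 ~ levels[2],
                    .data$median_2 < .data$median_1 ~ levels[1],
                    .default = "none"))
  names(tests)[names(tests) == "median_1"] <- paste0("median_", levels[1])
  names(tests)[names(tests) == "median_2"] <- paste0("median_", levels[2])
  structure(list(fractions = fr, tests = tests, levels = levels),
            class = "composition_result")
}

#' @export
tidy.composition_result <- function(x, ...) x$tests

#' Per-sample subtype ratio with a group test
#'
#' Ratio of two cell subtypes within each sample (e.g. atypical B cells to
#' memory B cells within total B cells, or CD4 to CD8 T cells), compared
#' between groups by Mann-Whitney. Samples with a zero denominator are
#' excluded and reported.
#'
#' @param meta Cell metadata.
#' @param numerator_type,denominator_type Cell-type labels; each may be a
#'   vector of labels pooled together.
#' @param group_field Grouping column (default `"group"`).
#' @return List: `ratios` (per-sample tibble), `test` (p value and group
#'   medians), `excluded_samples`.
#' @export
subtype_ratio <- function(meta, numerator_type, denominator_type,
                          group_field = "group") {
  per <- meta |>
    dplyr::group_by(.data$sample_id, grp = .data[[group_field]]) |>
    dplyr::summarise(n_num = sum(.data$cell_type %in% numerator_type),
                     n_den = sum(.data$cell_type %in% denominator_type),
                     .groups = "drop")
  excluded <- per$sample_id[per$n_den == 0]
  if (length(excluded)) {
    warn(paste0("samples with zero denominator excluded: ",
                paste(excluded, collapse = ", ")))
  }
  per <- dplyr::filter(per, .data$n_den > 0) |>
    dplyr::mutate(ratio = .data$n_num / .data$n_den)
  if (!nrow(per)) abort("all samples excluded: denominator type absent everywhere")
  levels <- sort(unique(per$grp))
  test <- NULL
  if (length(levels) == 2 && all(table(per$grp) >= 2)) {
    pv <- suppressWarnings(
      wilcox.test(per$ratio[per$grp == levels[2]],
                  per$ratio[per$grp == levels[1]], exact = FALSE)$p.value)
    test <- tibble::tibble(
      level_1 = levels[1], level_2 = levels[2],
      median_1 = stats::median(per$ratio[per$grp == levels[1]]),
      median_2 = stats::median(per$ratio[per$grp == levels[2]]),
      p_value = ifelse(is.na(pv), 1, pv))
  }
  list(ratios = per, test = test, excluded_samples = excluded)
}

#' Bar chart of per-sample cell-type fractions by group
#' @param x `composition_result` from [composition_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_result <- function(x, ...) {
  ggplot2::ggplot(x$fractions,
                  ggplot2::aes(.data$type, .data$fraction, fill = .data$grp)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "fraction of sample", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
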