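#' Per-cell-type log2 fold-change profile of a gene panel
#'
#' For each panel gene and cell type, computes
#' `log2((mean_SLE + eps) / (mean_CTL + eps))` of counts-per-10k normalized
#' (linear-scale) expression, where the means are taken over cells of that
#' type in each group. Each entry carries a significance flag from
#' [de_test()] run within the cell type at the package's thresholds.
#'
#' @param counts Genes-by-cells count matrix.
#' @param meta Cell metadata.
#' @param panel Character vector of panel genes; genes absent from the
#'   matrix are dropped with a warning.
#' @param group_field Two-level group column (default `"group"`).
#' @param celltype_field Cell-type column (default `"cell_type"`).
#' @param eps Pseudocount on the fold-change ratio (default 0.01).
#' @param group_levels Optional length-2 character, reference level first
#'   (default: alphabetical, so `CTL` is the reference for `SLE`/`CTL`).
#' @param test Run the per-type DE test for significance flags
#'   (default TRUE; set FALSE to skip the costly tests).
#' @return Tibble of class `fc_profile`: `gene`, `cell_type`, `log2fc`,
#'   `p_adj`, `significant`. Cell types missing either group are dropped
#'   (with a message).
#' @export
log2fc_profile <- function(counts, meta, panel, group_field = "group",
                           celltype_field = "cell_type", eps = 0.01,
                           group_levels = NULL, test = TRUE) {
  present <- intersect(panel, rownames(counts))
  if (length(present) < length(panel)) {
    warn(paste0(length(panel) - length(present),
                " panel genes absent from the matrix were dropped"))
  }
  if (!length(present)) abort("no panel genes present in the matrix")
  meta <- dplyr::filter(meta, .data$barcode %in% colnames(counts))
  levels <- group_levels %||% sort(unique(meta[[group_field]]))
  if (length(levels) != 2) abort("log2fc_profile requires exactly two groups")

  norm_lin <- counts %*% Matrix::Diagonal(x = 1e4 / pmax(Matrix::colSums(counts), 1))
  colnames(norm_lin) <- colnames(counts)
  norm_lin <- norm_lin[present, , drop = FALSE]

  types <- sort(unique(meta[[celltype_field]]))
  usable <- types[vapply(types, function(t) {
    g <- meta[[group_field]][meta[[celltype_field]] == t]
    all(levels %in% g) && all(table(factor(g, levels))[levels] >= 3)
  }, logical(1))]
  dropped <- setdiff(types, usable)
  if (length(dropped)) {
    inform(paste0("cell types without both groups (>=3 cells each) dropped: ",
                  paste(dropped, collapse = ", ")))
  }
  res <- purrr::map(usable, function(t) {
    bc_t <- meta$barcode[meta[[celltype_field]] == t]
    g <- meta[[group_field]][match(bc_t, meta$barcode)]
    m_ref <- Matrix::rowMeans(norm_lin[, bc_t[g == levels[1]], drop = FALSE])
    m_alt <- Matrix::rowMeans(norm_lin[, bc_t[g == levels[2]], drop = FALSE])
    out <- tibble::tibble(gene = present, cell_type = t,
                          log2fc = unname(log2((m_alt + eps) / (m_ref + eps))))
    if (test) {
      de <- de_test(counts[present, , drop = FALSE], meta,
                    group_field = group_field, cells_subset = bc_t,
                    group_levels = levels)
      out$p_adj <- de$p_adj[match(out$gene, de$gene)]
      out$significant <- dplyr::coalesce(de$significant[match(out$gene, de$gene)], FALSE)
    } else {
      out$p_adj <- NA_real_
      out$significant <- NA
    }
    out
  })
  out <- dplyr::bind_rows(res)
  attr(out, "levels") <- levels
  class(out) <- c("fc_profile", class(out))
  out
}

fc_profile_matrix <- function(profile) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(profile)[c("gene", "cell_type", "log2fc")],
                             names_from = "cell_type", values_from = "log2fc")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene
  m
}

#' Partition a gene panel into modules by K-means with silhouette selection
#'
#' Clusters panel genes on their per-cell-type log2 fold-change profiles
#' (Euclidean distance on the raw rows) for every candidate `K`, keeping the
#' best of `n_restarts` random initializations by within-cluster sum of
#' squares, and selects the `K` maximizing the mean silhouette width.
#' Cluster labels are renumbered `C1, C2, ...` by descending cluster size
#' (ties by first gene) so the labelling is deterministic.
#'
#' @param profile An `fc_profile` tibble from [log2fc_profile()], or a
#'   numeric genes-by-features matrix.
#' @param k_range Candidate cluster numbers (default `2:8`).
#' @param n_restarts Random restarts per `K` (default 50).
#' @param seed Integer seed for the restarts.
#' @return Object of class `module_partition`: `k` (selected K),
#'   `assignment` (tibble gene/module), `silhouette_by_k` (tibble),
#'   `centers`, `seed`.
#' @export
cluster_panel <- function(profile, k_range = 2:8, n_restarts = 50L, seed = 1L) {
  m <- if (is.matrix(profile)) profile else fc_profile_matrix(profile)
  if (nrow(m) < 3) abort("need at least 3 genes to cluster")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > nrow(m) - 1)) {
    abort("k_range must lie within [2, n_genes - 1]")
  }
  if (all(apply(m, 2, function(col) diff(range(col)) == 0))) {
    abort("no cluster structure: all profile rows are identical")
  }
  d <- stats::dist(m)
  fits <- withr::with_seed(seed, {
    lapply(k_range, function(k) {
      fit <- suppressWarnings(kmeans(m, centers = k, nstart = n_restarts,
                                     iter.max = 100))
      sil <- cluster::silhouette(fit$cluster, d)
      list(k = k, fit = fit, mean_sil = mean(sil[, "sil_width"]))
    })
  })
  sil_tbl <- tibble::tibble(k = k_range,
                            mean_silhouette = vapply(fits, `[[`, numeric(1), "mean_sil"))
  best <- fits[[which.max(sil_tbl$mean_silhouette)]]
  cl <- best$fit$cluster
  # deterministic relabelling: C1 is the largest cluster
  sizes <- table(cl)
  order_lab <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- setNames(seq_along(order_lab), names(sizes)[order_lab])
  module <- paste0("C", relab[as.character(cl)])
  centers <- best$fit$centers[as.integer(names(relab)[order(relab)]), , drop = FALSE]
  rownames(centers) <- paste0("C", seq_len(nrow(centers)))
  structure(list(k = best$k,
                 assignment = tibble::tibble(gene = rownames(m), module = module),
                 silhouette_by_k = sil_tbl,
                 centers = centers,
                 seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition: K =", x$k, "selected from {",
      paste(x$silhouette_by_k$k, collapse = ", "), "} by mean silhouette\n")
  print(table(x$assignment$module))
  invisible(x)
}

#' @export
tidy.module_partition <- function(x, ...) x$assignment

#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(k = x$k,
                 mean_silhouette = x$silhouette_by_k$mean_silhouette[
                   x$silhouette_by_k$k == x$k],
                 n_genes = nrow(x$assignment), seed = x$seed)
}

#' Silhouette curve of a module partition
#' @param object `module_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_partition <- function(object, ...) {
  ggplot2::ggplot(object$silhouette_by_k,
                  ggplot2::aes(.data$k, .data$mean_silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "K", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Per-cell gene-set module scores
#'
#' Scores each cell for each gene set as the mean normalized log1p
#' expression of the set's genes, optionally minus the mean of an
#' expression-bin-matched control gene set (the standard module-score
#' convention: genes are binned by average expression, and for each set
#' gene, control genes are drawn from its bin). Scores are then z-scored
#' across cells per module; when a module's score is constant the z-score
#' is defined as 0.
#'
#' @param counts Genes-by-cells count matrix.
#' @param gene_sets Named list: module -> character vector of genes. Genes
#'   absent from the matrix are dropped; a module with no present genes is
#'   dropped with a warning.
#' @param control Subtract bin-matched control scores (default TRUE; set
#'   FALSE for the plain aggregated mean).
#' @param n_bins Expression bins for control matching (default 24).
#' @param ctrl_per_bin Control genes drawn per set gene (default 100, capped
#'   at bin size).
#' @param seed Seed for control-gene sampling.
#' @return Tibble of class `module_scores`: `barcode` plus one z-scored
#'   numeric column per module. The scoring mode is recorded in the
#'   `mode` attribute.
#' @export
module_scores <- function(counts, gene_sets, control = TRUE, n_bins = 24L,
                          ctrl_per_bin = 100L, seed = 1L) {
  logn <- normalize_log1p(counts)
  present_sets <- lapply(gene_sets, function(g) intersect(g, rownames(counts)))
  empty <- names(present_sets)[lengths(present_sets) == 0]
  if (length(empty)) {
    warn(paste0("modules with no genes present were dropped: ",
                paste(empty, collapse = ", ")))
    present_sets <- present_sets[lengths(present_sets) > 0]
  }
  if (!length(present_sets)) abort("no scorable modules")

  set_score <- function(genes) Matrix::colMeans(logn[genes, , drop = FALSE])

  ctrl_pool <- NULL
  if (control) {
    avg <- Matrix::rowMeans(logn)
    bins <- cut(rank(avg, ties.method = "first"),
                breaks = min(n_bins, length(avg)), labels = FALSE)
    ctrl_pool <- split(rownames(counts), bins)
    bin_of <- setNames(bins, rownames(counts))
  }

  scores <- withr::with_seed(seed, {
    purrr::map(present_sets, function(genes) {
      s <- set_score(genes)
      if (control) {
        ctrl_genes <- unique(unlist(lapply(genes, function(g) {
          pool <- ctrl_pool[[bin_of[[g]]]]
          sample(pool, min(ctrl_per_bin, length(pool)))
        })))
        s <- s - set_score(ctrl_genes)
      }
      if (sd(s) == 0) rep(0, length(s)) else unname((s - mean(s)) / sd(s))
    })
  })
  out <- tibble::tibble(barcode = colnames(counts), !!!scores)
  attr(out, "mode") <- if (control) "bin_matched_control" else "plain_mean"
  class(out) <- c("module_scores", class(out))
  out
}

#' Compare module scores between groups of cells
#'
#' Per-group summary plus a Mann-Whitney (two groups) or Kruskal-Wallis
#' (more) test per module, BH-adjusted across modules.
#'
#' @param scores `module_scores` tibble (barcode + module columns).
#' @param meta Cell metadata.
#' @param grouping Metadata column defining the groups (e.g. `"group"` or
#'   `"timepoint"`).
#' @param cells_subset Optional barcodes restricting the comparison.
#' @param modules Modules to compare (default: all score columns).
#' @return List: `summary` (per group x module: n/mean/sd), `tests` (per
#'   module: test name, p, p_adj).
#' @export
compare_scores_by_group <- function(scores, meta, grouping = "group",
                                    cells_subset = NULL, modules = NULL) {
  modules <- modules %||% setdiff(names(scores), "barcode")
  df <- dplyr::inner_join(scores, meta, by = "barcode")
  if (!is.null(cells_subset)) df <- dplyr::filter(df, .data$barcode %in% cells_subset)
  grp <- df[[grouping]]
  groups <- unique(grp[!is.na(grp)])
  if (length(groups) < 2) abort("need at least two groups to compare")
  df <- df[!is.na(grp), ]
  grp <- grp[!is.na(grp)]
  small <- names(which(table(grp) < 2))
  if (length(small)) abort("every group needs at least 2 cells")

  long <- tidyr::pivot_longer(df[c("barcode", grouping, modules)],
                              dplyr::all_of(modules),
                              names_to = "module", values_to = "score")
  summary <- long |>
    dplyr::group_by(group = .data[[grouping]], .data$module) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = sd(.data$score), .groups = "drop")
  tests <- long |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      test = ifelse(length(groups) == 2, "mann_whitney", "kruskal_wallis"),
      p_value = {
        g <- .data[[grouping]]
        if (length(groups) == 2) {
          suppressWarnings(wilcox.test(.data$score[g == groups[1]],
                                       .data$score[g == groups[2]],
                                       exact = FALSE)$p.value)
        } else {
          kruskal.test(.data$score, factor(g))$p.value
        }
      }, .groups = "drop") |>
    dplyr::mutate(p_value = ifelse(is.na(.data$p_value), 1, .data$p_value),
                  p_adj = benjamini_hochberg(.data$p_value))
  list(summary = summary, tests = tests)
}

#' Heatmap of a fold-change profile
#' @param object `fc_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$cell_type, .data$gene, fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
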