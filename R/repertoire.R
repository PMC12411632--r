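# Accept either a bare count vector or a profile tibble with an `n` column.
profile_counts <- function(x, arg = "profile") {
  if (is.data.frame(x)) {
    stopifnot("n" %in% names(x))
    n <- x$n
    if ("clonotype_id" %in% names(x)) names(n) <- x$clonotype_id
  } else {
    n <- x
  }
  if (any(n < 0)) abort(paste0(arg, " contains negative counts"))
  n[n > 0]
}

#' Shannon entropy of a clonotype repertoire
#'
#' `H = -sum(p_i * log(p_i))` over clonotype proportions, computed on cell
#' counts per clonotype. Lower values indicate clonal restriction. Natural
#' log by default; the base is configurable and recorded as an attribute.
#'
#' @param profile Numeric vector of clonotype counts, or a profile tibble
#'   with an `n` column (as from [repertoire_from_calls()]).
#' @param base Logarithm base (default `exp(1)`).
#' @return Entropy in `[0, log(richness)]`.
#' @export
shannon_diversity <- function(profile, base = exp(1)) {
  n <- profile_counts(profile)
  if (!length(n)) abort("empty repertoire: Shannon entropy undefined")
  p <- n / sum(n)
  h <- -sum(p * log(p)) / log(base)
  structure(max(h, 0), base = base)
}

#' Morisita-Horn similarity between two repertoires
#'
#' Abundance-weighted overlap in `[0, 1]`:
#' `MH = 2 * sum(x_i * y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' over the union of clonotype keys (absent clones count 0). Equals 1 for
#' proportionally identical repertoires and 0 for disjoint ones; invariant
#' to proportional scaling of either side.
#'
#' @param x,y Named count vectors (names = clonotype ids) or profile tibbles
#'   with `clonotype_id` and `n` columns.
#' @return Similarity in `[0, 1]`.
#' @export
morisita_horn <- function(x, y) {
  xs <- profile_counts(x, "x"); ys <- profile_counts(y, "y")
  if (!length(xs) || !length(ys)) abort("Morisita-Horn undefined on an empty repertoire")
  if (is.null(names(xs)) || is.null(names(ys))) {
    abort("counts must be named by clonotype id (or pass profile tibbles)")
  }
  keys <- union(names(xs), names(ys))
  xv <- unname(xs[keys]); xv[is.na(xv)] <- 0
  yv <- unname(ys[keys]); yv[is.na(yv)] <- 0
  X <- sum(xv); Y <- sum(yv)
  denom <- (sum(xv^2) / X^2 + sum(yv^2) / Y^2) * X * Y
  mh <- 2 * sum(xv * yv) / denom
  min(max(mh, 0), 1)
}

#' Number of unique clonotypes (richness)
#' @inheritParams shannon_diversity
#' @return Integer count of distinct clonotypes with at least one cell.
#' @export
unique_clonotypes <- function(profile) {
  if (is.data.frame(profile) && !nrow(profile)) return(0L)
  if (!is.data.frame(profile) && !length(profile)) return(0L)
  length(profile_counts(profile))
}

#' Proportion of the repertoire held by the top n clonotypes
#'
#' Sum of the `n` largest clonotype proportions (all of them when richness is
#' below `n`). When clones are tied at the cutoff, selection among the tied
#' clones is lexicographic by clonotype id, so the result is deterministic.
#'
#' @inheritParams shannon_diversity
#' @param n Number of top clonotypes (default 10).
#' @return Proportion in `(0, 1]`.
#' @export
top_n_proportion <- function(profile, n = 10L) {
  stopifnot(n >= 1)
  cnt <- profile_counts(profile)
  if (!length(cnt)) abort("empty repertoire: top-n proportion undefined")
  ids <- names(cnt) %||% as.character(seq_along(cnt))
  ord <- order(-cnt, ids)
  sum(cnt[ord][seq_len(min(n, length(cnt)))]) / sum(cnt)
}

#' Per-stratum repertoire summary metrics
#'
#' Convenience wrapper computing Shannon entropy, richness and top-n
#' dominance for every stratum of a profile table.
#'
#' @param profiles Profile tibble from [repertoire_from_calls()].
#' @param stratify_by Columns identifying strata (default: everything except
#'   `clonotype_id`, `n`, `p`).
#' @param top_n `n` for [top_n_proportion()].
#' @return Tibble with one row per stratum: `n_cells`, `n_clonotypes`,
#'   `shannon`, `top_n_proportion`.
#' @export
repertoire_metrics <- function(profiles, stratify_by = NULL, top_n = 10L) {
  if (is.null(stratify_by)) {
    stratify_by <- setdiff(names(profiles), c("clonotype_id", "n", "p"))
  }
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratify_by))) |>
    dplyr::summarise(
      n_cells = sum(.data$n),
      n_clonotypes = dplyr::n(),
      shannon = as.numeric(shannon_diversity(.data$n)),
      top_n_proportion = top_n_proportion(setNames(.data$n, .data$clonotype_id), n = top_n),
      .groups = "drop")
}

#' Pairwise Morisita-Horn similarity matrix
#'
#' @param profiles Either a named list of count vectors / profile tibbles, or
#'   a single profile table with stratum columns (split on `stratify_by`).
#' @param stratify_by Stratum columns when `profiles` is one table.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = stratum
#'   labels.
#' @export
similarity_matrix <- function(profiles, stratify_by = "sample_id") {
  if (is.data.frame(profiles)) {
    key <- do.call(paste, c(profiles[stratify_by], sep = "/"))
    profiles <- split(setNames(profiles$n, profiles$clonotype_id), key)
  }
  k <- length(profiles)
  if (k < 2) abort("similarity_matrix needs at least two profiles")
  labs <- names(profiles) %||% as.character(seq_len(k))
  m <- diag(1, k)
  dimnames(m) <- list(labs, labs)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- morisita_horn(profiles[[i]], profiles[[j]])
    }
  }
  m
}

#' Subsample a repertoire to a common depth
#'
#' Optional depth normalization for diversity comparisons across unequal
#' cell numbers (off by default throughout the package; Shannon entropy is
#' depth-sensitive, so use this when comparing very unequal repertoires).
#'
#' @param profile Named count vector or profile tibble.
#' @param depth Target number of cells.
#' @param seed Integer seed for the draw.
#' @return Named count vector at the requested depth.
#' @export
subsample_repertoire <- function(profile, depth, seed = 1L) {
  cnt <- profile_counts(profile)
  if (sum(cnt) < depth) abort("repertoire smaller than requested depth")
  ids <- names(cnt) %||% as.character(seq_along(cnt))
  withr::with_seed(seed, {
    drawn <- sample(rep(ids, cnt), depth, replace = FALSE)
  })
  tab <- table(drawn)
  setNames(as.integer(tab), names(tab))
}

#' Heatmap of a cross-sample similarity matrix
#'
#' @param m Matrix from [similarity_matrix()].
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = ~c("from", "to", "mh"))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$mh)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Morisita-Horn") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
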