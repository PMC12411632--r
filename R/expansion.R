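#' Flare-expansion classification parameters
#'
#' A clonotype is called expanded when its flare size is at least
#' `fold_threshold` times its baseline size (or it is absent at baseline and
#' present at flare), it is represented by at least `min_flare_cells` cells
#' in the flare state, and — when `require_proportional` — its
#' within-repertoire proportion also increased. The minimum-cell gate applies
#' only to would-be expanded clones; it never blocks a `not_expanded` label.
#'
#' @param fold_threshold Fold-increase threshold on cell counts (default 2).
#' @param min_flare_cells Minimum flare-state cells (default 3).
#' @param require_proportional Also require `p_fl > p_bf` (default TRUE).
#' @return List of class `expansion_params`.
#' @export
expansion_params <- function(fold_threshold = 2, min_flare_cells = 3L,
                             require_proportional = TRUE) {
  stopifnot(fold_threshold >= 1, min_flare_cells >= 1)
  structure(list(fold_threshold = fold_threshold,
                 min_flare_cells = as.integer(min_flare_cells),
                 require_proportional = require_proportional),
            class = "expansion_params")
}

#' Classify flare-expanded clonotypes for one patient
#'
#' Compares a baseline (before-flare, BF) and a flare (FL) repertoire of the
#' same patient and labels every clonotype in the union:
#' `expanded_de_novo` (absent at baseline, at least `min_flare_cells` at
#' flare), `expanded_fold` (count fold at least `fold_threshold`, at least
#' `min_flare_cells` flare cells, and proportional increase when required),
#' `excluded_min_cells` (would be expanded but has too few flare cells), or
#' `not_expanded`. Both the count fold and the proportion fold are emitted
#' so either reading of "fold increase" is auditable.
#'
#' @param bf,fl Baseline / flare profiles: named count vectors or tibbles
#'   with `clonotype_id` and `n`.
#' @param params [expansion_params()].
#' @param patient_id Optional label stored in the output; when both profiles
#'   carry a `patient_id` column they must agree.
#' @return Tibble of class `expansion_calls`: `patient_id`, `clonotype_id`,
#'   `n_bf`, `n_fl`, `p_bf`, `p_fl`, `count_fold`, `prop_fold`, `status`,
#'   `expanded` (logical shorthand).
#' @export
classify_expansion <- function(bf, fl, params = expansion_params(),
                               patient_id = NA_character_) {
  pid <- function(x) if (is.data.frame(x) && "patient_id" %in% names(x))
    unique(x$patient_id) else NULL
  pb <- pid(bf); pf <- pid(fl)
  if (!is.null(pb) && !is.null(pf)) {
    if (length(pb) != 1 || length(pf) != 1 || pb != pf) {
      abort("baseline and flare profiles must come from a single, identical patient")
    }
    if (is.na(patient_id)) patient_id <- pb
  }
  bfc <- profile_counts0(bf); flc <- profile_counts0(fl)
  if (!length(flc) || sum(flc) == 0) abort("flare profile is empty")
  keys <- union(names(bfc), names(flc))
  n_bf <- unname(bfc[keys]); n_bf[is.na(n_bf)] <- 0
  n_fl <- unname(flc[keys]); n_fl[is.na(n_fl)] <- 0
  N_bf <- sum(n_bf); N_fl <- sum(n_fl)
  p_bf <- if (N_bf > 0) n_bf / N_bf else rep(0, length(keys))
  p_fl <- n_fl / N_fl

  tau <- params$fold_threshold; m <- params$min_flare_cells
  de_novo_raw <- n_bf == 0 & n_fl > 0
  fold_raw <- n_bf > 0 & n_fl >= tau * n_bf &
    (!params$require_proportional | p_fl > p_bf)
  would_expand <- de_novo_raw | fold_raw
  status <- dplyr::case_when(
    would_expand & n_fl < m ~ "excluded_min_cells",
    de_novo_raw ~ "expanded_de_novo",
    fold_raw ~ "expanded_fold",
    .default = "not_expanded")

  out <- tibble::tibble(
    patient_id = patient_id, clonotype_id = keys,
    n_bf = as.integer(n_bf), n_fl = as.integer(n_fl),
    p_bf = p_bf, p_fl = p_fl,
    count_fold = ifelse(n_bf > 0, n_fl / n_bf, Inf),
    prop_fold = ifelse(p_bf > 0, p_fl / p_bf, Inf),
    status = status,
    expanded = status %in% c("expanded_de_novo", "expanded_fold"))
  out <- dplyr::arrange(out, .data$clonotype_id)
  class(out) <- c("expansion_calls", class(out))
  out
}

# like profile_counts() but keeps an all-zero/no-row case as empty
profile_counts0 <- function(x) {
  if (is.data.frame(x)) {
    setNames(x[["n"]] %||% integer(0), x[["clonotype_id"]])
  } else x
}

#' Classify expansion for every patient in a cohort
#'
#' Builds per-patient BF/FL repertoires (optionally restricted to given cell
#' types, e.g. CD8 T subsets) and runs [classify_expansion()] on each
#' patient that has both timepoints.
#'
#' @param calls `clonotype_calls` object or calls tibble.
#' @param meta Cell metadata.
#' @param params [expansion_params()].
#' @param cell_types Optional character vector restricting to cell types
#'   (matched against `meta$cell_type`); `NULL` uses all cells with calls.
#' @return `expansion_calls` tibble over all eligible patients.
#' @export
classify_expansion_cohort <- function(calls, meta, params = expansion_params(),
                                      cell_types = NULL) {
  if (inherits(calls, "clonotype_calls")) calls <- calls$calls
  use_meta <- meta
  if (!is.null(cell_types)) use_meta <- dplyr::filter(meta, .data$cell_type %in% cell_types)
  prof <- repertoire_from_calls(calls, use_meta,
                                stratify_by = c("patient_id", "timepoint"))
  prof <- dplyr::filter(prof, !is.na(.data$timepoint))
  eligible <- prof |>
    dplyr::distinct(.data$patient_id, .data$timepoint) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::pull(.data$patient_id)
  res <- purrr::map(eligible, function(pat) {
    bf <- dplyr::filter(prof, .data$patient_id == .env$pat, .data$timepoint == "BF")
    fl <- dplyr::filter(prof, .data$patient_id == .env$pat, .data$timepoint == "FL")
    classify_expansion(bf[c("clonotype_id", "n")], fl[c("clonotype_id", "n")],
                       params = params, patient_id = pat)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("expansion_calls", class(out))
  out
}

#' @export
glance.expansion_calls <- function(x, ...) {
  tibble::tibble(
    n_clonotypes = nrow(x),
    n_expanded = sum(x$expanded),
    n_de_novo = sum(x$status == "expanded_de_novo"),
    n_fold = sum(x$status == "expanded_fold"),
    n_excluded_min_cells = sum(x$status == "excluded_min_cells"))
}

#' Clonotype fate table across BF and FL cell subtypes
#'
#' For expanded clonotypes, crosses each clonotype's baseline subtype
#' distribution with its flare subtype distribution. Attribution is at the
#' clonotype level: every clonotype carries total weight 1, split across
#' (BF subtype, FL subtype) pairs proportionally to its cell counts, so
#' large clones do not dominate the transition structure. A cell-weighted
#' variant (`weighting = "cell"`) multiplies by the clonotype's flare cell
#' count instead. Clonotypes with no baseline cells appear in the
#' `"absent"` row.
#'
#' @param calls `clonotype_calls` object or calls tibble.
#' @param meta Cell metadata with `cell_type` and `timepoint`.
#' @param expansion `expansion_calls` tibble; only rows with
#'   `expanded == TRUE` contribute.
#' @param weighting `"clonotype"` (default) or `"cell"`.
#' @return Tibble with `patient_id`, `bf_type`, `fl_type`, `weight`,
#'   `n_cells_bf`, `n_cells_fl`; per-clonotype weights sum to 1 under
#'   clonotype weighting.
#' @export
fate_table <- function(calls, meta, expansion, weighting = c("clonotype", "cell")) {
  weighting <- match.arg(weighting)
  if (inherits(calls, "clonotype_calls")) calls <- calls$calls
  exp_ids <- dplyr::filter(expansion, .data$expanded)
  if (!nrow(exp_ids)) {
    return(tibble::tibble(patient_id = character(), bf_type = character(),
                          fl_type = character(), weight = numeric(),
                          n_cells_bf = integer(), n_cells_fl = integer()))
  }
  cells <- dplyr::inner_join(calls[c("barcode", "clonotype_id")], meta, by = "barcode") |>
    dplyr::filter(!is.na(.data$timepoint)) |>
    dplyr::semi_join(exp_ids, by = c("patient_id", "clonotype_id"))
  dist <- cells |>
    dplyr::count(.data$patient_id, .data$clonotype_id, .data$timepoint,
                 .data$cell_type, name = "n_cells")

  one_clone <- function(d) {
    bf <- d[d$timepoint == "BF", c("cell_type", "n_cells")]
    fl <- d[d$timepoint == "FL", c("cell_type", "n_cells")]
    stopifnot(nrow(fl) > 0)  # expanded clonotypes must have flare cells
    if (!nrow(bf)) bf <- tibble::tibble(cell_type = "absent", n_cells = 0L)
    grid <- tidyr::expand_grid(bf_type = bf$cell_type, fl_type = fl$cell_type)
    wb <- if (sum(bf$n_cells) > 0) bf$n_cells / sum(bf$n_cells) else rep(1, nrow(bf))
    wf <- fl$n_cells / sum(fl$n_cells)
    grid$weight <- rep(wb, each = nrow(fl)) * rep(wf, times = nrow(bf))
    grid$n_cells_bf <- rep(bf$n_cells, each = nrow(fl))
    grid$n_cells_fl <- rep(fl$n_cells, times = nrow(bf))
    if (weighting == "cell") grid$weight <- grid$weight * sum(fl$n_cells)
    grid
  }
  dist |>
    dplyr::group_by(.data$patient_id, .data$clonotype_id) |>
    dplyr::group_modify(~one_clone(.x)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$patient_id, .data$bf_type, .data$fl_type) |>
    dplyr::summarise(weight = sum(.data$weight),
                     n_cells_bf = sum(.data$n_cells_bf),
                     n_cells_fl = sum(.data$n_cells_fl), .groups = "drop")
}

#' Compare module scores between expanded and non-expanded clonotypes
#'
#' Attaches per-cell module scores to expansion status (via each cell's
#' clonotype) and summarises each score per timepoint and expansion group,
#' with a two-group Mann-Whitney test per (timepoint, score) and
#' Benjamini-Hochberg adjustment across scores.
#'
#' @param scores Tibble of per-cell scores: `barcode` plus one numeric
#'   column per score/module (as from [module_scores()]).
#' @param expansion `expansion_calls` tibble.
#' @param calls `clonotype_calls` object or calls tibble (maps barcodes to
#'   clonotypes).
#' @param meta Cell metadata.
#' @return List with `summary` (per timepoint x group x score: n, mean, sd)
#'   and `tests` (per timepoint x score: Mann-Whitney p, BH-adjusted p).
#'   Groups with fewer than 2 cells are summarised but not tested.
#' @export
compare_expanded_scores <- function(scores, expansion, calls, meta) {
  if (inherits(calls, "clonotype_calls")) calls <- calls$calls
  score_cols <- setdiff(names(scores), "barcode")
  status <- dplyr::select(expansion, "patient_id", "clonotype_id", "expanded")
  df <- calls[c("barcode", "clonotype_id")] |>
    dplyr::inner_join(meta, by = "barcode") |>
    dplyr::inner_join(status, by = c("patient_id", "clonotype_id")) |>
    dplyr::inner_join(scores, by = "barcode") |>
    dplyr::filter(!is.na(.data$timepoint))
  long <- tidyr::pivot_longer(df, dplyr::all_of(score_cols),
                              names_to = "score", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$timepoint, .data$expanded, .data$score) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  tests <- long |>
    dplyr::group_by(.data$timepoint, .data$score) |>
    dplyr::summarise(p_value = {
      a <- .data$value[.data$expanded]; b <- .data$value[!.data$expanded]
      if (length(a) < 2 || length(b) < 2) NA_real_
      else suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    }, .groups = "drop") |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::mutate(p_adj = {
      pa <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p_value)
      if (any(ok)) pa[ok] <- benjamini_hochberg(.data$p_value[ok])
      pa
    }) |>
    dplyr::ungroup()
  skipped <- summary |> dplyr::filter(.data$n < 2)
  if (nrow(skipped)) {
    warn(paste0("groups with n < 2 were not tested: ",
                paste(unique(paste(skipped$timepoint, skipped$expanded, sep = "/")),
                      collapse = ", ")))
  }
  list(summary = summary, tests = tests)
}
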