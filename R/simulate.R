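#' Simulation configuration for a paired scRNA + scTCR cohort
#'
#' Defines the study design emulated by [simulate_cohort()]: SLE patients
#' sampled before flare (BF) and at flare (FL), healthy controls sampled
#' once, group-specific cell-type composition, per-patient power-law TCR
#' repertoires with planted flare expansions, and negative-binomial
#' expression with planted cell-type-specific gene-module activation in the
#' SLE group.
#'
#' Clone sizes are drawn i.i.d. from a discrete power law
#' `P(s) proportional to s^-clonotype_alpha` on `1..max_clone_size`; planted
#' expanded clones have flare count = `expansion_fold` times their baseline
#' count exactly (de novo clones have baseline 0 and `de_novo_cells` flare
#' cells), all other clones keep their baseline count at flare, so the
#' planted set coincides with the clones satisfying the expansion rule on
#' exact counts.
#'
#' @param n_patients Number of SLE patients (each with a BF and an FL
#'   sample). Default 4.
#' @param n_controls Number of healthy controls (one sample each).
#'   Default 4.
#' @param n_cells_per_sample Cells per sample (default 2000).
#' @param cell_type_fractions Named list with one named probability vector
#'   per group (`SLE`, `CTL`); each sums to 1.
#' @param n_genes_total Total gene universe size including the panel,
#'   mitochondrial and platelet genes (default 1516).
#' @param module_spec Tibble with columns `module`, `genes` (list), `elevated_types`
#'   (list), `delta` (log-scale effect). Default: 4 modules of 25 interferon-
#'   stimulated-gene-like genes (`ISG001..ISG100`) elevated in all types /
#'   lymphocytes / classical monocytes / plasmacytoid dendritic cells, each
#'   with `delta = log(2)`.
#' @param clonotype_alpha Power-law exponent of the clone-size distribution
#'   (default 3.5).
#' @param max_clone_size Truncation of the size law (default 15).
#' @param n_expanded_clones Planted expanded clones per patient (default 5).
#' @param expansion_fold Flare/baseline count ratio of planted clones
#'   (default 4; must be >= 1).
#' @param frac_de_novo Fraction of planted clones absent at baseline
#'   (default 0.4).
#' @param de_novo_cells Flare cells of each de novo clone (default 6).
#' @param nb_dispersion Negative-binomial dispersion shared by all genes
#'   (default 0.5; variance = mu + dispersion * mu^2).
#' @param library_size_mean Mean per-cell UMI total (default 2500).
#' @param library_size_sdlog Lognormal sdlog of library sizes (default
#'   0.25).
#' @param mito_share Expected mitochondrial fraction of each library
#'   (default 0.025).
#' @param frac_chain_dropout Fraction of T cells missing one chain
#'   (default 0).
#' @param frac_secondary_chain Fraction of T cells with an extra low-UMI
#'   alpha chain (default 0).
#' @param frac_low_confidence Fraction of T cells with an added decoy
#'   high-UMI contig flagged `high_confidence = FALSE` (default 0).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 4L, n_controls = 4L,
                       n_cells_per_sample = 2000L,
                       cell_type_fractions = default_cell_type_fractions(),
                       n_genes_total = 1516L,
                       module_spec = default_module_spec(),
                       clonotype_alpha = 3.5, max_clone_size = 15L,
                       n_expanded_clones = 5L, expansion_fold = 4,
                       frac_de_novo = 0.4, de_novo_cells = 6L,
                       nb_dispersion = 0.5,
                       library_size_mean = 2500L, library_size_sdlog = 0.25,
                       mito_share = 0.025,
                       frac_chain_dropout = 0, frac_secondary_chain = 0,
                       frac_low_confidence = 0, seed = 1L) {
  for (g in names(cell_type_fractions)) {
    s <- sum(cell_type_fractions[[g]])
    if (abs(s - 1) > 1e-8) abort(paste0("cell_type_fractions$", g, " sums to ", s, ", not 1"),
                                 class = "clonodyn_config_error")
  }
  if (expansion_fold < 1) abort("expansion_fold must be >= 1", class = "clonodyn_config_error")
  panel_genes <- unlist(module_spec$genes)
  if (anyDuplicated(panel_genes)) {
    abort("module gene lists must be disjoint", class = "clonodyn_config_error")
  }
  n_fixed <- length(mito_gene_names()) + length(platelet_gene_names())
  if (length(panel_genes) + n_fixed > n_genes_total) {
    abort(paste0("module genes (", length(panel_genes), ") exceed the configured ",
                 "total gene count (", n_genes_total, ") after reserving ",
                 n_fixed, " housekeeping genes"),
          class = "clonodyn_config_error")
  }
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_cells_per_sample = as.integer(n_cells_per_sample),
    cell_type_fractions = cell_type_fractions,
    n_genes_total = as.integer(n_genes_total), module_spec = module_spec,
    clonotype_alpha = clonotype_alpha, max_clone_size = as.integer(max_clone_size),
    n_expanded_clones = as.integer(n_expanded_clones),
    expansion_fold = expansion_fold, frac_de_novo = frac_de_novo,
    de_novo_cells = as.integer(de_novo_cells),
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    library_size_sdlog = library_size_sdlog, mito_share = mito_share,
    frac_chain_dropout = frac_chain_dropout,
    frac_secondary_chain = frac_secondary_chain,
    frac_low_confidence = frac_low_confidence,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default group-wise cell-type fractions
#'
#' SLE shows enrichment of effector-memory CD8 T cells and atypical B cells
#' at the expense of naive T and memory B compartments.
#' @return Named list of probability vectors for `SLE` and `CTL`.
#' @export
default_cell_type_fractions <- function() {
  list(
    SLE = c("CD4 naive" = 0.20, "CD8 naive" = 0.15, "CD8 Tem" = 0.20,
            "B mem" = 0.08, "ABC" = 0.07, "cM" = 0.22, "pDC" = 0.08),
    CTL = c("CD4 naive" = 0.25, "CD8 naive" = 0.20, "CD8 Tem" = 0.10,
            "B mem" = 0.12, "ABC" = 0.02, "cM" = 0.25, "pDC" = 0.06))
}

#' Default interferon-module specification
#'
#' Four modules of 25 genes (`ISG001..ISG100`): broadly elevated (C1-like),
#' lymphocyte-restricted (C2-like), classical-monocyte-restricted (C3-like)
#' and plasmacytoid-dendritic-cell-restricted (C4-like), each with effect
#' `delta = log(2)` in SLE cells of the elevated types.
#' @return Tibble with columns `module`, `genes`, `elevated_types`, `delta`.
#' @export
default_module_spec <- function() {
  genes <- sprintf("ISG%03d", 1:100)
  lymph <- c("CD4 naive", "CD8 naive", "CD8 Tem", "B mem", "ABC")
  all_types <- c(lymph, "cM", "pDC")
  tibble::tibble(
    module = c("M1", "M2", "M3", "M4"),
    genes = list(genes[1:25], genes[26:50], genes[51:75], genes[76:100]),
    elevated_types = list(all_types, lymph, "cM", "pDC"),
    delta = log(2))
}

mito_gene_names <- function() {
  c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6", "MT-CO3",
    "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB")
}

platelet_gene_names <- function() c("PPBP", "PF4", "NRGN")

#' Draw clonotype sizes from a truncated discrete power law
#'
#' Sizes are i.i.d. from `P(s) proportional to s^-alpha`, `s = 1..s_max`;
#' drawing stops once `n_cells` are allocated (the last clone is trimmed to
#' fit exactly).
#'
#' @param n_cells Total cells to allocate.
#' @param alpha Power-law exponent.
#' @param s_max Maximum clone size.
#' @return Integer vector of clone sizes summing to `n_cells`.
#' @export
rclone_sizes <- function(n_cells, alpha, s_max = 15L) {
  if (n_cells <= 0) return(integer(0))
  support <- seq_len(s_max)
  prob <- support^(-alpha)
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    k <- max(16L, ceiling((n_cells - sum(sizes)) / sum(support * prob / sum(prob))))
    sizes <- c(sizes, sample(support, k, replace = TRUE, prob = prob))
  }
  cum <- cumsum(sizes)
  last <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - n_cells)
  sizes[sizes > 0]
}

# --- deterministic chain construction ------------------------------------
.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.codon20 <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
              H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
              P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
              W = "TGG", Y = "TAT")

enc_aa <- function(v, width) {
  out <- character(length(v))
  for (i in seq_len(width)) {
    out <- paste0(.aa20[(v %% 20L) + 1L], out)
    v <- v %/% 20L
  }
  out
}

aa_to_nt <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) paste(.codon20[ch], collapse = ""),
         character(1))
}

# One TRA + one TRB per clonotype; the CDR3 encodes (patient, lineage, idx)
# in a 20-letter alphabet so clonotype keys never collide across patients.
clonotype_chains <- function(pat_num, lineage, idx) {
  lin <- ifelse(lineage == "CD8", 1L, 0L)
  uid <- (pat_num * 2L + lin) * 100000L + idx
  tra_cdr3 <- paste0("CA", enc_aa(uid, 7L), "F")
  trb_cdr3 <- paste0("CASS", enc_aa(uid, 7L), "F")
  tibble::tibble(
    idx = idx,
    tra_v = paste0("TRAV", (uid * 7L) %% 41L + 1L),
    tra_j = paste0("TRAJ", (uid * 11L) %% 53L + 1L),
    tra_cdr3_aa = tra_cdr3, tra_cdr3_nt = aa_to_nt(tra_cdr3),
    trb_v = paste0("TRBV", (uid * 13L) %% 29L + 1L),
    trb_d = paste0("TRBD", uid %% 2L + 1L),
    trb_j = paste0("TRBJ", (uid * 17L) %% 13L + 1L),
    trb_cdr3_aa = trb_cdr3, trb_cdr3_nt = aa_to_nt(trb_cdr3))
}

chains_key <- function(ch, mode = "genes_plus_cdr3aa") {
  calls <- tibble::tibble(tra_v = ch$tra_v, tra_j = ch$tra_j,
                          tra_cdr3_aa = ch$tra_cdr3_aa,
                          trb_v = ch$trb_v, trb_d = ch$trb_d, trb_j = ch$trb_j,
                          trb_cdr3_aa = ch$trb_cdr3_aa)
  clonotype_key(calls, mode)
}

# --- repertoire construction ---------------------------------------------
# Builds baseline/flare CD8 clone tables for one SLE patient (or baseline-
# only for CTL / CD4). Planted clones take fold * baseline exactly; de novo
# clones appear only at flare; everything else is stable.
build_cd8_repertoire <- function(cfg, n_cd8_bf, plant = TRUE, frac_naive = 0.5) {
  sizes <- rclone_sizes(n_cd8_bf, cfg$clonotype_alpha, cfg$max_clone_size)
  n_clones <- length(sizes)
  tab <- tibble::tibble(idx = seq_len(n_clones), n_bf = as.integer(sizes),
                        is_planted = FALSE, de_novo = FALSE)
  tab$phenotype <- ifelse(stats::runif(n_clones) < frac_naive, "CD8 naive", "CD8 Tem")
  tab$n_fl <- tab$n_bf
  if (plant && cfg$n_expanded_clones > 0) {
    n_dn <- round(cfg$frac_de_novo * cfg$n_expanded_clones)
    n_fold <- cfg$n_expanded_clones - n_dn
    cand <- which(tab$n_bf >= 3 & tab$n_bf <= 8)
    if (length(cand) < n_fold) {
      extra <- n_fold - length(cand)
      add <- tibble::tibble(idx = n_clones + seq_len(extra), n_bf = 4L,
                            is_planted = FALSE, de_novo = FALSE,
                            phenotype = "CD8 naive", n_fl = 4L)
      tab <- dplyr::bind_rows(tab, add)
      n_clones <- nrow(tab)
      cand <- c(cand, add$idx)
    }
    chosen <- sort(sample(cand, n_fold))
    tab$is_planted[chosen] <- TRUE
    tab$n_fl[chosen] <- as.integer(round(cfg$expansion_fold * tab$n_bf[chosen]))
    tab$phenotype[chosen] <- "CD8 naive"  # baseline phenotype of planted clones
    if (n_dn > 0) {
      dn <- tibble::tibble(idx = n_clones + seq_len(n_dn), n_bf = 0L,
                           is_planted = TRUE, de_novo = TRUE,
                           phenotype = "CD8 naive",
                           n_fl = cfg$de_novo_cells)
      tab <- dplyr::bind_rows(tab, dn)
    }
  }
  tab
}

#' Simulate a paired expression + TCR + metadata cohort
#'
#' Generates, from a [sim_config()], a full synthetic cohort: a sparse UMI
#' count matrix, per-cell metadata, TCR contigs (one alpha + one beta chain
#' per T cell, with optional chain-dropout / secondary-chain /
#' low-confidence noise), and the planted ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `counts` (dgCMatrix), `meta`
#'   (tibble), `contigs` (tibble), `truth` (list with `clonotype_table`,
#'   `module_assignment`, `composition`), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  fr <- cfg$cell_type_fractions
  types <- names(fr$SLE)
  cd8_types <- intersect(c("CD8 naive", "CD8 Tem"), types)
  cd4_types <- intersect(c("CD4 naive", "CD4 Tem", "CD4 Tcm"), types)

  samples <- dplyr::bind_rows(
    tidyr::expand_grid(patient_id = sprintf("P%02d", seq_len(cfg$n_patients)),
                       timepoint = c("BF", "FL")) |>
      dplyr::mutate(group = "SLE"),
    tibble::tibble(patient_id = sprintf("C%02d", seq_len(cfg$n_controls)),
                   timepoint = NA_character_, group = "CTL")) |>
    dplyr::mutate(sample_id = ifelse(is.na(.data$timepoint), .data$patient_id,
                                     paste0(.data$patient_id, "_", .data$timepoint)))

  # largest-remainder apportionment of n cells over types
  apportion <- function(n, p) {
    raw <- n * p
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    setNames(as.integer(base), names(p))
  }

  meta_rows <- list(); contig_rows <- list(); truth_rows <- list()
  cell_repertoires <- list()  # per patient: clone tables for expression reuse

  patients <- unique(samples$patient_id)
  for (pi in seq_along(patients)) {
    pat <- patients[pi]
    prows <- samples[samples$patient_id == pat, ]
    grp <- prows$group[1]
    p <- fr[[grp]]
    counts_by_type <- apportion(cfg$n_cells_per_sample, p)
    n_cd8 <- sum(counts_by_type[cd8_types])
    n_cd4 <- sum(counts_by_type[cd4_types])
    frac_naive <- if (n_cd8 > 0)
      counts_by_type["CD8 naive"] / n_cd8 else 0.5

    cd8 <- build_cd8_repertoire(cfg, n_cd8, plant = grp == "SLE",
                                frac_naive = frac_naive)
    cd4_sizes <- rclone_sizes(n_cd4, cfg$clonotype_alpha, cfg$max_clone_size)
    cd4 <- tibble::tibble(idx = seq_along(cd4_sizes),
                          n_bf = as.integer(cd4_sizes))
    cd4$n_fl <- cd4$n_bf

    cd8_chains <- clonotype_chains(pi, "CD8", cd8$idx)
    cd4_chains <- if (nrow(cd4)) clonotype_chains(pi, "CD4", cd4$idx) else NULL
    cd8$clonotype_id <- chains_key(cd8_chains)
    if (nrow(cd4)) cd4$clonotype_id <- chains_key(cd4_chains)

    for (si in seq_len(nrow(prows))) {
      smp <- prows$sample_id[si]; tp <- prows$timepoint[si]
      at_fl <- !is.na(tp) && tp == "FL"
      ncol_ <- if (at_fl) "n_fl" else "n_bf"

      cd8_here <- cd8[cd8[[ncol_]] > 0, ]
      cd8_cells <- tibble::tibble(
        clone_row = rep(seq_len(nrow(cd8_here)), cd8_here[[ncol_]]))
      cd8_cells$cell_type <- ifelse(
        cd8_here$is_planted[cd8_cells$clone_row] & at_fl, "CD8 Tem",
        cd8_here$phenotype[cd8_cells$clone_row])
      cd8_cells$clonotype_idx <- cd8_here$idx[cd8_cells$clone_row]
      cd8_cells$lineage <- "CD8"

      cd4_here <- cd4[cd4[[ncol_]] > 0, ]
      cd4_cells <- tibble::tibble(
        clone_row = rep(seq_len(nrow(cd4_here)), cd4_here[[ncol_]]))
      cd4_cells$cell_type <- cd4_types[1]
      cd4_cells$clonotype_idx <- cd4_here$idx[cd4_cells$clone_row]
      cd4_cells$lineage <- "CD4"

      other <- counts_by_type[setdiff(types, c(cd8_types, cd4_types))]
      other_cells <- tibble::tibble(
        cell_type = rep(names(other), other),
        clonotype_idx = NA_integer_, lineage = NA_character_, clone_row = NA_integer_)

      cells <- dplyr::bind_rows(cd8_cells, cd4_cells, other_cells)
      cells$barcode <- sprintf("%s_c%05d", smp, seq_len(nrow(cells)))
      cells$sample_id <- smp; cells$patient_id <- pat
      cells$timepoint <- tp; cells$group <- grp
      meta_rows[[smp]] <- cells[c("barcode", "sample_id", "patient_id",
                                  "timepoint", "group", "cell_type",
                                  "clonotype_idx", "lineage")]
    }

    # ground truth over the CD8 repertoire (SLE pairs only)
    if (grp == "SLE") {
      N_bf <- sum(cd8$n_bf); N_fl <- sum(cd8$n_fl)
      p_bf <- cd8$n_bf / N_bf; p_fl <- cd8$n_fl / N_fl
      de_novo_exp <- cd8$n_bf == 0 & cd8$n_fl >= 3
      fold_exp <- cd8$n_bf > 0 & cd8$n_fl >= 2 * cd8$n_bf & cd8$n_fl >= 3 &
        p_fl > p_bf
      truth_rows[[pat]] <- tibble::tibble(
        patient_id = pat, clonotype_id = cd8$clonotype_id,
        n_bf = cd8$n_bf, n_fl = cd8$n_fl,
        is_planted = cd8$is_planted,
        is_expanded = de_novo_exp | fold_exp,
        phenotype_bf = ifelse(cd8$de_novo, NA_character_, cd8$phenotype),
        phenotype_fl = ifelse(cd8$is_planted, "CD8 Tem", cd8$phenotype))
    }
    cell_repertoires[[pat]] <- list(cd8_chains = cd8_chains, cd4_chains = cd4_chains)
  }

  meta_full <- dplyr::bind_rows(meta_rows)

  # ---- contigs ----
  tcells <- meta_full[!is.na(meta_full$clonotype_idx), ]
  pat_index <- setNames(seq_along(patients), patients)
  ch <- clonotype_chains(pat_index[tcells$patient_id], tcells$lineage,
                         tcells$clonotype_idx)
  n_t <- nrow(tcells)
  tra_umis <- 2L + rpois(n_t, 2)
  trb_umis <- 2L + rpois(n_t, 3)
  contig_tra <- tibble::tibble(
    barcode = tcells$barcode, chain = "TRA", v_gene = ch$tra_v, d_gene = "",
    j_gene = ch$tra_j, cdr3_aa = ch$tra_cdr3_aa, cdr3_nt = ch$tra_cdr3_nt,
    umis = tra_umis, high_confidence = TRUE, productive = TRUE)
  contig_trb <- tibble::tibble(
    barcode = tcells$barcode, chain = "TRB", v_gene = ch$trb_v,
    d_gene = ch$trb_d, j_gene = ch$trb_j, cdr3_aa = ch$trb_cdr3_aa,
    cdr3_nt = ch$trb_cdr3_nt, umis = trb_umis,
    high_confidence = TRUE, productive = TRUE)

  # noise: chain dropout
  drop_cell <- stats::runif(n_t) < cfg$frac_chain_dropout
  drop_tra <- drop_cell & stats::runif(n_t) < 0.5
  drop_trb <- drop_cell & !drop_tra
  contig_tra <- contig_tra[!drop_tra, ]
  contig_trb <- contig_trb[!drop_trb, ]

  # noise: low-UMI secondary alpha chain from a shuffled donor cell
  sec_cell <- which(stats::runif(n_t) < cfg$frac_secondary_chain)
  contig_sec <- NULL
  if (length(sec_cell)) {
    donor <- sample(n_t, length(sec_cell), replace = TRUE)
    contig_sec <- tibble::tibble(
      barcode = tcells$barcode[sec_cell], chain = "TRA",
      v_gene = ch$tra_v[donor], d_gene = "", j_gene = ch$tra_j[donor],
      cdr3_aa = ch$tra_cdr3_aa[donor], cdr3_nt = ch$tra_cdr3_nt[donor],
      umis = 1L, high_confidence = TRUE, productive = TRUE)
  }

  # noise: decoy high-UMI beta contig flagged low-confidence; must be removed
  # by the confidence rule before the max-UMI rule sees it
  lc_cell <- which(stats::runif(n_t) < cfg$frac_low_confidence)
  contig_lc <- NULL
  if (length(lc_cell)) {
    donor <- sample(n_t, length(lc_cell), replace = TRUE)
    contig_lc <- tibble::tibble(
      barcode = tcells$barcode[lc_cell], chain = "TRB",
      v_gene = ch$trb_v[donor], d_gene = ch$trb_d[donor],
      j_gene = ch$trb_j[donor], cdr3_aa = ch$trb_cdr3_aa[donor],
      cdr3_nt = ch$trb_cdr3_nt[donor], umis = 50L,
      high_confidence = FALSE, productive = TRUE)
  }
  contigs <- dplyr::bind_rows(contig_tra, contig_trb, contig_sec, contig_lc) |>
    dplyr::arrange(.data$barcode, .data$chain, dplyr::desc(.data$umis))

  # ---- expression ----
  gene_objs <- build_gene_universe(cfg)
  counts <- simulate_expression(cfg, gene_objs, meta_full)

  meta <- tibble::as_tibble(meta_full[c("barcode", "sample_id", "patient_id",
                                        "timepoint", "group", "cell_type")])
  truth <- list(
    clonotype_table = dplyr::bind_rows(truth_rows),
    module_assignment = tidyr::unnest(
      cfg$module_spec[c("module", "genes")], "genes") |>
      dplyr::rename(gene = "genes") |>
      dplyr::select("gene", "module"),
    composition = purrr::imap_dfr(fr, function(p, g)
      tibble::tibble(group = g, cell_type = names(p), fraction = unname(p))))

  structure(list(counts = counts, meta = meta, contigs = contigs,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

build_gene_universe <- function(cfg) {
  panel <- unlist(cfg$module_spec$genes)
  mt <- mito_gene_names(); plt <- platelet_gene_names()
  n_bg <- cfg$n_genes_total - length(panel) - length(mt) - length(plt)
  bg <- sprintf("BG%04d", seq_len(n_bg))
  genes <- c(panel, bg, mt, plt)
  # relative abundances: skewed gamma, mitochondria pinned to mito_share,
  # platelet markers absent (no platelets are simulated)
  w <- rgamma(length(panel) + n_bg, shape = 0.45)
  props <- numeric(length(genes))
  props[seq_len(length(panel) + n_bg)] <- w / sum(w) * (1 - cfg$mito_share)
  wm <- rgamma(length(mt), shape = 2)
  props[length(panel) + n_bg + seq_along(mt)] <- wm / sum(wm) * cfg$mito_share
  list(genes = genes, props = props)
}

simulate_expression <- function(cfg, gene_objs, meta_full) {
  genes <- gene_objs$genes; props <- gene_objs$props
  G <- length(genes); N <- nrow(meta_full)
  lib <- rlnorm(N, log(cfg$library_size_mean) - cfg$library_size_sdlog^2 / 2,
                cfg$library_size_sdlog)
  # per-gene multiplier by (cell type, group): exp(delta) on module genes in
  # elevated types of SLE cells
  type_grp <- paste(meta_full$cell_type, meta_full$group, sep = "|")
  combos <- unique(type_grp)
  mult <- matrix(1, nrow = G, ncol = length(combos),
                 dimnames = list(genes, combos))
  for (mi in seq_len(nrow(cfg$module_spec))) {
    gset <- cfg$module_spec$genes[[mi]]
    elev <- cfg$module_spec$elevated_types[[mi]]
    dlt <- cfg$module_spec$delta[[mi]]
    hit <- combos %in% paste(elev, "SLE", sep = "|")
    if (any(hit)) mult[gset, hit] <- exp(dlt)
  }
  size <- 1 / cfg$nb_dispersion
  blocks <- list()
  chunk <- 2000L
  starts <- seq(1L, N, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, N)
    mu <- (props * mult[, match(type_grp[idx], combos), drop = FALSE]) *
      rep(lib[idx], each = G)
    cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                  nrow = G)
    blocks[[length(blocks) + 1L]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                                 "CsparseMatrix")
  }
  counts <- do.call(cbind, blocks)
  dimnames(counts) <- list(genes, meta_full$barcode)
  counts
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$counts), "cells x", nrow(x$counts), "genes;",
      nrow(x$contigs), "contigs;", length(unique(x$meta$sample_id)), "samples\n")
  invisible(x)
}

#' Write a simulated cohort as an on-disk fixture
#'
#' Emits exactly six files readable by the package's readers: `matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv`, `contigs.csv`, `cell_meta.csv`,
#' `ground_truth.json`.
#'
#' @param cohort A `sim_cohort`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the six file paths.
#' @export
emit_fixture <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(paste0("cannot create directory: ", outdir))
  p_mtx <- write_mtx_counts(cohort$counts, outdir)
  p_contig <- file.path(outdir, "contigs.csv")
  write_contigs(cohort$contigs, p_contig)
  p_meta <- file.path(outdir, "cell_meta.csv")
  readr::write_csv(cohort$meta, p_meta, progress = FALSE, na = "")
  p_truth <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(cohort$truth, p_truth, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(c(p_mtx, p_contig, p_meta, p_truth))
}

#' Read a cohort fixture back from disk
#' @param dir Directory written by [emit_fixture()].
#' @return List with `counts`, `meta`, `contigs`, `truth`.
#' @export
read_cohort_fixture <- function(dir) {
  counts <- read_mtx_counts(file.path(dir, "matrix.mtx"),
                            file.path(dir, "genes.tsv"),
                            file.path(dir, "barcodes.tsv"))
  meta <- read_cell_meta(file.path(dir, "cell_meta.csv"))
  contigs <- read_contigs(file.path(dir, "contigs.csv"), dialect = "tenx_csv")
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  truth$clonotype_table <- tibble::as_tibble(truth$clonotype_table)
  truth$module_assignment <- tibble::as_tibble(truth$module_assignment)
  truth$composition <- tibble::as_tibble(truth$composition)
  list(counts = counts, meta = meta, contigs = contigs, truth = truth)
}
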