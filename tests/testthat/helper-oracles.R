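# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# Chain-filtering + keying oracle: applies the four rules one barcode at a
# time and returns barcode -> clonotype_id for every cell that survives.
oracle_clonotype_calls <- function(contigs, mode = "genes_plus_cdr3aa",
                                   require_productive = TRUE) {
  out <- list()
  for (bc in unique(contigs$barcode)) {
    rows <- contigs[contigs$barcode == bc, , drop = FALSE]
    rows <- rows[rows$high_confidence, , drop = FALSE]                 # rule 1
    if (require_productive) rows <- rows[rows$productive, , drop = FALSE]
    best <- list()
    for (ch in c("TRA", "TRB")) {                                      # rule 2
      cand <- rows[rows$chain == ch, , drop = FALSE]
      if (nrow(cand) == 0) next
      cand <- cand[cand$umis == max(cand$umis), , drop = FALSE]
      cand <- cand[order(cand$cdr3_nt, cand$v_gene), , drop = FALSE]
      best[[ch]] <- cand[1, ]
    }
    if (is.null(best$TRA) || is.null(best$TRB)) next                   # rule 3
    a <- best$TRA; b <- best$TRB                                       # rule 4
    if (mode == "genes_plus_cdr3aa") {
      key <- paste0(a$v_gene, ".", a$j_gene, ".", a$cdr3_aa, "_",
                    b$v_gene, ".", b$d_gene, ".", b$j_gene, ".", b$cdr3_aa)
    } else {
      key <- paste0(a$v_gene, ".", a$j_gene, "_",
                    b$v_gene, ".", b$d_gene, ".", b$j_gene)
    }
    out[[bc]] <- key
  }
  if (!length(out)) {
    return(tibble::tibble(barcode = character(0), clonotype_id = character(0)))
  }
  tibble::tibble(barcode = names(out), clonotype_id = unlist(unname(out))) |>
    dplyr::arrange(barcode)
}

# Expansion truth table evaluated clone by clone with explicit arithmetic.
oracle_expansion_status <- function(n_bf, n_fl, tau = 2, m = 3,
                                    proportional = TRUE) {
  N_bf <- sum(n_bf); N_fl <- sum(n_fl)
  status <- character(length(n_bf))
  for (i in seq_along(n_bf)) {
    p_bf <- if (N_bf > 0) n_bf[i] / N_bf else 0
    p_fl <- n_fl[i] / N_fl
    de_novo <- n_bf[i] == 0 && n_fl[i] > 0
    fold <- n_bf[i] > 0 && n_fl[i] >= tau * n_bf[i] &&
      (!proportional || p_fl > p_bf)
    status[i] <- if ((de_novo || fold) && n_fl[i] < m) "excluded_min_cells"
      else if (de_novo) "expanded_de_novo"
      else if (fold) "expanded_fold"
      else "not_expanded"
  }
  status
}

# Benjamini-Hochberg step-up computed from the definition:
# adj_(i) = min_{j >= i} p_(j) * m / j on the sorted values.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, sorted[j] * m / j)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Shannon entropy from the definition, term by term.
oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}
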