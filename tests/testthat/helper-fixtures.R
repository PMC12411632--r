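# In-code fixture builders shared across test files.

# A contig row with sensible defaults; override any field.
make_contig <- function(barcode, chain = "TRA", v_gene = "TRAV1",
                        d_gene = "", j_gene = "TRAJ1", cdr3_aa = "CAVF",
                        cdr3_nt = "TGTGCTGTTTTT", umis = 3L,
                        high_confidence = TRUE, productive = TRUE) {
  tibble::tibble(barcode = barcode, chain = chain, v_gene = v_gene,
                 d_gene = d_gene, j_gene = j_gene, cdr3_aa = cdr3_aa,
                 cdr3_nt = cdr3_nt, umis = as.integer(umis),
                 high_confidence = high_confidence, productive = productive)
}

# A random contig table exercising every filtering rule: multiple chains per
# barcode, UMI ties, low-confidence and non-productive rows, non-T loci.
random_contigs <- function(n_rows, seed) {
  withr::with_seed(seed, {
    bcs <- sprintf("BC%02d", sample(1:6, n_rows, replace = TRUE))
    tibble::tibble(
      barcode = bcs,
      chain = sample(c("TRA", "TRB", "IGH"), n_rows, replace = TRUE,
                     prob = c(0.42, 0.42, 0.16)),
      v_gene = sample(paste0("V", 1:3), n_rows, replace = TRUE),
      d_gene = sample(c("", "D1", "D2"), n_rows, replace = TRUE),
      j_gene = sample(paste0("J", 1:3), n_rows, replace = TRUE),
      cdr3_aa = sample(c("CAF", "CSF", "CTF", "CGF"), n_rows, replace = TRUE),
      cdr3_nt = sample(c("TGTGCA", "TGTTCA", "TGTACA", "TGTGGA"), n_rows,
                       replace = TRUE),
      umis = sample(0:4, n_rows, replace = TRUE),
      high_confidence = sample(c(TRUE, TRUE, TRUE, FALSE), n_rows, replace = TRUE),
      productive = sample(c(TRUE, TRUE, TRUE, FALSE), n_rows, replace = TRUE))
  })
}

# Dense toy count matrix with dimnames (existing dimnames are kept).
make_counts <- function(m, genes = NULL, barcodes = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("G%d", seq_len(nrow(m)))
  colnames(m) <- barcodes %||% colnames(m) %||% sprintf("cell%d", seq_len(ncol(m)))
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "dMatrix"),
              "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal metadata for a set of barcodes.
make_meta <- function(barcodes, sample_id = "S1", patient_id = "P1",
                      timepoint = NA_character_, group = "SLE",
                      cell_type = "CD8 Tem") {
  tibble::tibble(barcode = barcodes, sample_id = sample_id,
                 patient_id = patient_id, timepoint = timepoint,
                 group = group, cell_type = cell_type)
}

# Planted-partition fold-change profile: K_true well-separated gene clusters
# across n_types pseudo cell types at a controlled between/within ratio.
make_planted_profile <- function(k_true, n_genes = 100, n_types = 8,
                                 sep_ratio = 5, noise_sd = 0.15, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k_true * n_types), k_true)
    d <- as.matrix(stats::dist(centers)); diag(d) <- Inf
    centers <- centers * (sep_ratio * noise_sd * sqrt(n_types) / min(d))
    assign <- rep_len(seq_len(k_true), n_genes)
    m <- centers[assign, , drop = FALSE] +
      matrix(rnorm(n_genes * n_types, sd = noise_sd), n_genes)
    rownames(m) <- sprintf("G%03d", seq_len(n_genes))
    colnames(m) <- sprintf("T%d", seq_len(n_types))
    list(profile = m, assignment = assign)
  })
}

# Partition equality up to label permutation.
same_partition <- function(labels_a, labels_b) {
  tab <- table(labels_a, labels_b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Small cohort config used by pipeline/fixture tests (QC gene threshold
# adapted to the reduced gene universe).
small_cohort_config <- function(seed = 1, ...) {
  sim_config(n_patients = 2, n_controls = 2, n_cells_per_sample = 400,
             n_genes_total = 200, seed = seed, ...)
}

small_qc_params <- function() qc_params(min_genes_per_cell = 30L)
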