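test_that("configuration invariants are validated", {
  bad_fr <- default_cell_type_fractions()
  bad_fr$SLE[1] <- bad_fr$SLE[1] + 0.1
  expect_error(sim_config(cell_type_fractions = bad_fr), "sums to",
               class = "clonodyn_config_error")
  expect_error(sim_config(expansion_fold = 0.5), "expansion_fold",
               class = "clonodyn_config_error")
  spec <- default_module_spec()
  spec$genes[[2]][1] <- spec$genes[[1]][1]        # duplicated across modules
  expect_error(sim_config(module_spec = spec), "disjoint",
               class = "clonodyn_config_error")
  expect_error(sim_config(n_genes_total = 50), "exceed",
               class = "clonodyn_config_error")
})

test_that("identical configurations give bit-identical cohorts", {
  cfg <- small_cohort_config(seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$meta, b$meta)
  expect_identical(a$contigs, b$contigs)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)
})

test_that("zero planted clones yields a truth table with no expansion flags", {
  co <- simulate_cohort(small_cohort_config(seed = 9, n_expanded_clones = 0))
  expect_equal(sum(co$truth$clonotype_table$is_planted), 0L)
  expect_equal(sum(co$truth$clonotype_table$is_expanded), 0L)
})

test_that("planted clones satisfy the expansion rule exactly by construction", {
  co <- simulate_cohort(small_cohort_config(seed = 3))
  tr <- co$truth$clonotype_table
  planted <- tr[tr$is_planted, ]
  expect_equal(nrow(planted), 2L * 5L)            # 5 per SLE patient
  expect_true(all(planted$is_expanded))
  expect_true(all(planted$n_fl >= 3))
  fold <- planted[planted$n_bf > 0, ]
  expect_true(all(fold$n_fl == 4L * fold$n_bf))   # exact fold by construction
  expect_identical(tr$is_planted, tr$is_expanded) # stable clones never qualify
})

test_that("clone sizes converge to the configured power law as n grows", {
  alpha <- 3.5; s_max <- 15L
  cdf_theory <- cumsum(seq_len(s_max)^(-alpha)) / sum(seq_len(s_max)^(-alpha))
  ks_one <- function(n, seed) {
    sizes <- withr::with_seed(seed, rclone_sizes(n, alpha, s_max))
    sizes <- sizes[-length(sizes)]  # last clone is trimmed to fit n
    emp <- cumsum(tabulate(sizes, s_max)) / length(sizes)
    max(abs(emp - cdf_theory))
  }
  # mean KS over replicate draws decreases monotonically with n
  ks <- vapply(c(200, 2000, 20000), function(n) {
    mean(vapply(1:20, function(s) ks_one(n, 500 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_lt(ks[3], 0.01)
})

test_that("module genes are elevated by exp(delta) in the designated cells", {
  co <- simulate_cohort(sim_config(n_patients = 1, n_controls = 1,
                                   n_cells_per_sample = 2000,
                                   n_genes_total = 300, seed = 13))
  m3 <- co$truth$module_assignment$gene[co$truth$module_assignment$module == "M3"]
  sle_cm <- co$meta$barcode[co$meta$cell_type == "cM" & co$meta$group == "SLE"]
  ctl_cm <- co$meta$barcode[co$meta$cell_type == "cM" & co$meta$group == "CTL"]
  ratio <- mean(as.matrix(co$counts[m3, sle_cm])) /
    mean(as.matrix(co$counts[m3, ctl_cm]))
  expect_equal(ratio, exp(log(2)), tolerance = 0.1)
  # non-elevated cell types are untouched
  sle_b <- co$meta$barcode[co$meta$cell_type == "B mem" & co$meta$group == "SLE"]
  ctl_b <- co$meta$barcode[co$meta$cell_type == "B mem" & co$meta$group == "CTL"]
  expect_equal(mean(as.matrix(co$counts[m3, sle_b])) /
                 mean(as.matrix(co$counts[m3, ctl_b])), 1, tolerance = 0.1)
})

test_that("noise fractions inject the advertised artifacts", {
  cfg <- small_cohort_config(seed = 8, frac_chain_dropout = 0.2,
                             frac_secondary_chain = 0.1,
                             frac_low_confidence = 0.1)
  co <- simulate_cohort(cfg)
  res <- call_clonotypes(co$contigs)
  expect_gt(res$report$n_barcodes_unpaired, 0)
  expect_gt(res$report$n_removed_secondary_chain, 0)
  expect_gt(res$report$n_removed_low_confidence, 0)
  # decoy low-confidence contigs never leak into calls (they carry 50 UMIs)
  expect_true(all(res$calls$trb_umis < 50))
})

test_that("fixtures round-trip through the readers and re-emit byte-identically", {
  co <- simulate_cohort(small_cohort_config(seed = 4))
  dir <- withr::local_tempdir()
  emit_fixture(co, dir)
  expect_setequal(list.files(dir),
                  c("matrix.mtx", "genes.tsv", "barcodes.tsv", "contigs.csv",
                    "cell_meta.csv", "ground_truth.json"))
  back <- read_cohort_fixture(dir)
  expect_identical(as.matrix(back$counts), as.matrix(co$counts))
  expect_identical(back$meta, co$meta)
  expect_identical(back$contigs, co$contigs)
  expect_identical(back$truth$clonotype_table$clonotype_id,
                   co$truth$clonotype_table$clonotype_id)
  expect_identical(back$truth$clonotype_table$n_fl, co$truth$clonotype_table$n_fl)

  dir2 <- withr::local_tempdir()
  emit_fixture(simulate_cohort(small_cohort_config(seed = 4)), dir2)
  for (f in list.files(dir)) {
    expect_identical(readBin(file.path(dir, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7),
                     info = f)
  }
})
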