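test_that("log2 fold-change profile hits closed forms on constructed groups", {
  # equal-libsize construction: normalized expression == raw count scale
  n <- 10
  genes <- c("ISG1", "FILL")
  counts <- matrix(0L, 2, 2 * n, dimnames = list(genes, sprintf("c%02d", 1:(2 * n))))
  counts["ISG1", ] <- rep(c(2L, 4L), each = n)     # CTL 2, SLE 4: exact 2x
  counts["FILL", ] <- 100L - counts["ISG1", ]      # equal library sizes
  meta <- make_meta(colnames(counts), group = rep(c("CTL", "SLE"), each = n),
                    cell_type = "T")
  profile <- log2fc_profile(make_counts(counts, genes = genes), meta,
                            panel = "ISG1", eps = 1e-9, test = FALSE)
  expect_equal(profile$log2fc, 1, tolerance = 1e-6)

  # identical groups give zero fold change everywhere
  counts["ISG1", ] <- 3L
  counts["FILL", ] <- 97L
  profile0 <- log2fc_profile(make_counts(counts, genes = genes), meta,
                             panel = "ISG1", test = FALSE)
  expect_equal(profile0$log2fc, 0)

  # absent panel genes are dropped with a warning
  expect_warning(
    log2fc_profile(make_counts(counts, genes = genes), meta,
                   panel = c("ISG1", "NOT_THERE"), test = FALSE),
    "absent")
})

test_that("K-means panel clustering recovers planted structure and is order/seed stable", {
  pp <- make_planted_profile(3, n_genes = 60, seed = 5)
  part <- cluster_panel(pp$profile, k_range = 2:6, seed = 11)
  expect_equal(part$k, 3L)
  expect_true(same_partition(part$assignment$module, pp$assignment))
  # argmax of the silhouette curve equals the selected K
  sil <- part$silhouette_by_k
  expect_equal(sil$k[which.max(sil$mean_silhouette)], part$k)

  # row-order invariance (up to row naming) and seed stability at high separation
  perm <- withr::with_seed(1, sample(nrow(pp$profile)))
  part_perm <- cluster_panel(pp$profile[perm, ], k_range = 2:6, seed = 99)
  merged <- merge(part$assignment, part_perm$assignment, by = "gene")
  expect_true(same_partition(merged$module.x, merged$module.y))

  # two identical-row groups: perfect 2-partition with silhouette near 1
  m <- rbind(matrix(0, 5, 4), matrix(3, 5, 4)) +
    withr::with_seed(2, matrix(rnorm(40, sd = 1e-3), 10, 4))
  rownames(m) <- sprintf("g%d", 1:10)
  part2 <- cluster_panel(m, k_range = 2, seed = 1)
  expect_equal(part2$k, 2L)
  expect_gt(part2$silhouette_by_k$mean_silhouette, 0.95)
  expect_true(same_partition(part2$assignment$module, rep(1:2, each = 5)))

  # determinism given seed
  expect_identical(cluster_panel(pp$profile, k_range = 2:6, seed = 7)$assignment,
                   cluster_panel(pp$profile, k_range = 2:6, seed = 7)$assignment)

  # degenerate input is refused
  flat <- matrix(1, 5, 3, dimnames = list(letters[1:5], NULL))
  expect_error(cluster_panel(flat, k_range = 2), "no cluster structure")
})

test_that("module scores are z-calibrated with a zero-variance guard", {
  co <- simulate_cohort(small_cohort_config(seed = 21))
  sets <- split(co$truth$module_assignment$gene, co$truth$module_assignment$module)
  sc <- module_scores(co$counts, sets, seed = 2)
  for (m in names(sets)) {
    expect_lt(abs(mean(sc[[m]])), 1e-6)
    expect_lt(abs(sd(sc[[m]]) - 1), 1e-6)
  }
  expect_equal(attr(sc, "mode"), "bin_matched_control")

  # constant matrix: sd-0 guard fires, scores defined as 0
  const <- make_counts(matrix(5L, 10, 8))
  sc0 <- module_scores(const, list(mod = c("G1", "G2")), control = FALSE)
  expect_true(all(sc0$mod == 0))

  # single-gene module without control = z-scored expression of that gene
  counts <- make_counts(matrix(c(0:7, rep(10L, 8)), nrow = 2, byrow = TRUE),
                        genes = c("A", "B"))
  sc1 <- module_scores(counts, list(solo = "A"), control = FALSE)
  logn <- log1p(as.matrix(counts["A", , drop = FALSE]) * 1e4 /
                  rep(Matrix::colSums(counts), each = 1))
  expect_equal(sc1$solo, as.numeric(scale(as.numeric(logn))))

  # modules with no present genes are dropped with a warning
  expect_warning(module_scores(counts, list(ok = "A", gone = "ZZZ"),
                               control = FALSE), "gone")
})

test_that("planted module elevation separates scores by cell type and group", {
  co <- simulate_cohort(sim_config(n_patients = 1, n_controls = 1,
                                   n_cells_per_sample = 1200,
                                   n_genes_total = 400, seed = 31))
  sets <- split(co$truth$module_assignment$gene, co$truth$module_assignment$module)
  sc <- module_scores(co$counts, sets["M3"], seed = 5)
  j <- dplyr::inner_join(sc, co$meta, by = "barcode")
  elevated <- j$cell_type == "cM" & j$group == "SLE"
  expect_gt(mean(j$M3[elevated]) - mean(j$M3[!elevated]), 0.5)

  cmp <- compare_scores_by_group(sc, co$meta, grouping = "group",
                                 cells_subset = j$barcode[j$cell_type == "cM"])
  expect_lt(cmp$tests$p_adj[cmp$tests$module == "M3"], 1e-6)
  expect_equal(cmp$tests$test[1], "mann_whitney")
})

test_that("group score comparison handles identical groups and >2 groups", {
  withr::with_seed(8, {
    scores <- tibble::tibble(barcode = sprintf("b%03d", 1:90),
                             m = rep(1:30, 3))
  })
  meta3 <- make_meta(scores$barcode,
                     cell_type = rep(c("A", "B", "C"), each = 30))
  cmp3 <- compare_scores_by_group(scores, meta3, grouping = "cell_type")
  expect_equal(cmp3$tests$test, "kruskal_wallis")
  expect_gt(cmp3$tests$p_value, 0.9)

  meta1 <- make_meta(scores$barcode, cell_type = "A")
  expect_error(compare_scores_by_group(scores, meta1, grouping = "cell_type"),
               "two groups")
})
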