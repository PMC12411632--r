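# all permutations of 1..n without extra packages
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

test_that("Benjamini-Hochberg matches hand computation and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.4), 0.4)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "0, 1")
  expect_error(benjamini_hochberg(c(0.1, NA)), "0, 1")

  # step-up oracle over all permutations of random p-value sets of size <= 6
  for (s in 1:10) {
    p <- withr::with_seed(s, round(stats::runif(sample(2:6, 1)), 3))
    perms <- combinat_perms(length(p))
    for (i in seq_len(nrow(perms))) {
      pp <- p[perms[i, ]]
      expect_equal(benjamini_hochberg(pp), oracle_bh(pp), tolerance = 1e-12)
    }
  }
})

test_that("differential expression finds planted genes and nothing under the null", {
  withr::with_seed(42, {
    n <- 500; g <- 60
    genes <- sprintf("G%02d", seq_len(g))
    mu <- rep(2, g)
    ctl <- matrix(rnbinom(g * n, mu = mu, size = 2), g)
    mu_sle <- mu; mu_sle[1] <- 4                       # planted 2x gene
    sle <- matrix(rnbinom(g * n, mu = mu_sle, size = 2), g)
  })
  counts <- make_counts(cbind(ctl, sle), genes = genes,
                        barcodes = sprintf("c%04d", 1:(2 * n)))
  meta <- make_meta(colnames(counts), group = rep(c("CTL", "SLE"), each = n))
  de <- de_test(counts, meta)
  expect_true(de$significant[de$gene == "G01"])
  expect_gt(de$fold_change[de$gene == "G01"], 1.5)
  expect_equal(sum(de$significant[de$gene != "G01"]), 0)

  # identical groups: nothing significant
  counts0 <- make_counts(cbind(ctl, ctl), genes = genes,
                         barcodes = sprintf("c%04d", 1:(2 * n)))
  de0 <- de_test(counts0, make_meta(colnames(counts0),
                                    group = rep(c("CTL", "SLE"), each = n)))
  expect_equal(sum(de0$significant), 0)
})

test_that("fold change exactly at the threshold is not significant", {
  # equal library sizes so normalized means are exact; group means engineered
  # to give (m2 + eps) / (m1 + eps) == 1.25 with eps = 0.01 at the 1e4 scale
  n <- 100
  gene_a <- c(rep(1L, 79), rep(0L, 21), rep(1L, 99), 0L)  # means 0.79 / 0.99
  counts <- matrix(0L, 2, 2 * n,
                   dimnames = list(c("A", "FILL"), sprintf("c%03d", 1:(2 * n))))
  counts["A", ] <- gene_a
  counts["FILL", ] <- 10000L - gene_a
  meta <- make_meta(colnames(counts), group = rep(c("CTL", "SLE"), each = n))
  de <- de_test(make_counts(counts, genes = rownames(counts)), meta)
  expect_equal(de$fold_change[de$gene == "A"], 1.25, tolerance = 1e-12)
  expect_false(de$significant[de$gene == "A"])
  # the gene is strongly differential by rank test, so only the strict
  # fold-change inequality blocks it
  expect_lt(de$p_adj[de$gene == "A"], 0.05)
})

test_that("null simulations stay clean at the printed thresholds", {
  hits <- 0
  for (s in 1:50) {
    withr::with_seed(6000 + s, {
      m <- matrix(rnbinom(100 * 120, mu = 2, size = 2), 100)
    })
    counts <- make_counts(m, genes = sprintf("G%03d", 1:100),
                          barcodes = sprintf("c%03d", 1:120))
    meta <- make_meta(colnames(counts), group = rep(c("CTL", "SLE"), each = 60))
    de <- de_test(counts, meta)
    hits <- hits + (sum(de$significant) > 0)
  }
  expect_lte(hits, 2)  # >= 95% of seeds with zero significant genes
})

test_that("composition comparison flags planted enrichment with correct direction", {
  # identical composition: nothing significant
  meta_null <- dplyr::bind_rows(lapply(1:8, function(i)
    make_meta(sprintf("s%d_%03d", i, 1:60), sample_id = paste0("S", i),
              patient_id = paste0("S", i),
              group = ifelse(i <= 4, "CTL", "SLE"),
              cell_type = rep(c("T", "B", "M"), each = 20))))
  res0 <- composition_compare(meta_null)
  expect_true(all(res0$tests$p_value > 0.9))
  sums <- tapply(res0$fractions$fraction, res0$fractions$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # planted 2x enrichment of ABC in SLE, 10 samples per group
  withr::with_seed(77, {
    meta_alt <- dplyr::bind_rows(lapply(1:20, function(i) {
      sle <- i > 10
      n_abc <- rpois(1, if (sle) 20 else 10)
      n_rest <- 100 - n_abc
      make_meta(sprintf("s%d_%03d", i, 1:100), sample_id = paste0("S", i),
                patient_id = paste0("S", i),
                group = ifelse(sle, "SLE", "CTL"),
                cell_type = c(rep("ABC", n_abc), rep("T", n_rest)))
    }))
  })
  res <- composition_compare(meta_alt)
  abc <- res$tests[res$tests$type == "ABC", ]
  expect_lt(abc$p_adj, 0.05)
  expect_equal(abc$direction, "SLE")
})

test_that("subtype ratios compute per sample and exclude zero denominators", {
  meta <- dplyr::bind_rows(
    make_meta(sprintf("a%d", 1:6), sample_id = "S1", patient_id = "S1",
              cell_type = rep(c("ABC", "B mem"), each = 3)),
    make_meta(sprintf("b%d", 1:9), sample_id = "S2", patient_id = "S2",
              cell_type = c(rep("ABC", 6), rep("B mem", 3))),
    make_meta(sprintf("c%d", 1:4), sample_id = "S3", patient_id = "S3",
              cell_type = "ABC"))
  expect_warning(res <- subtype_ratio(meta, "ABC", "B mem"), "S3")
  expect_equal(res$ratios$ratio[res$ratios$sample_id == "S1"], 1)
  expect_equal(res$ratios$ratio[res$ratios$sample_id == "S2"], 2)
  expect_equal(res$excluded_samples, "S3")

  meta_none <- make_meta("x1", cell_type = "ABC")
  expect_error(suppressWarnings(subtype_ratio(meta_none, "ABC", "B mem")),
               "excluded")
})
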