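prof <- function(...) {
  x <- c(...)
  tibble::tibble(clonotype_id = names(x), n = as.integer(x))
}

test_that("expansion rule anchors: de novo, fold, minimum flare cells, proportionality", {
  # de novo at the 3-cell boundary
  res <- classify_expansion(prof(other = 10), prof(other = 10, new = 3))
  expect_equal(res$status[res$clonotype_id == "new"], "expanded_de_novo")

  # twofold with equal totals passes all conjuncts
  res <- classify_expansion(prof(c1 = 2, pad = 98), prof(c1 = 4, pad = 96))
  expect_equal(res$status[res$clonotype_id == "c1"], "expanded_fold")

  # 1 -> 2 cells fails the >=3 flare-cell gate
  res <- classify_expansion(prof(c1 = 1, pad = 9), prof(c1 = 2, pad = 8))
  expect_equal(res$status[res$clonotype_id == "c1"], "excluded_min_cells")
  expect_false(res$expanded[res$clonotype_id == "c1"])

  # count fold 2 but proportion decreased: blocked by the proportional rule
  res <- classify_expansion(prof(c1 = 2, pad = 98), prof(c1 = 4, pad = 396))
  expect_equal(res$status[res$clonotype_id == "c1"], "not_expanded")
  # and allowed when the proportional conjunct is off
  res2 <- classify_expansion(prof(c1 = 2, pad = 98), prof(c1 = 4, pad = 396),
                             params = expansion_params(require_proportional = FALSE))
  expect_equal(res2$status[res2$clonotype_id == "c1"], "expanded_fold")

  # min-cell gate never blocks a not_expanded label
  res <- classify_expansion(prof(c1 = 5, pad = 5), prof(c1 = 2, pad = 8))
  expect_equal(res$status[res$clonotype_id == "c1"], "not_expanded")

  expect_error(classify_expansion(prof(a = 1), prof()), "empty")
})

test_that("classification matches the truth-table oracle exhaustively and at random", {
  params <- expansion_params()
  # exhaustive per-clonotype counts 0..10 x 0..10 embedded in a fixed context
  grid <- expand.grid(n_bf = 0:10, n_fl = 0:10)
  grid <- grid[grid$n_bf + grid$n_fl > 0, ]
  ctx_bf <- c(ctxA = 6L, ctxB = 4L); ctx_fl <- c(ctxA = 6L, ctxB = 4L)
  for (i in seq_len(nrow(grid))) {
    bf <- c(focal = grid$n_bf[i], ctx_bf)
    fl <- c(focal = grid$n_fl[i], ctx_fl)
    bf <- bf[bf > 0]; fl <- fl[fl > 0]
    got <- classify_expansion(prof(bf), prof(fl), params)
    keys <- got$clonotype_id
    want <- oracle_expansion_status(
      sapply(keys, function(k) if (k %in% names(bf)) bf[[k]] else 0L),
      sapply(keys, function(k) if (k %in% names(fl)) fl[[k]] else 0L))
    expect_equal(got$status, unname(want), info = paste("grid row", i))
  }
  # random repertoires with up to 6 clonotypes, counts <= 10
  for (s in 1:200) {
    withr::with_seed(s, {
      k <- sample(1:6, 1)
      ids <- paste0("cl", 1:k)
      n_bf <- setNames(sample(0:10, k, replace = TRUE), ids)
      n_fl <- setNames(sample(0:10, k, replace = TRUE), ids)
      if (sum(n_fl) == 0) n_fl[1] <- 1L
    })
    got <- classify_expansion(prof(n_bf[n_bf > 0]), prof(n_fl[n_fl > 0]), params)
    keys <- got$clonotype_id
    want <- oracle_expansion_status(unname(n_bf[keys]), unname(n_fl[keys]))
    expect_equal(got$status, unname(want), info = paste("seed", s))
  }
})

test_that("raising the fold or cell thresholds never grows the expanded set", {
  for (s in 1:30) {
    withr::with_seed(s, {
      k <- sample(2:6, 1)
      ids <- paste0("cl", 1:k)
      n_bf <- setNames(sample(0:10, k, replace = TRUE), ids)
      n_fl <- setNames(sample(1:10, k, replace = TRUE), ids)
    })
    base <- classify_expansion(prof(n_bf[n_bf > 0]), prof(n_fl), expansion_params())
    for (p2 in list(expansion_params(fold_threshold = 3),
                    expansion_params(min_flare_cells = 5))) {
      harder <- classify_expansion(prof(n_bf[n_bf > 0]), prof(n_fl), p2)
      expect_true(all(harder$clonotype_id[harder$expanded] %in%
                        base$clonotype_id[base$expanded]))
    }
  }
})

test_that("patient mismatch between profiles is rejected", {
  bf <- tibble::tibble(patient_id = "P1", clonotype_id = "a", n = 2L)
  fl <- tibble::tibble(patient_id = "P2", clonotype_id = "a", n = 6L)
  expect_error(classify_expansion(bf, fl), "patient")
})

test_that("fate table attributes clonotype-level mass across subtype pairs", {
  calls <- tibble::tibble(
    barcode = sprintf("b%d", 1:9),
    clonotype_id = c(rep("dn", 3), rep("sw", 6)))
  meta <- make_meta(calls$barcode,
                    timepoint = c(rep("FL", 3), rep("BF", 2), rep("FL", 4)),
                    cell_type = c(rep("CD8 Tem", 3), rep("CD8 naive", 2),
                                  rep("CD8 Tem", 4)))
  expansion <- tibble::tibble(patient_id = "P1",
                              clonotype_id = c("dn", "sw"),
                              expanded = TRUE)
  fate <- fate_table(calls, meta, expansion)
  # de novo clone: all mass on (absent -> CD8 Tem)
  dn <- fate[fate$bf_type == "absent", ]
  expect_equal(dn$fl_type, "CD8 Tem")
  expect_equal(dn$weight, 1)
  expect_equal(dn$n_cells_fl, 3L)
  # switching clone: naive -> Tem with weight 1
  sw <- fate[fate$bf_type == "CD8 naive", ]
  expect_equal(sw$fl_type, "CD8 Tem")
  expect_equal(sw$weight, 1)
  # conservation: total weight equals number of expanded clonotypes
  expect_equal(sum(fate$weight), 2)

  # cell weighting scales by flare cells
  fate_c <- fate_table(calls, meta, expansion, weighting = "cell")
  expect_equal(sum(fate_c$weight), 7)
})

test_that("expanded-vs-rest score comparison recovers a planted shift", {
  withr::with_seed(99, {
    n <- 200
    calls <- tibble::tibble(barcode = sprintf("b%04d", 1:(2 * n)),
                            clonotype_id = rep(c("exp", "rest"), each = n))
    meta <- make_meta(calls$barcode, timepoint = "FL")
    scores <- tibble::tibble(barcode = calls$barcode,
                             cytotox = c(rnorm(n, mean = 1), rnorm(n, mean = 0)),
                             flat = rnorm(2 * n))
    expansion <- tibble::tibble(patient_id = "P1",
                                clonotype_id = c("exp", "rest"),
                                expanded = c(TRUE, FALSE))
  })
  cmp <- compare_expanded_scores(scores, expansion, calls, meta)
  sm <- cmp$summary
  shift <- sm$mean[sm$expanded & sm$score == "cytotox"] -
    sm$mean[!sm$expanded & sm$score == "cytotox"]
  expect_equal(shift, 1, tolerance = 0.3)
  tst <- cmp$tests
  expect_lt(tst$p_adj[tst$score == "cytotox"], 1e-6)
  expect_gt(tst$p_adj[tst$score == "flat"], 0.01)

  # identical distributions give p near 1 and mean difference near 0
  scores2 <- scores; scores2$cytotox <- rep(seq_len(n), 2)
  cmp2 <- compare_expanded_scores(scores2, expansion, calls, meta)
  expect_gt(cmp2$tests$p_value[cmp2$tests$score == "cytotox"], 0.9)
})
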