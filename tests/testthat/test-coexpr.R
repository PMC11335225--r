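test_that("cell-type filter keeps clusters at or above 10% detection", {
  counts <- matrix(0L, 2, 150,
                   dimnames = list(c("anchor", "other"), paste0("c", 1:150)))
  labels <- rep(c("cl1", "cl2", "cl3"), each = 50)
  counts["anchor", 1:5] <- 1L    # cl1: exactly 10%
  counts["anchor", 51:54] <- 1L  # cl2: 8%
  counts["anchor", 101:140] <- 1L  # cl3: 80%
  cells <- filter_expressing_celltypes(counts, labels, "anchor")
  expect_setequal(cells, colnames(counts)[c(1:50, 101:150)])
  expect_error(filter_expressing_celltypes(counts, labels, "missing"),
               "absent")
  counts["anchor", ] <- 0L
  expect_length(filter_expressing_celltypes(counts, labels, "anchor"), 0L)
})

test_that("planted cluster-specific expression is isolated by the filter", {
  sim <- gen_count_matrix(20, c(60, 60, 60), zero_genes = 1, seed = 31)
  counts <- sim$counts
  # re-plant gene 1 in cluster 2 only
  idx2 <- which(sim$clusters == "cluster2")
  counts[1, idx2] <- rpois(length(idx2), 5)
  cells <- filter_expressing_celltypes(counts, sim$clusters, "gene0001")
  expect_setequal(cells, sim$cell_ids[idx2])
})

test_that("dot-plot statistics report detection percentage and hidden flags", {
  counts <- matrix(0L, 3, 100,
                   dimnames = list(c("all", "none", "some"), paste0("c", 1:100)))
  labels <- rep(c("cl1", "cl2"), each = 50)
  counts["all", ] <- 3L
  counts["some", 1:15] <- 2L  # 30% of cl1, 0% of cl2
  st <- dotplot_stats(counts, labels, c("all", "none", "some"))
  expect_equal(st$pct_expressing[st$gene == "all"], c(100, 100))
  expect_true(all(st$hidden[st$gene == "none"]))
  expect_false(any(st$hidden[st$gene == "all"]))
  expect_equal(st$pct_expressing[st$gene == "some" & st$cluster == "cl1"], 30)

  # binomial sampling: a 30%-detection gene lands within +/- 3% at 500 cells
  sim <- gen_count_matrix(5, 500, seed = 32)
  counts2 <- sim$counts
  set.seed(33)
  counts2[1, ] <- rbinom(500, 1, 0.3) * (1L + rpois(500, 2))
  st2 <- dotplot_stats(counts2, rep("cl", 500), "gene0001")
  expect_lt(abs(st2$pct_expressing - 30), 3 * 100 * sqrt(0.3 * 0.7 / 500) / 1)
})

test_that("bootstrap PCC is seeded, degenerate for a perfect copy, and null-covering", {
  sim <- gen_count_matrix(3, 800, seed = 41)
  counts <- sim$counts
  counts[2, ] <- counts[1, ]  # perfect copy
  b <- pcc_with_bootstrap(counts, NULL, "gene0001", "gene0002", seed = 1)
  expect_equal(b$pcc, 1.0)
  expect_equal(unname(diff(b$whiskers)), 0)

  b2 <- pcc_with_bootstrap(counts, NULL, "gene0001", "gene0003", seed = 9)
  b3 <- pcc_with_bootstrap(counts, NULL, "gene0001", "gene0003", seed = 9)
  expect_identical(b2$boot, b3$boot)

  # independent genes: small correlation, bootstrap interval covering 0
  expect_lt(abs(b2$pcc), 0.1)
  expect_lte(b2$whiskers[1], 0)
  expect_gte(b2$whiskers[2], 0)

  constant <- counts
  constant[3, ] <- 5L
  expect_error(pcc_with_bootstrap(constant, NULL, "gene0001", "gene0003"),
               "constant")
})

test_that("percentile ranks a perfect copy at its maximum and keeps books straight", {
  sim <- gen_count_matrix(51, 300, seed = 51)
  counts <- sim$counts
  counts[2, ] <- counts[1, ]
  res <- pcc_percentile(counts, NULL, "gene0001", "gene0002")
  # ties are not "below": the copy itself caps the percentile at 100 (n-1)/n
  expect_equal(res$percentile, 100 * (res$n_genes_compared - 1) /
                 res$n_genes_compared)
  expect_equal(res$n_genes_compared, 50L)
  expect_error(pcc_percentile(counts[1:5, ], NULL, "gene0001", "gene0002"),
               "fewer than 10")
})

test_that("percentile is monotone in the planted latent correlation", {
  percs <- vapply(c(0, 0.25, 0.5, 0.9), function(r) {
    pairs <- if (r > 0) list(list(geneA = 1, geneB = 2, corr = r)) else list()
    sim <- gen_count_matrix(301, 400, planted_pairs = pairs, seed = 61)
    pcc_percentile(sim$counts, NULL, "gene0001", "gene0002")$percentile
  }, numeric(1))
  expect_true(all(diff(percs) >= 0))
  expect_gt(percs[4], percs[1])
})

test_that("results on a filtered subset do not depend on discarded cells", {
  sim <- gen_count_matrix(30, c(100, 100),
                          planted_pairs = list(list(geneA = 1, geneB = 2,
                                                    corr = 0.6)),
                          seed = 71)
  keep <- sim$cell_ids[sim$clusters == "cluster1"]
  full <- pcc_percentile(sim$counts, keep, "gene0001", "gene0002")
  trimmed <- pcc_percentile(sim$counts[, keep], NULL, "gene0001", "gene0002")
  expect_equal(full$pcc, trimmed$pcc)
  expect_equal(full$percentile, trimmed$percentile)
})
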