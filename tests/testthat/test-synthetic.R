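# Generators: gating-model recordings, clustered count matrices, PLA image
# stacks, and plate-assay tables -- reproducibility and planted ground truth.

test_that("gating model hits its Boltzmann anchors", {
  g <- gating_params(Vh = -20, s = 9)
  expect_equal(n_inf(-20, g), 0.5)
  expect_equal(n_inf(1e6, g), 1)
  expect_lt(n_inf(-120, g), 0.001)
  expect_error(gating_params(s = 0), "slope")
  expect_error(gating_params(tau_max = -1), "tau_max")
})

test_that("steady current matches the hand oracle g*(V - E_rev)", {
  # g_max = 2 nS, fully activated, V = +20 mV, E_rev = -86 mV, no leak:
  # I = 2 * 106 = 212 pA
  g <- gating_params(Vh = -200, s = 5, g_max = 2, E_rev = -86, g_leak = 0,
                     tau_max = 5)
  rec <- gen_recordings(g, voltage_protocol(), noise_sd = 0, seed = 1)[[1]]
  step_idx <- which(rec$protocol$step_levels == 20)
  step_end <- round((rec$protocol$holding_duration + rec$protocol$step_duration) *
                      rec$protocol$sample_rate / 1000)
  expect_equal(unname(rec$sweeps[step_end, step_idx]), 212, tolerance = 1e-6)
})

test_that("recordings are reproducible per seed and sized by the protocol", {
  g <- gating_params()
  p <- voltage_protocol()
  r1 <- gen_recordings(g, p, n_cells = 2, noise_sd = 5, seed = 42)
  r2 <- gen_recordings(g, p, n_cells = 2, noise_sd = 5, seed = 42)
  expect_identical(r1[[2]]$sweeps, r2[[2]]$sweeps)
  r3 <- gen_recordings(g, p, n_cells = 2, noise_sd = 5, seed = 43)
  expect_false(identical(r1[[1]]$sweeps, r3[[1]]$sweeps))
  n_expected <- (p$holding_duration + p$step_duration + p$tail_duration) *
    p$sample_rate / 1000
  expect_equal(nrow(r1[[1]]$sweeps), n_expected)
  expect_equal(ncol(r1[[1]]$sweeps), length(p$step_levels))
  expect_true(all(is.finite(r1[[1]]$sweeps)))
})

test_that("count matrices plant correlation and keep decoys null", {
  sim <- gen_count_matrix(102, 500,
                          planted_pairs = list(list(geneA = 1, geneB = 2,
                                                    corr = 0.9)),
                          mean_log_range = log(c(5, 5)), seed = 3)
  expect_identical(dim(sim$counts), c(102L, 500L))
  l2 <- log2(sim$counts + 1)
  planted_pcc <- cor(l2[1, ], l2[2, ])

  # large-sample oracle under the same generator settings
  big <- gen_count_matrix(2, 100000,
                          planted_pairs = list(list(geneA = 1, geneB = 2,
                                                    corr = 0.9)),
                          mean_log_range = log(c(5, 5)), seed = 99)
  lb <- log2(big$counts + 1)
  oracle <- cor(lb[1, ], lb[2, ])
  expect_lt(abs(planted_pcc - oracle), 0.15)

  # decoy pairs are uncorrelated
  decoy_pcc <- sapply(seq(3, 101, by = 2), function(i) cor(l2[i, ], l2[i + 1, ]))
  expect_lt(mean(abs(decoy_pcc)), 0.1)
})

test_that("count matrices respect zero-mean genes, empty-cluster and corr bounds", {
  sim <- gen_count_matrix(10, c(20, 20), zero_genes = 4, seed = 1)
  expect_true(all(sim$counts[4, ] == 0L))
  expect_error(gen_count_matrix(10, c(20, 0), seed = 1), "empty")
  expect_error(gen_count_matrix(10, 20,
                                planted_pairs = list(list(geneA = 1, geneB = 2,
                                                          corr = 1.2)),
                                seed = 1),
               "latent_corr")
  s1 <- gen_count_matrix(20, 30, seed = 5)
  s2 <- gen_count_matrix(20, 30, seed = 5)
  expect_identical(s1$counts, s2$counts)
})

test_that("PLA stacks carry exact truth and honour separation constraints", {
  st <- gen_pla_stack(2, 10, 5, seed = 7,
                      noise = list(noise_sd = 0.005, poisson_scale = NULL))
  expect_equal(st$truth$counts$inside, c(10L, 10L))
  expect_equal(st$truth$counts$outside, 5L)
  expect_equal(st$truth$counts$total, 25L)
  # dots where truth says they are
  on_mask <- st$truth$mask[cbind(st$truth$dots$x, st$truth$dots$y)]
  expect_equal(on_mask, st$truth$dots$cell)
  # pairwise dot separation >= 3 px
  d <- st$truth$dots
  dist2 <- as.matrix(dist(cbind(d$x, d$y)))^2
  diag(dist2) <- Inf
  expect_true(all(dist2 >= 9))

  blank <- gen_pla_stack(0, 0, 3, seed = 8)
  expect_equal(blank$truth$counts$outside, 3L)
  expect_length(blank$truth$counts$inside, 0L)
  expect_true(all(blank$truth$mask == 0L))
})

test_that("Cq tables encode one doubling per cycle", {
  ab <- c(A = 2, B = 1, Hprt = 1, Sdha = 1, Tfrc = 1)
  cq <- gen_cq_table(ab, c("Hprt", "Sdha", "Tfrc"), n_samples = 8,
                     noise_sd_cycles = 0, seed = 2)
  expect_equal(nrow(cq), 5 * 8 * 2)
  wide <- reshape(cq, direction = "wide", idvar = c("sample", "replicate"),
                  timevar = "gene", drop = "tissue")
  expect_equal(wide$cq.A, wide$cq.B - 1, tolerance = 1e-12)
  expect_error(gen_cq_table(c(A = 1, Hprt = NA), "Hprt", seed = 1),
               "reference")
})

test_that("RLU tables have the stated layout and exact noiseless means", {
  rl <- gen_rlu_table(c(control = 1000, boosted = 1500),
                      n_oocytes_per_group = 20, background_mean = 50,
                      noise_sd = 0, n_experiments = 3, batch_sd = 0,
                      seed = 4)
  expect_equal(sum(rl$group == "control"), 60L)
  expect_equal(unique(rl$rlu[rl$group == "boosted"]), 1500)
  expect_equal(unique(rl$rlu[rl$group == "uninjected"]), 50)
  expect_error(gen_rlu_table(c(control = 10), n_oocytes_per_group = 1),
               "2 oocytes")
})
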