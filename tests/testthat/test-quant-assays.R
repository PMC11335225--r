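test_that("identical Cq everywhere gives relative expression 1", {
  genes <- c("Kcnq2", "Kcnv1", "Hprt", "Sdha", "Tfrc")
  t <- expand.grid(gene = genes, sample = c("s1", "s2"), replicate = 1:2,
                   stringsAsFactors = FALSE)
  t$tissue <- "drg"
  t$cq <- 25
  re <- relative_expression(t, c("Hprt", "Sdha", "Tfrc"), "Kcnq2")
  expect_equal(re$per_gene$mean_rel, rep(1, 5), tolerance = 1e-12)
})

test_that("one cycle below the calibrator doubles relative expression", {
  genes <- c("target", "cal", "Hprt", "Sdha", "Tfrc")
  t <- expand.grid(gene = genes, sample = paste0("s", 1:4), replicate = 1:2,
                   stringsAsFactors = FALSE)
  t$tissue <- "drg"
  t$cq <- ifelse(t$gene == "target", 24, 25)
  re <- relative_expression(t, c("Hprt", "Sdha", "Tfrc"), "cal")
  expect_equal(re$per_gene$mean_rel[re$per_gene$gene == "target"], 2,
               tolerance = 1e-12)
})

test_that("zero-noise round trip recovers planted abundances below 1e-9", {
  ab <- c(Kcnq2 = 1, Kcnv1 = 0.37, Kcnv2 = 0.004, Hprt = 4, Sdha = 2,
          Tfrc = 1.5)
  cq <- gen_cq_table(ab, c("Hprt", "Sdha", "Tfrc"), n_samples = 8,
                     noise_sd_cycles = 0, seed = 1)
  re <- relative_expression(cq, c("Hprt", "Sdha", "Tfrc"), "Kcnq2")
  truth <- ab / ab[["Kcnq2"]]
  err <- abs(re$per_gene$mean_rel / truth[re$per_gene$gene] - 1)
  expect_lt(max(err), 1e-9)
  # calibrator tissue mean is exactly 1 by construction
  expect_equal(re$per_gene$mean_rel[re$per_gene$gene == "Kcnq2"], 1)
})

test_that("per-sample Cq offsets cancel under reference normalization", {
  ab <- c(A = 1.3, B = 0.2, Hprt = 1, Sdha = 2, Tfrc = 4)
  base <- gen_cq_table(ab, c("Hprt", "Sdha", "Tfrc"), n_samples = 4,
                       noise_sd_cycles = 0, sample_shift_sd = 0, seed = 2)
  shifted <- base
  offsets <- c(s01 = 1.7, s02 = -2.3, s03 = 0.4, s04 = 5)
  shifted$cq <- shifted$cq + offsets[shifted$sample]
  r1 <- relative_expression(base, c("Hprt", "Sdha", "Tfrc"), "A")
  r2 <- relative_expression(shifted, c("Hprt", "Sdha", "Tfrc"), "A")
  expect_equal(r2$per_gene$mean_rel, r1$per_gene$mean_rel, tolerance = 1e-12)
})

test_that("non-detects and duplicate disagreements are handled explicitly", {
  ab <- c(A = 1, ND = NA, Hprt = 1, Sdha = 1, Tfrc = 1)
  cq <- gen_cq_table(ab, c("Hprt", "Sdha", "Tfrc"), n_samples = 3,
                     noise_sd_cycles = 0, seed = 3)
  re <- relative_expression(cq, c("Hprt", "Sdha", "Tfrc"), "A")
  nd <- re$per_gene[re$per_gene$gene == "ND", ]
  expect_equal(nd$n_detected, 0L)
  expect_true(is.na(nd$mean_rel))

  bad <- cq
  bad$cq[bad$gene == "A" & bad$sample == "s01" & bad$replicate == 2] <-
    bad$cq[bad$gene == "A" & bad$sample == "s01" & bad$replicate == 1] + 2
  expect_warning(relative_expression(bad, c("Hprt", "Sdha", "Tfrc"), "A"),
                 "discarded")

  ref_nd <- cq
  ref_nd$cq[ref_nd$gene == "Hprt"] <- NA
  expect_error(relative_expression(ref_nd, c("Hprt", "Sdha", "Tfrc"), "A"),
               "reference")
  expect_error(relative_expression(cq, c("Hprt", "Sdha", "Tfrc"), "ND"),
               "calibrator")
})

test_that("RLU normalization pins the control at 1 and cancels batch factors", {
  rl <- gen_rlu_table(c(control = 1000, kv81 = 1500, kv82 = 700),
                      n_oocytes_per_group = 20, background_mean = 50,
                      noise_sd = 0, n_experiments = 3, batch_sd = 0.6,
                      seed = 11)
  nr <- suppressWarnings(normalize_rlu(rl, "control", "uninjected"))
  s <- nr$summary
  expect_equal(s$mean[s$group == "control"], 1, tolerance = 1e-12)
  # batch factor cancels: planted effects recovered exactly despite batches
  expect_equal(s$mean[s$group == "kv81"], (1500 - 50) / (1000 - 50),
               tolerance = 1e-9)
  expect_equal(s$mean[s$group == "kv82"], (700 - 50) / (1000 - 50),
               tolerance = 1e-9)
  # per-experiment values identical across experiments
  v <- nr$normalized$rlu_norm[nr$normalized$group == "kv81"]
  expect_lt(diff(range(v)), 1e-9)
})

test_that("Dunnett flags a planted 1.5x surface-expression group", {
  rl <- gen_rlu_table(c(control = 1000, boosted = 1500, same = 1000),
                      n_oocytes_per_group = 20, background_mean = 50,
                      noise_sd = 150, n_experiments = 3, seed = 12)
  nr <- normalize_rlu(rl, "control", "uninjected")
  s <- nr$summary
  expect_lte(s$p_value[s$group == "boosted"], 0.05)
  expect_gt(s$p_value[s$group == "same"], 0.05)
  expect_error(normalize_rlu(rl, "control", "nope"), "background")
})
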