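test_that("series-resistance filter excludes at exactly 7 MOhm", {
  mk <- function(id, rs) list(meta = list(id = id, Rs = rs))
  res <- qc_filter(list(mk("keep", 6.99), mk("drop", 7.0), mk("high", 12),
                        mk("nors", NA)))
  expect_equal(vapply(res$kept, function(r) r$meta$id, ""), "keep")
  expect_setequal(res$log$id, c("drop", "high", "nors"))
  expect_match(res$log$reason[res$log$id == "nors"], "missing")
  # pure filter: retained recordings are untouched
  rec <- gen_recordings(gating_params(), voltage_protocol(), noise_sd = 1,
                        rs_dist = list(meanlog = log(4), sdlog = 0), seed = 1)
  expect_identical(qc_filter(rec)$kept[[1]], rec[[1]])
  empty <- qc_filter(list())
  expect_length(empty$kept, 0L)
  expect_equal(nrow(empty$log), 0L)
})

test_that("steady-state density matches the hand oracle and handles leak-only cells", {
  g <- gating_params(Vh = -200, s = 5, g_max = 2, E_rev = -86, g_leak = 0,
                     tau_max = 5)
  rec <- gen_recordings(g, voltage_protocol(), noise_sd = 0,
                        cm_dist = list(mean = 10, sd = 0), seed = 1)[[1]]
  expect_equal(steady_state_density(rec, 20), 21.2, tolerance = 1e-6)
  expect_error(steady_state_density(rec, 33), "step level")

  leak_only <- gen_recordings(gating_params(g_max = 0, g_leak = 1,
                                            E_leak = -80),
                              voltage_protocol(), noise_sd = 0,
                              cm_dist = list(mean = 10, sd = 0), seed = 2)[[1]]
  expect_equal(steady_state_density(leak_only, 20), 1 * (20 - -80) / 10,
               tolerance = 1e-6)
})

test_that("noiseless tail amplitudes are affine in the steady-state activation", {
  g <- gating_params()
  rec <- gen_recordings(g, recovery_protocol(), noise_sd = 0, seed = 1)[[1]]
  ta <- extract_tail_amplitudes(rec)
  ninf <- n_inf(ta$voltage, g)
  fit <- lm(ta$amplitude ~ ninf)
  # affine up to the ~e^-15 residual of activation settling within the step
  expect_gt(summary(fit)$r.squared, 1 - 1e-7)
  # far below Vh the amplitude vanishes: the -100 mV point sits within
  # n_inf(-100) ~ 1.4e-4 of the zero-activation intercept
  expect_lt(abs(ta$amplitude[1] - predict(fit, data.frame(ninf = 0))) /
              diff(range(ta$amplitude)), 1e-3)
  expect_error(extract_tail_amplitudes(rec, window_ms = 1e5), "shorter")
})

test_that("Boltzmann symmetry: amplitudes at Vh +/- x sum to I_min + I_max", {
  g <- gating_params(Vh = -20, s = 9)
  p <- voltage_protocol(step_levels = c(-60, -40, -30, -10, 0, 20))
  rec <- gen_recordings(g, p, noise_sd = 0, seed = 1)[[1]]
  ta <- extract_tail_amplitudes(rec)
  ft <- fit_boltzmann(ta$voltage, ta$amplitude)
  # -40 and 0 are symmetric about Vh = -20
  expect_equal(ta$amplitude[ta$voltage == -40] + ta$amplitude[ta$voltage == 0],
               ft$I_min + ft$I_max, tolerance = 1e-6)
})

test_that("Boltzmann fit recovers exact curve samples and validates input", {
  V <- seq(-80, 40, length.out = 11)
  amp <- -30 + (120 - -30) / (1 + exp((V - -20) / -9))
  ft <- fit_boltzmann(V, amp)
  expect_equal(ft$Vh, -20, tolerance = 1e-6)
  expect_equal(ft$s, -9, tolerance = 1e-6)
  expect_equal(ft$I_min, -30, tolerance = 1e-6)
  expect_equal(ft$I_max, 120, tolerance = 1e-6)
  # the fitted curve passes through its own midpoint at Vh
  expect_equal(predict_boltzmann(ft, ft$Vh), (ft$I_min + ft$I_max) / 2)

  expect_error(fit_boltzmann(V[1:3], amp[1:3]), "4 distinct")
  expect_error(fit_boltzmann(V, rep(5, 11)), "flat")
})

test_that("G-V normalization is exact, scale-invariant, and guards degenerate fits", {
  V <- seq(-80, 40, length.out = 11)
  amp <- 10 + (200 - 10) / (1 + exp((V - -25) / -8))
  ft <- fit_boltzmann(V, amp)
  gv <- normalize_gv(ft, V, amp)
  # amplitudes equal to the asymptotes map to exactly 0 and 1
  ends <- normalize_gv(ft, c(-1e6, 1e6), c(ft$I_min, ft$I_max))
  expect_equal(ends$g_norm, c(0, 1))
  # noiseless normalized curve equals the gating model's n_inf
  g <- gating_params(Vh = -25, s = 8)
  expect_equal(gv$g_norm, n_inf(V, g), tolerance = 1e-6)

  k <- 3.7
  ftk <- fit_boltzmann(V, k * amp)
  gvk <- normalize_gv(ftk, V, k * amp)
  expect_equal(gvk$g_norm, gv$g_norm, tolerance = 1e-12)

  ft0 <- ft
  ft0$I_max <- ft0$I_min
  expect_error(normalize_gv(ft0, V, amp), "undefined")
})

test_that("end-to-end noiseless recovery is exact to 0.01 mV", {
  g <- gating_params(Vh = -23.5, s = 8.2)
  rec <- gen_recordings(g, recovery_protocol(), noise_sd = 0, seed = 1)[[1]]
  ta <- extract_tail_amplitudes(rec)
  ft <- fit_boltzmann(ta$voltage, ta$amplitude)
  expect_lt(abs(ft$Vh - g$Vh), 0.01)
  expect_lt(abs(abs(ft$s) - g$s) / g$s, 0.001)
})

test_that("group summary normalizes to the reference and flags planted effects", {
  set.seed(21)
  df <- data.frame(
    group = rep(c("ref", "double", "same"), each = 15),
    value = c(rnorm(15, 10, 2), rnorm(15, 20, 4), rnorm(15, 10, 2)))
  gs <- group_summary(df, "ref")
  expect_equal(gs$summary$norm_mean[gs$summary$group == "ref"], 1.0)
  expect_lte(gs$summary$p_value[gs$summary$group == "double"], 0.05)
  expect_error(group_summary(df, "absent"), "absent")

  # power: a planted 2x group at 20% noise is flagged in >= 90/100 runs
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    d <- data.frame(group = rep(c("ref", "double"), each = 15),
                    value = c(rnorm(15, 10, 2), rnorm(15, 20, 4)))
    gs <- group_summary(d, "ref")
    gs$summary$p_value[gs$summary$group == "double"] <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
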