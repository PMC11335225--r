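test_that("composition enumeration matches brute-force stars-and-bars", {
  one <- kv_mix(kv_species("a", "KV7", availability = 1))
  expect_equal(enumerate_compositions(one), matrix(4L, 1, 1,
                                                   dimnames = list(NULL, "a")))

  two <- mix_all_wt()
  c2 <- enumerate_compositions(two)
  expect_equal(nrow(c2), 5L)
  expect_equal(c2[, 1L], c(4L, 3L, 2L, 1L, 0L), ignore_attr = TRUE)

  three <- kv_mix(kv_species("a", "KV7", availability = 0.2),
                  kv_species("b", "KVS", availability = 0.3),
                  kv_species("c", "KVS", availability = 0.5))
  c3 <- enumerate_compositions(three)
  # independent oracle: filter the full grid
  grid <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  oracle_n <- sum(rowSums(grid) == 4L)
  expect_equal(nrow(c3), oracle_n)
  expect_equal(nrow(c3), 15L)
  expect_true(all(rowSums(c3) == 4L))
  expect_false(anyDuplicated(c3) > 0)
})

test_that("mix construction validates availabilities and mass ratios", {
  expect_error(kv_mix(kv_species("a", "KV7", availability = 0.4),
                      kv_species("b", "KVS", availability = 0.4)),
               "sum to 1")
  m <- kv_mix(kv_species("Kv8.1", "KVS"), kv_species("Kv7.2", "KV7"),
              mass_ratio = c(4, 1))
  expect_equal(m$availability, c(0.8, 0.2))
  expect_error(kv_mix(kv_species("a", "KV7", availability = 1),
                      kv_species("a", "KV7", availability = 0)),
               "unique")
})

test_that("stochastic distribution is the multinomial law; 1/16 is exact", {
  mix <- mix_wt7_dn_kvs()
  d <- composition_distribution(mix, assembly_rule("stochastic"))
  expect_identical(d$probabilities[1L], 0.0625)  # all-wild-type tetramer
  expect_equal(sum(d$probabilities), 1, tolerance = 1e-12)
  expect_equal(d$probabilities, dbinom(4:0, 4, 0.5), tolerance = 1e-12,
               ignore_attr = TRUE)

  one <- kv_mix(kv_species("a", "KV7", availability = 1))
  for (v in c("stochastic", "per_site", "tetramer_class", "dimer_pairs")) {
    expect_equal(composition_distribution(one, assembly_rule(v, 3))$probabilities,
                 1)
  }
})

test_that("every variant collapses to the multinomial law at f = 1", {
  mixes <- list(mix_wt7_dn_kvs(),
                kv_mix(kv_species("a", "KV7", availability = 0.2),
                       kv_species("b", "KVS", availability = 0.8)),
                kv_mix(kv_species("a", "KV7", availability = 0.5),
                       kv_species("b", "KVS", availability = 0.3),
                       kv_species("c", "KVS", availability = 0.2)))
  for (mix in mixes) {
    base <- composition_distribution(mix, assembly_rule("stochastic"))
    for (v in c("per_site", "tetramer_class", "dimer_pairs")) {
      d <- composition_distribution(mix, assembly_rule(v, 1))
      expect_lt(max(abs(d$probabilities - base$probabilities)), 1e-12)
    }
  }
})

test_that("per_site law matches its closed form for an equal two-species mix", {
  # nucleus first: P(homotetramer of species 1) = p1 * (f p1 / (f p1 + p2))^3
  mix <- mix_wt7_dn_kvs()
  d <- composition_distribution(mix, assembly_rule("per_site", 5))
  expect_equal(d$probabilities[1L], 0.5 * (5 / 6)^3, tolerance = 1e-12)
  expect_equal(d$probabilities[5L], 0.5 * (5 / 6)^3, tolerance = 1e-12)
})

test_that("Monte-Carlo assembly is reproducible and matches the analytic law", {
  mix <- mix_wt7_dn_kvs()
  rule <- assembly_rule("per_site", 5)
  s1 <- simulate_assembly(mix, rule, 2e4, seed = 11)
  s2 <- simulate_assembly(mix, rule, 2e4, seed = 11)
  expect_identical(s1$probabilities, s2$probabilities)
  s3 <- simulate_assembly(mix, rule, 2e4, seed = 12)
  expect_false(identical(s1$probabilities, s3$probabilities))

  d <- composition_distribution(mix, rule)
  expect_lt(tv_distance(s1, d), 0.02)

  single <- simulate_assembly(mix, rule, 1, seed = 1)
  expect_equal(sum(single$probabilities == 1), 1L)
  expect_error(simulate_assembly(mix, rule, 0), "n_draws")
})

test_that("dominant-negative prediction gives 1/16 under stochastic assembly", {
  mix <- mix_wt7_dn_kvs()
  pred <- predict_relative_current(mix, assembly_rule("stochastic"),
                                   conductance_rule(), "kv7_alone")
  expect_identical(pred$relative_current, 0.0625)
  # and the anticipated reduction is exactly 1 - 1/16
  expect_identical(1 - pred$relative_current, 0.9375)
})

test_that("beta-subunit mode is blind to KvS pore mutations", {
  pred <- predict_relative_current(mix_wt7_dn_kvs(), assembly_rule("stochastic"),
                                   conductance_rule("beta_subunit"), "wt_mix")
  expect_equal(pred$relative_current, 1.0, tolerance = 1e-12)
})

test_that("independent-channels mode leaves a residual current under Kv7 pore mutation", {
  pred <- predict_relative_current(
    mix_dn7_wt_kvs(), assembly_rule("stochastic"),
    conductance_rule("independent_channels", standalone_kvs_conductance = 0.5),
    "wt_mix")
  expect_gt(pred$relative_current, 0)
  # while the shared-pore and beta-subunit modes predict zero
  tab <- compare_modes(mix_dn7_wt_kvs(), assembly_rule("stochastic"),
                       conductance_rule(standalone_kvs_conductance = 0.5),
                       baseline = "wt_mix")
  expect_equal(tab$relative_current[tab$mode == "single_pore_heteromer"], 0)
  expect_equal(tab$relative_current[tab$mode == "beta_subunit"], 0)
})

test_that("an all-wild-type mix predicts 1 in every mode", {
  tab <- compare_modes(mix_all_wt(), assembly_rule("stochastic"),
                       conductance_rule(standalone_kvs_conductance = 0.3),
                       baseline = "wt_mix")
  expect_equal(tab$relative_current, rep(1, 3), tolerance = 1e-12)
})

test_that("baseline without conducting channels raises an error", {
  mix <- kv_mix(kv_species("Kv7.2gys", "KV7", pore_functional = FALSE),
                kv_species("Kv8.1", "KVS"), equalize = TRUE)
  expect_error(predict_relative_current(mix, assembly_rule("stochastic"),
                                        conductance_rule(), "kv7_alone"),
               "no conducting")
})

test_that("preference fitting round-trips and matches closed forms", {
  mix <- mix_wt7_dn_kvs()
  for (v in c("per_site", "tetramer_class", "dimer_pairs")) {
    for (f_star in c(1, 2, 5, 10, 20)) {
      r <- predict_relative_current(mix, assembly_rule(v, f_star),
                                    conductance_rule(), "wt_mix")$relative_current
      fit <- fit_preference(r, mix, v)
      expect_lt(abs(fit$preference_f - f_star), 1e-3)
    }
  }
  # closed-form inversions at a 50% residual:
  # per_site: 0.5 u^3 / (1 - 0.5 u^3) = 0.5 with u = f/(f+1)  =>  u^3 = 2/3
  ps <- fit_preference(0.5, mix, "per_site")
  u <- ps$preference_f / (ps$preference_f + 1)
  expect_equal(u^3, 2 / 3, tolerance = 1e-4)
  # tetramer_class: f / (f + 14) = 0.5  =>  f = 14
  tc <- fit_preference(0.5, mix, "tetramer_class")
  expect_equal(tc$preference_f, 14, tolerance = 1e-3)
  # dimer_pairs: supremum of the attainable ratio is 1/3 < 0.5
  expect_error(fit_preference(0.5, mix, "dimer_pairs"), "attainable range")
})
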