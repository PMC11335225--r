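#!/usr/bin/env Rscript
# Co-assembly model of Kv7 with silent Kv subunits: what fraction of channels
# survives a dominant-negative pore mutant, which interaction mode is
# compatible with the observations, and how strong a homomer preference the
# observed ~50% residual current implies.

suppressMessages(library(silentkv))
dir.create("results", showWarnings = FALSE)

mix <- kv_mix(kv_species("Kv7.2", "KV7"),
              kv_species("Kv8.1dn", "KVS", pore_functional = FALSE),
              equalize = TRUE)

## 1. Fully stochastic co-assembly: composition distribution and the 1/16
d <- composition_distribution(mix, assembly_rule("stochastic"))
comp_tab <- data.frame(d$compositions, probability = d$probabilities)
write.table(comp_tab, "results/assembly_composition_distribution.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
pred <- predict_relative_current(mix, assembly_rule("stochastic"),
                                 conductance_rule(), "kv7_alone")
message(sprintf(
  "Stochastic equal-availability assembly: P(all-wild-type tetramer) = %.4f;",
  d$probabilities[1]))
message(sprintf(
  "  only those conduct with a pore-dead KvS, so the predicted residual current is %.4f (a %.2f%% reduction).",
  pred$relative_current, 100 * (1 - pred$relative_current)))

## 2. Interaction modes under each pore-mutant configuration
modes_dead_kvs <- compare_modes(mix, assembly_rule("stochastic"),
                                conductance_rule(standalone_kvs_conductance = 0.5),
                                baseline = "wt_mix")
modes_dead_kvs$mutant <- "pore-dead KvS"
mix_dn7 <- kv_mix(kv_species("Kv7.2gys", "KV7", pore_functional = FALSE),
                  kv_species("Kv8.1", "KVS"), equalize = TRUE)
modes_dead_kv7 <- compare_modes(mix_dn7, assembly_rule("stochastic"),
                                conductance_rule(standalone_kvs_conductance = 0.5),
                                baseline = "wt_mix")
modes_dead_kv7$mutant <- "pore-dead Kv7"
modes <- rbind(modes_dead_kvs, modes_dead_kv7)
write.table(modes, "results/assembly_mode_discrimination.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Mode discrimination (relative current vs all-wild-type mix):")
for (i in seq_len(nrow(modes))) {
  message(sprintf("  %-22s %-15s %.4f", modes$mode[i], modes$mutant[i],
                  modes$relative_current[i]))
}
message("  -> a beta-subunit model predicts no effect of a KvS pore mutation,")
message("     independent channels predict a residual current from a Kv7 pore")
message("     mutant; only a shared single pore matches both observations.")

## 3. Homomer preference explaining a ~50% residual, per generative variant
fits <- lapply(c("per_site", "tetramer_class", "dimer_pairs"), function(v) {
  res <- tryCatch(fit_preference(0.5, mix, v), error = function(e) e)
  if (inherits(res, "error")) {
    message(sprintf("  %-15s infeasible: %s", v, conditionMessage(res)))
    data.frame(variant = v, preference_f = NA_real_,
               note = "50% residual not attainable")
  } else {
    message(sprintf("  %-15s f = %.3f", v, res$preference_f))
    data.frame(variant = v, preference_f = res$preference_f, note = "")
  }
})
message("Preference factor reproducing a 50% residual current, per variant:")
write.table(do.call(rbind, fits), "results/assembly_preference_fits.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

## 4. Monte-Carlo check of the analytic laws
tv_rows <- list()
for (v in c("stochastic", "per_site", "tetramer_class", "dimer_pairs")) {
  f <- if (v == "stochastic") 1 else 5
  rule <- assembly_rule(v, f)
  tv <- tv_distance(simulate_assembly(mix, rule, 1e5, seed = 100),
                    composition_distribution(mix, rule))
  tv_rows[[v]] <- data.frame(variant = v, preference_f = f, tvd_1e5 = tv)
}
tv_tab <- do.call(rbind, tv_rows)
write.table(tv_tab, "results/assembly_mc_agreement.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf(
  "Monte-Carlo frequencies at 1e5 draws agree with the analytic laws (max TVD %.4f).",
  max(tv_tab$tvd_1e5)))
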