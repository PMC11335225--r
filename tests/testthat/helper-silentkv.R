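# Shared fixtures: canonical subunit mixes, a fast protocol for fit tests,
# and small geometry helpers for image tests.

# wild-type Kv7.2 with a dominant-negative (pore-dead) KvS, equally available
mix_wt7_dn_kvs <- function() {
  kv_mix(kv_species("Kv7.2", "KV7"),
         kv_species("Kv8.1dn", "KVS", pore_functional = FALSE),
         equalize = TRUE)
}

# pore-dead Kv7.2 with wild-type KvS
mix_dn7_wt_kvs <- function() {
  kv_mix(kv_species("Kv7.2gys", "KV7", pore_functional = FALSE),
         kv_species("Kv8.1", "KVS"),
         equalize = TRUE)
}

mix_all_wt <- function() {
  kv_mix(kv_species("Kv7.2", "KV7"), kv_species("Kv8.1", "KVS"),
         equalize = TRUE)
}

# 11-voltage activation protocol used for parameter-recovery simulations
recovery_protocol <- function() {
  voltage_protocol(step_levels = seq(-100, 60, length.out = 11))
}

# trace-noise SD corresponding to "5% of the maximal tail amplitude"
tail_noise_sd <- function(gating, protocol = recovery_protocol()) {
  0.05 * gating$g_max * abs(protocol$tail_voltage - gating$E_rev)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# greedy one-to-one matching of detections to truth dots within a tolerance
match_dots <- function(dots, truth, tol_px = 2) {
  matched <- 0L
  used <- rep(FALSE, max(1L, nrow(dots)))
  if (nrow(dots)) {
    for (i in seq_len(nrow(truth))) {
      d2 <- (dots$x - truth$x[i])^2 + (dots$y - truth$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= tol_px^2 && !used[j]) {
        matched <- matched + 1L
        used[j] <- TRUE
      }
    }
  }
  list(recall = matched / nrow(truth),
       precision = if (nrow(dots)) matched / nrow(dots) else 1)
}
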