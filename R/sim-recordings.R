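# Synthetic whole-cell voltage-clamp recordings from a first-order gating
# model with Boltzmann steady state. The activation gate n relaxes within each
# constant-voltage epoch as
#   n(t) = n_inf(V) + (n0 - n_inf(V)) * exp(-t / tau(V)),
#   n_inf(V) = 1 / (1 + exp((Vh - V) / s)),
#   tau(V)  = tau_max / cosh((V - Vh) / (2 s)),
# and the current is I = g_max * n * (V - E_rev) + g_leak * (V - E_leak)
# plus filtered Gaussian noise. The model is linear per voltage epoch, so the
# updates are piecewise-exact exponentials -- no ODE solver, hence no solver
# tolerance to confound downstream fits.

#' Gating-model parameters
#'
#' @param Vh Half-maximal activation voltage (mV).
#' @param s Slope factor magnitude (mV, activation convention: larger V opens
#'   the channel; must be > 0).
#' @param g_max Maximal conductance (nS).
#' @param E_rev Reversal potential of the conducted current (mV).
#' @param tau_max Maximal activation time constant (ms), attained at `V = Vh`.
#' @param g_leak Leak conductance (nS).
#' @param E_leak Leak reversal potential (mV).
#' @return List of class `"kv_gating_params"`.
#' @export
gating_params <- function(Vh = -20, s = 9, g_max = 2, E_rev = -86,
                          tau_max = 100, g_leak = 0.2, E_leak = -80) {
  if (s <= 0) stop("slope factor s must be > 0")
  if (tau_max <= 0) stop("tau_max must be > 0")
  if (g_max < 0 || g_leak < 0) stop("conductances must be >= 0")
  structure(list(Vh = Vh, s = s, g_max = g_max, E_rev = E_rev,
                 tau_max = tau_max, g_leak = g_leak, E_leak = E_leak),
            class = "kv_gating_params")
}

#' Steady-state activation of the gating model
#' @param V Membrane voltage(s), mV.
#' @param gating A [gating_params()].
#' @return Open probability `n_inf(V)` in (0, 1).
#' @export
n_inf <- function(V, gating) 1 / (1 + exp((gating$Vh - V) / gating$s))

#' Voltage-dependent activation time constant
#' @inheritParams n_inf
#' @return `tau(V)` in ms.
#' @export
tau_act <- function(V, gating) {
  gating$tau_max / cosh((V - gating$Vh) / (2 * gating$s))
}

#' Voltage-step protocol
#'
#' Default: hold at -80 mV, 100 ms of holding padding, depolarising steps
#' from -100 to +60 mV in 20 mV increments for 1500 ms, then a tail at
#' -30 mV for 500 ms, sampled at 5 kHz.
#'
#' @param holding Holding potential (mV).
#' @param step_levels Strictly increasing step voltages (mV).
#' @param step_duration Step length (ms).
#' @param tail_voltage Tail potential (mV).
#' @param tail_duration Tail length (ms).
#' @param holding_duration Pre-step holding padding included in each sweep (ms).
#' @param sample_rate Sampling rate (Hz).
#' @return List of class `"kv_protocol"`.
#' @export
voltage_protocol <- function(holding = -80, step_levels = seq(-100, 60, by = 20),
                             step_duration = 1500, tail_voltage = -30,
                             tail_duration = 500, holding_duration = 100,
                             sample_rate = 5000) {
  stopifnot(all(diff(step_levels) > 0), step_duration > 0, tail_duration > 0,
            holding_duration >= 0, sample_rate > 0)
  structure(list(holding = holding, step_levels = step_levels,
                 step_duration = step_duration, tail_voltage = tail_voltage,
                 tail_duration = tail_duration,
                 holding_duration = holding_duration,
                 sample_rate = sample_rate),
            class = "kv_protocol")
}

# samples per protocol segment
.proto_samples <- function(protocol) {
  per_ms <- protocol$sample_rate / 1000
  c(holding = round(protocol$holding_duration * per_ms),
    step = round(protocol$step_duration * per_ms),
    tail = round(protocol$tail_duration * per_ms))
}

# Emulate the acquisition low-pass filter on the noise term only (the
# deterministic signal is band-limited already): Gaussian smoothing with
# sigma matched to the filter cutoff.
.filtered_noise <- function(n, sd, sample_rate, cutoff_hz = 2500) {
  if (sd == 0) return(numeric(n))
  eps <- rnorm(n, sd = sd)
  sigma <- 0.1325 * sample_rate / cutoff_hz  # samples; -3 dB Gaussian cutoff
  half <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  pad <- c(rev(eps[seq_len(half)]), eps, rev(eps[n - seq_len(half) + 1L]))
  as.numeric(stats::filter(pad, kern, sides = 2L))[half + seq_len(n)]
}

#' Generate synthetic whole-cell recordings
#'
#' @param gating A [gating_params()] (ground truth, carried in the output).
#' @param protocol A [voltage_protocol()].
#' @param n_cells Number of cells to simulate.
#' @param noise_sd Gaussian current-noise SD (pA) before low-pass filtering.
#' @param rs_dist Lognormal series-resistance distribution,
#'   `list(meanlog, sdlog)` (MOhm).
#' @param cm_dist Normal membrane-capacitance distribution,
#'   `list(mean, sd)` (pF), truncated below at 2 pF.
#' @param group Group label stored in each cell's metadata.
#' @param seed Optional integer seed; same seed gives identical output.
#' @param cell_prefix Prefix for generated cell ids.
#' @return List of recordings; each is a list with `sweeps` (time x step-level
#'   matrix, pA), `time_ms`, `protocol`, `meta` (`id`, `Cm`, `Rs`, `group`)
#'   and `truth` (the gating parameters used).
#' @examples
#' rec <- gen_recordings(gating_params(), voltage_protocol(), noise_sd = 0)[[1]]
#' dim(rec$sweeps)
#' @export
gen_recordings <- function(gating, protocol = voltage_protocol(), n_cells = 1L,
                           noise_sd = 10,
                           rs_dist = list(meanlog = log(4.5), sdlog = 0.35),
                           cm_dist = list(mean = 10, sd = 1.5),
                           group = "group1", seed = NULL,
                           cell_prefix = "cell") {
  stopifnot(inherits(gating, "kv_gating_params"),
            inherits(protocol, "kv_protocol"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  ns <- .proto_samples(protocol)
  dt_ms <- 1000 / protocol$sample_rate
  n_total <- sum(ns)
  time_ms <- (seq_len(n_total) - 1L) * dt_ms

  sweep_for <- function(V_step, Cm) {
    volts <- c(protocol$holding, V_step, protocol$tail_voltage)
    n0 <- n_inf(protocol$holding, gating)  # steady at holding before sweep
    trace <- numeric(0)
    for (k in seq_along(volts)) {
      if (ns[k] == 0L) next
      V <- volts[k]
      ni <- n_inf(V, gating)
      tau <- tau_act(V, gating)
      t_loc <- seq_len(ns[k]) * dt_ms
      n_t <- ni + (n0 - ni) * exp(-t_loc / tau)
      I <- gating$g_max * n_t * (V - gating$E_rev) +
        gating$g_leak * (V - gating$E_leak)
      trace <- c(trace, I)
      n0 <- n_t[length(n_t)]
    }
    trace + .filtered_noise(n_total, noise_sd, protocol$sample_rate)
  }

  lapply(seq_len(n_cells), function(ci) {
    Rs <- rlnorm(1L, rs_dist$meanlog, rs_dist$sdlog)
    Cm <- max(2, rnorm(1L, cm_dist$mean, cm_dist$sd))
    sweeps <- vapply(protocol$step_levels, sweep_for, numeric(n_total), Cm = Cm)
    colnames(sweeps) <- protocol$step_levels
    structure(list(sweeps = sweeps, time_ms = time_ms, protocol = protocol,
                   meta = list(id = sprintf("%s%03d", cell_prefix, ci),
                               Cm = Cm, Rs = Rs, group = group),
                   truth = gating),
              class = "kv_recording")
  })
}

#' @export
print.kv_recording <- function(x, ...) {
  cat(sprintf("Whole-cell recording %s: %d sweeps (%s mV), %d samples @ %g kHz, Cm %.1f pF, Rs %.2f MOhm\n",
              x$meta$id, ncol(x$sweeps),
              paste(range(x$protocol$step_levels), collapse = ".."),
              nrow(x$sweeps), x$protocol$sample_rate / 1000,
              x$meta$Cm, x$meta$Rs))
  invisible(x)
}
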