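# Whole-cell patch-clamp analysis: series-resistance quality control,
# steady-state current densities, tail-current extraction, two-state
# Boltzmann fits of the voltage dependence of activation, G-V normalization,
# and many-vs-control group summaries.
#
# The fitted equation is the two-state Boltzmann
#   I = I_min + (I_max - I_min) / (1 + exp((V - Vh) / s)),
# under whose sign convention an activation curve rising with V has s < 0.
# The fitter leaves s unconstrained and reports it signed; compare |s| when a
# slope-factor magnitude is wanted.

RS_EXCLUSION_MOHM <- 7

#' Series-resistance quality control
#'
#' Keeps recordings with Rs strictly below 7 MOhm; recordings at or above the
#' threshold, or with missing Rs, are excluded and listed in the log.
#' Retained recordings are passed through unmodified.
#'
#' @param recordings List of recordings from [gen_recordings()] (or any list
#'   whose elements carry `meta$Rs` and `meta$id`).
#' @param rs_max Exclusion threshold in MOhm (exclusive bound for keeping).
#' @return List with `kept` (sub-list of recordings) and `log`
#'   (`data.frame` of excluded ids with `Rs` and `reason`).
#' @export
qc_filter <- function(recordings, rs_max = RS_EXCLUSION_MOHM) {
  keep <- logical(length(recordings))
  log_rows <- list()
  for (i in seq_along(recordings)) {
    rs <- recordings[[i]]$meta$Rs
    id <- recordings[[i]]$meta$id %||% sprintf("recording%03d", i)
    if (is.null(rs) || is.na(rs)) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(id = id, Rs = NA_real_, reason = "missing Rs")
    } else if (rs >= rs_max) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(id = id, Rs = rs,
                   reason = sprintf("Rs >= %g MOhm", rs_max))
    } else {
      keep[i] <- TRUE
    }
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(id = character(0), Rs = numeric(0), reason = character(0))
  list(kept = recordings[keep], log = log_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# index ranges of the three protocol segments within a sweep
.segment_index <- function(protocol) {
  ns <- .proto_samples(protocol)
  hold <- seq_len(ns[["holding"]])
  step <- ns[["holding"]] + seq_len(ns[["step"]])
  tail <- ns[["holding"]] + ns[["step"]] + seq_len(ns[["tail"]])
  list(holding = hold, step = step, tail = tail)
}

#' Steady-state current density at a step voltage
#'
#' Mean current over the final fraction of the voltage step, divided by the
#' cell's membrane capacitance.
#'
#' @param rec A recording.
#' @param at_voltage Step voltage (mV); must be one of the protocol's levels.
#' @param steady_frac Final fraction of the step to average (default 10%).
#' @return Current density in pA/pF.
#' @export
steady_state_density <- function(rec, at_voltage = 20, steady_frac = 0.1) {
  lvl <- match(at_voltage, rec$protocol$step_levels)
  if (is.na(lvl)) {
    stop("voltage ", at_voltage, " mV is not a protocol step level")
  }
  idx <- .segment_index(rec$protocol)$step
  n_last <- max(1L, round(length(idx) * steady_frac))
  window <- idx[(length(idx) - n_last + 1L):length(idx)]
  mean(rec$sweeps[window, lvl]) / rec$meta$Cm
}

#' Extract tail-current amplitudes per pre-pulse voltage
#'
#' For each sweep, the tail-current amplitude is the extremum of
#' `I - I_tail_steady` within the first `window_ms` of the tail after a short
#' blanking window (capacitive-transient guard), where `I_tail_steady` is the
#' mean over the final fraction of the tail. The trace is boxcar-smoothed
#' over `smooth_ms` before the extremum is taken: the extremum of a raw noisy
#' trace is biased away from the steady level (a max over many noisy samples),
#' which distorts the activation curve; smoothing attenuates the peak by a
#' factor that is constant across sweeps (the tail relaxation rate is set by
#' the fixed tail voltage), so the voltage dependence is unaffected. The
#' amplitude keeps its sign, so rising and decaying tails are measured
#' consistently and the amplitudes across pre-pulse voltages trace the
#' activation curve.
#'
#' @param rec A recording.
#' @param blank_ms Blanking window at the start of the tail (ms).
#' @param window_ms Search window for the extremum after the blank (ms).
#' @param smooth_ms Boxcar width for pre-measurement smoothing (ms); 0
#'   disables.
#' @param steady_frac Final fraction of the tail averaged as the steady level.
#' @return `data.frame` with `voltage` (pre-pulse, mV) and `amplitude` (pA).
#' @export
extract_tail_amplitudes <- function(rec, blank_ms = 0.5, window_ms = 25,
                                    smooth_ms = 25, steady_frac = 0.1) {
  seg <- .segment_index(rec$protocol)$tail
  per_ms <- rec$protocol$sample_rate / 1000
  n_blank <- ceiling(blank_ms * per_ms)
  n_window <- round(window_ms * per_ms)
  if (n_blank + n_window > length(seg)) {
    stop("tail segment shorter than blanking plus search window")
  }
  n_last <- max(1L, round(length(seg) * steady_frac))
  steady_idx <- seg[(length(seg) - n_last + 1L):length(seg)]
  search_idx <- seg[(n_blank + 1L):(n_blank + n_window)]
  n_sm <- max(1L, round(smooth_ms * per_ms))
  kern <- rep(1 / n_sm, n_sm)
  amps <- vapply(seq_len(ncol(rec$sweeps)), function(j) {
    steady <- mean(rec$sweeps[steady_idx, j])
    trace <- rec$sweeps[seg, j]
    if (n_sm > 1L) {
      trace <- as.numeric(stats::filter(trace, kern, sides = 1L))
    }
    dev <- trace[(n_blank + 1L):(n_blank + n_window)] - steady
    dev <- dev[is.finite(dev)]
    dev[which.max(abs(dev))]
  }, numeric(1L))
  data.frame(voltage = rec$protocol$step_levels, amplitude = amps)
}

#' Fit a two-state Boltzmann function to tail amplitudes
#'
#' Nonlinear least squares (Levenberg-Marquardt) on
#' `I = I_min + (I_max - I_min) / (1 + exp((V - Vh)/s))`. Initial values:
#' `I_min = min(amplitudes)`, `I_max = max(amplitudes)`, `Vh` at the voltage
#' nearest the half-range crossing, `s = -8` mV (activation convention).
#'
#' @param voltages Pre-pulse voltages (mV), >= 4 distinct values.
#' @param amplitudes Tail amplitudes (pA), same length.
#' @param s_init Initial slope (mV).
#' @param max_iter Iteration cap.
#' @return Object of class `"kv_boltzmann"`: `I_min`, `I_max`, `Vh`, `s`
#'   (signed as fitted), `rss`, `n_points`, `fitted`.
#' @export
fit_boltzmann <- function(voltages, amplitudes, s_init = -8, max_iter = 1000) {
  stopifnot(length(voltages) == length(amplitudes))
  ok <- is.finite(voltages) & is.finite(amplitudes)
  voltages <- voltages[ok]; amplitudes <- amplitudes[ok]
  if (length(unique(voltages)) < 4L) {
    stop("need at least 4 distinct voltages for a Boltzmann fit")
  }
  rng <- range(amplitudes)
  if (diff(rng) <= max(1e-12, 1e-9 * max(abs(rng)))) {
    stop("amplitudes are flat; Boltzmann parameters are not identifiable")
  }
  mid <- mean(rng)
  start <- list(I_min = rng[1L], I_max = rng[2L],
                Vh = voltages[which.min(abs(amplitudes - mid))], s = s_init)
  df <- data.frame(V = voltages, I = amplitudes)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I_min + (I_max - I_min) / (1 + exp((V - Vh) / s)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter, ftol = 1e-12, ptol = 1e-10)),
    error = function(e) stop("Boltzmann fit failed: ", conditionMessage(e)))
  cf <- coef(fit)
  structure(list(I_min = unname(cf["I_min"]), I_max = unname(cf["I_max"]),
                 Vh = unname(cf["Vh"]), s = unname(cf["s"]),
                 rss = sum(residuals(fit)^2), n_points = nrow(df),
                 fitted = fitted(fit), voltages = voltages),
            class = "kv_boltzmann")
}

#' @export
print.kv_boltzmann <- function(x, ...) {
  cat(sprintf("Boltzmann fit: Vh = %.2f mV, s = %.2f mV (|s| = %.2f), I_min = %.1f, I_max = %.1f pA (n = %d, RSS = %.3g)\n",
              x$Vh, x$s, abs(x$s), x$I_min, x$I_max, x$n_points, x$rss))
  invisible(x)
}

#' Evaluate a fitted (or specified) Boltzmann curve
#' @param fit A `"kv_boltzmann"` object.
#' @param V Voltages (mV).
#' @return Predicted amplitudes (pA).
#' @export
predict_boltzmann <- function(fit, V) {
  fit$I_min + (fit$I_max - fit$I_min) / (1 + exp((V - fit$Vh) / fit$s))
}

#' Normalised conductance-voltage curve
#'
#' `(amplitude - I_min) / (I_max - I_min)` per voltage; values may slightly
#' exceed `[0, 1]` because of noise and are deliberately not clipped.
#'
#' @param fit A `"kv_boltzmann"` object.
#' @param voltages,amplitudes Data to normalise (default: the fit's own).
#' @return `data.frame` with `voltage` and `g_norm`.
#' @export
normalize_gv <- function(fit, voltages = NULL, amplitudes = NULL) {
  if (is.null(voltages)) voltages <- fit$voltages
  if (is.null(amplitudes)) amplitudes <- fit$fitted
  denom <- fit$I_max - fit$I_min
  if (denom == 0) stop("I_max equals I_min; G-V normalization undefined")
  data.frame(voltage = voltages, g_norm = (amplitudes - fit$I_min) / denom)
}

.stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "ns")))
}

#' Group summary with normalization to a reference group
#'
#' Per-group mean +/- SEM of a per-cell measurement (e.g. current density at
#' +20 mV or fitted Vh), normalised to the reference-group mean, with
#' many-vs-control Dunnett comparisons against the reference and significance
#' stars at P <= 0.05 / 0.01 / 0.001.
#'
#' @param df `data.frame` with columns `group` and `value` (one row per cell).
#' @param reference_group Group to normalise to and compare against.
#' @param normalize If `FALSE`, skip normalization (e.g. for Vh summaries).
#' @return List with `summary` (`data.frame`: group, n, mean, sem, norm_mean,
#'   norm_sem, p_value, stars) and `dunnett` (the `multcomp::glht` summary).
#' @export
group_summary <- function(df, reference_group, normalize = TRUE) {
  stopifnot(all(c("group", "value") %in% names(df)))
  if (!reference_group %in% df$group) {
    stop("reference group '", reference_group, "' absent from data")
  }
  if (length(unique(df$group)) < 2L) stop("need at least 2 groups")
  df$group <- stats::relevel(factor(df$group), ref = reference_group)
  agg <- do.call(rbind, lapply(split(df$value, df$group), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  agg$group <- rownames(agg); rownames(agg) <- NULL
  ref_mean <- agg$mean[agg$group == reference_group]
  if (normalize) {
    agg$norm_mean <- agg$mean / ref_mean
    agg$norm_sem <- agg$sem / abs(ref_mean)
  }
  fit <- stats::aov(value ~ group, data = df)
  dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett")))
  pvals <- as.numeric(dn$test$pvalues)
  cmp_groups <- sub(" - .*$", "", names(dn$test$coefficients))
  agg$p_value <- NA_real_
  agg$p_value[match(cmp_groups, agg$group)] <- pvals
  agg$stars <- ifelse(is.na(agg$p_value), "", .stars(agg$p_value))
  agg <- agg[, c("group", setdiff(names(agg), "group"))]
  list(summary = agg, dunnett = dn)
}
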