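# Tetramer co-assembly model for mixtures of Kv7 and silent Kv (KvS) subunits.
#
# Functional Kv channels are tetramers of pore-forming alpha-subunits. When a
# cell co-expresses several subunit species (e.g. wild-type Kv7.2 together with
# a pore-dead KvS mutant), the distribution of channel compositions at the
# membrane determines the macroscopic current. This file implements that model:
# composition distributions under several assembly rules (fully stochastic and
# three homomer-preference variants), conductance/trafficking rules for three
# imaginable modes of Kv7-KvS interaction, relative whole-cell current
# predictions, and inversion of the model to fit a homomer-preference factor
# from an observed current ratio.

TETRAMER_SIZE <- 4L

#' Define a channel subunit species
#'
#' @param name Unique text label, e.g. `"Kv7.2"`.
#' @param family Either `"KV7"` (pore-forming, trafficking-competent) or
#'   `"KVS"` (silent subunit: no functional homomeric channel, ER-retained
#'   when expressed alone).
#' @param pore_functional `FALSE` for dominant-negative pore mutants
#'   (e.g. GYG->AAA), `TRUE` for wild type.
#' @param availability Fraction of the available subunit pool in `[0, 1]`.
#'   Within a mix, availabilities must sum to 1.
#' @return A one-row `data.frame` describing the species.
#' @seealso [kv_mix()]
#' @export
kv_species <- function(name, family = c("KV7", "KVS"), pore_functional = TRUE,
                       availability = NA_real_) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(pore_functional), length(pore_functional) == 1L)
  if (!is.na(availability) && (availability < 0 || availability > 1)) {
    stop("availability must lie in [0, 1]")
  }
  data.frame(name = name, family = family,
             pore_functional = pore_functional,
             availability = as.numeric(availability),
             stringsAsFactors = FALSE)
}

#' Assemble a subunit mix
#'
#' Combines species into a mix whose availabilities sum to one. Availabilities
#' can be given directly, derived from transfection mass ratios (treated as
#' directly proportional to mass, so a 4:1 mass ratio gives 0.8/0.2), or forced
#' equal with `equalize = TRUE` -- the idealisation used when reasoning about
#' "equally available" subunits irrespective of the transfected ratio.
#'
#' @param ... One or more species created by [kv_species()] (or a single
#'   `data.frame` of such rows).
#' @param mass_ratio Optional numeric vector of relative plasmid masses, one
#'   per species; converted to availabilities by normalisation.
#' @param equalize If `TRUE`, all species get equal availability.
#' @return A `data.frame` of class `"kv_mix"`.
#' @examples
#' kv_mix(kv_species("Kv7.2", "KV7"),
#'        kv_species("Kv8.1dn", "KVS", pore_functional = FALSE),
#'        equalize = TRUE)
#' @export
kv_mix <- function(..., mass_ratio = NULL, equalize = FALSE) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1L]]) &&
      !inherits(parts[[1L]], "kv_mix") && nrow(parts[[1L]]) > 1L) {
    mix <- parts[[1L]]
  } else {
    mix <- do.call(rbind, parts)
  }
  stopifnot(nrow(mix) >= 1L)
  if (anyDuplicated(mix$name)) stop("species names must be unique")
  if (equalize) {
    mix$availability <- rep(1 / nrow(mix), nrow(mix))
  } else if (!is.null(mass_ratio)) {
    stopifnot(length(mass_ratio) == nrow(mix), all(mass_ratio >= 0),
              sum(mass_ratio) > 0)
    mix$availability <- mass_ratio / sum(mass_ratio)
  }
  if (anyNA(mix$availability)) {
    stop("availabilities missing; supply them, mass_ratio, or equalize = TRUE")
  }
  if (any(mix$availability < 0)) stop("availabilities must be nonnegative")
  if (abs(sum(mix$availability) - 1) > 1e-12) {
    stop("availabilities must sum to 1 (got ", sum(mix$availability), ")")
  }
  rownames(mix) <- NULL
  class(mix) <- c("kv_mix", "data.frame")
  mix
}

#' @export
print.kv_mix <- function(x, ...) {
  cat("Subunit mix (", nrow(x), " species)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Assembly rule
#'
#' @param variant One of `"stochastic"` (multinomial draws of 4 subunits),
#'   `"per_site"` (a nucleus subunit is drawn by availability and each of the
#'   three remaining positions is drawn with weight availability x
#'   `preference_f` for the nucleus species, availability x 1 otherwise),
#'   `"tetramer_class"` (multinomial probabilities reweighted by
#'   `preference_f` for homomeric compositions, then renormalised), or
#'   `"dimer_pairs"` (dimers drawn with weight `preference_f * p_i^2` for
#'   homodimers and `2 p_i p_j` for heterodimers, a tetramer being two
#'   independent dimers).
#' @param preference_f Homomer preference factor, >= 1. At `preference_f = 1`
#'   every variant reduces exactly to stochastic (multinomial) assembly.
#' @return A list of class `"kv_assembly_rule"`.
#' @export
assembly_rule <- function(variant = c("stochastic", "per_site",
                                      "tetramer_class", "dimer_pairs"),
                          preference_f = 1) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(preference_f), length(preference_f) == 1L,
            is.finite(preference_f), preference_f >= 1)
  structure(list(variant = variant, preference_f = preference_f),
            class = "kv_assembly_rule")
}

#' Conductance / trafficking rule for an interaction mode
#'
#' The three imaginable modes of Kv7-KvS interaction make different
#' predictions for pore-mutant co-expression:
#' \describe{
#'   \item{single_pore_heteromer}{both species contribute to one shared pore;
#'     a tetramer conducts iff it contains at least one Kv7 subunit and no
#'     pore-dead subunit of either family.}
#'   \item{independent_channels}{species form only homotypic channels side by
#'     side; KvS homomers conduct with `standalone_kvs_conductance`.}
#'   \item{beta_subunit}{KvS acts as an ancillary subunit outside the pore;
#'     conduction depends only on the Kv7 subunits' pore status.}
#' }
#' Under the defaults, compositions made purely of KvS subunits have
#' trafficking weight 0 (ER retention) and all Kv7-containing compositions
#' weight 1; in `independent_channels` mode homotypic KvS channels traffic by
#' that mode's premise. Custom per-composition weights may be supplied as
#' functions of the integer composition.
#'
#' @param mode Interaction mode (see Details).
#' @param conductance_weight,trafficking_weight Optional
#'   `function(counts, mix) -> numeric` overriding the defaults, where
#'   `counts` is an integer vector (one entry per species, summing to 4).
#' @param standalone_kvs_conductance Relative unitary conductance of a
#'   homotypic KvS channel, used only by `independent_channels`.
#' @return A list of class `"kv_conductance_rule"`.
#' @export
conductance_rule <- function(mode = c("single_pore_heteromer",
                                      "independent_channels", "beta_subunit"),
                             conductance_weight = NULL,
                             trafficking_weight = NULL,
                             standalone_kvs_conductance = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(standalone_kvs_conductance),
            standalone_kvs_conductance >= 0,
            is.finite(standalone_kvs_conductance))
  structure(list(mode = mode,
                 conductance_weight = conductance_weight,
                 trafficking_weight = trafficking_weight,
                 standalone_kvs_conductance = standalone_kvs_conductance),
            class = "kv_conductance_rule")
}

#' Enumerate all tetramer compositions of a mix
#'
#' @param mix A [kv_mix()].
#' @return Integer matrix, one row per composition (rows sum to 4), columns
#'   named by species, in deterministic lexicographic order with the count of
#'   the first species decreasing ((4,0), (3,1), ... for two species).
#' @export
enumerate_compositions <- function(mix) {
  k <- nrow(mix)
  stopifnot(k >= 1L)
  rec <- function(remaining, slots) {
    if (slots == 1L) return(matrix(remaining, ncol = 1L))
    out <- lapply(seq.int(remaining, 0L), function(first) {
      rest <- rec(remaining - first, slots - 1L)
      cbind(first, rest, deparse.level = 0L)
    })
    do.call(rbind, out)
  }
  comps <- rec(TETRAMER_SIZE, k)
  storage.mode(comps) <- "integer"
  colnames(comps) <- mix$name
  comps
}

# multinomial pmf over rows of a composition matrix; tolerates zero
# availabilities (0^0 = 1)
.multinom_probs <- function(comps, p, size = TETRAMER_SIZE) {
  apply(comps, 1L, function(cnt) {
    coef <- exp(lgamma(size + 1) - sum(lgamma(cnt + 1)))
    coef * prod(p^cnt)
  })
}

.comp_key <- function(comps) apply(comps, 1L, paste, collapse = ",")

#' Analytic composition distribution under an assembly rule
#'
#' @param mix A [kv_mix()].
#' @param rule An [assembly_rule()].
#' @return A list of class `"kv_composition_distribution"` with elements
#'   `compositions` (matrix from [enumerate_compositions()]) and
#'   `probabilities` (nonnegative, summing to 1).
#' @examples
#' mix <- kv_mix(kv_species("wt", "KV7"), kv_species("dn", "KVS", FALSE),
#'               equalize = TRUE)
#' d <- composition_distribution(mix, assembly_rule("stochastic"))
#' d$probabilities[1]  # P(all-wild-type tetramer) = 1/16
#' @export
composition_distribution <- function(mix, rule) {
  stopifnot(inherits(rule, "kv_assembly_rule"))
  comps <- enumerate_compositions(mix)
  p <- mix$availability
  k <- nrow(mix)
  f <- rule$preference_f
  probs <- switch(
    rule$variant,
    stochastic = .multinom_probs(comps, p),
    per_site = {
      # law of total probability over the nucleus subunit
      acc <- numeric(nrow(comps))
      for (i in seq_len(k)) {
        if (p[i] == 0) next
        q <- p * ifelse(seq_len(k) == i, f, 1)
        q <- q / sum(q)
        has_i <- comps[, i] >= 1L
        rest <- comps
        rest[, i] <- rest[, i] - 1L
        contrib <- numeric(nrow(comps))
        contrib[has_i] <- .multinom_probs(rest[has_i, , drop = FALSE], q,
                                          size = TETRAMER_SIZE - 1L)
        acc <- acc + p[i] * contrib
      }
      acc
    },
    tetramer_class = {
      w <- .multinom_probs(comps, p)
      homo <- apply(comps, 1L, max) == TETRAMER_SIZE
      w[homo] <- w[homo] * f
      w / sum(w)
    },
    dimer_pairs = {
      # dimer law, then tetramer = convolution of two independent dimers
      dimers <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
      dw <- apply(dimers, 1L, function(ij) {
        i <- ij[1L]; j <- ij[2L]
        if (i == j) f * p[i]^2 else 2 * p[i] * p[j]
      })
      dw <- dw / sum(dw)
      key <- .comp_key(comps)
      acc <- numeric(nrow(comps))
      for (a in seq_len(nrow(dimers))) for (b in seq_len(nrow(dimers))) {
        cnt <- tabulate(c(dimers[a, ], dimers[b, ]), nbins = k)
        idx <- match(paste(cnt, collapse = ","), key)
        acc[idx] <- acc[idx] + dw[a] * dw[b]
      }
      acc
    },
    stop("unknown assembly variant: ", rule$variant)
  )
  stopifnot(all(probs >= -1e-12), abs(sum(probs) - 1) < 1e-9)
  structure(list(compositions = comps, probabilities = pmax(probs, 0)),
            class = "kv_composition_distribution")
}

#' Monte-Carlo simulation of tetramer assembly
#'
#' Draws tetramers one by one following the rule's generative process (not by
#' sampling from the analytic law), so the empirical distribution serves as an
#' independent oracle for [composition_distribution()]. `per_site` draws a
#' nucleus and three weighted sites; `tetramer_class` and `dimer_pairs` use
#' exact rejection sampling (heteromeric draws accepted with probability
#' `1/preference_f`).
#'
#' @inheritParams composition_distribution
#' @param n_draws Number of tetramers to assemble (>= 1).
#' @param seed Optional integer seed; same seed gives identical output.
#' @return As [composition_distribution()], with empirical frequencies, plus
#'   `n_draws`.
#' @export
simulate_assembly <- function(mix, rule, n_draws, seed = NULL) {
  stopifnot(inherits(rule, "kv_assembly_rule"))
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1) {
    stop("n_draws must be >= 1")
  }
  n_draws <- as.integer(n_draws)
  if (!is.null(seed)) set.seed(seed)
  p <- mix$availability
  k <- nrow(mix)
  f <- rule$preference_f
  comps <- enumerate_compositions(mix)
  key <- .comp_key(comps)

  draw_cols <- switch(
    rule$variant,
    stochastic = rmultinom(n_draws, TETRAMER_SIZE, p),
    per_site = {
      nuclei <- sample.int(k, n_draws, replace = TRUE, prob = p)
      out <- matrix(0L, nrow = k, ncol = n_draws)
      for (i in seq_len(k)) {
        sel <- which(nuclei == i)
        if (!length(sel)) next
        q <- p * ifelse(seq_len(k) == i, f, 1)
        sites <- rmultinom(length(sel), TETRAMER_SIZE - 1L, q)
        sites[i, ] <- sites[i, ] + 1L
        out[, sel] <- sites
      }
      out
    },
    tetramer_class = {
      got <- matrix(0L, nrow = k, ncol = 0L)
      while (ncol(got) < n_draws) {
        m <- max(2L * (n_draws - ncol(got)), 100L)
        cand <- rmultinom(m, TETRAMER_SIZE, p)
        homo <- apply(cand, 2L, max) == TETRAMER_SIZE
        keep <- homo | (runif(m) < 1 / f)
        got <- cbind(got, cand[, keep, drop = FALSE])
      }
      got[, seq_len(n_draws), drop = FALSE]
    },
    dimer_pairs = {
      draw_dimers <- function(n) {
        got <- matrix(0L, nrow = k, ncol = 0L)
        while (ncol(got) < n) {
          m <- max(2L * (n - ncol(got)), 100L)
          cand <- rmultinom(m, 2L, p)
          homo <- apply(cand, 2L, max) == 2L
          keep <- homo | (runif(m) < 1 / f)
          got <- cbind(got, cand[, keep, drop = FALSE])
        }
        got[, seq_len(n), drop = FALSE]
      }
      draw_dimers(n_draws) + draw_dimers(n_draws)
    },
    stop("unknown assembly variant: ", rule$variant)
  )

  freq <- tabulate(match(apply(draw_cols, 2L, paste, collapse = ","), key),
                   nbins = nrow(comps))
  structure(list(compositions = comps, probabilities = freq / n_draws,
                 n_draws = n_draws),
            class = "kv_composition_distribution")
}

#' Total variation distance between two composition distributions
#'
#' @param d1,d2 Objects from [composition_distribution()] /
#'   [simulate_assembly()] over the same mix.
#' @return TVD in `[0, 1]`.
#' @export
tv_distance <- function(d1, d2) {
  stopifnot(identical(dim(d1$compositions), dim(d2$compositions)))
  sum(abs(d1$probabilities - d2$probabilities)) / 2
}

# per-composition conducting weight g(c) * trafficking t(c); vectorised over
# rows of the composition matrix
.conducting_weights <- function(comps, mix, cond) {
  kv7 <- mix$family == "KV7"
  dead <- !mix$pore_functional
  n_kv7 <- comps[, kv7, drop = FALSE]
  n_kv7 <- if (ncol(n_kv7)) rowSums(n_kv7) else numeric(nrow(comps))
  n_dead <- comps[, dead, drop = FALSE]
  n_dead <- if (ncol(n_dead)) rowSums(n_dead) else numeric(nrow(comps))
  n_dead_kv7 <- comps[, kv7 & dead, drop = FALSE]
  n_dead_kv7 <- if (ncol(n_dead_kv7)) rowSums(n_dead_kv7) else numeric(nrow(comps))

  g <- switch(cond$mode,
    single_pore_heteromer = as.numeric(n_kv7 >= 1 & n_dead == 0),
    beta_subunit = as.numeric(n_kv7 >= 1 & n_dead_kv7 == 0),
    stop("composition-level conductance undefined for mode ", cond$mode))
  tw <- as.numeric(n_kv7 >= 1)  # pure-KvS tetramers are ER-retained
  if (!is.null(cond$conductance_weight)) {
    g <- apply(comps, 1L, cond$conductance_weight, mix)
  }
  if (!is.null(cond$trafficking_weight)) {
    tw <- apply(comps, 1L, cond$trafficking_weight, mix)
  }
  stopifnot(all(is.finite(g)), all(is.finite(tw)), all(g >= 0), all(tw >= 0))
  g * tw
}

# expected conducting weight per assembled channel for a mix under a mode
.conducting_sum <- function(mix, rule, cond) {
  if (cond$mode == "independent_channels") {
    # no cross-species co-assembly: each species' share of the pool forms
    # homotypic channels
    per_species <- ifelse(mix$family == "KV7",
                          as.numeric(mix$pore_functional),
                          as.numeric(mix$pore_functional) *
                            cond$standalone_kvs_conductance)
    return(sum(mix$availability * per_species))
  }
  d <- composition_distribution(mix, rule)
  sum(d$probabilities * .conducting_weights(d$compositions, mix, cond))
}

.baseline_mix <- function(test_mix, baseline = c("kv7_alone", "wt_mix")) {
  baseline <- match.arg(baseline)
  if (baseline == "kv7_alone") {
    b <- test_mix[test_mix$family == "KV7", , drop = FALSE]
    if (!nrow(b)) stop("kv7_alone baseline requires a KV7 species in the mix")
    b$availability <- b$availability / sum(b$availability)
  } else {
    b <- test_mix
    b$pore_functional <- TRUE
  }
  class(b) <- c("kv_mix", "data.frame")
  b
}

#' Predict the relative whole-cell current for a subunit mix
#'
#' The expected conducting weight \eqn{\sum_c P(c)\, g(c)\, t(c)} of the test
#' mix is divided by the same sum for a baseline: `"kv7_alone"` (the mix's
#' Kv7 species alone at availability 1) or `"wt_mix"` (the same mix with every
#' pore-dead species made pore-functional). Under fully stochastic assembly of
#' equally available wild-type Kv7 and pore-dead KvS subunits this yields
#' (1/2)^4 = 1/16 against the Kv7-alone baseline: only all-wild-type
#' tetramers conduct.
#'
#' @param test_mix A [kv_mix()] containing at least one KV7 species.
#' @param rule An [assembly_rule()].
#' @param cond A [conductance_rule()].
#' @param baseline `"kv7_alone"` or `"wt_mix"`.
#' @return List of class `"kv_current_prediction"` with `relative_current`,
#'   `baseline`, `mode`, and the two conducting-weight sums.
#' @export
predict_relative_current <- function(test_mix, rule, cond,
                                     baseline = c("kv7_alone", "wt_mix")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(cond, "kv_conductance_rule"))
  if (!any(test_mix$family == "KV7")) {
    stop("test mix must contain at least one KV7 species")
  }
  bmix <- .baseline_mix(test_mix, baseline)
  num <- .conducting_sum(test_mix, rule, cond)
  den <- .conducting_sum(bmix, rule, cond)
  if (den <= 0) {
    stop("baseline mix induces no conducting channels (sum = 0)")
  }
  structure(list(relative_current = num / den, baseline = baseline,
                 mode = cond$mode, test_sum = num, baseline_sum = den),
            class = "kv_current_prediction")
}

#' @export
print.kv_current_prediction <- function(x, ...) {
  cat(sprintf("Relative current %.6g (mode %s, baseline %s)\n",
              x$relative_current, x$mode, x$baseline))
  invisible(x)
}

#' Fit the homomer-preference factor from an observed current ratio
#'
#' Inverts [predict_relative_current()] as a function of `preference_f` by
#' bisection on `[1, f_max]`, after numerically checking on a log grid that
#' the prediction is monotone in f for the given mix/mode. An observed ratio
#' outside the attainable range raises an infeasibility error naming that
#' range. A roughly 50% residual current for an equal wild-type-Kv7 /
#' pore-dead-KvS mix corresponds to f of about 6.9 (per_site) or 14
#' (tetramer_class) and is unattainable under dimer_pairs.
#'
#' @param observed_ratio Observed relative current in `(0, 1]`.
#' @param mix Test mix, as for [predict_relative_current()].
#' @param variant Assembly-rule variant to fit under.
#' @param cond A [conductance_rule()].
#' @param baseline Baseline for the ratio.
#' @param f_max Upper bracket for the preference factor.
#' @param tol Convergence tolerance on the predicted ratio.
#' @return List with `preference_f`, `achieved_ratio`, `variant`,
#'   `attainable_range`.
#' @export
fit_preference <- function(observed_ratio, mix, variant,
                           cond = conductance_rule("single_pore_heteromer"),
                           baseline = c("wt_mix", "kv7_alone"),
                           f_max = 1e6, tol = 1e-6) {
  baseline <- match.arg(baseline)
  stopifnot(is.numeric(observed_ratio), length(observed_ratio) == 1L,
            observed_ratio > 0)
  ratio_at <- function(f) {
    predict_relative_current(mix, assembly_rule(variant, f), cond,
                             baseline)$relative_current
  }
  grid_f <- unique(c(1, 10^seq(0, log10(f_max), length.out = 25L)))
  grid_r <- vapply(grid_f, ratio_at, numeric(1L))
  dr <- diff(grid_r)
  if (!(all(dr >= -1e-12) || all(dr <= 1e-12))) {
    stop("prediction is not monotone in preference_f for this mix/mode; ",
         "bisection is not applicable")
  }
  rng <- range(grid_r)
  if (observed_ratio < rng[1L] - tol || observed_ratio > rng[2L] + tol) {
    stop(sprintf(paste0("observed ratio %.6g is outside the attainable range ",
                        "[%.6g, %.6g] for variant '%s' over f in [1, %g]"),
                 observed_ratio, rng[1L], rng[2L], variant, f_max))
  }
  increasing <- grid_r[length(grid_r)] >= grid_r[1L]
  lo <- 1; hi <- f_max
  for (iter in seq_len(200L)) {
    mid <- sqrt(lo * hi)  # bisect in log space: f spans orders of magnitude
    r_mid <- ratio_at(mid)
    if (abs(r_mid - observed_ratio) < tol) {
      return(list(preference_f = mid, achieved_ratio = r_mid,
                  variant = variant, attainable_range = rng))
    }
    below <- if (increasing) r_mid < observed_ratio else r_mid > observed_ratio
    if (below) lo <- mid else hi <- mid
    if (hi / lo - 1 < 1e-12) break
  }
  f_hat <- sqrt(lo * hi)
  list(preference_f = f_hat, achieved_ratio = ratio_at(f_hat),
       variant = variant, attainable_range = rng)
}

#' Compare the three interaction modes for one mix
#'
#' Evaluates [predict_relative_current()] for each imaginable interaction
#' mode with a shared mix and assembly rule, reproducing the model
#' discrimination logic: a pore-dead Kv7 with wild-type KvS yields ~0 under a
#' shared single pore, ~0 under a beta-subunit model, but a residual current
#' under independent channels; a pore-dead KvS with wild-type Kv7 leaves a
#' beta-subunit model entirely unaffected (ratio 1 against the wild-type
#' mix).
#'
#' @inheritParams predict_relative_current
#' @param cond_base Conductance rule supplying shared settings (notably
#'   `standalone_kvs_conductance`); its `mode` is ignored.
#' @return `data.frame` with one row per mode.
#' @export
compare_modes <- function(test_mix, rule,
                          cond_base = conductance_rule(),
                          baseline = c("wt_mix", "kv7_alone")) {
  baseline <- match.arg(baseline)
  modes <- c("single_pore_heteromer", "independent_channels", "beta_subunit")
  rows <- lapply(modes, function(m) {
    cond <- conductance_rule(
      m,
      conductance_weight = cond_base$conductance_weight,
      trafficking_weight = cond_base$trafficking_weight,
      standalone_kvs_conductance = cond_base$standalone_kvs_conductance)
    pred <- predict_relative_current(test_mix, rule, cond, baseline)
    data.frame(mode = m, relative_current = pred$relative_current,
               baseline = baseline, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
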