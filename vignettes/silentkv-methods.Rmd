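---
title: "Models and methods behind silentkv"
author: "silentkv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind silentkv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silentkv)
```

silentkv analyses the functional interaction between Kv7 potassium-channel
subunits and the electrically silent Kv subunits (KvS: Kv5, Kv6, Kv8, Kv9).
KvS cannot form functional channels on their own — expressed alone they are
retained in the endoplasmic reticulum — but they can co-assemble with a
partner subunit and reshape its current. The package implements the
quantitative backbone of such a study: a tetramer co-assembly model with
dominant-negative predictions, patch-clamp voltage-dependence analysis, a
single-cell co-expression screen, PLA image quantification, and qPCR /
surface-expression normalizations. Every stage runs on synthetic data with
planted ground truth, so each estimator can be checked against a known
answer before it is pointed at real data.

## The co-assembly model

A functional channel is a tetramer. Given a mix of subunit species with
availabilities $p_1, \dots, p_k$ (summing to 1), the fully stochastic model
assembles each channel by four independent draws, so composition
$c = (c_1, \dots, c_k)$, $\sum_i c_i = 4$, has multinomial probability
$\binom{4}{c_1 \cdots c_k} \prod_i p_i^{c_i}$. With equal availability of a
wild-type Kv7 and a pore-dead subunit, the all-wild-type tetramer — the only
one that conducts if all four subunits line a single shared pore — has
probability $(1/2)^4 = 1/16$, i.e. a 93.75% predicted current reduction.

Observed dominant-negative effects are often weaker than that, which the
model expresses as a homomer preference factor $f \ge 1$. Because the data
do not identify *where* in the assembly pathway the preference acts, three
generative variants are provided and reported side by side:

* **per_site** — a nucleus subunit is drawn by availability; each of the
  three remaining positions is drawn with weight $f p_i$ for the nucleus
  species and $p_j$ otherwise. For an equal two-species mix,
  $P(\text{homotetramer of species }i) = \tfrac12 u^3$ with $u = f/(f+1)$.
* **tetramer_class** — the multinomial law reweighted by $f$ on homomeric
  compositions, then renormalised. For an equal mix the homomer share is
  $f/(2f + 14)$.
* **dimer_pairs** — channels assemble from two independent dimers, with
  homodimers reweighted by $f$; the tetramer law is the convolution of the
  dimer law with itself. The all-homomer probability saturates at $1/4$ as
  $f \to \infty$, so this variant cannot produce arbitrarily mild
  dominant-negative effects.

At $f = 1$ all variants reduce exactly to the multinomial law (tested to
1e-12), and `simulate_assembly()` provides a generative Monte-Carlo oracle
for each variant that is independent of the analytic code path (per_site is
simulated literally; the reweighted variants by exact rejection sampling).

Whether a composition conducts depends on the interaction mode
(`conductance_rule()`):

* *single_pore_heteromer*: conducts iff it contains at least one Kv7 subunit
  and no pore-dead subunit; pure-KvS tetramers are ER-retained
  (trafficking weight 0).
* *independent_channels*: no cross-species co-assembly; KvS homomers conduct
  with a configurable standalone conductance. Under this mode's premise the
  KvS channels reach the surface, so their trafficking weight is 1.
* *beta_subunit*: KvS sits outside the pore; only the Kv7 subunits' pore
  status matters.

These give sharply different predictions for pore-mutant experiments: a
beta-subunit model predicts *no* effect of mutating the KvS pore (relative
current exactly 1 against the all-wild-type mix), while independent channels
predict a residual current when the Kv7 pore is mutated. Only the shared
single pore reproduces both a strong KvS-mutant effect and a near-zero
Kv7-mutant current.

`fit_preference()` inverts the prediction by bisection on $\log f$ over
$[1, 10^6]$ after verifying monotonicity on a log-spaced grid, converging to
1e-6 on the predicted ratio; an observed ratio outside the attainable range
raises an error naming that range. A 50% residual current maps to
$f \approx 6.9$ (per_site, from $u^3 = 2/3$), $f = 14$ (tetramer_class,
from $f/(f+14) = 1/2$), and is infeasible under dimer_pairs — one observed
ratio does not pin down "the" preference factor, which is why the package
always reports per variant.

Availabilities derive from transfection mass ratios proportionally (4:1
mass gives 0.8/0.2), with `equalize = TRUE` for the idealised
equal-availability reasoning; both entry points are exposed because the two
assumptions bracket the truth and neither is verifiable from current
amplitudes alone.

## Gating model and synthetic recordings

Sweeps follow a first-order activation gate with Boltzmann steady state

$$n_\infty(V) = \frac{1}{1 + e^{(V_h - V)/s}}, \qquad
  \tau(V) = \frac{\tau_{max}}{\cosh((V - V_h)/2s)},$$

and current $I = g_{max}\, n\, (V - E_{rev}) + g_{leak}(V - E_{leak})$ plus
Gaussian noise. Within each constant-voltage epoch the gate relaxes as an
exact exponential, so sweeps are computed piecewise-analytically — there is
no ODE solver and hence no solver tolerance entangled with downstream fit
accuracy. The $\cosh$ form of $\tau(V)$ is a conventional modelling choice;
all that matters downstream is that activation saturates within the step.
The acquisition low-pass filter (2.5 kHz at 5 kHz sampling) is emulated by
Gaussian smoothing of the noise term only, since the deterministic signal is
already band-limited and the real filter topology is immaterial at half the
sampling rate.

Defaults: holding −80 mV, 100 ms holding padding, 1500 ms steps from −100 to
+60 mV in 20 mV increments, 500 ms tail at −30 mV, 5 kHz sampling;
$V_h = -20$ mV, $s = 9$ mV, $g_{max} = 2$ nS, $E_{rev} = -86$ mV,
$\tau_{max} = 100$ ms; Cm ~ N(10, 1.5) pF, Rs lognormal around 4.5 MΩ.
These are ordinary values for Kv7-like currents in small transfected cells.

## Patch-clamp analysis

Recordings with series resistance ≥ 7 MΩ are excluded (strictly-below-7
kept; the boundary itself is excluded), with an exclusion log; Rs is
metadata only — compensation electronics are not modelled. Steady-state
current density is the mean over the final 10% of the step divided by Cm.

Voltage dependence comes from tail currents at the fixed tail potential:
per sweep, the amplitude is the extremum of $I - I_{tail,steady}$ within a
25 ms window after a 0.5 ms blank, where $I_{tail,steady}$ is the mean over
the final 10% of the tail. The trace is boxcar-averaged over 25 ms before
the extremum is taken. This filter matters: the extremum of a *raw* noisy
trace is a maximum over ~100 noisy samples and is therefore biased away
from the steady level, in the direction of each sweep's true deviation.
That bias distorts the activation curve deterministically — it drags the
fitted $V_h$ toward the tail potential's own activation level and flattens
the apparent slope — and at 5% trace noise it is large enough to push every
run outside ±1 mV. Averaging over roughly a third of the tail time constant
(τ ≈ 86 ms at −30 mV under the defaults) removes the bias while attenuating
the true peak by a factor that is *constant across sweeps*, because the tail
relaxation rate is set by the fixed tail voltage; a sweep-constant factor is
absorbed into $I_{max} - I_{min}$ and leaves $V_h$ and $s$ untouched. Both
window and filter are configurable and should be shortened for fast tails.

Amplitudes are fitted with the two-state Boltzmann
$I = I_{min} + (I_{max} - I_{min}) / (1 + e^{(V - V_h)/s})$ by
Levenberg–Marquardt least squares (initialised at the amplitude range, the
half-range crossing, and $s = -8$ mV). Under this equation's sign
convention an activation curve rising with voltage fits with $s < 0$; the
fitter leaves $s$ unconstrained and reports it signed, so compare $|s|$
between groups. G–V curves are $(I - I_{min})/(I_{max} - I_{min})$, not
clipped to $[0, 1]$. On noiseless synthetic data the full chain recovers
$V_h$ to better than 0.01 mV (the tail amplitude is exactly affine in
$n_\infty$ of the pre-pulse); at 5% noise, 100-seed simulations recover
$V_h$ within ±1 mV in every run and $|s|$ within 5% in ≈98 of 100, and a
planted +10 mV between-group shift is recovered with < 0.05 mV bias.

Group summaries report mean ± SEM, normalised to a reference group, with
Dunnett many-vs-control comparisons (via `multcomp` over `aov`) and stars at
P ≤ 0.05/0.01/0.001. Dunnett is the appropriate member of the usual test
family here because every comparison is against the same control.

## Single-cell co-expression screen

Counts are analysed raw except for the two deliberately separate
normalizations: dot-plot colour uses library-size-normalised, log1p,
per-gene z-scaled values (mean per cluster), while correlations use
$\log_2(\text{count} + 1)$ of raw counts. "Expressing" means count > 0, and
the 10% detection boundary is inclusive both for retaining cell types and
for dot-plot visibility flags.

`pcc_percentile()` ranks the Pearson correlation of an anchor–partner pair
against the anchor's correlation with every other gene detected in ≥ 3
cells with nonzero variance; the percentile counts genes *strictly* below,
with ties (including the partner itself) counted as not below, so a perfect
duplicate tops out at $100 (n-1)/n$. Zero-variance and barely-detected
genes are excluded from the null rather than assigned a correlation of 0,
which would dilute the null with undefined values.

`pcc_with_bootstrap()` resamples cells (the individual observations) with
replacement, n = 100, and summarises the resampled correlations
box-plot-style: quartile hinges and whiskers at the last resample within
1.5 interquartile ranges of the hinges. One statistical point deserves
emphasis: the *hinges* form a central 50% interval of a distribution centred
on the point estimate, so they bracket the true (large-sample) correlation
in only about half of repeated experiments — that is a property of any
bootstrap, not of this implementation. The whisker interval (≈ ±2.7
bootstrap SDs) is the summary that brackets the estimand reliably (≈95% of
simulated experiments when the generator's mean profiles are held fixed),
and it is what the box-and-whisker presentation communicates.

The count generator plants correlation at the latent level: a planted pair
shares a bivariate-Gaussian latent log-mean with stated correlation; all
other genes get independent latents on top of cluster-specific mean
profiles, and counts are negative binomial (dispersion 0.5). Note that the
*observed* log-count correlation of a planted pair is substantially smaller
than the latent correlation (count noise dilutes it; latent 0.9 yields
observed ≈ 0.48 at typical means), which is exactly why percentile ranking
against a decoy null, rather than the raw coefficient, carries the
inference. With 1000 independent decoys and 500 cells, a planted latent
correlation of 0.5 ranks above 99% of decoys in ≈100 of 100 seeds. Decoy
nulls are computed within one cell population; pooling cell types with
different mean profiles adds genuine cluster-driven correlation to the null,
which is a property of real data the screen must live with, not a bug of
the generator.

## PLA quantification

Segmentation of the immunofluorescence channel: Gaussian blur (σ = 2 px),
Otsu threshold computed over the image's own intensity range (hence
invariant to uniform offsets), hole filling, connected components, and a
minimum area of 50 µm². Otsu always splits a histogram, including a
featureless one, so a separability guard — Otsu's between-class variance as
a fraction of total variance, ≈0.64 for pure Gaussian noise versus ≈1 for a
real foreground — returns an empty mask set on blank fields. Dot detection:
Gaussian smoothing matched to the punctum PSF (σ = 1.5 px), white top-hat
with a generous disc (radius 8 px, so the smoothed peak is barely
attenuated while cell-scale structure is removed), threshold at the top-hat
mean + 5 SD, local maxima with 2 px minimum separation. Dots are assigned
to cells by their centre pixel; PLA puncta are subcellular, so area overlap
would add nothing. Counts are conserved by construction (per-cell + outside
= total) and the whole image pipeline is deterministic.

The 5·SD threshold is set by max statistics: an image offers ~10⁴ candidate
maxima, so a featureless field stays at zero false detections only for
thresholds near 5σ. This has a hard flip side at low contrast. For spots of
σ = 1.5 px at peak-to-noise ratio 2, the matched filter — the optimal
linear detector — delivers an effective peak z of about
$(A/\sigma_n)\,\sigma_d\sqrt{\pi} \approx 5.3$, and an oracle-thresholded
ROC of that detector tops out around min(recall, precision) ≈ 0.82: no
threshold reaches 0.9/0.9 simultaneously, and at the zero-false-positive
threshold recall is ≈0.55. Reliable 0.9/0.9 counting needs spots either
brighter (peak ≥ ~2.5× noise SD) or larger (σ ≥ ~2 px). This is a
detectability bound of the imaging regime, not an implementation artifact,
and it is why dim-spot recall should be reported alongside counts on real
data.

## qPCR and surface-expression normalization

Technical duplicates are averaged on the Cq scale, with pairs disagreeing
by more than 1 cycle discarded with a warning; non-detect means missing Cq
or Cq ≥ 40 (both cutoffs configurable; neither is a measurement standard so
they are package conventions). ΔCq is taken against the reference genes
(Hprt/Sdha/Tfrc by convention), relative quantity is $2^{-\Delta Cq}$ (one
doubling per cycle; amplification efficiency fixed at 2), and per-gene
quantities are expressed relative to the calibrator gene's tissue mean,
which is exactly 1 by construction. The reference aggregation defaults to
the arithmetic mean of the reference Cq values — equivalently the geometric
mean of the reference expression quantities, the standard multi-reference
normalization — because it is the aggregation under which a per-sample
loading offset added to every Cq cancels *exactly*; the geometric mean
taken on the Cq scale itself is offered as an option (`"cq_geomean"`) and
differs only in the third decimal at typical Cq, but is not exactly
shift-invariant. Per-sample linear-scale quantities are averaged
(log-scale averaging would estimate the geometric mean expression; the
linear mean matches the calibrator-mean convention used here).

RLU normalization works per experiment: subtract the mean uninjected
(background) luminescence, clip negative per-oocyte values to zero, divide
by the experiment's mean background-subtracted control signal. Any
per-experiment multiplicative batch factor cancels exactly, which the
round-trip test verifies to 1e-9 against the generator's planted factors.
Pooled normalised values feed an ordinary one-way ANOVA with post hoc
Dunnett comparisons against the control; at 20 oocytes × 3 experiments and
15% noise, a planted 1.5× group is flagged at P ≤ 0.05 in ≈100 of 100
simulations.

## Problem sizes, determinism, limitations

Simulation studies in the test suite use the sizes at which the estimators
are specified to operate: 100 seeds for ephys parameter recovery and for
the co-expression percentile/bootstrap studies, 10⁵ draws for assembly
Monte-Carlo checks, 20 seeds for dim-spot detection, 100 simulations for
the Dunnett power checks; these complete in about a minute in total.
All generators take explicit seeds and are bitwise reproducible;
`run_pipeline()` refuses to run stochastic stages without one and writes a
run manifest (stage, parameters, seed, package version) next to every
output.

What the synthetic data do *not* emulate — and therefore what passing tests
do not show about real data: series-resistance voltage errors and imperfect
space clamp; channel inactivation or rundown; ambient RNA, doublets and
batch structure in single-cell counts; realistic optics (the PSF is an
isotropic Gaussian, cells are ellipses); qPCR efficiency differences
between assays; oocyte-to-oocyte expression heterogeneity beyond Gaussian
noise. The assembly model treats availability as a free parameter —
converting transfection mass ratios to molar subunit availability would
require plasmid lengths and expression kinetics the data do not contain,
which is also why results are reported both at nominal and equalised
availability.
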