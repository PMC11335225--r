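# silentkv

Analysis toolkit for the interaction between **Kv7 potassium channels** and
the **electrically silent Kv subunits** (KvS: Kv5/Kv6/Kv8/Kv9). KvS subunits
form no functional channels on their own — alone they stay in the ER — but
they can co-assemble with partner subunits and reshape the partner's
current. Deciding *how* they interact (shared-pore heterotetramer,
independent channels side by side, or an ancillary beta-subunit) and *how
strongly* assembly favours homomers is a quantitative problem, and this
package implements the computations that answer it, together with the
downstream analyses such a study uses.

For channel tetramers assembled from subunit species with availabilities
$p_i$, fully stochastic assembly gives composition $c$ the multinomial
probability $\binom{4}{c}\prod_i p_i^{c_i}$. Co-expressing a wild-type Kv7
with an equally available dominant-negative (pore-dead) subunit, only the
all-wild-type tetramer conducts under a shared pore, so the predicted
residual current is $(1/2)^4 = 1/16$. Milder observed effects are modelled
by a homomer-preference factor $f \ge 1$ under three generative variants
(per-site preference, reweighted tetramer classes, dimer-of-dimers), and
`fit_preference()` inverts the model to find the $f$ that reproduces an
observed residual — e.g. a 50% residual implies $f \approx 6.9$ (per-site)
or $f = 14$ (tetramer-class), and is unattainable under dimer pairing.

The package also provides:

* **Ephys analysis** — series-resistance QC (exclude Rs ≥ 7 MΩ),
  steady-state current densities (pA/pF at +20 mV), tail-current
  extraction, two-state Boltzmann fits
  $I = I_{min} + (I_{max}-I_{min})/(1+e^{(V-V_h)/s})$, G–V normalization to
  $I_{max}-I_{min}$, Dunnett group summaries.
* **Single-cell co-expression screen** — detection filters (cell types with
  ≥ 10% anchor detection), dot-plot statistics, Pearson correlation of
  log2(count+1) values with a cell-level bootstrap (n = 100, box-plot
  hinges and 1.5-IQR whiskers), and a genome-wide percentile rank of a
  candidate pair against all other detected transcripts.
* **PLA quantification** — Otsu segmentation of immunopositive cells,
  top-hat spot detection, inside/outside dot counting.
* **qPCR / surface assays** — ΔCq relative expression against a
  reference-gene panel with calibrator scaling; oocyte luminescence (RLU)
  normalization with background subtraction, per-experiment control
  scaling, and ANOVA + Dunnett testing.
* **Synthetic data generators** for all of the above, with planted ground
  truth (gating parameters, latent gene–gene correlations, dot coordinates
  and masks, abundances, group effects), so every estimator is testable
  against a known answer.

## Worked example

```r
library(silentkv)

mix <- kv_mix(kv_species("Kv7.2", "KV7"),
              kv_species("Kv8.1dn", "KVS", pore_functional = FALSE),
              equalize = TRUE)

# stochastic co-assembly: only all-wild-type tetramers conduct
predict_relative_current(mix, assembly_rule("stochastic"),
                         conductance_rule(), baseline = "kv7_alone")
#> Relative current 0.0625 (mode single_pore_heteromer, baseline kv7_alone)

# homomer preference explaining a 50% residual current, per variant
fit_preference(0.5, mix, "per_site")$preference_f
#> [1] 6.910189
fit_preference(0.5, mix, "tetramer_class")$preference_f
#> [1] 14.00002

# mode discrimination for a pore-dead Kv7 with wild-type KvS
mix_dn7 <- kv_mix(kv_species("Kv7.2gys", "KV7", pore_functional = FALSE),
                  kv_species("Kv8.1", "KVS"), equalize = TRUE)
compare_modes(mix_dn7, assembly_rule("stochastic"),
              conductance_rule(standalone_kvs_conductance = 0.5),
              baseline = "wt_mix")
#>                    mode relative_current baseline
#> 1 single_pore_heteromer        0.0000000   wt_mix
#> 2  independent_channels        0.3333333   wt_mix
#> 3          beta_subunit        0.0000000   wt_mix
```

The 0.0625 is the 1/16 residual: a 93.75% predicted current reduction. The
mode table carries the discrimination argument: if Kv7 and KvS coexisted as
independent channels, a pore-dead Kv7 would still leave a visible KvS
current (0.33 here); under a shared pore it leaves none.

The numbered drivers in `analysis/` run each stage end to end on synthetic
data and write tables under `results/`; e.g.
`Rscript analysis/02_ephys_recovery.R` simulates two cohorts with a planted
+10 mV half-activation shift and prints

```
QC: 22 of 24 recordings kept (Rs < 7 MOhm); 2 excluded.
Current densities at +20 mV (normalized to the kv7_alone mean):
  kv7_alone  n=12  43.00 +/- 1.47 pA/pF (rel 1.00)
  kv7_kvs    n=10  26.86 +/- 1.71 pA/pF (rel 0.62) ***
Half-activation voltage: planted +10 mV between-group shift, recovered +10.10 mV.
```

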