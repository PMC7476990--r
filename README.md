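# egmorph

Automated morphology analysis of paced unipolar contact electrograms
(EGMs) under gap-junction uncoupling, with a mechanistic simulator of the
recordings it analyses.

## The problem

Gap-junction blockers such as carbenoxolone (CBX) uncouple cardiomyocytes:
conduction slows and wavefronts become discontinuous. On a unipolar EGM
this reads out as a longer interval from the pacing stimulus to the maximal
negative slope (-dV/dt)max (the local activation marker), a lower
(-dV/dt)max, deeper S waves and fractionated complexes. Quantifying those
changes across a 4x4 grid mapping catheter at 16 epicardial sites requires
extracting a consistent set of per-beat morphology features from thousands
of activations — by hand this is impractical, and ad hoc scripts are
untestable.

`egmorph` provides, for electrophysiology researchers working with paced
multielectrode recordings:

* **`synthetic` layer** — seeded paced-EGM studies from a 2-D conduction
  model. Activation is exact shortest-path (eikonal-style) propagation over
  a velocity field with `cv = cv0 * sqrt(c) * exp(g)` for coupling factor
  `c`, log-normal heterogeneity and disc-shaped conduction-block
  micro-patches scaling with `1 - c`; electrode potentials come from a
  zero-sum-corrected current-source sum `phi_e = k * sum_i I_i / r_ie`,
  with a bulk-conductivity gain `(1 + rho)/(1 + rho c)` reflecting the
  loss of the intracellular conduction pathway.
* **`features` layer** — band filtering (0.3-500 Hz conventions, 1 kHz),
  stimulus detection, beat segmentation, landmark location (onset, Q, R,
  S, endpoint, activation) and 19 time-domain features per beat plus the
  stimulus-to-(-dV/dt)max latency: intervals, amplitudes, gradients,
  widths, ratios and a fractionation index (count of distinct
  downstrokes).
* **`stats` layer** — pooled condition summaries, Welch t-tests, percent
  change from baseline, and a four-parameter logistic (4PL) dose-response
  fit `L(d) = A + (B - A)/(1 + (d50/d)^h)`.
* **IO** — self-contained CSV and WFDB-style recording formats, long-format
  feature tables, YAML/JSON configuration, and a manifest-writing pipeline
  runner (also exposed as a CLI script in `inst/cli/`).

## Worked example

Simulate a paired 16-site baseline/CBX study, extract every beat's
features, and compare conditions:

```r
library(egmorph)

study      <- simulate_paired_study(simulation_config(seed = 42))
features   <- extract_study_features(study)   # 2048 beats, 26 columns
comparison <- compare_conditions(features)

comparison[comparison$feature %in%
  c("stim_to_dvdt_latency", "dvdt_max", "s_point",
    "fractionation_index", "amplitude"), ]
#>   feature              bl_mean cbx_mean   p_value percent_change significant
#> 1 s_point               -1.41    -2.22  1.18e-115         -57.6  TRUE
#> 2 fractionation_index    1.32     1.40  3.51e-  2           6.38 TRUE
#> 3 dvdt_max               0.648    0.602 1.70e- 54          -7.09 TRUE
#> 4 amplitude              6.42     8.37  2.17e-218          30.4  TRUE
#> 5 stim_to_dvdt_latency  54.7     76.2   0                  39.2  TRUE
```

The signs are the electrophysiological signature of uncoupling: activation
latency up (54.7 to 76.2 ms here), maximal downstroke rate down, S point
deeper, fractionation up. The baseline mean amplitude (R - S) sits at the
calibrated ~6.5 mV scale of epicardial unipolar recordings.

Dose-response of the conduction delay over a 0-50 ml escalation:

```r
series <- simulate_dose_response(simulation_config(seed = 42))
dl  <- dose_latency_summary(series)
fit <- fit_dose_response(dl$dose_ml, dl$latency_mean, dl$latency_sd)
fit
#> <dose_response_fit> A = 56.60 ms, B = 78.03 ms, d50 = 33.31 ml, h = 3.09, rmse = 0.112 ms
```

`A` is the baseline latency asymptote, `B` the saturating delay, `d50` the
half-effect dose and `h` the Hill slope of the fitted sigmoid.

The whole chain (simulate, write recordings, extract, compare, fit, write
a checksummed manifest) is one call:

```r
run_pipeline(simulation_config(), out_dir = "egm_out", seed = 42)
```

## Documentation

The methods vignette (`vignettes/egm-uncoupling-methods.Rmd`) describes
the conduction and forward models, every analysis threshold and its
default, the design decisions behind them, and what passing synthetic
tests do and do not establish about real recordings.
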