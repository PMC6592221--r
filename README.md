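# pacbench

Simulation and surrogate-based evaluation of phase-amplitude coupling
(PAC) measures for EEG/MEG-like signals.

PAC — the dependence of a fast oscillation's amplitude envelope on the
instantaneous phase of a slower rhythm (e.g., theta-gamma coupling) — is
quantified in the literature by several competing statistics. pacbench is
for methodologists and electrophysiologists who need to know how those
statistics behave *under a known ground truth*: it simulates realistic
EEG with controllable implanted coupling, computes four standard PAC
statistics with surrogate-based standardization, and runs factorial
specificity/sensitivity studies over the moderators that matter in
practice (coupling strength and width, mono- vs biphasic coupling, data
length, sampling rate, noise level).

## The statistics

Given per-sample slow-band phase θ_t and fast-band envelope a_t
(Hilbert-derived, trials concatenated):

* **PLV** `= |Σ_t exp(i(θ_lt − θ_ut))/n|`, where θ_ut is the phase of the
  Hilbert-transformed envelope;
* **MVL** `= |Σ_t a_t exp(iθ_t)/n|`, and the amplitude-normalized
  **direct MVL** `= |Σ_t a_t exp(iθ_t)|/√(n Σ_t a_t²)`;
* **MI** `= (ln N − H(p))/ln N`, with p the normalized mean envelope in
  N = 18 phase bins and H its Shannon entropy (natural log) — the
  normalized Kullback–Leibler distance from uniformity;
* **GLM-CFC** `= max_φ |A_spline(φ) − A_null|/A_null`, from a gamma/log-link
  GLM of the envelope on a periodic cubic spline basis of phase.

Each raw value is standardized against within-trial cut-and-swap
surrogates: `z = (CV_obs − μ_shuffled)/σ_shuffled`. Because the null
z-distribution is right-skewed, significance thresholds are calibrated
empirically from thousands of no-coupling simulations rather than taken
from the Gaussian 1.64.

## Worked example

```r
library(pacbench)

# one dataset: theta (5-7 Hz) phase modulating low gamma (33-47 Hz),
# coupling intensity I = 1 (envelope doubled at the slow peaks),
# 30 trials x 2500 ms at 1000 Hz, band-matched noise at 100%
cfg <- sim_config(pair = "theta_low_gamma", intensity = 1, seed = 11)
trials <- simulate_pac(cfg)
trials
#> <pac_trials: 30 trials x 2500 samples @ 1000 Hz (simulated)>

estimate_pac(trials, method = c("plv", "mvl", "mi", "glm_cfc"),
             n_perm = 200, seed = 2,
             critical_z = c(plv = 1.91, mvl = 1.91, mi = 1.94,
                            glm_cfc = 2.08))
#>    method      raw surrogate_mean surrogate_sd    z n_perm seed significant
#> 1     plv 0.035096       1.18e-02     6.07e-03 3.84    200    2        TRUE
#> 2     mvl 0.000566       1.74e-04     8.89e-05 4.42    200    2        TRUE
#> 3      mi 0.000628       7.94e-05     5.78e-05 9.49    200    2        TRUE
#> 4 glm_cfc 0.145155       3.83e-02     1.30e-02 8.24    200    2        TRUE
```

The `raw` column is the coupling statistic itself (scale-dependent and
not comparable across methods); `z` is its distance from the surrogate
null in standard deviations — here every method detects the implanted
coupling beyond its calibrated threshold. With `intensity = 0` the same
pipeline yields z-values scattered around zero.

Study-level runners return tidy tables:

```r
spec <- run_specificity(pair = "theta_low_gamma",
                        methods = c("plv", "mvl", "mi"),
                        n_sims = 500, n_perm = 200, master_seed = 1)
spec$critical          # empirical critical z per method
glance(spec)           # critical z + null means
autoplot(spec)         # null distributions

sens <- run_sensitivity(pair = "alpha_high_gamma", methods = "mi",
                        n_sims = 20, n_perm = 200, master_seed = 2)
marginal_means(sens, "intensity")
autoplot(sens, margin = "data_length_ms")
```

A thin command-line front end ships in `inst/cli/pacbench`
(`pacbench simulate|estimate|specificity|sensitivity|fixtures`).

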