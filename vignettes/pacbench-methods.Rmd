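---
title: "Simulating and benchmarking phase-amplitude coupling measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking phase-amplitude coupling measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Phase-amplitude coupling (PAC) is the statistical dependence of a fast
oscillation's amplitude envelope on the instantaneous phase of a slower
rhythm — in EEG, for example, a gamma envelope waxing at particular theta
phases. Many statistics quantify it, and they disagree in sensitivity,
specificity and failure modes. pacbench implements a controlled testbed:
a realistic EEG simulator with implantable coupling, four PAC statistics
standardized by surrogate permutation, and factorial evaluation runners
that measure specificity (false positives under no coupling) and
sensitivity (response to coupling strength, width, multimodality, data
length, sampling rate and noise).

```{r setup, eval = FALSE}
library(pacbench)
```

## The generative model

A synthetic dataset is built in a fixed pipeline, always on the continuous
record, with trials cut only at the very end:

1. **Background process.** Brownian noise, i.e. a power-law process with
   spectral exponent $\beta = 2$ ($P(f) \propto 1/f^\beta$), synthesized in
   the frequency domain: a white complex Gaussian spectrum scaled by
   $f^{-\beta/2}$ and inverse transformed. Frequency-domain shaping was
   chosen over integrating white noise because it gives exact control of
   $\beta$; `spectral_slope()` recovers $-\beta \pm 0.3$ on realizations of
   a few minutes. Human EEG background activity is well approximated by
   this $1/f^2$ regime.
2. **Band splitting.** The record is band-pass filtered into a slow,
   phase-providing band (theta 5–7 Hz or alpha 8–10 Hz; 2 Hz wide) and a
   fast, amplitude-providing band. The fast band must contain the
   modulation sidebands, so its edges are the center frequency ± the upper
   edge of the slow band: 33–47 Hz for a 40 Hz center, 50–70 Hz for 60 Hz
   (`amplitude_band_limits()`).
3. **Filter design.** Zero-phase Hamming-windowed sinc FIR. The automatic
   order rule is the classic one: transition bandwidth
   $\min(\max(0.25\,f_{low}, 2\,\mathrm{Hz}), f_{low})$ and order
   $\lceil 3.3/(tbw/f_s)\rceil$ rounded up to even, so the kernel is
   symmetric with integer group delay; the delay is compensated in one
   pass. Half a filter order at each end is treated as edge transient and
   never enters a trial.
4. **Coupling implantation.** Relative maxima (monophasic) or maxima and
   minima (biphasic) of the filtered slow signal — phases 0° and ±180° —
   are detected by sign changes of the first difference (plateaus
   contribute their first sample). Centered on each, the fast signal is
   multiplied by $1 + I\,\mathrm{hann}(L)$: gain exactly $1 + I$ at the
   center ($I = 1$ doubles the envelope there), exactly 1 at the window
   edges. The window length is a fraction of one slow cycle; "one cycle"
   is defined as the reciprocal of the band's center frequency (6 Hz →
   166.7 ms), since a 2 Hz-wide band does not fix a unique cycle. At the
   studied widths (22.5–27.5% of a cycle) windows never overlap even in
   biphasic mode; if a user forces overlap, gains multiply.
5. **Band-matched noise.** An independent Brownian realization is filtered
   with the same band design and added, scaled so its RMS is
   `noise_scale` times the RMS of the series it corrupts (both measured on
   the edge-trimmed interior). "Signal strength" is thus RMS within band;
   0.9/1.0/1.1 correspond to the 90/100/110% noise conditions.
6. **Resampling.** Generation is at 1000 Hz; a 500 Hz condition is
   produced by anti-aliased integer decimation of the continuous series,
   as the last modification before extraction. (Whether noise is added
   before or after decimation is not fixed by the design; pacbench adds it
   before, so decimation is purely an observation-rate change.)
7. **Extraction and segmentation.** The Hilbert transform of each
   continuous band-limited series yields instantaneous phase (slow band)
   and amplitude envelope (fast band). Only then are `n_trials`
   non-overlapping trials cut, separated by at least one slow cycle to
   create the discontinuities typical of event-related data. Trial onsets
   are random by default (`"regular"` spacing is available); the default
   record length is `n_trials × trial_length + 30 s`, mirroring 42/105/180 s
   records for 30 trials of 400/2500/5000 ms.

## The four statistics

All estimators consume the concatenated per-sample phase $\theta_t$ and
envelope $a_t$ (concatenation at the extracted level; nothing is
re-filtered across trial boundaries):

* **PLV** — the envelope is Hilbert-transformed a second time, giving
  envelope phases $\theta_{ut}$;
  $\mathrm{PLV} = |\sum_t e^{i(\theta_{lt}-\theta_{ut})}/n| \in [0,1]$.
  Optionally the envelope is band-passed in the slow band first
  (`envelope_prefilter`), the classical remedy when the envelope is not a
  narrow-band oscillation; off by default since the main simulations do
  not require it.
* **MVL** — $|\sum_t a_t e^{i\theta_t}/n|$, plus the amplitude-normalized
  direct variant $|\sum_t a_t e^{i\theta_t}|/\sqrt{n\sum_t a_t^2} \in
  [0,1]$. The raw MVL scales with the envelope; its permutation-standardized
  z does not, which the tests assert exactly.
* **MI** — mean envelope per phase bin (18 bins of 20°, half-open
  $[\mathrm{edge}, \mathrm{next})$, $+\pi$ wrapped into the last bin),
  normalized to a distribution $p(j)$; Shannon entropy with the natural
  log; $\mathrm{MI} = (\ln N - H)/\ln N \in [0,1]$, the normalized
  Kullback–Leibler distance from uniform. $0\ln 0 \equiv 0$; an *empty*
  bin is an error (too little data for the bin count).
* **GLM-CFC** — a gamma-family, log-link GLM of the envelope on a periodic
  cubic B-spline basis of phase (control points evenly spaced over
  $(-\pi,\pi]$; the basis rows sum to one so the intercept-only null model
  is nested). The statistic is
  $\max_\phi |A_{spline}(\phi) - A_{null}|/A_{null}$ over a dense phase
  grid — the maximal modelled envelope change as a proportion of the null
  (intercept-only) envelope. The exact spline parameterization in the
  original literature is not fully specified; the periodic cubic basis
  here is a documented choice. For the gamma/log family the IRLS weights
  are identically one, so the fit is iterated least squares against a
  fixed design: one QR factorization serves every iteration and every
  surrogate. Coefficients agree with `stats::glm` to machine precision.
  Default 10 control points, deviance tolerance 1e-8, max 100 iterations;
  an AIC scan over control-point counts {4, 6, 8, 10, 12} is available
  (`select_by_aic`).

## Surrogate standardization

Raw PAC values are not comparable across data lengths, envelopes or
methods, so each observed value is standardized against within-trial
cut-and-swap surrogates: per trial, the amplitude series is cut at a
uniformly random interior point and the two parts swapped (a circular
rotation; the interpretation of "swapping the parts" as rotation is the
standard null-preserving surrogate — it leaves every marginal property of
the series intact and destroys only the phase-amplitude alignment). Cuts
are drawn independently per trial and permutation; cut 0 is excluded.
Then $z = (CV_{obs} - \mu_{shuffled})/\sigma_{shuffled}$ with the sample
SD ($n-1$; the choice is documented since the definition leaves it open).

Because the null z-distribution of these statistics is right-skewed,
significance is not taken from the Gaussian 1.64 but calibrated: the
empirical 95th percentile (type-7 linear interpolation) of z-values from
thousands of no-coupling simulations (`run_specificity()`,
`empirical_critical_z()`).

A note on the GLM measure's null mean: a statistic that depends on the
data only through the (phase, amplitude) pairing is exchangeable with its
rotation surrogates, so its expected null z is 0 — and that is what this
implementation measures, with or without the AIC scan. Reports of a
clearly positive GLM-CFC null mean (and a correspondingly higher
calibrated threshold than the other measures) therefore cannot be
reproduced by any pairing-only statistic under these surrogates; they
must reflect implementation details of the original GLM-CFC code that the
published description does not pin down. This is a known, documented
divergence. The evaluation runners still enable observed-side AIC
selection for the GLM by default, for procedural fidelity; the
single-shot `pac_glm()` keeps a fixed count for speed.

## The factorial studies

`run_specificity()` simulates base datasets at $I = 0$ and modifies each
across data length (400/2500/5000 ms) × sampling rate (500/1000 Hz) ×
noise (90/100/110%) — the within-dataset factorial of the original design.
Each noise *level* receives its own independent band-noise realization
(merely rescaling one shared realization would make a dataset's noise-level
cells near-duplicates and waste replication); each length condition draws
its trials from a record of that condition's own duration
(`n_trials × length + 30 s`), so 400 ms trials are packed into a 42 s
window just as 5000 ms trials span 180 s. It
returns the pooled critical z per method (one value per method and
frequency pair: the null z was found not to depend on length, rate or
noise, which justifies pooling), per-cell means, and false-positive counts
in consecutive subsamples of 50 datasets. `run_sensitivity()` adds
strength (0.9/1.0/1.1) × width (22.5/25/27.5%) × multimodality (mono/bi).
`marginal_means()` averages z at each level of one factor over all others;
with the balanced grid this equals the unweighted average of cell means,
and factor levels (including the intensity levels) enter marginals with
equal weight. Standard errors are computed across per-dataset means,
matching the repeated-measures design.

Paper-scale replication (5000 null datasets, 100 sensitivity datasets,
1000 permutations) is the documented default; every runner exposes
`n_sims`, `n_perm` and grid subsetting as first-class arguments, and the
GLM measure has separate `glm_n_sims`/`glm_n_perm` knobs because its cost
exceeds the other methods by about two orders of magnitude. Inferential
statistics (repeated-measures ANOVA and post hoc procedures) are outside
the toolkit's scope; the tidy z tables and `write_pac_csv()` exports are
the interface to external statistics software.

## Numerical engineering

Permutation testing dominates runtime, and three exact identities keep it
tractable:

* **MVL/MI surrogates via circular cross-correlation.** For a trial
  rotated by cut $c$, any statistic of the form $\sum_t w_t\,a_{(t+c)
  \bmod L}$ is the circular cross-correlation $(w \star a)[c]$, computable
  for *all* cuts at once with three FFTs per trial. With $w = e^{i\theta}$
  this gives every surrogate MVL; with per-bin indicators (packed in
  pairs into single complex transforms) every surrogate MI histogram. The
  surrogate cost of these methods is therefore independent of the number
  of permutations.
* **Two Hilbert transforms per FFT pair.** The PLV needs the analytic
  signal of each surrogate envelope. Packing two real envelopes as
  $a_1 + i a_2$, applying the analytic mask to the packed spectrum and
  inverting gives $z_1 + i z_2$; since $a_1, a_2$ are known, both Hilbert
  transforms unmix exactly. This halves the FFT count of the dominant
  loop.
* **One QR for all GLM surrogates.** See above; surrogate fits warm-start
  from the observed coefficients (typically 4 iterations to a 1e-8
  deviance tolerance).

Small C++ kernels (via Rcpp) implement the rotation gather, the complex
packing and the PLV resultant as single fused passes; each is
cross-checked in the test suite against a plain-R brute-force path at
1e-10 or better. All FFTs use R's built-in mixed-radix `fft`.

Reproducibility: every run derives child seeds from one master seed by a
counter scheme (`derive_seed()`), so any dataset or grid cell can be
recomputed in isolation, independent of iteration order, and all derived
seeds stay within the 32-bit integer range.

## What the simulation does and does not emulate

The generator reproduces the features that matter for PAC estimation:
$1/f^2$ background, band-limited components, phase-locked multiplicative
modulation, band-matched noise, trial discontinuities, finite sampling.
It does not emulate volume conduction or multi-channel structure,
non-stationary (transient) coupling, heartbeat/ocular artifacts, or line
noise. Passing the test battery therefore shows the statistics behave
correctly under the stated generative model — continuous, stationary
coupling — not that they are robust to every pathology of recorded EEG.
In particular, coupling here is present throughout the record, which is
why measured coupling grows with data length; transiently coupled data
need not behave this way.

## Problem sizes used in the shipped checks

The full-scale studies are not reproducible in a test run, so the shipped
acceptance checks run the same machinery at reduced replication: null
calibration with 28 base datasets × 18 grid cells (504 null estimates per
method and pair) at 200 permutations; the GLM null at 10–12 bases (AIC
selection on, 40–100 permutations), with its critical value calibrated on
the 500 Hz cells; sensitivity grids with 1–3 bases per cell at 20–30
permutations, the GLM on the 1000 Hz subgrid. Because cells within a base
dataset share one background realization, the pooled 95th percentile at
this scale carries a sampling standard error of roughly 0.2–0.3 z-units
(about 0.1 at 100 bases); that, not estimator bias, bounds how tightly
the reproduced thresholds can match the full-scale ones.

## Known limitations

* Only integer decimation factors are supported for resampling (1000 →
  500 Hz covers the study design).
* The GLM-CFC confidence-interval machinery of the original method is not
  implemented — only the point statistic with surrogate standardization.
* Comodulogram scans over frequency grids are out of scope; the bands of
  a single pair are explicit arguments.
* `preferred_phase` is reported for PLV/MVL only and is meaningless under
  biphasic coupling (opposed bumps cancel in the circular mean); inspect
  the polar plot (`plot_coupling_polar()`) before interpreting it.
* Under genuine biphasic coupling the standardized PLV/MVL do not sit
  exactly at zero: the second-harmonic dependence inflates the variance of
  the observed resultant relative to the rotation surrogates, leaving a
  small positive mean z (~0.1–0.2 at the default conditions) even though
  the first circular moment cancels.
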