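---
title: "Separating reward positivity and feedback negativity by time-frequency PCA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating reward positivity and feedback negativity by time-frequency PCA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Feedback-locked ERPs from gambling tasks superimpose two components with
overlapping latencies but distinct spectral content: a centro-parietal
delta-band (0.5–3 Hz) deflection that is larger after gains (the reward
positivity, RewP) and a mediofrontal theta-band (4–8 Hz) burst that is
larger after losses (the feedback-related negativity, FRN). Conventional
time-domain scoring confounds them. This package implements the
decomposition route: band pre-filtering, a quadratic time-frequency
transform of the condition ERPs, principal components analysis of the
vectorized surfaces with varimax rotation, and scalar PC-weighted scores
per subject and condition at the sensors where each component is maximal
(Cz for delta-RewP, FCz for theta-FRN). The scores and the risky-choice
behavior are then related to clinical covariates (four PTSD symptom
subscale severities, an alcohol-use score, mTBI severity, age) with robust
linear mixed-effects models.

Because no EEG of this kind is publicly deposited, the package ships a
synthetic-data generator whose statistical structure matches what the
analysis assumes. Every stage is therefore testable end to end, with
ground truth available for recovery checks.

# The generative model

`generator_config()` fixes the reference study conditions:

* **Task.** 256 trials in 8 blocks; each trial offers a pair drawn
  uniformly from {5/5, 5/25, 25/25} cents; feedback is a fair coin
  independent of choice. On mixed offers the probability of choosing the
  risky (25-cent) option follows
  `plogis(b0 + b_prevloss * I(previous loss) + b_audit * audit_z)` with
  `b_prevloss = 0.5` (risk appetite rises after losses) and
  `b_audit = 0.15`.
* **Covariates.** A Gaussian copula produces four gamma-distributed
  symptom severities with pairwise Pearson correlation 0.5 (the latent
  correlation is calibrated by two-dimensional Gauss–Hermite quadrature so
  the *output* correlation, not the latent one, matches the configured
  value), an integer AUDIT-C score on 0–12 via a binomial quantile map
  (mean ≈ 4.2), a gamma mTBI severity, uniform age on 22–59 years, and
  threshold-based diagnosis flags. Two latent neural traits per subject
  are the random intercepts of the amplitude model below.
* **Amplitudes.** Per-trial component amplitudes (unitless, ≈1) follow
  `A_delta = 1 + 0.5 I(gain) − 0.15 audit_z + u_d + e` and
  `A_theta = 1 + 0.8 I(loss) + (0.3 reexp_z − 0.15 audit_z) I(loss)
  − 0.1 age_z + u_t + e`, with subject traits `u` (SD 0.3) and trial noise
  `e` (SD 0.5). The signs encode the pattern the analysis is designed to
  detect: gains boost delta; losses boost theta; reexperiencing amplifies
  and alcohol use dampens loss-theta; delta is reduced by alcohol use; age
  mildly lowers theta overall (so the age screen has something to find at
  large n).
* **EEG rendering.** The delta template is a Gaussian deflection (peak
  8 µV, center 350 ms, SD 80 ms) and the theta template a 6-Hz
  Gaussian-windowed burst (peak 6 µV, center 325 ms, SD 55 ms); both are
  spread over a flattened 10–20 montage by 2-D Gaussian topographies
  centred on Cz and FCz respectively (σ = 0.45 head radii) — the simplest
  model consistent with "maximal at Cz/FCz". Channels carry 1/f noise
  (exponent 1, 8 µV RMS), and blinks (Poisson rate 0.25/s, ~120 µV,
  400 ms positive half-cosine) enter the EOG channels and leak into the
  EEG through fixed distance-decaying propagation coefficients — which
  makes ocular regression testable against known ground truth.
* **Scale.** The default montage is 16 EEG + 2 EOG channels at 256 Hz
  (the container supports arbitrary montages); epochs span −1000 to
  +2000 ms around feedback.

What the generator does *not* emulate: volume conduction from realistic
sources, muscle/movement artifact taxonomies beyond blinks, reaction
times, non-stationary noise, or learning across blocks. Passing recovery
tests therefore demonstrates the correctness of the pipeline's machinery
under its own assumptions, not its performance on any particular real
recording.

# Preprocessing

The chain is fixed: baseline correction (closed interval −150–0 ms,
endpoints included), ocular regression, amplitude-based artifact
rejection, condition averaging; each stage appends to the provenance log.
Ocular regression estimates one coefficient per EOG channel per EEG
channel by least squares pooled over all concatenated epochs of a subject
(no raw/ERP split), and subtracts the fitted EOG contribution. Rejection
drops an epoch when any monitored channel (default: the two most frontal
EEG channels) exceeds 100 µV in magnitude within −800–0 or 0–1500 ms;
samples outside those windows never trigger rejection. A visual-inspection
pass has no automatable rule, so an explicit list of epoch indices to drop
stands in for it. Whether the original threshold applied before or after
ocular regression is not documented anywhere we could verify; the package
rejects *after* regression, which is the only order in which a 100 µV
bound on frontal channels is meaningful when blinks reach ~40 µV there.

# The binomial reduced interference distribution

The transform is a discrete Cohen-class distribution built from the local
autocorrelation `K(n, τ) = Σ_m w_τ(m) x(n+m+τ) x(n+m−τ)`, where the
time-smoothing weights at lag τ are the binomial coefficients of order
2|τ| normalized to sum 1 — the canonical binomial RID kernel. The surface
is the Fourier transform of `K` over lag. Numerical choices:

* **Energy contract.** The lag-0 smoothing window is the single weight 1,
  so `K(n, 0) = x(n)²` exactly; with the `1/M` FFT normalization and the
  folding below, `Σ_{t,f} TF = Σ_n x(n)²` holds to float rounding. The
  validity suite checks < 1e-6 relative error on 100 random signals.
* **Real signal, folded axis.** The transform operates on the real signal
  (no analytic-signal step; cross-term suppression is the kernel's job).
  The discrete distribution of a real signal is alias-free only up to a
  quarter of the sampling rate, so the frequency axis spans 0 to fs/4 and
  the mirrored negative-frequency bins are folded (doubled) into it. At
  the default 128 Hz analysis rate the axis reaches 32 Hz — four times
  the top of the theta band.
* **Downsampling.** ERPs are decimated to 128 Hz (Butterworth order-6
  anti-alias at 80% of the target Nyquist, zero phase) before the O(N·L²)
  lag computation; configurable off. The lag cap and FFT length follow
  from the requested number of frequency bins (default 65 bins, 0.5 Hz
  spacing).
* **Windows.** Surfaces are cropped to −500 to +1000 ms after the
  transform; the long epoch exists precisely to push filter and RID edge
  effects outside the analysis crop.

Band pre-filters are third-order zero-phase Butterworths (4-Hz low-pass
for delta, 2-Hz high-pass for theta), applied forward–backward with odd
reflection padding; the effective magnitude response is the squared
single-pass response, which the tests verify against the closed form
`1/(1 + (f/fc)^6)` at probe frequencies.

# Time-frequency PCA

The surfaces of all subjects, conditions and EEG channels form the rows of
a data matrix (one row per subject × condition × channel, columns the
flattened TF points). Rows include condition and channel because
condition contrasts and topographies of the loadings are part of the
analysis; "observations by TF points" is the operative reading. Design
choices, each exposed in the API:

* **Separate fits per band.** Delta and theta decompositions are fully
  independent (their variance fractions need not sum below one).
* **Covariance, not correlation.** Columns are mean-centered only; TF
  cells share units, so rescaling them would distort the energy
  structure.
* **Retention.** The automatic rule retains the components before the
  largest drop in successive eigenvalue ratios (minimum one), standing in
  for a visual scree; an explicit count always overrides.
* **Rotation.** Varimax is implemented in the package (SVD-form iteration,
  relative criterion gain < 1e-8 or 500 sweeps, no Kaiser normalization by
  default since loadings share units); `stats::varimax` and a 2-D
  rotation-angle grid search serve as independent oracles in the tests.
  Loadings are scaled by the component SD before rotation (flag
  `scale_loadings`); the unscaled variant is one flag away.
* **Sign and selection.** Each component's largest-|loading| cell is made
  positive, removing the PCA sign indeterminacy. The delta-RewP component
  is the retained component with maximal squared-loading energy in
  0.5–3 Hz × 200–500 ms, the theta-FRN in 4–8 Hz × 250–400 ms; manual
  overrides are honored with a logged warning.
* **Scores.** A score is the mean over TF points of the elementwise
  product of a subject/condition surface at the scoring sensor with the
  component loading. Scores are linear in the (uncentered) surface, hence
  invariant to row order and to the presence of the other band's stack.

# Statistics

All DVs and continuous predictors are z-scored (binary diagnosis flags
stay 0/1); a scaling record allows exact back-transformation. Models are
`dv ~ Outcome + Σ covariate + Σ Outcome:covariate (+ age) + (1 | subject)`
— within × between interactions only, never between × between.
Multicollinearity is screened with VIFs (`1/(1−R²)`, flag at ≥ 5). The
theta model adds age as a covariate when the subject-mean DV correlates
with age at p < .05.

Robust fitting is Huber-weighted iterative reweighting around the mixed
model: residuals from the current fit receive Huber weights (tuning
constant 1.345 on MAD-scaled residuals) and the model is refit until the
weights stabilize. This is an observation-level M-estimation scheme; its
contract — bounded influence of gross outliers, agreement with the
unweighted fit on clean Gaussian data — is what the robustness study
verifies (robust beats plain ML in ≥ 90% of contaminated replicates;
< 2% disagreement without contamination at n = 200). Degrees of freedom
are Kenward–Roger on the final weighted fit, with Satterthwaite as the
recorded fallback when the Kenward–Roger computation is unavailable.
Simple slopes at each Outcome level are linear combinations of the fixed
effects with SEs from the coefficient covariance and the same df
machinery. P-values are reported unadjusted across models.

# Simulation studies and their problem sizes

Three replicate-level studies quantify what the pipeline recovers; their
sizes were chosen so each completes in minutes on a single core while
keeping the checks well-powered:

* **End-to-end recovery** uses the full reference conditions: 40
  subjects, 256 trials, 16 + 2 channels at 256 Hz. The extracted
  theta-FRN score correlates r ≥ 0.9 with the planted per-subject
  loss-theta amplitude (scores are energies, hence quadratic in
  amplitude, but the amplitudes are positive so the association remains
  essentially linear), and both condition main effects are recovered at
  p < .01 in the planted directions.
* **Effect-sign recovery** runs 20 replicate cohorts of 80 subjects with
  the EEG rendering scaled to replicate size (96 trials, 6 EEG + 1 EOG
  channels, 128 Hz acquisition, 64 Hz analysis) — the effect coefficients
  and noise model are unchanged. The loss-condition simple slope for
  reexperiencing is positive and significant, and the AUDIT-C slope
  negative, in at least 80% of replicates.
* **Null calibration and robustness** operate on the generative chain's
  condition-mean amplitudes (cohort → trials → per-trial amplitudes →
  condition means) rather than rendered EEG: the DV the EEG pipeline
  estimates, with the rendering step removed so that 200 null replicates
  and 50 contamination replicates are a matter of minutes. With all
  covariate coefficients zero, covariate terms reject at 0.05 ± 0.03.

# Degenerate inputs and tie-breaks

Zero-variance EOG channels, windows outside the epoch span, cutoffs at or
above Nyquist, non-finite waveforms, rank-exceeding retention requests,
singular between-subject designs and zero-variance z-score columns are
all errors with named causes. All-equal offers yield a flagged undefined
risky-choice proportion, not an error; rejection of every epoch of a
condition is an error (the ERP would be undefined). Ties in component
selection (exactly equal window energies) resolve to the lower index;
ties in `which.max` sign fixing resolve to the first maximal cell.

# Known limitations

The robust mixed-model scheme is an observation-level Huber IRLS; it does
not downweight extreme random effects separately, and its inference rests
on the weighted-fit covariance rather than a full robust sandwich. The
scree rule is a heuristic stand-in for visual inspection and can retain
too few components when eigenvalue ratios decay smoothly — the explicit
`n_components` override is the escape hatch. Blink propagation is linear
and instantaneous, which is exactly the assumption of regression-based
ocular correction; real ocular artifacts are only approximately so. The
generator's topographies are single Gaussians, so component mixtures that
real volume conduction produces (e.g. RewP/P300 overlap) are not
represented.
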