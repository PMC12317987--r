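---
title: "Estimating linear and non-linear directed connectivity with ncreann"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating linear and non-linear directed connectivity with ncreann}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncreann)
```

## The model

`ncreann` estimates directed interactions between source-level
electrophysiological time courses with a nonlinear multivariate
autoregressive (nMVAR) model. For an M-channel series $x(n)$, the model
writes the current sample vector as a function of the $p$ past samples of
all channels plus noise,

$$x(n) = f(x_p) + \sigma(n), \qquad
  x_p = [x_1(n-1),\,x_2(n-1),\,\dots,\,x_M(n-p)]^\top,$$

and realizes $f$ with a one-hidden-layer perceptron (10 tanh units by
default). The fitted predictor is then decomposed as
$f = f^{\mathrm{Lin}} + f^{\mathrm{NonLin}}$: the linear part is the
first-order Taylor expansion of the network at the standardized input mean
(the zero vector), and the nonlinear part is whatever the network does
beyond that tangent map. From the two parts we read off two unitless
directed-strength matrices:

* **lC** — `lC[i, j]` is the mean over lags of the absolute Taylor
  coefficient of channel *i* on channel *j*: the linear influence *i → j*.
* **NC** — `NC[i, j]` is the mean, over observed lag vectors and lags, of
  the absolute deviation of the instantaneous Jacobian
  $\partial \hat x_j / \partial x_i(n-\tau)$ from the Taylor coefficient:
  how much the fitted input–output slope *changes* with the state, i.e.
  genuinely nonlinear influence.

Two contracts pin these definitions down and are enforced by tests: a
network with identity activation has NC identically zero and lC equal to
the absolute least-squares VAR coefficients in the well-trained limit; and
NC shrinks to zero as the inputs are scaled toward the expansion point.
The aggregation (mean absolute coefficient over lags; mean absolute
Jacobian deviation over samples and lags) is isolated in one function
(`compute_lc_nc()`) so an alternative weighting can be substituted without
touching anything else.

## Training protocol

Lag-vector samples are built per trial (rows whose lag window would cross
a trial boundary are excluded, so concatenated trials never leak into each
other's history), channels are standardized to zero mean and unit variance
(parameters are stored on the model for exact inversion), and the network
is trained by *incremental* error back-propagation: weights are updated
after every sample, with momentum $\alpha$ and an adaptive learning rate
$\eta$. The adaptation is the classic heuristic: after an epoch whose
training error decreased, $\eta$ is multiplied by 1.05; an epoch whose
error grew by more than 4% is rejected outright (weights restored,
momentum cleared) and $\eta$ is multiplied by 0.7. Early stopping watches
a validation split and restores the best-validation weights after 20
stagnant epochs (restoring-best rather than keeping-last is a deliberate
choice; it makes the returned model independent of how far past the
optimum training wandered).

Cross-validation permutes the rows once under the configured seed, cuts
them into ten blocks, and lets fold *k* test on block *k*, validate on the
next block, and train on the remaining 80%. With 10 folds every row is
tested exactly once. Reported connectivity is the average over fold
models, which damps the dependence on the random initial weights (weights
start uniform in $[-0.5, 0.5]$). A `perm_seed` configuration field can
freeze the permutation while varying the initialization seed, which is how
the test suite isolates and measures that damping.

Defaults: $p = 5$, $H = 10$, $\eta = 0.001$, $\alpha = 0.9$, 500 epochs
maximum, patience 20, 10 folds. The learning-rate default was chosen by
measuring convergence on linear VAR fixtures: at $\eta = 0.01$ the
per-sample updates (effective step $\eta/(1-\alpha) = 0.1$) leave a
stochastic-gradient noise floor of roughly 0.1 in standardized-coefficient
units and the training error oscillates without converging; at 0.001 the
identity-activation network reaches the least-squares solution to within
0.02–0.05 per coefficient. The per-sample update order is the (fixed)
permutation order, so a fit is bit-reproducible given its configuration.

The model order is selected by fitting linear VAR models of increasing
order by least squares and scoring them with the Akaike and Schwartz
(Bayesian) criteria; the pipeline defaults to the Schwartz choice when the
two disagree, on parsimony grounds.

## Surrogate significance testing

Edge significance uses time-shifted surrogates: every channel is
independently circularly shifted by a uniform random offset in
$[L/8,\,7L/8]$ samples. This preserves each channel's marginal
distribution and autocorrelation while destroying cross-channel temporal
alignment — both driver and response are resampled. Each surrogate is
re-estimated with the *identical* configuration (same hyperparameters;
fresh weight initialization under a derived child seed), and an edge is
significant when its randomization p-value
$(1 + \#\{\text{null} \ge \text{observed}\})/(n+1)$ is at most
$1 - \text{percentile}/100$. At the default 95th percentile with 100
surrogates this rule is exactly calibrated (rejection probability
5/101 ≈ 0.0495 under exchangeability), which the test suite confirms
empirically on independent white-noise channels. Surrogates whose
training diverges are dropped and logged; more than 20% drops abort the
analysis. Non-significant edges are reported as missing values so that
downstream group statistics can restrict themselves to complete cases.

## The synthetic-data module

All validation runs on synthetic systems with known ground truth; the
generator is first-class, tested code.

* **Coupled nMVAR series** — a linear VAR part (stationarity is enforced
  by rejecting any spec whose companion-matrix spectral radius reaches 1)
  plus optional smooth nonlinear terms: `quadratic`
  ($c\,x_i(n-\tau)^2$), `tanh` ($c\tanh x_i(n-\tau)$), and `product`
  ($c\,x_i(n-\tau)\,x_j(n-\tau)$, a source-by-target interaction — the
  algebra of this form is our choice; only its name was given).
  Innovations are i.i.d. Gaussian per channel. Burn-in defaults to 500
  samples, enough for transients at pole magnitudes up to 0.98.
* **Band-resonant dynamics** — `band_resonant_coeffs()` places an AR(2)
  pole pair at the band center ($a_1 = 2r\cos(2\pi f_0/f_s)$,
  $a_2 = -r^2$), giving theta/alpha/beta-band spectra at 256 Hz without
  any filtering.
* **Activity volumes** — baseline plus Gaussian blobs plus noise on a
  5 mm grid, emulating a neural-activity-index map with suprathreshold
  clusters.
* **Behavior** — a 2×2 prime–probe design (response repetition vs
  alternation × feature overlap none vs full). Correctness is Bernoulli
  around cell accuracies with subject intercepts on the logit scale;
  reaction times are Gaussian around subject-and-cell means and are drawn
  only for correct probe responses (matching the convention of
  conditioning RT summaries on correct trials). `subject_sd` is a single
  dimensionless spread: one unit corresponds to 1 logit of accuracy and
  100 ms of reaction time (independent draws per subject). Default cell
  values for power checks are near the observed behavioral means of the
  emulated design (≈0.79–0.96 accuracy, crossover interaction).

What the generator does *not* emulate: volume conduction and source
leakage, non-Gaussian and nonstationary noise, inter-subject anatomy, or
any forward model. Passing tests therefore demonstrate estimator
correctness on the assumed model class, not robustness to every property
of real recordings.

## Signal preparation

Band-pass filtering uses a windowed-sinc (Hamming) FIR applied forward and
backward, so the net phase is zero. The filter order is
$3.3\,f_s/\min(\text{lower edge},\ \text{bandwidth})$ rounded to even: the
usual $3\,f_s/\text{lower edge}$ rule leaves a transition band wider than
the narrow theta and alpha passbands themselves (measured center-band gain
well below 0.9), while tying the order to the bandwidth keeps the
center-band gain at 1 and one-octave stopband gain below 0.01. Channel
means are removed before filtering, making the DC response exactly zero.
Epochs cover the half-open window [0, 1000) ms after each stimulus onset
(256 samples at 256 Hz); concatenation records every epoch start so lag
vectors never span trial joins.

**A caution on filtering before directed estimation.** Zero-phase
filtering is non-causal: each filtered sample mixes past *and future*
input. On a ground-truth system with strictly lagged coupling this smears
directed structure into the reverse direction, and for narrow bands a
time-shifted surrogate stays partially phase-locked to the original over
the autocorrelation time, further weakening the test. We observed both
effects directly on synthetic alpha-band systems: after refiltering,
reverse-direction edges reached surrogate significance about as often as
true ones. The pipeline therefore exposes `prep$filter`; the bundled
synthetic scenario generates band-resonant sources and skips refiltering,
the way band-specific beamformer time courses are already band-limited.
For broadband inputs the filter remains the default.

## Cluster extraction

The activity index is source power divided by the local noise estimate per
voxel. Thresholding keeps the top percent (default 1%) of the masked value
distribution, with a linear-interpolation percentile and *inclusive*
handling of ties at the threshold (deterministic; a degenerate all-equal
volume returns every voxel with a warning). Clustering groups suprathreshold
voxels whose centers lie within `eps = 1.5 × spacing` of each other —
face and edge neighbors connect, corner neighbors do not — and discards
groups smaller than `min_pts = 5` voxels as noise. We read "minimum of
five voxels per cluster" as a cluster-size threshold rather than a
density-core neighborhood count: with at most three grid neighbors inside
1.5 × spacing of any voxel on a line, a core-point rule with
neighborhood 5 could never form the thin clusters the parameters clearly
intend. Under the size reading, clusters are unique connected components,
so labels are order-invariant; the implementation is verified against a
brute-force transitive-closure oracle on hundreds of random fixtures.
Whether the threshold population is one band across all conditions or
per condition is exposed via the `mask` argument rather than fixed.

## Group statistics

The behavioral layer computes per-subject hit rates (correct probe
responses over *all* events in the cell, misses and false responses
included in the denominator) and mean reaction times over correct trials.
The 2×2 repeated-measures ANOVA exploits the fact that every effect in a
fully within-subject 2×2 design has one numerator degree of freedom: each
F is the squared paired-t of the corresponding subject-level contrast, and
partial eta squared is $F/(F + n - 1)$. This is verified against base R's
`aov()` error-stratum decomposition on random data.

Paired comparisons are routed by a normality check on the differences —
Lilliefors-corrected Kolmogorov–Smirnov by default (the plain KS variant
with estimated parameters is a switch), since means and variances are
estimated from the sample. Normal-looking differences get a two-tailed
paired t; otherwise a Wilcoxon signed-rank with Pratt handling of zero
differences (zeros are ranked, then dropped from the statistic; normal
approximation with tie and zero variance corrections). Spearman
correlation matrices use midranks and pairwise-complete observations,
reporting the n used per pair; p-values use the t approximation from
n = 10 and the exact null distribution below. The Benjamini–Hochberg
step-up is implemented directly (sorted p-values against $(i/m)q$) and
cross-checked against both `p.adjust` and a brute-force search over all
candidate thresholds.

## Pipeline and reproducibility

`run_pipeline()` executes: per-band volume → activity index → threshold →
clusters; then per band and condition: simulate-or-load → (optional
filter) → epoch → concatenate → standardize → fit → connectivity →
surrogate test; then behavioral statistics; writing every intermediate and
a JSON manifest (package version, master seed, per-stage status, outputs).
A band whose volume yields fewer than two clusters skips connectivity with
the skip recorded in the manifest, since directed connectivity needs at
least two regions. All randomness descends from one master seed through a
documented child-seed scheme (`child_seed()`, a fixed
linear-congruential mix of the master seed and small stage/unit
coordinates), so the whole run — and any single stage — is exactly
reproducible; the test suite checks byte-identical outputs across repeated
runs.

Problem sizes in the validation suite are desk-scale by design: series of
1 024–16 000 samples, 20 seeds per property, 50–100 surrogates, two or ten
folds depending on what the property probes. The bundled two-region
scenario uses a resonant driver (pole 0.85) and a weakly damped receiver
(pole 0.4) with lag-1 coupling 0.8: with equal strong resonances the
receiver's variance is amplified ~100-fold and the *standardized* coupling
coefficient drops below 0.08, burying the effect in estimator noise — an
instructive property of resonant driven systems rather than a bug.

## Known limitations

* **Linear coupling can leak into NC on the coupled edge.** A tanh network
  fitted to a *strongly linearly* coupled pair develops curvature along
  the fitted pathway; time-shifted surrogates (whose refits lack the
  coupling) cannot reproduce it, so the genuinely-coupled edge's NC can
  reach significance at well above the nominal rate (we measured ~40–60%
  at coupling 0.5) even though the interaction is purely linear. On
  linearly *uncoupled* channels — including channels with strong linear
  self-dynamics — NC is correctly calibrated (~5%). NC significance on an
  edge should therefore be interpreted jointly with its lC.
* Surrogate power degrades for narrowband signals (circular shifts
  approximate phase shifts); prefer broader bands or longer series.
* The NC aggregation follows the testable contracts above; other
  weightings over lags or samples are plausible and can be swapped in at
  the single substitution point.
* Fit quality (R², MSE) is reported per fold on held-out data, but the
  theoretical explainable-variance comparisons in the tests assume the
  generating model is known — on real data only the train/test gap is
  observable.
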