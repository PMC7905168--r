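---
title: "Methods: complexity and symmetricity of pupillary hippus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity and symmetricity of pupillary hippus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices
behind `pupilkinetics` — what each stage assumes, which knobs matter, and
what the synthetic-data experiments can and cannot establish about real
recordings.

## Preprocessing

Bilateral pupil recordings (left/right diameter in mm, 300 Hz) are cut
into non-overlapping 2-s epochs (600 samples) anchored at the recording
start; a trailing partial epoch is discarded. Missing samples — `NA`,
empty fields, or non-positive diameters, since remote trackers emit zeros
on track loss — are counted per eye *before* any repair. An epoch missing
strictly more than `max_missing_fraction` (default 0.10) of its length in
*either* eye is excluded; an epoch missing exactly 10% is retained (the
exclusion rule is a strict inequality). The per-eye rule is deliberate:
transfer entropy needs both eyes valid, so one bad eye invalidates the
pair. Surviving gaps are linearly interpolated between their flanking
samples; leading/trailing runs, which have only one flank, take the
nearest valid value. Interpolation is idempotent on gap-free epochs.

Filtering follows interpolation (the natural reading of the processing
order) and is a 4th-order Butterworth low-pass at 50 Hz applied
forward–backward, so it is zero-phase and does not displace hippus
features in time. The series is extended by 150 samples of odd reflection
at each end before filtering; this is long enough for the zero-initial-
condition transient of the filter to die out, so a constant epoch passes
through unchanged to ~1e-15 and a symmetric pulse stays symmetric to
better than 1e-8 relative. The passband includes DC, so epoch baselines
(temporal means) are preserved within 1%.

## Sample entropy

Complexity is quantified as sample entropy on the z-scored epoch:
`h(r, m) = −log(A/B)` where `B` and `A` count ordered template pairs
matching within tolerance `r` at lengths `m` and `m + 1`. Conventions,
each of which the equations leave open:

* **Norm** — Chebyshev (max-coordinate), the Richman–Moorman convention.
* **Template range** — both `B` and `A` are counted over templates
  `1..N−m`, so the ratio is a valid conditional probability; the raw
  counts are returned so other normalisations remain recoverable.
* **Tolerance** — strict inequality (`distance < r`), with `r` applied
  after z-scoring, so `r = 0.2` means 0.2 SD exactly. Consequently the
  measure is exactly invariant to affine maps of the series.
* **Logarithm** — natural; all entropies in this package are in nats.

Degenerate inputs are surfaced, not silently patched: constant series and
series with no length-`m` matches raise errors, and matches that never
extend to `m + 1` return `Inf` flagged `undefined`. Defaults `m = 2`,
`r = 0.2` follow standard practice for short physiological series.

## Transfer entropy

Symmetricity is the direction-averaged transfer entropy between the
z-scored eyes: `T_{X→Y} = I(y_{t+τ}; x_t^{d_x} | y_t^{d_y})`, with delay
`τ = 10` samples (0.033 s at 300 Hz) and embedding dimensions
`d_x = d_y = 5`. On a 600-sample epoch that leaves 550 usable
(target, source-past, target-past) triples in an 11-dimensional joint
space — far too sparse for histogram estimation, so the default estimator
is the Kraskov/Frenzel–Pompe k-nearest-neighbour conditional mutual
information (Chebyshev metric, `k = 4`). Two properties of this choice
matter downstream:

* small **negative** estimates are possible and are reported as-is;
  clipping at zero would bias the paired surrogate comparison;
* exact coordinate ties (possible on interpolated flat segments) break
  the neighbour counts, so a seeded sub-resolution jitter (1e-10 SD) is
  added — but *only when ties are present*. Untied data are left
  untouched, which keeps the degenerate identical-series case exact: when
  the two inputs coincide, the source embedding duplicates the
  target-past embedding, every marginal count cancels, and the estimate
  is exactly zero.

An equiquantal binned estimator (4 bins/dimension; series with small
finite alphabets keep their own values as categories) is provided for
low-dimensional problems, where it is consistent and can be checked
exactly against enumeration on discrete Markov chains. It is the
cross-check, not the workhorse.

## IAAFT surrogate testing

The null hypothesis — the series is a linear Gaussian stochastic process
observed through a static monotone nonlinearity — is realised by
iterative amplitude-adjusted Fourier-transform surrogates: starting from
a seeded random permutation, 50 iterations alternate between imposing the
original amplitude spectrum (keeping current phases) and rank-remapping
onto the original's sorted values. The count is fixed at 50 (no
convergence-based early stop), and the final step is the amplitude remap,
so the surrogate's value multiset equals the original's exactly while its
spectrum is approximate.

Per epoch, the metric is computed on the original and on each of 10
surrogates, the surrogate values are averaged, and one paired difference
per epoch enters a two-tailed paired t-test. The reported `t` is for
surrogate-minus-original, so positive `t` means the surrogates score
higher — the signature of destroyed deterministic structure when the
metric is entropy. Zero-variance differences are flagged degenerate
rather than reported as infinite t. For sample entropy, left and right
eyes are tested separately; for transfer entropy the two eyes'
surrogates are generated independently, which destroys linear
cross-correlation *as well as* nonlinearity. The bilateral transfer-
entropy test is therefore a test of any cross-dependence, not of
nonlinearity specifically, and the package's specificity experiments (the
linear-AR null) use the sample-entropy metric, for which the null is
exact.

## Inverted-U extraction

The scatter of a metric against epoch baseline is pooled across all
epochs and recordings and fitted with an exact Gaussian process —
squared-exponential kernel plus learned observation noise, inputs and
outputs standardised internally, hyperparameters maximising the log
marginal likelihood (L-BFGS-B from three seeded restarts; log-noise is
allowed down to e^−27 so noise-free inputs are interpolated to ~1e-6). A
GP is used because epoch baselines are inhomogeneously distributed along
the diameter axis; it smooths without imposing a parametric shape.
Prediction is on a 200-point uniform grid over the observed range, with a
±2 posterior-SD band. A centered moving average (default window 5% of
the x-range, truncated at the edges) then stabilises the profile, and the
peak is the argmax of the smoothed curve, ties broken to the lower index;
a peak on the first or last grid point is flagged non-interior. Peak
*locations* on such curves are meaningful; absolute peak heights depend
on the kernel and window and are not treated as calibrated quantities.

## The neural model

Bilateral LC populations are modelled as two Lorenz systems
(`a = 10`, `b_L = 8/3`, `c = 28`) diffusively coupled through their X
variables with `J = 0.7`, integrated by fixed-step RK4 from initial
values `(0, 1, 1)` and `(0, 1.1, 1.1)`. The step is `dt = 0.001` (well
inside RK4's stability region for these parameters) and the state is
recorded every 0.05 time units; analysis uses `10 ≤ t ≤ 300` (5,801
samples), excluding the transient while retaining the intermittent
switching between synchronised and desynchronised episodes. At `J = 0.7`
the pair is weakly synchronised; because the trajectory is chaotic, the
X₁–X₂ correlation over the window is sensitive to integrator details at
the few-percent level.

LC activity is `x_i = L·zscore(X_i) + b` with `L = 1.5` — by
construction `mean(x) = b` and `SD(x) = L` on the analysis window, so `b`
*is* the baseline firing rate. The symbol `b` is reserved for this
baseline; the Lorenz dissipation parameter is named `lorenz_b` to keep
the two from colliding in configuration. The parasympathetic arm is
`S_i = tanh(−w_ii x_i − w_ji x_j + β) + 1` with `w_11 = w_22 = 0.3`,
`w_12 = w_21 = w_c`, bounded in (0, 2); the sympathetic arm is
`D_i = 0.3·x_i`; pupil diameter is `P_i = D_i − S_i + P_0`, `P_0 = 3`.

Sweeps reuse a single Lorenz trajectory across all `b`, `w_c`, `β`
values — the downstream maps are static, so this is exact, not an
approximation — and compute SampEn (per side) and direction-averaged
TranEn on the z-scored `P_i` with the same settings as the data analysis
(`m = 2`, `r = 0.2`; `τ = 10` samples, `d_x = d_y = 5`, knn `k = 4`).
The headline sweep is `b ∈ [3, 7]` in steps of 0.1 at `w_c = 0.15`,
`β = 2.0`. The mechanism behind the inverted-U is visible in the
sphincter statistics: at small `b` the tanh saturates near 2 (low
variability), at intermediate `b` it traverses its sensitive region
(variability maximal), at large `b` it is driven to 0. That sensitive
region sits near `b ≈ β/(w_ii + w_c)`; for `β = 2` this is ≈ 4.4, inside
[3, 7], but for `β = 3.5` and `5.0` it moves to ≈ 7.8 and ≈ 11.1. The
β-shift experiment therefore sweeps `b ∈ [3, 12]` (step 0.2) so that all
three peaks are interior and their ordering is measurable; on [3, 7]
alone the larger-β argmax would clamp to the grid boundary.

## Synthetic data

The generator emulates what the pipeline needs from real recordings, not
their full physiology. Defaults: 120-s recordings at 300 Hz, baseline
diameters drawn from 2.5–7.5 mm, hippus fluctuation rescaled to 0.15 mm
SD (a plausible resting amplitude; entropy measures are scale-invariant,
so this choice is cosmetic), white measurement noise of 0.02 mm SD,
blinks at 0.2 /s (Poisson arrivals) lasting 100–400 ms, hitting both eyes
simultaneously — so the expected missing fraction is
0.2 × 0.25 s = 5%. Two hippus sources:

* `lcewn_model` — the neural simulation, with the drawn baseline mapped
  affinely from [2.5, 7.5] mm onto baseline firing rates [3, 7]; this
  encodes the assumed monotone link between pupil size and tonic LC
  activity, and makes the pooled cohort scatter trace the model's
  inverted-U.
* `linear_ar` — a bilaterally correlated Gaussian AR(2)
  (`φ = (1.8, −0.81)`, innovation correlation 0.8): exactly the
  surrogate-test null, used to calibrate specificity.

Everything is reproducible bit-for-bit from the seed. What passing tests
on these data show: the estimators, the surrogate machinery and the curve
extraction behave correctly on signals with the right gross structure
(slow bilateral fluctuations, blinks, noise, baselines spanning the
domain). What they cannot show: that real hippus has the model's
amplitude statistics, blink structure, or nonstationarities — participant
recordings were never available to fit against, and the generator's
parameters are plausibility defaults, not estimates.

## Problem sizes and runtime choices

The test suite and the acceptance script run at the study's native sizes
where results are quantitative (full 41-point sweeps on 5,801-sample
simulations; 600-sample epochs; a 50,000-sample chain for the discrete
transfer-entropy oracle) and at reduced sizes where the check is
structural (short cohorts for pipeline round-trips; 50 replicates of
12–14-epoch experiments for sensitivity/specificity rates; 120-point
scatters for peak-recovery coverage). Sample-entropy and neighbour
counting are O(N²) in compiled code; a full sweep condition evaluates in
about a minute on one CPU.

## Known limitations

* The knn transfer-entropy estimator's absolute scale depends on `k` and
  on series length; comparisons are meaningful within a fixed
  configuration, which is how the package uses them.
* The bilateral surrogate test conflates linear cross-correlation with
  nonlinearity (see above); a bivariate-preserving surrogate family would
  separate them but is out of scope.
* GPR peak heights are smoothing-dependent; only peak locations and the
  presence/absence of interior peaks are treated as findings.
* The model is a two-population caricature: no spiking, no multi-ensemble
  LC structure, no photic reflex input, and no parameter fitting to data.
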