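---
title: "Generative modelling of the bilateral face perception network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative modelling of the bilateral face perception network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facedcm)
```

## The scientific problem

Face perception engages a hierarchically organised network — early visual
cortex (EVC), the occipital face area (OFA) and the fusiform face area
(FFA) — in both hemispheres, with a well-documented right-hemispheric
dominance in right-handed observers. Whether left-handers engage this
network differently, and *how* (stronger recruitment of the left FFA
versus weaker recruitment of the right), is a question about directed,
task-dependent coupling, not about regional activation levels. `facedcm`
implements the full analysis chain used to address such questions with
dynamic causal modelling (DCM): a generative model of six-region BOLD
data under a lateralised block paradigm, a systematic 96-model space,
variational Bayesian model inversion, random-effects model and family
comparison, Bayesian model averaging, the frequentist group statistics
layered on top, and a pupillometry block metric as an independent
physiological read-out. A synthetic-cohort generator makes every stage
runnable, testable and calibratable without access to subject data.

## The generative model

Neural dynamics are bilinear. With `z` the vector of neural states (one
per region), `u` the experimental inputs, the state equation is

$$\dot z = \Big(A + \sum_j u_j B^{(j)}\Big) z + C u .$$

`A` (Hz) holds endogenous, task-independent coupling; each `B^(j)`
describes how input `j` modulates specific connections; `C` routes
driving inputs into the network. The structure is fixed across the model
space: within each hemisphere EVC, OFA and FFA are reciprocally
connected (including a direct EVC→FFA route); between hemispheres only
the homotopic OFA↔OFA and FFA↔FFA pairs are linked; the right-visual-field
input drives left EVC and vice versa. Self-connections are parameterised
directly in Hz with prior mean −0.5 Hz (no exponential
reparameterisation), matching the bilinear-era model generation this
pipeline reproduces.

Each region's neural activity passes through a balloon–windkessel
haemodynamic cascade — vasodilatory signal `s`, inflow `f`, venous
volume `v`, deoxyhaemoglobin `q` — with the classical constants
κ = 0.64 /s, γ = 0.32 /s, τ = 2.0 s, α = 0.32, E₀ = 0.4, V₀ = 0.04
(`default_hemo()`), and the standard percent-signal read-out with
k₁ = 7E₀, k₂ = 2, k₃ = 2E₀ − 0.2. During inversion only τ and E₀ are
estimated (as log-deviations with variance 1/16); the other constants
stay fixed, mirroring common practice for this model generation.

Integration is fixed-step fourth-order Runge–Kutta at microtime
resolution (default TR/16), one step per microtime bin. Inputs are
piecewise-constant boxcars, so a fixed step makes trajectories — and
hence finite-difference gradients and tests — exactly reproducible; a
step-halving check in the test suite bounds the discretisation error of
noiseless trajectories below 10⁻⁴ relative amplitude.

## Paradigm and regressors

The block design shows faces, objects or Fourier-scrambled images in the
left or right visual field: six conditions, each repeated 7 times in a
pseudo-randomised order (no condition thrice in a row), in 14.5-s blocks
(10 scans at TR = 1.45 s), each followed by an equally long fixation
block, across three runs separated by 60.9-s rest breaks. The default
session therefore has 84 blocks (42 stimulus + 42 fixation) and 924
scans; lead-in/lead-out scans are exposed as configuration because
acquired scan counts in real sessions include settle-in and tail periods
that the block arithmetic alone does not determine.

Five binary input functions feed the DCM — `RVF`, `LVF`, `faces`,
`faces|RVF`, `faces|LVF` — and six condition boxcars, convolved with a
double-gamma canonical HRF (peak 6 s, undershoot 16 s, ratio 6), form
the GLM regressors. The GLM applies a discrete-cosine high-pass filter
(cut-off 1/128 Hz) to data and design and evaluates the face-sensitivity
contrast `[2*F]-[O+S]` with weights (1, 1, −½, −½, −½, −½); the weight
convention is configurable. Region summary series are first
eigenvariates, sign-aligned with the mean voxel series.

## The model space

Models differ only in their modulatory structure, along three factors:
the *site* of intrahemispheric forward modulation (six families:
A = EVC→OFA; B = EVC→OFA and OFA→FFA; C = OFA→FFA; D = EVC→FFA;
E = EVC→OFA and EVC→FFA; F = all three — families B and F are the
anchored compositions; A, C, D and E are configuration defaults); the *context* modulating those intrahemispheric sites; and
the *context* modulating the four interhemispheric links. Each context
is one of S (visual field: RVF on left-hemisphere/left-to-right
connections, LVF mirrored), F (faces, bilateral), F+S (union), or F×S
(the conditional `faces|RVF` / `faces|LVF` inputs, lateralised like S).
Models are named inter/intra, interhemispheric context first. That
yields 16 context combinations per family and 96 models
(`enumerate_model_space()`), all sharing the endogenous skeleton, with
modulation restricted to forward and interhemispheric connections —
feedback is never modulated.

## Inversion: variational Laplace

`variational_laplace()` maximises the negative free energy `F`, the
variational lower bound on log model evidence, under Gaussian prior and
posterior assumptions. Design choices:

* **Priors** (`default_priors()`): zero-mean shrinkage with variance
  1/16 on endogenous off-diagonal and modulatory parameters, variance 1
  on driving inputs, variance 1/256 on self-connection deviations around
  −0.5 Hz — deliberately tight, echoing the regularising priors of the
  software generation being reproduced. All variances are arguments and
  are echoed into the posterior's metadata.
* **Gradients** by central finite differences (step 10⁻⁴ on the
  parameter scale) on the forward model; robustness and transparency
  were preferred over hand-coded sensitivities.
* **Ascent**: Gauss–Newton steps with Levenberg–Marquardt damping;
  a step is retained only if it increases `F`, so the stored trace is
  monotone by construction. Convergence requires two consecutive
  accepted increases below 10⁻⁴ nats (cap 128 iterations).
* **Noise**: per-region log-precisions with a Gaussian hyperprior whose
  mean is set optimistically from the data scale (log precision of the
  total data variance plus 2); hyperparameter updates are frozen for the
  first four accepted iterations. Both choices keep the likelihood
  informative early, when the parameters are still near the prior mean
  and residuals are large.
* **Baselines**: data and predictions are mean-centred per region, so
  fits are invariant to additive offsets.

### Multimodality and the multistart policy

In the generative regime defined by the group tables the network is
strongly recurrent (interhemispheric reciprocal couplings ≈ 0.2 Hz,
driving inputs ≈ 0.8 Hz sustained over 14.5-s blocks), and the
free-energy landscape develops well-separated local optima: a spurious
solution exists in which the signs of the feedback connections flip and
the driving inputs inflate by roughly a factor of two, producing nearly
the same BOLD predictions through the saturating haemodynamics. The
attraction basin of that solution contains the prior mean, so a single
ascent initialised there (the classical default, which remains this
package's `variational_laplace()` default) can return estimates biased
in exactly that pattern, some 20 nats below the better optimum.

`invert_dcm()` therefore runs a deterministic two-candidate multistart:
the prior mean, and `hierarchy_start()` — a data-independent pattern
encoding the textbook organisation of the ventral visual hierarchy
(feedforward mildly excitatory, feedback onto EVC mildly inhibitory,
back-projections between adjacent face-selective areas mildly
excitatory, interhemispheric homotopic links excitatory, positive
driving inputs; generic magnitudes of 0.1–0.8 Hz). The candidate with
the higher negative free energy is returned, so the data arbitrate.
Seeded random restarts (`restarts`, perturbations scaled by the prior
standard deviations) are also available but are not part of the default
path.

## Model comparison and averaging

`rfx_bms()` implements hierarchical (random-effects) model-frequency
inference: a variational Dirichlet update over model frequencies,
expected probabilities as normalised concentrations, and exceedance
probabilities by seeded Monte-Carlo sampling (default 10⁵ draws; the
repeat-run spread at that size is below 0.02). `family_bms()` assigns
per-model prior concentrations proportional to 1/family-size (uniform
prior over families) and aggregates sampled frequencies within families.
`compare_group_frequencies()` asks whether two groups share one
frequency profile by comparing the variational evidence bound of a
pooled Dirichlet-multinomial model against independent per-group models
at equal prior odds; exact constructions of this comparison vary across
published implementations, so this one is documented here and fully
seeded.

`occams_window()` retains models with posterior odds against the
subject's best model above 0.05, and `bma_subject()` averages posterior
means over the retained set with weights ∝ exp(F − F_best), imputing
zero for parameters absent from a model's structure (a model without a
connection asserts its absence). Averaging is per subject — the
"individual estimates entered into group statistics" workflow — with the
group-frequency-weighted variant deliberately out of the default path.

## Group statistics

`ttest_and_fdr()` applies one- or two-sample t-tests per parameter with
Benjamini–Hochberg correction *within* parameter classes (endogenous,
one class per modulatory input, driving); zero-variance parameters are
flagged, not tested. `mixed_anova_2x2()` and `mixed_anova_3way()` are
classical mixed ANOVAs built on `aov()` error strata; the three-level
stimulus factor uses uncorrected degrees of freedom by default with
Greenhouse–Geisser available by flag (reported df conventions for this
design vary across software and are not treated as normative).
`bootstrap_li()` computes the lateralization index
LI = (ΣL − ΣR)/(ΣL + ΣR) over bootstrap resamples of suprathreshold
voxel values, reporting a 25%-trimmed mean of 10⁴ resamples; the
threshold defaults to half the overall maximum, and a side emptied by
thresholding contributes a zero sum (full dominance of the other side).
These bootstrap internals follow the trimmed-bootstrap philosophy of the
standard lateralization toolboxes but are explicit choices here, all
configurable.

## Pupillometry

Pupil traces (500 Hz) are preprocessed in a fixed order — cubic-spline
interpolation over annotated blinks (edge blinks are filled by
nearest-valid-value extension first, because spline extrapolation is
unstable), z-normalisation over the whole session using all interpolated
samples, then a centred 50-ms moving average (25 samples at 500 Hz,
edge-replicated) — and the order is recorded in the trace metadata.
Blink *detection* is out of scope: blinks arrive as annotations, as from
an eye-tracker's detector. The per-block metric is the mean over
[onset + 9 s, onset + 11 s) minus the mean over [onset, onset + 50 ms),
with half-open, left-aligned windows; condition averages feed the
3-way mixed ANOVA. Whether the normalisation statistics should exclude interpolated spans
is a genuinely open choice; the default includes all samples (matching
the fixed pipeline order) and a flag is available.

## The synthetic cohort

`generate_cohort()` produces complete right- and left-handed cohorts:
per-subject connectivity parameters drawn Gaussian around the group
means with the tabulated between-subject standard deviations
(self-connections truncated negative), BOLD sessions simulated at a
configured signal-to-noise ratio (SNR = noiseless signal sd / noise sd;
default 1, since no empirical ROI SNR is available — the tests exercise
0.5–2), pupil traces (per-block square responses with a 500-ms
half-cosine onset, condition- and group-specific amplitudes, pink noise,
Poisson blinks), and per-region suprathreshold voxel sets with
configured lateralization. The default generating models are family B
(S/F) for right-handers and family F (S/F) for left-handers — the two
winning families — which makes family recovery a meaningful test.
Parameters whose group-level estimates are not significant still use
their tabulated means/sds: they are the best available estimates. The pupil amplitude
defaults implement a faces-only group difference (−0.30 vs −0.15 in
z-units for faces, equal amplitudes for objects and scrambled images),
and the LI targets make the FFA right-dominant in right-handers only.

An `antithetic` option draws consecutive subject pairs as mirror images
around the group means. The marginal distribution per subject is
unchanged, but the cohort mean of every generative parameter equals its
table value exactly, which removes draw luck from cohort-level recovery
experiments; the acceptance script uses it for that reason.

What the generator does *not* emulate: scanner drift and motion,
physiological noise structure (observation noise is i.i.d. Gaussian),
voxel-level spatial structure, eye movements, and any nonstationarity of
the neural parameters within a session. Passing recovery tests on these
cohorts therefore demonstrates the correctness and calibration of the
pipeline under its own assumptions, not performance on real fMRI data.

## Problem sizes used by the tests

The packaged test suite runs the recovery experiment at 10 subjects with
18 stimulus blocks per session (360 scans, the full paradigm scaled to a
single run) on a TR/8 microtime grid, and the family-recovery experiment
at 6 subjects, two families × four context combinations, 360-scan
sessions, fixed haemodynamic constants, a 32-iteration cap and relaxed
(10⁻³ nat) convergence for the per-model inversions. The acceptance
script runs the recovery experiment at the default TR/16 microtime.
These sizes keep the whole suite inside a lunch break on one laptop core
while preserving each experiment's discriminative power (the step-halving
check bounds the TR/8-vs-TR/16 trajectory difference below 10⁻⁴ relative
amplitude); the full-session, full-space configuration is a parameter
change, not a code change.

## Known limitations

* The variational scheme shares the usual fragility of Laplace-style
  DCM inversion: multimodality is mitigated by the multistart policy,
  not eliminated; single-subject estimates can still select a spurious
  basin, which inflates cohort-level dispersion.
* Free energies are comparable across models only for identical data;
  the package does not guard against comparing evidences computed on
  different series.
* `compare_group_frequencies()` uses variational evidence bounds, not
  exact marginal likelihoods; its posterior probability is approximate.
* The 3-way ANOVA assumes complete, balanced cells and offers no
  missing-data handling.
* Pupil preprocessing assumes externally supplied blink annotations and
  a constant sampling rate.
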