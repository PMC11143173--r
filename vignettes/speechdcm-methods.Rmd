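---
title: "Methods: dynamic causal modeling of the audiovisual speech network"
author: "speechdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic causal modeling of the audiovisual speech network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechdcm)
```

## The scientific problem

The McGurk effect — hearing /pa/ while watching [ka] and perceiving /ta/ —
is a window on how the brain fuses auditory and visual speech. `speechdcm`
implements an effective-connectivity analysis of this system over four
left-hemisphere regions: precentral gyrus (PrG, articulatory motor cortex),
posterior superior temporal gyrus (pSTG, multisensory integration), mid
superior temporal gyrus (mSTG, auditory speech) and fusiform gyrus (FuG,
visual lip movements). The pipeline asks three questions: which directed
network architecture best explains the regions' BOLD dynamics during
audiovisual syllable perception; how strong are the couplings; and do the
couplings differ between people who are strongly vs weakly susceptible to
the illusion.

## The generative model

Neuronal dynamics follow the bilinear form

$$\dot z = (A + u\,B)\,z + C\,u,$$

where $z$ is the four-region neuronal state, $u(t)$ the 0/1 stimulation
indicator, $A$ (Hz) the endogenous coupling, $B$ (Hz) its input-dependent
modulation, and $C$ the driving weights. Driving input enters at mSTG
(auditory) and FuG (visual) in every model. Each region's neuronal state
drives a Balloon–Windkessel cascade — vasodilatory signal $s$, inflow $f$,
venous volume $v$, deoxyhemoglobin $q$ —

$$\dot s = z - \kappa s - \gamma(f-1),\quad \dot f = s,\quad
\tau\dot v = f - v^{1/\alpha},\quad
\tau\dot q = f\,\frac{1-(1-E_0)^{1/f}}{E_0} - v^{1/\alpha}\frac{q}{v},$$

with BOLD read-out $y = V_0\,(k_1(1-q) + k_2(1-q/v) + k_3(1-v))$,
$k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$. Hemodynamic defaults are
$\kappa = 0.64\,\mathrm{s^{-1}}$, $\gamma = 0.32\,\mathrm{s^{-1}}$,
$\tau = 2$ s, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$ — standard
literature values, echoed in every output's metadata and configurable per
region.

Integration uses fixed-step RK4 on a microtime grid (default TR/16 =
0.125 s for simulation) with the input held piecewise-constant within a
step; halving the step changes the simulated BOLD by well under $10^{-3}$
relative RMS, and the compiled trajectory is cross-checked in the test
suite against an independent stiff-solver integration and, in the linear
limit, against the matrix-exponential solution.

## The model space

Candidate networks share a fully bidirectional core among pSTG, mSTG and
FuG and differ in (i) which of the three PrG pairings exist endogenously —
the seven non-empty subsets define families 1–7 — and (ii) how modulation
acts on the existing PrG pairings (factor codes a ∈ 1..4 for PrG–pSTG,
b, c ∈ 1..3 for PrG–mSTG and PrG–FuG). Enumerating admissible codes within
each family (a fastest, then b, then c) yields exactly 44 models with
family sizes (16, 4, 8, 8, 4, 2, 2). The bottom-up modulations
mSTG→pSTG and FuG→pSTG are present in all models by default; because the
factorial description leaves open whether they belong to every model or
only the winning one, the switch `pstg_bottom_up` makes this assumption
explicit and reversible.

## Stimulation timing and identifiability

The study protocol has 3 sessions of 199 volumes at TR = 2 s: a 20-s
fixation, then 18 contiguous 21-s blocks (7 trials each of 2 s stimulation
plus 1 s fixation); the first 10 volumes are discarded. Because
18 × 21 s exactly fills the retained window, a block-level boxcar is
constant over the analyzed data and carries no information. The default
input is therefore the trial-level on/off train, the experiment's actual
stimulation schedule (`input_unit = "block"` is provided for comparison).

This timing has a consequence that shapes the whole estimator: the input's
duty cycle never varies across the session, so the data identify the
*sustained* dynamics $S = A + \bar u B$ (with $\bar u \approx 0.63$ the
session-mean input) far better than $A$ and $B$ separately. Fitting in raw
$(A, B)$ coordinates produces sign-flipped posterior modes even from
perfect starting values. The estimator therefore centers the bilinear
input internally (the common input-centring convention of neuroimaging
DCM software), places its working priors on $(S, B)$ — with
$\mathrm{var}(S) = \mathrm{var}(A) + \bar u^2\,\mathrm{var}(B)$ as implied
by the uncentered scales — and maps estimates back exactly via
$A = S - \bar u B$ (the posterior covariance is transformed by the same
linear map). All reported quantities are in the uncentered convention.

## Priors and inversion

Free parameters are the structurally present couplings: off-diagonal $A$
entries (prior $\mathcal N(0, 1/8)$), $B$ and $C$ entries
($\mathcal N(0, 1)$), the self-connection log-scales with
$A_{ii} = -2\,e^{\theta_{ii}}$ ($\mathcal N(0, 1/64)$), and global
log-scales on $\kappa$ and $\tau$ ($\mathcal N(0, 1/256)$). The
self-connection baseline of −2 Hz (rather than the conventional −0.5) is a
stability requirement of this network's coupling magnitudes: with
modulatory strengths of up to ±4 Hz, the group-mean effective matrices
$A + B$ have a positive spectral abscissa unless self-inhibition is of
order −2 Hz, and the synthetic ground truths use the same scale so that
estimator and generator live in the same regime.

Inversion is a variational-Laplace scheme: Gauss–Newton ascent on the
log-joint under independent Gaussian observation noise per region, with
a Levenberg damping ladder and step-halving so that the recorded free
energy never decreases; per-region noise precisions are updated by
restricted maximum likelihood (guarded so the update is only accepted when
it does not lower the recorded free energy); gradients are central finite
differences (step $10^{-4}$) on the integrated forward model. Session
means (and optional discrete-cosine drift terms) are projected out of data
and prediction alike. The free energy is the Laplace bound
$F = \text{accuracy} - \text{complexity}$ including the expected-accuracy
trace correction; on a conjugate linear-Gaussian model it reproduces the
exact log marginal likelihood to $10^{-6}$. Because the log-joint is
non-convex, each fit runs a small multistart (prior mean plus one seeded
prior draw by default) and keeps the best free energy. Defaults: tolerance
$10^{-4}$ nats, 64 iterations maximum, prediction integrated at TR/4
(free energies change by under 0.1 nat vs finer steps on probe data).

## Group inference

Random-effects model selection treats the model as a subject-level random
variable with Dirichlet-distributed frequencies, estimated by the standard
variational fixed point; exceedance probabilities come from seeded
Monte-Carlo Dirichlet draws ($10^6$ by default, matching two-decimal
reporting precision). For family inference the per-model prior counts are
max-family-size/|family| so every family carries equal prior mass despite
sizes ranging from 16 to 2; family exceedance sums sampled frequencies
within families before taking the max. Bayesian model averaging within the
best family weights each member by its renormalized model exceedance
probability — the convention this pipeline follows by default — with the standard
expected-frequency and per-subject-responsibility weightings available as
options. The variational scheme is mildly overconfident relative to exact
posterior integration at very small n (deviations up to ~0.05 in expected
frequencies at n = 3), which the test suite documents; the closed-form
Beta checks of the exceedance computation hold to $10^{-3}$.

## Behavior

Susceptibility is the proportion of /ta/ reports among the 10 trials at
the +133 ms SOA (visual leading), where the group fusion curve peaks;
subjects above 50% are strong perceivers, below 50% weak, and a
configurable closed band (default the single point 0.5) excludes "medial"
perceivers, since the original exclusion rule is not numerically specified.

## Parameter statistics

Per connection and per block (A, B, and A+B on the modulated connections):
values are adjusted by OLS on mean-centered age, gender (0/1) and years of
education — adjusted value = covariate-adjusted mean + residual, so the
one-sample t test of the mean is not vacuous, and the adjustment is
invariant to covariate shifts; then the all-subject one-sample t, Spearman
correlation (Pearson on mid-ranks, t-approximation with df = n−2) with
susceptibility, per-group one-sample t, and pooled-variance two-sample t
(Welch switchable). Benjamini–Hochberg FDR at q = 0.05 is applied within
each statistic family per block — the 12 A, 6 B and 6 A+B one-sample
tests form separate families, and likewise the correlations, per-group
tests and group differences — mirroring the column structure of the
reported table.

## The synthetic cohort

The generator emulates the study conditions: 25 strong and 20 weak
perceivers; per-connection ground-truth couplings drawn from the published
group means/SDs on the winning structure, with rejection resampling until
$A + uB$ is stable for $u \in \{0, 1\}$; the full session/block/trial
timing; demographics (age 21.84 ± 2.115 vs 20.60 ± 2.257 years, education
15.40 ± 1.443 vs 15.20 ± 1.824, male fractions 12/25 vs 13/20, mean
frame-wise displacement 0.088 ± 0.051 vs 0.087 ± 0.040 mm). Observation
noise is white Gaussian per region with SD = SD(session-mean-corrected
noiseless signal)/SNR — the field's usual task-signal-to-noise convention.
Susceptibility targets come from a logistic link on the sign-weighted
coupling z-score over the connections whose behavior correlations are
reported as significant (slope 1.2, logit noise 0.3), truncated to the side
of 50% consistent with the group label; the trial generator realizes the
target as the peak of a Gaussian-in-SOA fusion curve (width 100 ms —
within the breadth of reported audiovisual temporal-binding windows) with
non-fusion mass split 3:1 between /pa/ and /ka/.

What the generator does *not* emulate: temporally autocorrelated
physiological noise, motion artifacts, voxel-level spatial structure
(voxel fixtures for the signal-conditioning functions are rank-1 signal
plus noise), session-order effects, or any dependence of the BOLD response
on SOA (the scanner task used synchronous syllables). Passing recovery
tests on these data therefore demonstrate internal consistency of the
pipeline under idealized noise, not performance on real fMRI.

## Known limitations

The continuous-stimulation design bounds what any estimator can recover at
realistic noise. A Fisher-information analysis at the generating values
shows the modulatory block has near-flat eigendirections (likelihood
precision comparable to the prior's), and a linearized-optimal estimate of
the total coupling A+B attains a pooled truth-correlation of only ~0.66 at
SNR 1.0; the full pipeline reaches ~0.75–0.8 because model averaging pools
information. Family-level inference is nevertheless decisive (the
generating family is recovered with exceedance ≈ 0.99), while the
fine-grained distinction between the two leading family-1 members (models
13 and 11, which differ only in weakly identified modulatory entries) is
not reliable at that noise level. Individual A/B splits should be
interpreted with caution on data of this design; the sustained coupling
S, the family, and group contrasts are the robust quantities.

## Problem sizes used by the test suite

Unit tests invert a reduced single-session design (6 blocks, 63 retained
volumes) where a fit takes well under a second; the recovery study uses
the full 3-session design with 8 subjects, the four models {13, 11, 37,
43} and 10 seeds; the statistical-calibration study uses 200 null
replicates at n = 8 + 8 and 20 effect replicates at n = 10 + 10 on
generator ground truths. These sizes are the package's own
reproducibility envelope: large enough for the qualitative claims above,
small enough to run routinely.
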