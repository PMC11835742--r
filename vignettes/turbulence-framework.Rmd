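---
title: "Whole-brain turbulent dynamics: models, measures and design choices"
author: "turbfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain turbulent dynamics: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Resting-state BOLD activity shows highly variable, vortex-like pockets of
local phase synchronization whose statistics resemble fluid turbulence.
`turbfmri` quantifies this regime on parcellated BOLD time series and uses
it in two complementary ways: *model-free*, as a family of
turbulence-based information-flow measures that can differ between
clinical groups and correlate with treatment outcome; and *model-based*,
through a whole-brain network of Stuart–Landau oscillators whose fitted
global coupling supports in-silico perturbation experiments.

The package ships a synthetic-cohort generator so that the entire
analysis — measures, group inference, response classification, model
fitting, perturbation — runs end to end without any external data.

# Model-free measures

All measures derive from the instantaneous phases of narrowband BOLD.
Each region's series is mean-removed, band-pass filtered (default
0.008–0.08 Hz, the conventional resting-state band) with a zero-phase
second-order Butterworth filter, and turned into phases
$\varphi_k(t)$ via the analytic signal. The first and last 10 volumes are
dropped after the transform to suppress edge artifacts. The analytic
signal is computed by the standard FFT half-spectrum construction
implemented directly in the package.

The central object is the **local Kuramoto order parameter** at
inverse-distance scale $\lambda$ (units 1/mm):

$$R_j(t)\, e^{i\theta_j(t)} \;=\;
  \frac{\sum_k e^{-\lambda d_{jk}}\, e^{i\varphi_k(t)}}
       {\sum_k e^{-\lambda d_{jk}}},$$

with $d_{jk}$ the Euclidean distance between region centroids in MNI-like
mm coordinates and the self term included, so the kernel is normalized
and full synchrony gives $R = 1$ exactly. The characteristic probing
length is $1/\lambda$: $\lambda = 0.01$ integrates over ~100 mm (near
whole-brain), $\lambda = 0.3$ over ~3.3 mm (local neighborhoods). The
default grid is the eleven scales $\{0.01, 0.03, 0.06, \dots, 0.30\}$.

From $R$ the package derives:

* **Amplitude turbulence** — the sample SD (n−1 denominator) of $R$
  pooled over regions and volumes; the spatiotemporal variability of
  local synchronization.
* **Node-level metastability** — the per-region SD of $R$ over time.
* **Information cascade flow** — the Pearson correlation, pooled over
  regions and time, between $R_\lambda(t)$ and
  $R_{\lambda-\Delta\lambda}(t+1)$ for adjacent scales (one-volume lag);
  **information cascade** is the mean flow across adjacent pairs.
* **Information transfer** — for one scale, the pairwise correlation over
  time of $R$ rows is averaged in 2 mm distance bins and
  $\log \bar c(r)$ is regressed on $\log r$ over a fit range (default
  10–75 mm, an inertial-subrange stand-in). The statistic is the
  *negative* slope, so larger values mean faster spatial decay; a planted
  power law $c(r) = r^{-s}$ yields exactly $s$. The sign convention is
  recorded in the serialized output.

```{r}
library(turbfmri)
geom <- generateGeometry(60, seed = 1)
bold <- readTimeseries("subject01.tsv", tr = 2)
profile <- computeProfile(bold, geom)
turbulence(profile)[c("0.01", "0.03", "0.06")]
informationCascade(profile)
```

# The whole-brain model

Each region follows the normal form of a supercritical Hopf bifurcation
(Stuart–Landau oscillator) with bifurcation parameter $a$ (default
−0.02: noise-driven fluctuations just below oscillation onset), intrinsic
angular frequency $\omega_j$ estimated from the empirical spectral peak
in 0.04–0.07 Hz, and diffusive coupling through the anatomy:

$$dx_j = \big[(a_j - x_j^2 - y_j^2)x_j - \omega_j y_j +
  G \textstyle\sum_k C_{jk}(x_k - x_j)\big]dt + \sigma\sqrt{dt}\,\xi_j$$

and symmetrically for $y_j$ with $+\omega_j x_j$. The coupling matrix
follows the **exponential distance rule** $C_{jk} = e^{-\gamma d_{jk}}$
(default decay 0.18/mm, the primate EDR rate conventional for this model
class), with long-range connectome exceptions merged on top by an
elementwise maximum after normalizing the connectome to a unit maximum.

Integration is Euler–Maruyama at $dt = 0.1$ s with $\sqrt{dt}$ noise
scaling, a 20 s discarded transient, and the $x$ component recorded at
the output TR. The scheme is validated in the test suite against the
closed-form radial solution of the uncoupled oscillator (limit-cycle
radius $\sqrt a$, cycle frequency $\omega/2\pi$, subcritical decay).

The **global coupling $G$** is fitted by sweeping a grid, simulating
repeatedly per grid value, and minimizing the mean squared difference
between model and empirical functional-connectivity-versus-distance
curves (2 mm bins). Ties break toward the smaller, more subcritical G.
MSE was chosen as the error norm because only the fitted quantity, not
the norm, is prescribed by the framework; the curves are smooth and
low-dimensional, so the choice is not critical.

# In-silico perturbation

At the fitted working point, each trial draws an independent shift
$\Delta a_j \sim \mathrm{Uniform}(0, \Delta a_{\max})$ per region
(positive shifts, mimicking a global increase in excitability; a
symmetric option exists), simulates perturbed and unperturbed runs with
the *same* noise seed (paired design, for variance reduction), and
records the difference in the spatiotemporal mean of $R$ at the readout
scale ($\lambda = 0.01$, the scale most sensitive to group differences).
**Susceptibility** is the mean absolute per-trial shift; the
**information encoding capability** is the SD of the absolute shifts.
The modulus is taken per trial before aggregation.

A saturation property of this protocol is worth knowing: with the
baseline at $a = -0.02$, shifts of order 0.05 already push most regions
well past the bifurcation, so the mean order parameter approaches its
ceiling and the susceptibility dose–response flattens — and can decline
slightly — between $\Delta a_{\max} = 0.1$ and $0.2$, as amplitude
heterogeneity across regions weakens effective phase coupling. The
dose–response is steep and monotone below that range.

# Group inference and classification

Group contrasts use a **permutation test on the Wilcoxon rank-sum
statistic** (default 1000 label shuffles, two-sided, add-one convention,
so the smallest attainable p is $1/(n_{perm}+1)$), Cohen's d with pooled
SD, and Benjamini–Hochberg FDR across the measure family or across
nodes. Node-level analysis selects, among FDR-significant nodes, those
in the bottom 30% quantile of the significant raw p-values and tallies
their resting-state networks; a mode taking the quantile over all nodes
is available, as the selection rule admits both readings.

The **response classifier** consumes exactly seven baseline features —
turbulence and information transfer at $\lambda \in \{0.01, 0.03,
0.06\}$ plus the information cascade — and trains a Gaussian
radial-kernel SVM (cost 1, kernel width from the median pairwise
training distance) on class-balanced subsamples with stratified 90/10
splits, standardizing with training-fold statistics only. Significance
comes from re-running the identical evaluation under shuffled labels.
A 10-fold stratified cross-validation mode is also provided; the two
modes correspond to the two descriptions that coexist for this design in
the source literature. At small samples (≈20 per class) the repeated
90/10 estimator is noticeably pessimistic under the null (validation
folds of a fixed finite sample anti-correlate with their training
folds), which matters when interpreting near-chance AUCs.

# The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions for all downstream tests:

* **Geometry** — centroids sampled in an ellipsoid of semi-axes
  70 × 85 × 60 mm (brain-like extent) with ≥ 3 mm spacing; RSN labels by
  spatial k-means into the canonical eight networks.
* **Connectome** — EDR kernel plus a configurable number of boosted
  long-range (> 40 mm) pairs with weights Uniform(0.5, 1), emulating
  diffusion-MRI exceptions. The cohort default is 40 boosted pairs.
* **Cohorts** — three groups (controls / responders / non-responders,
  default 20 each) of 300-volume, TR = 2 s subjects simulated from the
  Hopf model at group-specific coupling (default G = 1.3 / 1.5 / 0.9),
  with per-subject derived noise seeds and one shared draw of intrinsic
  frequencies (uniform in 0.04–0.07 Hz). Group differences are planted
  *through the coupling mechanism* — the same mechanism the model-based
  analysis fits — rather than through additive signal.
* **Outcomes** — HAMD6 percent change is generated by a Gaussian copula
  on the rank of each patient's baseline turbulence at $\lambda = 0.01$
  (score scale 50 ± 20), so the population correlation matches the
  target (default 0.4) without distributional assumptions; baselines are
  uniform on the moderate-to-severe range 12–22. Controls carry NA
  scores. The empirical distribution of percent change is not modeled;
  only its rank-correlation structure is.

What the generator does **not** emulate: scanner and physiological
noise, motion, preprocessing artifacts, hemodynamic convolution,
subject-level anatomy. Passing tests therefore demonstrate that the
implementation recovers effects planted through coupled-oscillator
dynamics at realistic problem sizes — not that real MDD cohorts will
show the same effect sizes.

# Numerical choices

* Sample SD (n−1) throughout, matching the reference lineage of the
  framework.
* $R$ values within kernel-sum rounding error ($10^{-10}$) of 1 are
  snapped to 1, so perfectly synchronized inputs give turbulence 0
  exactly.
* Correlations over zero-variance inputs raise errors rather than
  returning NaN; the one deliberate exception is the information
  transfer of a fully synchronized field, which is the degenerate
  no-decay case and returns 0.
* Distance bins are indexed by `floor(d / width)` with centers at
  `(index + 0.5) * width`; bins with non-positive mean correlation are
  excluded from the log–log fit.
* All randomness flows from explicit integer seeds through one affine
  counter scheme; package calls never disturb the caller's RNG state.
* G grids are built from integer sequences (`seq(6, 18) / 10`) so grid
  membership is exact in floating point.

# Problem sizes used by the shipped tests

The test suite and the acceptance script run on 25–60-region geometries,
cohorts of up to 20 subjects per group at 300 volumes, 1000-permutation
tests, 100-repetition classifier evaluations and 30-trial perturbation
experiments — sizes chosen so the full suite completes in minutes on one
CPU while keeping every planted effect comfortably detectable.

# Known limitations

* The susceptibility dose–response saturates above shift ranges ~0.1
  (see above); dose comparisons should stay below the saturation knee.
* Euler–Maruyama at dt = 0.1 s slightly inflates limit-cycle radii
  (second-order in $\omega\,dt$); the closed-form tests integrate at
  dt = 0.01 s where the bias is negligible, and FC-based fitting is
  insensitive to it.
* Node frequencies are group-averaged when fitting; per-subject
  frequency fits are not implemented.
* Regional (single-node) perturbation maps are out of scope; the
  protocol is global by design.
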