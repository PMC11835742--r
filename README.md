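# turbfmri

Whole-brain **turbulent dynamics** for parcellated resting-state fMRI:
model-free information-flow measures built on the local Kuramoto order
parameter, a Stuart–Landau (Hopf) whole-brain model with
exponential-distance-rule coupling, in-silico perturbation readouts, and
the statistics and classification layer needed to relate all of it to
clinical treatment response — plus a synthetic-cohort generator so the
whole analysis runs with no external data.

## Who this is for

Computational neuroscientists and neuroimaging methodologists who want
to (a) compute turbulence-based measures (amplitude turbulence, node
metastability, information cascade and transfer) on region × time BOLD
matrices, (b) fit and perturb anatomy-constrained whole-brain oscillator
models, and (c) test whether such baseline measures separate clinical
groups or predict outcomes — for example, SSRI treatment response in
depression, the setting the framework was developed in.

## The core quantities

With phases $\varphi_k(t)$ from band-passed (0.008–0.08 Hz) BOLD and
centroid distances $d_{jk}$ in mm, the local Kuramoto order parameter at
inverse-distance scale $\lambda$ (1/mm) is

$$R_j(t)\,e^{i\theta_j(t)} = \frac{\sum_k e^{-\lambda d_{jk}} e^{i\varphi_k(t)}}{\sum_k e^{-\lambda d_{jk}}}.$$

Amplitude turbulence is the pooled SD of $R$ over space and time; node
metastability its per-region SD over time; the information cascade the
mean lag-1 correlation of $R$ across adjacent scales; information
transfer the decay rate of the spatial correlation of $R$ with distance.
The model-based layer couples Stuart–Landau oscillators
($dx_j = [(a - x_j^2 - y_j^2)x_j - \omega_j y_j + G\sum_k C_{jk}(x_k - x_j)]dt + \sigma\sqrt{dt}\,\xi_j$)
through $C_{jk} = e^{-0.18\,d_{jk}}$ with long-range exceptions, fits the
global coupling $G$ to FC-vs-distance curves, and measures susceptibility
and information encoding capability under random positive shifts of the
bifurcation parameter.

## Worked example

```r
library(turbfmri)

geom    <- generateGeometry(60, seed = 1)              # brain-like centroids + RSN labels
conn    <- generateConnectome(geom, nLongrange = 40, seed = 2)
spec    <- CohortSpec(60, groupSizes = c(20L, 20L, 20L),
                      groupG = c(1.3, 1.5, 0.9), seed = 11L)
cohort  <- generateCohort(spec, geom, connectome = conn)

prof <- computeProfile(cohort[[1]]@bold, geom)
prof
#> TurbulenceProfile
#>   turbulence: 0.01=0.2032 0.03=0.2064 0.06=0.2032 0.09=0.1592 0.12=0.1095 ...
#>   information cascade: 0.8924 over 10 scale pairs
#>   information transfer: 0.01=0.0050 0.03=0.0690 0.06=0.3701 0.09=0.6679 ...
```

The turbulence map reads: at near-global scales (λ = 0.01–0.06,
kernel length 100–17 mm) local synchronization fluctuates with SD ≈ 0.20;
variability shrinks at finer scales. The cascade value 0.89 says
adjacent-scale synchronization levels are strongly coupled one volume
apart; the transfer values say spatial correlations of R decay faster at
finer scales.

Group inference and classification on the patients of a cohort:

```r
groups <- vapply(cohort, subjectGroup, "")
profiles <- lapply(cohort, function(s) computeProfile(s@bold, geom))
names(profiles) <- vapply(cohort, function(s) s@subjectId, "")
pat <- groups != "control"

turb01 <- vapply(profiles[pat], function(p) turbulence(p)[["0.01"]], 0)
groupComparison(turb01[groups[pat] == "responder"],
                turb01[groups[pat] == "non_responder"], seed = 1)
#> $cohensD
#> [1] 1.139739
#> $pPerm
#> [1] 0.000999001

tab <- assembleFeatures(profiles[pat], setNames(groups[pat], names(profiles)[pat]))
repeatedSplitEval(tab, nReps = 100, balanceTo = 20, seed = 1)
#> ClassifierReport: AUC 0.845 +/- 0.236 (p = NA), accuracy 0.718 +/- 0.202 (p = NA), 100 repetitions
```

(the printed numbers come from the acceptance run with seed 1; your
values match when you use the same seeds). `runPipeline()` drives the
same stages end to end and writes stamped JSON/TSV artifacts plus a
MANIFEST.

## Layout

- `R/` — S4 classes (`ParcelGeometry`, `BoldTimeseries`, `PhaseField`,
  `LocalOrderField`, `TurbulenceProfile`, `CouplingMatrix`,
  `HopfParams`, `FitResult`, `PerturbationReport`, ...) and the
  camelCase function layer over them.
- `vignettes/turbulence-framework.Rmd` — the methods vignette: models,
  assumptions, parameter defaults, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code.
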