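---
title: "Methods: cell-cycle scaling, growth simulation and gradient profiles in the wing pouch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle scaling, growth simulation and gradient profiles in the wing pouch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingscaling)
```

`wingscaling` quantifies how the average cell-cycle time of *Drosophila*
wing-pouch cells scales with organ size, and what that scaling implies for
organ growth. This vignette is the package's own account of the models it
implements, the parameters that matter, the design decisions that were
genuinely open, and what the synthetic-data tests do and do not establish
about real microscopy data.

## From morphometry to volumes

All unit conventions are fixed package-wide: lengths in µm, areas in µm²,
volumes in nL (1 nL = 10⁶ µm³), weights in mg, times in hours.

* **Larval volume** treats the larva as a cylinder: midline length is the
  height, mean body width the diameter, so `V = π (w/2)² L`
  (`larval_volume()`).
* **Pouch volume** multiplies pouch thickness (measured at the AP∩DV
  midline intersection) by total surface area. Late discs fold under
  themselves, so the apical and the two basal (dorsal/ventral) areas are
  measured separately and summed; missing basal areas are treated as zero,
  which is the geometry of immature discs without deep folds
  (`pouch_volume()`). Volume is invariant to how a fixed total area is
  partitioned among the three fields — a property the tests assert.

## Inferring cell-cycle time from the mitotic index

Under uniform, asynchronous proliferation the fraction of cells in M phase
at fixation equals the ratio of M-phase duration to total cycle length.
With PHH3 marking mitotic nuclei,

$$MI = \frac{\text{PHH3}^+\ \text{cells}}{\text{total cells}},
\qquad T_{CC} = \frac{t_M}{MI}.$$

The M-phase transit time defaults to $t_M = 0.34$ hr (20.5 min), a
live-imaging constant for third-instar wing-pouch cells; it is a plain
argument everywhere, and estimating it is outside this package's scope.
Total cell number per pouch is estimated by segmented-subdomain density
(count / subdomain area × pouch area), and a genotype-level linear
conversion $\text{cells} = \beta_0 + \beta_1 V$ is fitted by OLS
(`fit_cellcount_model()`); the wildtype preset uses
$\beta_0 = 352.0$, $\beta_1 = 7261.3$ cells/nL and the Ds-knockdown preset
$\beta_0 = 653.9$, $\beta_1 = 4533.5$ cells/nL.

Choices worth flagging:

* $MI$ is a plug-in ratio with no small-sample correction; the estimator
  $t_M/MI$ is asymptotically unbiased but mildly biased upward at small
  PHH3 counts (Jensen's inequality). The tests quantify this: on pouches
  with thousands of cells the median relative error stays under 5%.
* Pouches with zero PHH3 counts have an unbounded $T_{CC}$; they are
  returned as `NA` with a warning and excluded from regressions, never
  imputed.
* Whether mitotic indices should be pooled per disc or per timepoint
  before regression is ambiguous in general; this package estimates per
  disc, which preserves disc-level variation for the regressions.

## Scaling regressions

`fit_tcc_vs_volume()` fits $T_{CC}$ against pouch volume by ordinary least
squares; the slope, in hr/nL, is the *scaling coefficient*. The wildtype
preset generates with 16 hr/nL — the cell cycle lengthens 16 hours per
nanolitre of pouch growth — and an intercept of 8 hr at zero volume.
`fit_tcc_vs_time()` fits $T_{CC} = T_0 + \beta_1 t$ against larval age;
its slope standard error is what the growth simulator propagates.

Genotype comparisons use the interaction regression

$$T_{CC} = \beta_0 + \beta_1 V + \beta_2 G + \beta_3 V G,$$

with the genotype dummy $G$ coded 0 for the reference (control) group and
1 for the comparison — the coding is a package convention, made explicit
because different codings change the meaning of $\beta_2, \beta_3$. The
identity $\beta_1 + \beta_3 = $ comparison-group marginal slope is
asserted in tests. All tests are two-sided t-tests with homoskedastic OLS
standard errors and no multiple-testing correction across genotype
comparisons; robust or errors-in-variables alternatives are deliberately
out of scope.

## Two-phase allometry

Organ-vs-body scaling is fitted in log10-log10 space. The two-phase model
is a continuous hinge: slope $s_1$ below the breakpoint, $s_2$ above,
continuous at the break. When the breakpoint is supplied (biologically,
the weight at feeding cessation) it is used as-is; otherwise it is
estimated by a profiled grid search over interior data quantiles followed
by golden-section refinement of the residual sum of squares between the
bracketing grid points, which recovers noise-free hinges essentially
exactly. Each phase's slope is classified against 1 at α = 0.05:
*isometric* if 1 is not rejected, otherwise *positive* or *negative
allometry* by sign. Slopes within numerical precision of 1 (the exact-fit
degenerate case, where the standard error is also ~0) are isometric by
convention. Phase-2 slope standard errors come from the coefficient
covariance of the hinge parameterization; they are conditional on the
estimated breakpoint, so recovery tests check the free-breakpoint fit for
breakpoint accuracy and the known-breakpoint fit for slope coverage.

## Growth simulation and uncertainty

The simulator converts cell-cycle time to an instantaneous exponential
rate $r = \ln(2)/T_{CC}$ and iterates

$$V_t = (1 + r_t \Delta t)\, V_{t-\Delta t},
\qquad r_t = \frac{\ln 2}{T_0 + \beta_1 t},$$

from a starting volume $V_0$ (taken from the earliest measured mean volume
in practice). $\Delta t = 1$ hr is the default and the canonical
discretization; other steps use the same first-order form, and as
$\Delta t \to 0$ the trajectory approaches continuous exponential doubling
$V_0 2^{t/T_{CC}}$ (asserted within 0.5% at $\Delta t = 0.01$). Cell size
is assumed invariant, so cell number is proportional to volume and no
separate cell-size state is tracked. Spans where $T_{CC}$ would fall to or
below $t_M$ are rejected as unphysical.

Uncertainty propagation is Monte Carlo over the sampling distribution of
the fitted age slope: draws $\beta_1^{(k)} \sim N(\hat\beta_1,
SE(\hat\beta_1))$, one simulated trajectory per draw, pointwise 2.5/97.5
percentile bands. Slope-only propagation is the default because the
uncertainty of interest concentrates in the slope; intercept uncertainty
could be added via the joint covariance but is intentionally omitted, with
the visible consequence that the band has zero width at the simulation
start and widens with time. Draws that make the cell cycle unphysical
anywhere in the span are rejected and counted; more than 20% rejections
aborts, since percentile bands over a heavily truncated sample would be
misleading.

`compare_to_observed()` scores a trajectory against measured volumes:
per-timepoint residuals of observed means, their RMSE, and the fraction of
means inside the band.

## Gradient profile extraction and collapse

Intensity profiles along the AP or DV midline are extracted as on the
acquisition pipeline:

1. at each polyline point, intensity is averaged along a transect
   orthogonal to the local tangent — 25 pixels each side, nearest-pixel
   sampling, clipped to the pouch mask;
2. transect means are smoothed with a centred moving average 100 pixels
   long sliding along the arc;
3. positions are cumulative arc length (curvature respected) in µm, signed
   about the AP∩DV centre, anterior/dorsal negative.

Numerical choices: the local tangent is the secant over ±2 polyline
points (the underlying pipeline leaves tangent estimation unspecified);
transect sampling is nearest-pixel for determinism and speed; the moving
window shrinks *symmetrically* at the profile ends, so edge values are not
biased inward — with these choices a noise-free synthetic scene is
recovered within 1% of dynamic range everywhere, which the tests assert.
Window sizes are specified in pixels, not µm, matching how they are
defined on the acquisition scale (0.25 µm/px context); images at very
different resolution need rescaled windows, and this is deliberately not
automatic.

Profiles from multiple discs are aligned at their centres and averaged on
a common grid restricted to the intersection of supports, with SEM across
discs (n−1 denominator). Axis normalization maps positions to
$[-0.5, 0.5]$, each side scaled by its own half-axis so the centre stays
at 0 even for asymmetric axes.

**Collapse** — whether normalized profiles from different-sized pouches
superimpose — is scored as the mean pairwise RMS difference divided by the
family's pooled dynamic range, with verdict "collapsed" below a threshold
of 0.1. The underlying phenomenon is qualitative, so the threshold is a
package convention: it is configurable and reported with every verdict.
The score is invariant to common affine intensity rescaling.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with known
ground truth:

* `gen_pouch_growth()` grows a mean volume by the same discrete recursion
  the simulator uses, driven by one cell-cycle law per genotype — either
  the volume law $T_{CC} = a + b V$ (scaling-coefficient form) or the time
  law $T_{CC} = T_0 + \beta_1 t$. The two laws are near-equivalent along a
  growth trajectory but not identical; using exactly one per genotype
  keeps every generated dataset attributable to a single generating
  equation, which the recovery tests then target. Specimen volumes get
  multiplicative lognormal jitter (volumes are positive and errors scale
  with size); the default jitter SD of 0.1 log units reproduces the
  visual spread of timepoint measurements.
* `gen_mitotic_counts()` draws total cells from the linear conversion with
  Gaussian noise (rounded, floored at 1) and PHH3 counts binomially with
  success probability $t_M / T_{CC}$ — each cell independently in M phase,
  the sampling model implicit in mitotic-index estimation. The segmented
  subdomain receives a binomial share of cells so its density is
  consistent with the total.
* Cell-count residual SD defaults to 530 cells (wildtype) / 330 cells
  (Ds-knockdown): chosen analytically, once, so the conversion regression
  has $R^2 \approx 0.95$ over the 0.1–1.2 nL design spread
  ($\sigma^2 = \beta_1^2 \mathrm{Var}(V)\,(1-R^2)/R^2$), since coefficient
  standard errors rather than residual variances are what conversion
  tables report.
* `gen_gradient_image()` renders an elliptical pouch whose intensity is a
  quadratic function of normalized elliptical radius — border-high
  (Ds-like) or centre-high (Fat-like) — with optional anterior amplitude
  asymmetry, plus midlines, mask, and Gaussian pixel noise. Its
  `scaling_mode` ties the generator to the collapse metric: `axis_scaling`
  families are a fixed function of normalized position (verdict:
  collapsed), `max_decay` families lose amplitude in proportion to pouch
  size (verdict: not collapsed). The quadratic radial form is a modelling
  choice; real gradients are known only as figure shapes.
* `gen_allometry_series()` and `gen_larvae()` produce hinge-law allometry
  pairs and cylinder-consistent larvae, both with stored hidden truths.

Every generator takes an integer seed and restores the RNG state
afterwards (`withr::with_seed`), so a fixed seed fixes every artifact
byte-for-byte. Each generator call seeds its own stream; pipeline stages
derive sub-seeds by offset.

Per-timepoint sample sizes and the measurement-noise magnitude of
cell-cycle estimates are not universally known quantities; the defaults
(5 specimens per 4-hr timepoint over 36 hr, 1 hr Tcc noise) are
configurable arguments, not inferences.

**What passing tests show — and do not.** The synthetic data reproduce
the *statistical structure* the analysis assumes: linear scaling laws,
binomial M-phase sampling, lognormal size jitter, radially symmetric
gradients on ideal ellipses. They do not reproduce segmentation error,
peripodial contamination, depth-dependent attenuation, non-elliptical
pouch shapes, or spatially correlated staining noise. Recovery on
synthetic data therefore validates the estimators and their plumbing, not
the upstream imaging steps, which are inputs here.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen as the smallest designs that
leave the Monte-Carlo conclusions stable: 50 pouches per scaling-recovery
replicate (200 replicates), 30 per conversion-model replicate (200
replicates), 30 per group for interaction-test calibration (1000 null
replicates, 200 alternative), 100 replicates for gradient-collapse
verdicts on three pouch sizes (100, 150, 200 µm AP semiaxis), and 100
replicates for noisy allometry recovery at n = 60. The full suite runs in
about a minute on one core.

## Known limitations

* All regressions are homoskedastic OLS; measurement error in $T_{CC}$
  enters only the response, and errors-in-variables attenuation of the
  scaling coefficient is not modelled.
* The growth simulator has no apoptosis, recruitment, or spatial
  structure; it is the minimal model linking cell-cycle kinetics to bulk
  volume.
* Gradient extraction is strictly 2D on pre-projected images; 3D surface
  projection and peripodial removal are upstream concerns.
* The collapse verdict depends on a configurable threshold; borderline
  families should be judged on the score, not the binary verdict.
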