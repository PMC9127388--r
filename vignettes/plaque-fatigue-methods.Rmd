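---
title: "Thin-slice vessel mechanics and stenosis progression: models and methods"
author: "plaqueFatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-slice vessel mechanics and stenosis progression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueFatigue)
```

# The scientific question

Coronary plaques live in a pulsating environment: every cardiac cycle
loads the wall between the diastolic and systolic luminal pressures.
The cyclic variation of wall stress and strain — a fatigue-type loading
— is a candidate driver of stenosis progression, the loss of lumen area
between a baseline and a follow-up imaging session. This package
implements the full analysis chain for that hypothesis on
cross-sectional vessel geometry:

1. mechanical modelling of a single imaged cross-section (a *thin
   slice*) under luminal pressure, with plaque-component-specific
   hyperelastic materials;
2. extraction of per-slice *fatigue amplitudes* (maximum and average
   principal stress/strain variation over the cycle, on the lumen
   surface) and morphology (plaque burden, lumen/wall areas and their
   cycle amplitudes);
3. dependence-adjusted correlation of each baseline factor with the
   delta lumen area (DLA = baseline minus follow-up lumen area) using a
   patient-level random-intercept model;
4. random-forest classification of narrowing (DLA > 0) versus
   non-narrowing slices, with out-of-bag (OOB) tuning of `mtry` and
   `ntree`, Gini-importance backward elimination, and the standard
   confusion-matrix metric suite.

Because no patient IVUS data ships with the package, a synthetic cohort
generator produces baseline/follow-up slice pairs with the geometric
and statistical structure the analysis assumes; every stage is tested
against it.

# The mechanical model

## Constitutive law

All tissues use a modified Mooney–Rivlin strain energy. Writing
$\bar I_1 = J^{-2/3} I_1$ and $\bar I_2 = J^{-4/3} I_2$ for the
deviatoric invariants of the right Cauchy–Green tensor $C = X^T X$,
$I_4 = C_{ij} (n_c)_i (n_c)_j$ for the squared fibre stretch along the
circumferential direction $n_c$, and $J = \det X$:

$$W = c_1 (\bar I_1 - 3) + c_2 (\bar I_2 - 3)
    + D_1 \left[ e^{D_2 (\bar I_1 - 3)} - 1 \right]
    + \frac{K_1}{K_2}\left[ e^{K_2 (I_4 - 1)^2} - 1 \right]
    + \kappa (J - 1)^2 .$$

The fibre term is active only for the anisotropic vessel-wall tissue;
lipid and calcification are isotropic. The shipped literature
parameters are: lipid $c_1 = 0.5$, $D_1 = 0.5$, $D_2 = 1.5$;
calcification $c_1 = 92$, $D_1 = 36$, $D_2 = 2$; other vessel tissue
$c_1 = -278.7$, $c_2 = 24.35$, $D_1 = 133.7$, $D_2 = 2$, $K_1 = 7.19$,
$K_2 = 23.5$ (kPa where dimensional). Note the negative $c_1$ of the
wall: the exponential term dominates, and the reference shear modulus
$2(c_1 + D_1 D_2 + c_2) \approx 26$ kPa is positive; the analytic
tangent is verified positive over the strain range visited by the
tests.

Two formulation choices deserve comment:

* **Deviatoric invariants.** The energy is often written with raw
  $I_1, I_2$ under an incompressibility constraint enforced by the
  solver. In a displacement-based formulation with a volumetric
  penalty, raw invariants would leave a spurious hydrostatic stress at
  the reference state for every tissue. We therefore use the standard
  nearly-incompressible split above, which is stress-free and
  energy-free at the identity and coincides with the raw-invariant form
  in the incompressible limit. The `I4 - 1` bracket is written so that
  the fibre term also vanishes at the reference; the alternative
  reading of the exponent (constant shifted inside) differs only by an
  additive constant and produces identical stresses.

* **Volumetric penalty.** Near-incompressibility is enforced by
  $\kappa (J-1)^2$ with $\kappa = 2 \times 10^3$ kPa by default,
  evaluated with the element-averaged $J$ (mean dilatation). Sensitivity
  is weak well below that value: on the thin-ring benchmark the luminal
  stress changes by 0.6% between $\kappa = 10^2$ and $10^3$ kPa, while
  the volumetric error $J - 1 \sim p/\kappa$ stays near 0.3% — an order
  below the 1% area tolerances used throughout. Much stiffer penalties
  shrink the Newton attraction basin (the quadratic kinematics of $J$
  make the linearized step overshoot in proportion to $\kappa$) without
  measurable change in the stresses; $\kappa$ is user-overridable in
  `materialParams()`.

## Generalized plane strain instead of a 3D extrusion

The imaged slice is 0.5 mm thick (the catheter pullback inter-frame
spacing). Instead of extruding and solving a thin 3D model, the solver
works in generalized plane strain: the deformation gradient is
$\mathrm{diag}(F_{2d}, \lambda_z)$ with a fixed axial stretch
$\lambda_z = 1/(1 - 0.05)$ representing the 5% axial shrinkage of
in vivo vessel segments. A uniform axial stretch through a thin slice
with plane-parallel faces produces the same in-plane fields as the
extruded solid at a fraction of the cost; the slice thickness then only
scales energies, never stresses.

## Discretization and solution

The wall ring between the lumen and external-elastic-membrane (EEM)
contours is meshed with six-node (quadratic) triangles on a structured
annular grid: both contours are resampled at a common set of angles
about the lumen centroid and connected by radial rays. Quadratic
elements with three-point quadrature and the mean-dilatation volumetric
treatment avoid the locking a linear-triangle penalty formulation would
suffer. Elements take the tissue label of the plaque-component polygon
containing their centroid (calcium wins where components overlap).

The luminal pressure is a follower load on the deformed lumen edge;
the outer boundary is traction-free. Because the load is
self-equilibrated, rigid-body modes are removed by three
Lagrange-multiplier constraints (zero net translation and rotation).
Equilibrium is solved by incremental Newton–Raphson: the element
tangent is a forward-difference linearization of the analytic element
residual (the residual itself uses the exact stress), a geometric-ladder
line search handles the overshoot produced by the exponential fibre
stiffening, and load increments that remain out of reach are bisected
adaptively down to 1/64 of the configured step. Intermediate load
levels are solved to a loose tolerance ($10^{-4}$ relative); only the
target pressure is solved to the configured `newtonTol`
($10^{-8}$ by default). Nodal stress/strain fields are recovered by
area-weighted averaging of element quadrature values; the reported
"stress" and "strain" are the in-plane maximum principal Cauchy stress
and maximum principal Green–Lagrange strain (the strain measure is a
package choice, standard in image-based plaque modelling).

Verification rests on oracles with known answers: zero pressure gives
exactly zero fields; a thin-wall ring ($t/r = 0.1$) reproduces the
Laplace hoop stress $p\,r/t$ within 10%; the response is linear at
small loads; the computed follower load satisfies the discrete
virtual-work identity $\oint x \cdot p\,n \, ds = 2 p A$ within 1%;
rotating the mesh rotates the solution (objectivity); and halving the
target edge length moves the peak luminal stress by less than 5%.

## Shrinkage pre-processing

VH-IVUS frames are gated at the R-wave peak, i.e. the imaged geometry
is loaded at the *minimum* (diastolic) pressure — it is not a
stress-free reference. `findCircumferentialShrink()` finds the uniform
in-plane scale $s$ such that inflating the scaled geometry to the
diastolic pressure recovers the imaged lumen area, by the fixed-point
update $s \leftarrow s \sqrt{A_{target}/A_{computed}}$. Because the
pressurized hyperelastic problem has no intrinsic length scale, the
computed area is exactly proportional to $s^2$, and the iteration lands
within tolerance after a single update in practice (two solves). The
default tolerance of 1% relative lumen-area mismatch sits below IVUS
segmentation precision. The shrink parameterization (uniform scaling
about the lumen centroid) is a package decision; only the purpose of
the step is fixed by the modelling context. With the axial pre-stretch
active, a very stiff wall can require $s$ slightly above one (the
incompressible trade between axial stretch and in-plane area), which
the container admits.

# Feature extraction

Each baseline slice yields exactly 19 factors, in a fixed, documented
column order (`featureNames()`): 12 biomechanical — maximum and average
luminal stress and strain at each of the two cycle pressures (8), plus
their four cycle amplitudes — and 7 morphological — plaque burden at
minimum pressure, lumen and wall areas at both pressures, and the two
area amplitudes. Amplitudes are definitions (`at pmax` minus
`at pmin`) and are tested as exact identities. Luminal statistics are
node-based (unweighted) means over the lumen boundary nodes; an
arc-length-weighted mean would differ negligibly on the near-uniform
boundary meshes used here, and the node-based reading is documented as
the package's choice. Plaque burden uses the deformed configuration at
minimum pressure. The outcome is `DLA = baseline - followup` imaged
lumen area, with label 1 for strictly positive DLA (narrowing); a DLA
of exactly zero is non-progressive.

A closed-form *surrogate mode* replaces the finite-element solve with
Laplace thin-wall statistics ($\sigma = p\,r_{equiv}/t$, strains scaled
by an effective modulus, compliance-driven area gains). It preserves
orderings, signs and the table layout at negligible cost and is used
for fast screening and for the statistical large-replication tests; it
is not a substitute for the solver where stress magnitudes matter.

# The synthetic cohort generator

`generateCohort()` draws per-patient pressures and per-slice geometry:
64-vertex lumen contours $r(\theta) = r_b (1 + e \cos(\theta - \phi) +
\text{low-order Fourier perturbation})$, an eccentric wall thickness
profile, a lipid sector annulus (40–120° span) with probability 0.4 and
a thin calcium arc with probability 0.2. Follow-up geometry changes
only the lumen, rescaled uniformly to the area implied by the
generative rule

$$\mathrm{DLA} = \gamma_0 + \gamma_{fat} A + \gamma_{pb} \mathrm{PB}
  + b_{patient} + \varepsilon,$$

where $A$ is the closed-form hoop-stress amplitude surrogate
$\Delta P \, r_{equiv} / \bar t$ and PB the plaque burden (%).

The defaults *are* the study conditions: 7 patients, 40–50 slices each
adjusted to 305 pairs total, lumen radius $1.5 \pm 0.25$ mm, wall
thickness $0.7 \pm 0.12$ mm, pressures centred on 80/120 mmHg
(10.67/16.0 kPa) with patient-level jitter, $\gamma_{fat} = 0.06$
mm²/kPa, $\gamma_{pb} = -0.05$ mm²/%, $\gamma_0 = 1.90$ mm²,
$\sigma_{patient} = 0.25$ and $\sigma_{noise} = 0.45$ mm². The
coefficients were calibrated once against the reported characteristics
of the motivating cohort — a class split near 160 non-narrowing / 145
narrowing, dependence-adjusted correlations of roughly $+0.3$ to $+0.5$
(average stress amplitude vs DLA) and $\approx -0.6$ (PB vs DLA), and
OOB classification accuracy near 80% — and then frozen. Two
characteristics trade off against each other in this simple generative
family (correlation magnitudes vs accuracy), because the thick-wall
slices have high PB *and* low amplitude, so the two effects reinforce;
the defaults sit between the two.

What the generator deliberately does **not** emulate: imaging physics
and segmentation error, plaque-component remodelling between
timepoints (components and EEM are frozen; only the lumen rescales),
vessel curvature and bifurcations, and any dependence of DLA on factors
outside the generative rule. Passing tests therefore demonstrate that
the pipeline recovers structure *of the kind assumed*, not that real
IVUS cohorts behave this way.

# Statistics

For each factor $x$, the model $y_{ij} = \beta_0 + \beta_1 x_{ij} + b_j
+ \varepsilon_{ij}$ (patient random intercept $b_j$) is fitted by
maximum likelihood via `lme4`, and the dependence-adjusted correlation

$$r = \hat\beta_1 \sqrt{\widehat{var}(x) / \widehat{var}(y)}$$

uses plain sample variances ignoring the grouping. ML (not REML) keeps
the Wald test on $\hat\beta_1$ standard; the Wald choice itself is a
package decision, as is the absence of any multiple-testing correction
across the 19 factors (each factor is screened on its own terms — the
output documents this caveat). With a single group the fit degenerates
to ordinary least squares and $r$ is exactly the Pearson correlation;
$|r| > 1$ can occur numerically when the within-group slope exceeds the
marginal scaling and is clipped with a warning. Calibration is tested
by simulation: slope recovery at the study design (7 × 44) and a
type-I error rate within [0.03, 0.07] at nominal 5%.

# Random forest

Forests are grown by `randomForest`; all tuning and selection logic is
package code. `tuneMtry()` minimizes OOB error over a candidate grid at
fixed forest size (ties to the smallest mtry); `tuneNtree()` reads the
cumulative OOB trace of one large forest and returns the smallest
scheduled size from which the trace stays flat within 0.5 percentage
points. `selectFactors()` performs varSelRF-style backward elimination:
drop the least important 20% of factors by mean decrease in Gini index,
refit, and finally pick the smallest set whose OOB error is within one
standard error (binomial SE) of the minimum — the 1-SE rule; the
drop fraction and SE multiplier are the established defaults of that
procedure and are configurable. The mean-decrease-Gini importance is
the node-sample-weighted impurity-decrease estimator reported by the
forest implementation (the textbook formula abbreviates the weighting).
OOB is the sole validation surface by design; no holdout is used by
default.

The metric suite (`classificationMetrics()`) computes accuracy,
sensitivity, specificity, PPV and NPV as percentages from the OOB
confusion matrix, with an explicit positive-class parameter. For the
reference confusion matrix shipped in the tests the printed percentages
are mutually consistent only with the *non-narrowing* class as
positive, so that is the default. Undefined ratios (zero denominators)
are reported as `NA`, never as zero.

# Problem sizes and reproducibility

The test and acceptance workloads use deliberately chosen sizes:
cylinder benchmarks at 0.1–0.2 mm edge length, cohort finite-element
runs at 0.18 mm edge with four load increments and `newtonTol` 1e-6
(stress errors well under the 10% oracle tolerance), surrogate-mode
cohorts at the full 305 pairs, mixed-model simulations at 200–500
replications, and a reduced 30–60-slice FE cohort for end-to-end sign
recovery. One master seed drives everything: per-patient substreams
derive deterministically from it, and re-running any stage with the
same configuration reproduces the feature table bit-for-bit
(`runPipeline()` records MD5 hashes in its manifest).

# Known limitations

* Single cross-sections cannot represent vessel curvature,
  bifurcations, axial tethering gradients, or 3D plaque architecture.
* No fluid–structure interaction: wall shear stress is outside the
  model, and the luminal pressure is spatially uniform.
* Fatigue is measured as cyclic stress/strain amplitude only; no
  damage accumulation or fatigue-life model is implied.
* The residual-stress state is approximated by the shrinkage procedure
  alone (no opening-angle/residual-strain modelling).
* The generator's follow-up rule rescales only the lumen; morphological
  co-evolution of plaque components is not simulated.
* The one-parameter uniform shrink matches the imaged *lumen* area at
  diastolic pressure; the nearly incompressible wall ring then carries
  the shrunken ($s^2$-scaled) cross-sectional area, so the
  finite-element plaque burden at minimum pressure sits systematically
  below the image-derived value (by ~15% at typical $s \approx 0.9$).
  Rankings and correlation signs are unaffected; matching both areas
  would need a two-parameter (non-uniform) shrink.
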