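---
title: "Modelling spring-assisted cranioplasty: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spring-assisted cranioplasty: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springsim)
```

# The clinical problem

Sagittal craniosynostosis is the premature fusion of the sagittal suture in
infancy: the skull cannot widen, compensatory growth elongates it, and the
head becomes scaphocephalic (cephalic index, the ratio of biparietal to
occipitofrontal diameter, around 70% instead of 76-80%). Spring-assisted
cranioplasty (SAC) treats it minimally invasively: a midline strip
craniectomy frees the fused suture, parasagittal relief osteotomies mobilize
the parietal plates, and two compressed metallic springs are seated in bone
grooves across the gap. The springs expand over weeks, widening the vault.

Predicting how far the springs will open — on the operating table, at the
first follow-up (~1 day) and at the second (~1 month) — requires a
mechanical model of the infant calvarium, and the bone properties of this
population are poorly constrained (literature moduli for paediatric skull
span an order of magnitude). `springsim` implements the full workflow for
deriving a *population-specific* material model from retrospective spring
measurements: forward viscoelastic finite-element simulation, a
design-of-experiments (DoE) sensitivity study, per-patient response-surface
calibration, and population averaging — together with the synthetic-data
generator that stands in for the clinical cohort, since patient CT anatomy
is not publicly available.

# Model components

## Synthetic anatomy

The calvarium is idealized as a half-ellipsoid shell (outer semi-axes
OFD/2, BPD/2, height; inner surface offset by the shell thickness), meshed
by a structured azimuth x elevation x thickness grid whose hexahedral cells
are split into six conforming tetrahedra. The coronal and lambdoid sutures
are patent strips of soft (suture) material; the sagittal strip is fused
bone — the pathology. The base ring (the nasion cutting plane, z = 0) is
fully constrained, standing in for the skull base.

Surgery removes the midline craniectomy strip over the osteotomy length and
cuts two parasagittal relief osteotomies that stop short of the strip ends,
so the spring-bearing bone strips stay anchored anteriorly and posteriorly.
The groove node sets are the kept rim nodes bordering the gap at the
planned anterior/posterior spring positions. Removal operates on whole
structured cells, which keeps a symmetric plan exactly mirror-symmetric;
small bone fragments that end up face-disconnected from the anchored vault
are discarded with the craniectomy bone (as they would be in theatre), and
a plan that would detach a large segment is rejected.

Default dimensions (OFD 140 mm, cephalic index ~70%, shell thickness
1.2 mm, craniectomy 15 mm, relief cuts 20 mm off-midline) were chosen once
to put the model in the clinically reported regime: insertion openings of
roughly 21-28 mm against a 60 mm nominal spring opening, expanding by a
further 15-30% over the first month. Spring stiffnesses (0.4-0.6 N/mm by
model) give implant forces of roughly 15-20 N at insertion. A deliberate
informativeness condition sits behind these choices: the spring-opening
response to the calibrated parameters must comfortably exceed the 1 mm
reading precision of the measurements, as it does in the clinical data the
generator emulates — otherwise the inverse problem the package exists to
solve would be ill-posed by construction. These are
synthetic stand-ins: the real device constants and patient anatomies live
in clinical sources, not in this package.

## Growth model

Calvarial size between the CT scan and surgery (typically 1-2 months apart)
is bridged by the logarithmic growth law

$$V = a + b \log(\mathrm{age} + 1),$$

fitted by least squares to an unoperated cohort's (age, control-volume)
points. The natural logarithm is used throughout; since only the fitted
curve matters, the base is a representation choice and b absorbs it.
Rescaling to surgery age uses only the growth rate,
$V_{SAC} = V_{CT} + b\log\frac{1+age_{SAC}}{1+age_{CT}}$, and meshes are
scaled isotropically about the base centroid by $(V_{SAC}/V_{CT})^{1/3}$,
which preserves shape (and hence the cephalic index) exactly and makes
repeated rescaling exactly transitive. The generator's growth law
(a = 153.6, b = 489.7 mm^3) is anchored to the printed endpoint volumes of
an unoperated scaphocephaly cohort (640 mm^3 at 1.7 months, 1184 mm^3 at
7.2 months), and the volume noise (sigma = 40 mm^3) reproduces the
characteristic fit quality of such cohorts (R^2 in the low 90s percent).
One caveat follows from that noise level: the fitted *curve* is recovered
to a few percent across the cohort age range, but the intercept a — an
extrapolation to age 0 — carries ~30% standard error at n = 24, so exact
coefficient recovery is only meaningful on noiseless data.

## Finite-element core

The solver is a standard small-strain constant-strain-tetrahedron code:
isotropic linear elasticity with per-label Young's modulus (bone E_B,
suture E_s) and fixed Poisson ratios (defaults 0.22 bone, 0.45 suture —
literature-typical values, configurable). Dirichlet constraints are imposed
by row/column elimination, not penalties, which is why the affine patch
test is exact to near machine precision.

Viscoelasticity follows a Prony relaxation law with two population scale
factors: relative moduli are scaled as $\alpha_i' = \alpha_G\,\alpha_i$ and
time constants as $\tau_i' = \alpha_\tau\,\tau_i$, and the long-term
modulus is recomputed as $1 - \sum_i \alpha_G \alpha_i$ so that g(0) = 1
holds for any $\alpha_G$ — the instantaneous stiffness keeps its meaning
and only the *depth* and *speed* of relaxation are rescaled. Relaxation is
applied as a scalar multiplier on the full isotropic stiffness (constant
Poisson ratio), the simplest law consistent with a single printed shear
relaxation function; a deviatoric-only variant would need a bulk law that
the available sources do not provide.

The default Prony series is a single term with relative modulus 0.5 and
base time constant 0.4 days. The time constant deserves a note. Under
spring load the structure relaxes on a *coupled* time scale stretched by
roughly $(k + K)/(k + g_\infty K) \approx 1/g_\infty$ relative to the
material constant (the classic standard-linear-solid result), about a
factor two here. With $\alpha_\tau$ spanning 1-21, a 0.4-day base puts the
coupled relaxation times between about a day and three weeks: the first
follow-up (1 day) then responds to the relaxation *speed*
($\alpha_\tau$) and the second follow-up (28 days) to the relaxation
*depth* ($\alpha_G$) — the sensitivity structure reported clinically. A
10-day base constant, by contrast, would make the 1-day follow-up
insensitive to $\alpha_\tau$ and confound the two scale factors at one
month, so the shorter default was adopted; it is fully configurable.

Time integration uses the standard recursive internal-variable exponential
update (one internal variable per Prony term, exact for piecewise-linear
strain histories) on a log-spaced grid (60 substeps to 28 days by
default; halving the step changes openings by well under 0.1%). Each
spring exerts a force $k(L_0 - d)$ along the line joining the deformed
centroids of its two groove sets, distributed evenly over the groove
nodes; the solver re-equilibrates the spring force against the relaxing
structure at every step by a few Newton-type iterations on the gap, and
springs push only (the force drops to zero if the opening reaches the free
length). Verification rests on a one-dimensional surrogate: a prismatic
bar with Poisson ratio zero and fixed lateral displacements has axial
stiffness exactly $EA/L$, and its spring-loaded relaxation has the
closed-form standard-linear-solid solution used as the oracle.

## Calibration

The four calibrated parameters and their ranges are E_B 186-1317 MPa,
E_s 8-30 MPa, $\alpha_\tau$ 1-21, $\alpha_G$ 1-1.2, with the literature
baseline (421, 16, 1, 1). Three choices matter:

* **Face-centered central composite design.** The bounds are hard physical
  ranges, so the axial points sit on the faces (alpha = 1): all 25 runs
  (16 corners, 8 face points, 1 center) respect the box.
* **Log coding of wide factors.** E_B, E_s and $\alpha_\tau$ span close to
  a decade, and the opening response is hyperbolic in stiffness; a
  quadratic surface in *linear* coordinates misfits it badly enough to
  corrupt the calibration. These factors are therefore sampled and
  modelled on a logarithmic axis (corners and face points are unchanged —
  they sit on the bounds — and the center moves to the geometric mean).
  $\alpha_G$ spans only 1-1.2 and stays linear.
* **Factor screening.** Before fitting, factors with zero observed effect
  across every matched design pair are dropped; their coefficients are
  structurally zero. This is what makes the sensitivity of the on-table
  opening to $\alpha_G$ and $\alpha_\tau$ *exactly* zero — the t = 0 solve
  does not touch them — rather than zero up to surrogate lack-of-fit.

One quadratic surface per output (normalized insertion, FU1, FU2 openings)
is fitted to the 25 forward simulations. Local sensitivities sweep one
factor across its range with the others at the baseline, reporting
sign(slope) x (output swing)/(reference output) x 100.

Per-patient optimization minimizes the unweighted sum of squared
differences between surface-predicted and measured normalized openings
over the three time points, box-constrained, by multi-start local search
(the surfaces are smooth quadratics). Two safeguards make the estimate
well-posed:

* With three averaged targets and four parameters the problem is
  underdetermined: the bone/suture stiffness split is an exactly flat
  valley (relaxation scales both tissues equally, so time dynamics cannot
  separate them). The objective therefore carries a small
  minimum-deviation term (lambda = 1e-3 in coded space) that selects,
  among near-equal fits, the parameter set closest to the literature
  baseline — the same role the reference model plays in the clinical
  workflow.
* A direct-simulation refinement pass re-scores the distinct surrogate
  optima against the true forward model and polishes the winner with a
  short derivative-free search. Along a flat valley the quadratic
  surrogate's lack-of-fit (a few tenths of a percent point) is otherwise
  large enough to pick an arbitrary valley end; validating candidates
  against the simulator removes that artifact at the cost of a few dozen
  extra forward runs per patient.

Population parameters are the componentwise mean (with SD) over the
calibrated patients, kept on the natural parameter scale.

## Shape outcome metrics

Predicted head shapes are compared to reference surfaces by rigid ICP
registration (nearest-point correspondence, Kabsch rotation from the SVD
of the cross-covariance; the RMSE sequence is non-increasing), followed by
area-weighted sampling of unsigned nearest-surface distances (RMSE and the
fraction below the 2 mm planning threshold). The scalp is recreated from
the outer skull surface by offsetting along area-weighted vertex normals
by a patient-specific amount. The cephalic index is computed as
100 x BPD/OFD — the conventional width/length ratio, the only reading
consistent with scaphocephalic values near 70%. For the simulated CI
trajectory the extents are read above a measurement plane at 40% of head
height: the idealized model clamps the base ring rigidly, so at the base
itself the width cannot change; the supra-auricular band is where the
mobilized parietal walls actually carry the expansion (in an infant the
widest point, the eurion, lies well above the skull base).

# The synthetic study

`run_study()` chains the stages exactly as the retrospective study design
prescribes: generate an unoperated growth cohort (n = 24) and fit the
growth law; generate the patient cohort (default 18) with "measured"
spring openings — each spring read separately with 1 mm Gaussian error
(sterile-ruler / X-ray precision), then averaged per time point — from
forward simulations on each patient's true at-surgery anatomy under the
generating material model (E_B = 600 MPa, E_s = 20 MPa, alpha_tau = 10,
alpha_G = 1.1); rebuild each patient from the CT-age geometry, rescale to
surgery age with the *fitted* growth law (so growth-model error propagates
realistically), and validate the rescaling by surface RMSE against the
true anatomy; run the baseline (literature-material) simulations; run the
DoE calibration on the first nine patients only — the held-out patients'
measurements are never read by the calibration stage; re-simulate all
patients with the population-averaged optimized model; and report
prediction errors (signed percent points of the 60 mm nominal opening),
local sensitivities and the simulated cephalic-index trajectory.

What passing this synthetic study shows — and what it does not: it
verifies the machinery end to end (mechanics against closed forms,
surrogate calibration recovering a known truth through realistic noise,
directional cephalic-index dynamics). It does not validate the idealized
anatomy against real skulls: an ellipsoid shell with strip sutures has no
fontanelles, no real suture topology, no scalp or intracranial loading,
and its absolute stiffness depends on idealization choices. Problem sizes
are chosen for a desk machine: ~5,000 tetrahedra per patient (about three
orders of magnitude coarser than a CT-derived mesh), 25-run designs and
18-patient cohorts; every size is a config parameter.

# Numerical choices and degenerate inputs

* Tetrahedra are positively oriented at generation (node swap on negative
  volume); assembly aborts naming the first inverted element.
* The constrained solve is a sparse Cholesky factorization; spring
  coupling enters through a rank-two Woodbury update, so one
  factorization serves a whole simulation.
* Zero spring stiffness is valid (no load, opening = initial gap); zero
  Prony terms degenerate to pure elasticity; constant-volume growth data
  give b = 0 with r-squared defined as 1.
* Collinear point sets are rejected by ICP; an empty surface or a surface
  entirely below the base plane is rejected by the distance and CI
  metrics.
* All random draws (cohorts, sampling, optimizer starts) run under local
  seeds derived from the study seed; rerunning a study writes
  byte-identical outputs.

# Known limitations

* The calvarium idealization fixes the load path through two bone strips;
  real anatomies distribute load through curved plates and patent
  fontanelles, so absolute stiffness (and hence absolute opening) should
  not be read as clinical prediction.
* The bone/suture modulus split is structurally unidentifiable from
  averaged spring openings alone; only the baseline-anchored selection
  makes it unique.
* Long-term outcome after spring removal involves growth and remodelling,
  which the quasi-static model does not represent.
* Small strains are assumed throughout, while real (and simulated)
  openings reach a few centimetres; the linear model matches the
  clinical modelling practice it emulates but inherits its error at the
  largest expansions.
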