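---
title: "Modeling conduction-disturbance risk after self-expanding TAVR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling conduction-disturbance risk after self-expanding TAVR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

New-onset left bundle branch block and high-degree atrioventricular block are
the most common complications of transcatheter aortic valve replacement
(TAVR) with self-expanding frames. Mechanistically they arise where the
expanding nitinol frame presses on the interventricular membranous septum,
beneath which the atrioventricular bundle and the proximal left bundle run.
Patient-specific simulation of the frame–root interaction summarizes that
interaction with two scores computed over a membranous-septum region of
interest (ROI):

* **CPI** (contact pressure index): the percentage of the ROI *area*
  subjected to contact pressure by the deployed frame;
* **CPMax**: the maximum element contact pressure (MPa) within the ROI.

Clinically useful cutoffs are CPI ≥ 20 % and CPMax ≥ 0.40 MPa; implantation
depth ≥ 5 mm is the classical anatomical risk marker. `thvcpi` implements a
desk-scale version of this pipeline — synthetic parametric anatomy, a
quasi-static contact solver, the two scores, an implantation-depth planner,
a synthetic outcome cohort generator, and the validation statistics — so
that every quantity the scoring consumes can be computed, tested and audited
on a single CPU.

## Anatomy model

The aortic root is a surface of revolution. Five perimeter-derived diameter
levels (LVOT, annulus, sinus of Valsalva, sinotubular junction, ascending
aorta) are joined by a monotone cubic radius profile along the axial
coordinate `z`, with the annulus plane at `z = 0` and the ventricular
(caudal) direction negative. The default axial positions of the levels are
−10, 0, +12, +22 and +30 mm; the mesh spans −20 to +30 mm. Angles are
degrees, with cusp nadirs at 0°/120°/240° (NCC/RCC/LCC). The default
resolution is 72 circumferential nodes × 0.5 mm axial spacing, which the
mesh-sensitivity study (below) shows is inside the mesh-independent regime.

Monotone cubic interpolation is used rather than a natural spline so the
reconstructed diameters pass exactly through the requested levels without
overshoot; measuring the generated mesh recovers the input diameters — a
round-trip property tested for arbitrary parameter sets.

Wall mechanics are condensed to a per-node radial stiffness with three
additive parts:

* a thin-shell hoop term `E·t·A/r²` (wall `E` = 2 MPa, ν = 0.45, default
  thickness 2 mm, `A` the node's tributary area);
* a leaflet resistance band (E = 0.6 MPa, effective thickness 1.5 mm)
  between annulus and sinus, standing in for the crushed native leaflets;
* a foundation spring representing surrounding cardiac structures,
  0.02 N/mm per node at the reference resolution. The foundation value is
  stored per reference node but internally converted to a stiffness
  *density* (scaled by tributary area), otherwise refining the mesh would
  stiffen the wall and the contact solution would never be mesh-independent.

Calcium (E = 4 MPa, yield 0.6 MPa) is realized as contiguous node patches
per (region × cusp) cell — leaflet, upper leaflet, device landing zone and
LVOT bands crossed with the three 120° cusp sectors. Only volumes are
specified clinically, so patches conserve the requested volume exactly
(spread evenly over the patch) rather than attempting shape realism.
Calcified nodes get the `E_calcium/E_wall` stiffness multiplier and an
elastic–perfectly-plastic cap: past 0.6 MPa nodal pressure the incremental
stiffness drops to 1 % of its elastic value.

## Devices

Four self-expanding frames are built in: Evolut PRO 23/26/29 mm (with outer
pericardial wrap) and Evolut R 34 mm (without). Each is a frame-height
diameter profile (constant inflow segment, constricted waist, flared
outflow) plus a chronic-outward-force characteristic: outward force per mm
of frame height, flat at strong crimp and decaying linearly to zero at the
local free diameter. Frame dimensions are engineering configuration values;
no frame mechanical constants are published for these devices, so the force
magnitudes (1.6–2.4 N/mm plateau by size) are explicit configuration, chosen
to preserve the orderings that matter — force grows with device size at any
common diameter — and none of the package's validation statistics depend on
their absolute scale. The pericardial wrap is metadata only: no quantified
mechanical parameter is attributed to it.

## Deployment solver

The frame is idealized as a stack of independent circumferential rings, one
per mesh row it overlaps, coupled to the wall by radial penalty contact
(default 10 N/mm per node). For each ring the equilibrium radius balances
the frame's outward force against the summed nodal reactions (penalty spring
in series with the wall spring, plastic cap where calcified). Each scalar
equilibrium is found by a damped Newton fixed-point iteration
(under-relaxation 0.5, tolerance 1e−4 mm, cap 10,000 iterations); the force
laws are monotone, so the root is unique and the solve is deterministic.
Sheath retraction is staged distal→proximal over 20 steps, rings reaching
equilibrium as they are released. The outer-curvature displacement force of
a real deployment is represented as a prescribed lateral offset of the frame
axis (default 0, configurable as a fraction of the annulus radius), since no
force magnitude is available to calibrate against.

Nodal forces are converted to element pressures by incidence-weighted
averaging: each node donates `1/(number of incident elements)` of its force
to each incident element. This makes `Σ pressure·area = Σ |nodal force|`
hold to machine precision on every solve — the package's central
conservation invariant, asserted in the test suite.

Verification is against closed forms: a single ring with linear springs has
the algebraic equilibrium `d* = (a + k·d_wall)/(b + k)` for a linear force
curve `F(d) = a − b·d`, which the solver matches to 1e−6 mm; on a cylinder
the uniform contact pressure has a 1-DOF closed form that the meshed solution
converges to as resolution doubles; and a rigid narrow wall forces each ring
to carry exactly the force curve's value at the wall diameter.

## The region of interest and the scores

The membranous septum is located at three landmarks (NCC at 30°, mid-course
at 60°, RCC at 90° by default, depths 5.1/3.5/1.7 mm). The ROI runs
angularly from the NCC landmark through mid-course to the RCC landmark plus
a 25° lateral extension (away from the NCC, following the course of the
bundle), and axially 15 mm caudal from the annulus plane. The ROI's superior
boundary is the annulus plane itself; the membranous-septum depths are kept
as landmarks and covariates but do not clip the ROI — the defining
construction references only the annulus and the 15 mm extent. Both choices
are switchable (`lateral_extension_deg`, `caudal_extent_mm`).

CPI is area-weighted, not element-count-weighted, with a contact threshold
of 1e−6 MPa (a numerical zero — "subject to pressure" carries no published
threshold). CPMax is the maximum element pressure over the ROI. Implantation
depth is measured from the annulus plane to the frame inflow edge at the
non-coronary and left-coronary cusps; risk flags use closed (≥) comparisons
at 20 %, 0.40 MPa and 5 mm.

Because contact deepens as the frame sits lower, CPI is non-decreasing in
implantation depth until the ROI saturates; this mechanistic monotonicity is
tested and is what makes the depth planner meaningful: `depth_scan()` solves
one deployment per candidate depth (default grid 0–10 mm; high-implant
preset 0–3 mm), recommends the argmin-CPI depth (CPMax, then lowest depth,
as tiebreaks) and flags residual risk when CPMax at the best depth still
reaches 0.40 MPa. Embolization risk of very high implants is outside the
mechanical scope; the planner prints a fixed caution instead.

## Synthetic cohorts

The generator's defaults are the study conditions of an 80-patient
current-generation self-expanding TAVR cohort and are not tuning knobs:

* anatomy: LVOT 25.4 ± 3.1, annulus 25.1 ± 2.5, sinus 34.3 ± 4.0,
  STJ 28.9 ± 3.5, ascending 32.1 ± 3.2 mm; membranous-septum depths
  5.1 ± 3.0 / 3.5 ± 2.3 / 1.7 ± 2.2 mm (zero-truncated); per-region,
  per-cusp calcium volumes with leaflet totals 172.1/80.2/91.5 mm³;
* procedure: implantation depth 6.2 ± 2.3 mm; device mix dominated by the
  29-mm Evolut PRO (43.8 %) and 34-mm Evolut R (33.8 %);
* outcomes: major conduction disturbance (MCD) prevalence 33.8 %; CPI
  28.3 ± 15.8 (events) vs 15.6 ± 11.2 % (non-events); CPMax 0.51 ± 0.20 vs
  0.36 ± 0.24 MPa; pacemaker incidence 40.5 %/14.0 % by CPI ≥ 20 % stratum;
  length of stay log-normal with median 4.0 days and IQR 2.0–6.0 (the
  log-normal is fitted to the median and the IQR ratio; a two-parameter
  family cannot match both asymmetric quartiles exactly); 30-day LVEF
  change +3.8 % (non-MCD) vs −1.3 % (MCD) with SD 9 % (group SDs are not
  published; 9 % reproduces the published confidence-interval widths at the
  cohort's group sizes); exponential survival with 13.3 % three-year
  mortality in the low-CPMax stratum and a hazard ratio of 5.63 on the
  CPMax ≥ 0.40 MPa flag, administratively censored at 3 years.

**Statistical mode** draws the MCD label first and the two scores from their
group-conditional Gaussians, coupled by a Gaussian copula (ρ = 0.5 — joint
analyses imply correlation but no value is published; configurable).
Gaussians are deliberately untruncated by default: clipping to [0, 100] or
[0, ∞) creates ties and point masses that bias rank statistics such as the
AUC. **Physics mode** runs the full anatomy → deployment → scoring pipeline
per patient and draws the outcome from a logistic model on (CPI, CPMax,
depth). Its default coefficients were calibrated once, by a small search,
so that prevalence sits near 33.8 % under the default generator conditions
with CPMax the dominant per-SD predictor; they are recorded as configuration
defaults.

A deliberate scale caveat: the ring-stack model spreads contact around the
full circumference, so its absolute pressures sit roughly an order of
magnitude below the contact pressures a full 3-D finite-element model
concentrates at calcium spikes and septal bulges — wall stiffness caps the
nodal pressure near 0.1 MPa at typical oversizing. CPI, an area fraction, is
unaffected. Consequently the clinical CPMax cutoff is meaningful for
statistical-mode scores (which live on the clinical scale) and for
custom-configured high-force devices, while physics-mode CPMax should be
read on the model's own scale; the physics-mode outcome model is calibrated
accordingly. Passing tests therefore demonstrate internal mechanical
consistency and correct score arithmetic, not absolute pressure fidelity to
tissue measurements.

What the generator does *not* emulate: bicuspid geometries (the cohort is
95 % tricuspid), inter-site differences, CT screening attrition, cardiac
motion, repositioning/postdilatation, and His-bundle anatomical variation —
the last being the key biological reason even the original method's
diagnostic accuracy is modest.

## Validation statistics

Diagnostic 2×2 metrics, the empirical (midrank Mann-Whitney) AUC with
DeLong confidence intervals, Youden-optimal cutoffs, logistic odds ratios,
Kaplan-Meier/log-rank/Cox survival, and explicit group tests are provided.
Choices made where the analysis convention was open:

* zero-cell odds ratios use the Haldane–Anscombe 0.5 correction, flagged in
  the output;
* the two-group t-test defaults to the Welch correction;
* AUC confidence intervals use DeLong's method (no method is named for the
  published intervals);
* no multiple-testing adjustment, matching the α = 0.05 convention of the
  analysis being emulated;
* complete separation in logistic fits is detected and flagged rather than
  silently penalized.

The AUC implementation is cross-checked in the test suite against `pROC`
(point estimate and DeLong interval) and against the binormal closed form
`Φ((μ₁−μ₀)/√(σ₁²+σ₀²))`; at the published group parameters the binormal
values are 0.744 for CPI and 0.684 for CPMax.

## Worked example

```{r, eval = FALSE}
library(thvcpi)

model <- generate_root(root_params())           # cohort-mean anatomy
model <- place_calcium(model, seed = 1)
dep   <- deploy(model, get_device("EvolutPRO-29"),
                deployment_config(implantation_depth_target = 6.2))
conduction_metrics(dep, model)

scan <- depth_scan(model, get_device("EvolutPRO-29"))
scan$recommended_depth

cohort <- attach_secondary_outcomes(generate_statistical_cohort(5000, seed = 1))
roc_auc(cohort$cpi, cohort$outcome_mcd)
```

## Problem sizes and determinism

The package's own reference scales, used throughout the tests: meshes of
72 × 101 nodes (0.5 mm spacing) solve a deployment in about 0.1 s;
mesh-sensitivity studies compare against 144 × 0.25 mm; statistical cohorts
of 2 × 10⁵ records power the AUC consistency checks; physics cohorts of tens
of patients exercise the full pipeline. Every stochastic path takes an
integer seed and is bitwise reproducible; the contact solver itself contains
no randomness.

## Known limitations

Beyond the pressure-scale caveat above: the ring-stack idealization has no
axial coupling between rings and no frame bending, so oblique deployments
are represented only through the lateral-offset approximation; depths are
identical at both measured cusps (no frame tilt); elastic rather than
hyperelastic tissue (the linearization is the same one the full-scale
simulations justify); statics only; and the published cohort's
patient-level data are not available, so cohort-level agreement is assessed
through reconstruction arithmetic and distributional consistency, never by
refitting the original patients.
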