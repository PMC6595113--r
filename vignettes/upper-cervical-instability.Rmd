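---
title: "Modelling upper cervical spine instability: kinematics, ligament mechanics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling upper cervical spine instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucspine)
```

## The problem

Instability of the upper cervical spine — the occipito-atlanto-axial complex
(occiput C0, atlas C1, axis C2, with C3 as a fixed base) — is difficult to
diagnose from static radiographs: the standard imaging criterion
(intervertebral angulation above 11 degrees or horizontal displacement above
3.5 mm) was developed for the sub-axial spine, and the upper cervical joints
move through much of that angular range physiologically. What distinguishes
the unstable spine is its *dynamic* behaviour: how far each joint rotates
under a controlled moment, and how the restraining ligaments load while it
does.

`ucspine` implements a complete, testable desk-scale version of that
analysis: it generates optical motion-capture trials with known ground truth,
registers a rigid vertebral template to observed markers, recovers per-joint
sagittal angle series and ranges of motion (ROM), evaluates tension-only
spring-ligament stress and pressure, solves a quasi-static sagittal
moment-rotation equilibrium, and runs the validation statistics used for
this class of model (regression against experimental strains, containment in
cadaver-literature ROM intervals, and paired agreement testing).

## Coordinate convention and template geometry

All geometry is in millimetres in a right-handed frame: +X anterior, +Y left
(the medio-lateral axis), +Z cranial, with the foramen magnum horizontal in
neutral. Flexion is a positive rotation of the upper body about +Y relative
to the lower body.

The vertebral template (a versioned JSON asset, `spine_template_v1.json`)
fixes four labelled marker points per vertebra — emulating bone-mounted
screws at the posterior foramen magnum and its sides, the posterior tubercle
and transverse processes of the atlas, and the spinous process and
transverse processes of the axis — plus named ligament attachment points and
the three sagittal joint centers. The published source of the parameter
tables gives no coordinates, so the template's absolute geometry is a
canonical, anatomically plausible choice. This is a deliberate free
parameter: ligament stress depends only on length *changes*, and joint
angles only on relative rotations, so the template's role is to supply
consistent rest lengths and lever arms. What the choice does fix is the sign
pattern — posterior ligaments (ligamenta flava, interspinous, supraspinous,
posterior longitudinal) lengthen in flexion while anterior structures
slacken, and the alar ligament engages in extension — which the test suite
asserts.

## The synthetic motion-capture generator

`generate_trajectory()` emulates the in vitro experiment the analysis is
designed for: a 500 Hz optical system watching four markers on each of
C0-C2 above a fixed base, during slow flexion followed by extension.

* **Motion profile.** Each joint follows a raised-cosine ramp from neutral
  to full flexion, back through neutral to full extension, and back — zero
  velocity at every turning point, matching a "slowly moving" quasi-static
  torque protocol. The frame grid is padded by up to three frames so the
  end-range configurations are sampled exactly.
* **ROM defaults are the study conditions.** Physiological:
  3.49/8.84 degrees flexion and 11.16/14.20 degrees extension at C0-C1 and
  C1-C2; after ligament fatigue (the instability condition): 5.51/13.70 and
  12.96/17.20. C2-C3 is quasi-fixed. A trial default of 2.4 s at 500 Hz
  gives ~1200 frames, the scale of the original point-data collection.
* **Noise and occlusion.** Marker noise is iid isotropic Gaussian,
  default sigma 0.1 mm (typical optical mocap precision; the source reports
  none). Occlusion is iid per frame-marker. Both are seeded: identical
  seeds give byte-identical TRC files.
* **Ground truth** (the exact prescribed angles) is emitted with every
  trial, as a return value and as a JSON sidecar, so downstream tests never
  re-derive it.

What the generator does *not* emulate: soft-tissue artifact, camera
geometry/reconstruction error, correlated noise, and out-of-plane motion.
Passing tests therefore demonstrate correctness of the processing chain
under the stated noise model, not robustness to every artifact of real
capture.

## Registration

The neutral-frame registration implements the triangle-matching
construction used to align a geometric model to experimental markers: pick
three of the four markers (the maximal-area triple, for conditioning, with
a deterministic label-order tie-break), translate vertex 1 onto its
counterpart, rotate about the axis perpendicular to the two vertex-1 edges
to superimpose the 1-2 edge directions, then rotate about that common edge
to bring vertex 3 into the target plane. For congruent triangles this is
exact; for merely similar triangles no scaling is applied — the vertex-3
residual is surfaced instead — because the downstream mechanics assumes
rigid bodies.

`fit_rigid_procrustes()` (Kabsch/orthogonal Procrustes with a reflection
guard) serves as the independent least-squares oracle; on congruent
noise-free input the two agree to better than 1e-6 in rotation and
translation, which the acceptance suite checks over 1000 random rigid
transforms. Per-frame pose estimation uses the Procrustes fit over all
visible markers (it is the minimum-variance choice under isotropic noise);
a registration RMS above 1 mm triggers a warning, since no acceptance
tolerance is published for the original matching.

## Kinematics

The relative rotation at a joint is `R_rel = t(R_lower) %*% R_upper`; the
sagittal angle is the signed component of its rotation vector along the
lower vertebra's medio-lateral axis (axis-angle projection). This
definition is exact for single-plane motion and degrades gracefully for
small out-of-plane components. AP translation is the anterior component of
the upper origin's displacement in the lower body's frame. ROM is taken as
end-range extrema of the cleaned series (missing frames flagged and
excluded, never silently interpolated); whether the published angles were
extrema or averages over repeats is not stated, and extrema are assumed.

For noisy data the pose stage offers zero-phase low-pass smoothing
(second-order Butterworth at 6 Hz, filtered forward and backward via
`signal::filtfilt`, with symmetric-reflection padding at the series ends —
quasi-static trials start and end at rest, so even reflection introduces no
edge transient). The motion itself lives below ~1 Hz, so the filter
suppresses marker noise by more than an order of magnitude while
attenuating the end ranges by well under 0.01 degree. It is off by default
and requires gap-free data; the acceptance analysis of 0.2 mm-noise trials
switches it on and requires every end range within 0.5 degrees over 100
seeded replicates.

## Instability classification

`classify_instability()` is the strict radiographic predicate: unstable iff
angle > 11 degrees or displacement > 3.5 mm; values exactly at a threshold
are stable. Applying this blindly to ROM would mislabel every healthy
upper cervical spine, because physiological *extension* already reaches
11.16-14.20 degrees — precisely the known limitation of the sub-axial
criterion in this region. `instability_report()` therefore applies the
angular branch to the flexion end range (the imaging domain the criterion
comes from) and the displacement branch to the largest AP translation, and
reports extension angles flagged as outside the criterion's domain of
validity. Under this reading the physiological condition is stable at
every joint while the unstable condition trips the atlanto-axial flexion
test (13.70 > 11).

## Ligament mechanics

Ligaments are tension-only springs along straight attachment lines:
`F = k * max(dl, 0)`, `P = F / A_eff` (engineering stress over a constant
effective area). Although the source describes nonlinear springs, every
published table row satisfies the linear law exactly, so piecewise-linear
tension-only is the default, with a hook for user-supplied
force-displacement curves.

Two areas are carried per ligament. The material table's printed
cross-sections are kept as `cross_section_A`; pressures are computed over
`effective_area_A_eff`, the area consistent with the published
stress/pressure ratios. The two agree (to <0.1%) for the flavum, anterior
longitudinal and posterior longitudinal ligaments; the alar (10.3 vs
3.4 mm^2), apical odontoid (2.5 vs 2.7 mm^2) and cruciate (no printed
value) areas are calibrated from the tables via
`effective_area_from_row()`. Whether paired bands divide force over one or
both cross-sections is unstated; the calibrated area absorbs that choice.

`state_table_comparison()` reproduces all four condition-by-direction
tables from their length-change and rigidity columns. Three tables
reproduce to 1e-6 relative in every cell. The instability-extension table
is internally inconsistent in two rows as printed — its alar stress cell
(88.035 vs 3.303 x 25.32 = 83.632; note its *pressure* cell matches the
recomputed stress to 0.02%) and its posterior-longitudinal pressure cell
(0.76% off) — and these are flagged as discrepancies rather than matched.

```{r tables}
cmp <- state_table_comparison()
cmp[cmp$flagged, c("condition", "direction", "ligament",
                   "stress_rel_err", "pressure_rel_err")]
```

Rigidities use the published per-ligament values where printed (their
provenance is not stated in the source); the remaining 16 ligaments fall
back to the axial estimate `E * A / L0` from the material table and the
template rest length.

## The equilibrium surrogate

`solve_static()` and `moment_sweep()` provide a sagittal-plane stand-in for
the continuum finite-element run: three rotational unknowns, loaded by a
100 N compressive preload (applied 10 mm anterior of the C0-C1 center —
the original load point, "the center of gravity of the skull", is not
quantified) and a moment ramp to 1.5 N.m (300 N.mm reproduces the lighter
literature load). Restraints are the discrete spring ligaments acting
through their actual lever arms, a per-joint aggregate torsional stiffness
(defaults 150/100/200 N.mm/degree at C0-C1/C1-C2/C2-C3) standing in for
the membranous structures that are in the material table but not in the
22-spring set, and unilateral facet stops (defaults 15/16/12 degrees
flexion, 18/20/12 extension, 5000 N.mm/degree) with Coulomb friction
(mu = 0.10) engaging past the 0.01 mm joint clearance converted through a
20 mm effective facet radius. A scalar `stiffness_scale` softens the whole
soft-tissue envelope — ligaments *and* aggregate — which is both the
physical reading of fatigue and what makes softening strictly increase
every joint angle; a named vector scales individual ligaments only.

The solver is damped Newton on the stacked residual (finite-difference
Jacobian, tolerance 1e-6 N.mm) with per-joint bisection sweeps as a
fallback; the residual is monotone in each angle, so the solution is
initial-guess independent in the monotone regime. Because preload and
ligament moments are evaluated from the actual geometry (Jacobian-transpose
generalized forces), the work-energy audit closes to ~1e-7 over a 200-step
sweep, far inside the 1% acceptance band.

This surrogate is validated by closed forms and consistency properties
(single-torsional-spring limit, monotone moment-angle curves, path
independence, strict softening, energy balance). It is *not* claimed to
reproduce the continuum model's printed angles, and the package nowhere
asserts that it does.

## Validation statistics

* `linear_regression()` — OLS with R^2, for strain-validation regressions
  (the published coefficients y = 1.348x - 0.723, R^2 = 0.891 serve here
  only as generator parameters in tests; the underlying strain data are
  not deposited).
* `range_check()` — containment of model ROM in cadaver-literature
  intervals, inclusive at the bounds and judged at the bounds' printed
  resolution (tolerance 0.05 degrees, half of the 0.1-degree quoting
  precision). This matters once: the atlanto-axial flexion angle 8.84
  against an upper bound quoted as "8.8" is containment at printed
  precision.
* `paired_agreement_test()` — two-sided paired t-test at alpha = 0.05
  (paired by joint x direction x condition, small n; the original analysis
  names only the statistics package, not the test, and a paired design
  makes the paired t the natural choice); Wilcoxon signed-rank is available
  behind a flag. Conventions: identical sets give p = 1, a zero-variance
  nonzero shift gives p = 0.

```{r validation}
rc <- range_check(data.frame(joint = c("C0C1", "C1C2"),
                             flexion_deg = c(3.49, 8.84),
                             extension_deg = c(11.16, 14.20)))
rc
paired_agreement_test(c(3.49, 8.84, 11.16, 14.20, 5.51, 13.70, 12.96, 17.20),
                      c(3.82, 8.01, 10.4, 14.89, 4.91, 14.08, 12.55, 16.41))$p_value
```

## Numerical choices, problem sizes, limitations

* Tolerances: registration equivalence 1e-6; noise-free ROM recovery
  0.01 degree; noisy recovery 0.5 degree at sigma = 0.2 mm (100
  replicates, 1.2 s trials, smoothing on); equilibrium residual 1e-6 N.mm;
  energy balance 1%; state tables 1e-6 relative (0.5% for the
  inconsistent-as-printed table, with its two flagged rows excluded).
* Problem sizes used in the shipped tests and acceptance analysis:
  noise-free trials at the full 2.4 s/500 Hz length (1201 frames); noisy
  replicates at 1.2 s; 1000 random transforms for the registration
  equivalence; 200-step moment sweeps. These sizes make the whole suite
  run in a few minutes on one core while keeping every estimate stable.
* Degenerate inputs fail loudly: collinear triangles name the offending
  vertices, vertebrae with fewer than three visible markers name the
  vertebra, all-missing angle series refuse to summarise, malformed TRC
  input aborts before any output is written (all writers are atomic).
* Limitations: rigid vertebrae (no bone or disc deformation), straight-line
  ligaments (no wrapping), no musculature or neurovascular structures, a
  single canonical geometry rather than subject-specific anatomy, and a
  planar equilibrium (flexion/extension only — axial rotation and lateral
  bending are out of scope). Conclusions about real pathology require the
  continuum model this package deliberately does not replace.
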