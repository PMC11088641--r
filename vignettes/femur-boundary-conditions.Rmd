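---
title: "Constraining an isolated femur: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraining an isolated femur: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`femurbc` compares six ways of constraining an isolated femur in quasi-static
finite-element analysis of walking: inertia relief (the free-body benchmark),
a fully fixed distal femur ("fixed knee"), weak grounded springs, an
isostatic three-landmark pin set, a mid-shaft constraint, and a
"biomechanical" constraint built around an axial connector between the
femoral head centre and the knee centre. This vignette records the model, its
assumptions, the design decisions that were genuinely open, and what the
desk-scale benchmark can and cannot show.

## Mechanical model

The solver uses 4-node linear (constant-strain) tetrahedra with small-strain,
small-displacement linear elasticity. Cortical bone strained at walking
levels stays below a few thousand microstrain, so geometric and material
nonlinearity are out of scope; the seven stance instances are independent
linear solves sharing one factorisation per method. The unit system is
mm-N-MPa-tonne: apparent densities in g/cm^3 are converted to tonne/mm^3
(factor 1e-9) so stresses emerge in MPa.

Material mapping follows the calibrated CT relations
`rho_app = 0.001029 GV + 0.114259` (g/cm^3) and `E = 6850 rho_app^1.49`
(MPa), Poisson ratio 0.3 everywhere. Elements are grouped into ten
equal-width greyscale bins (each represented by its members' mean greyscale);
equal-width binning is the simplest reading of "sets of material properties",
and the representative-mean choice approximately preserves total stiffness.
The mapping is applied exactly as printed even though it yields
supra-physiological densities near the top of the 12-bit range (about
4.33 g/cm^3 at GV 4095); `gv_to_density()` flags rather than clamps these.
A sensitivity harness (`material_sensitivity()`) confirms that refining from
10 to 20 bins changes the peak von Mises stress by well under 5% on the
reference problem.

All constraint types are enforced through one Lagrange-multiplier
saddle-point system `[K C'; C 0]`: directional Dirichlet rows expressed in
the local anatomical frame, slider rows for the connector reference point,
rigid-coupling rows tying a small patch to a 6-DoF reference point, and the
mass-orthogonality rows of inertia relief. A single mechanism (rather than
row elimination plus master-slave reduction plus a special IR path) keeps
every method on the same code path, and the multipliers double as reported
reaction forces. Grounded springs augment the stiffness diagonal. Systems are
solved with a sparse LU factorisation shared across the seven instances;
equilibrium residuals are checked below 1e-8 relative.

Inertia relief computes rigid modes `R` about the mass centroid,
accelerations `a = (R'MR)^-1 R'f` with a lumped (row-sum) mass matrix, and
solves the balanced load `f - MRa` under the gauge `R'Mu = 0`. The lumped
mass is exact for the rigid-body resultants that inertia relief needs; the
consistent-mass alternative would change nothing at equilibrium level.

## The synthetic femur

The generator builds a generalized cylinder: elliptical cross-sections
stacked along a centreline that runs from a widened condylar block up the
shaft, around a filleted bend at the neck base, and along the neck into an
exactly spherical head; cross-section triangulations are joined into prisms
and split into three tetrahedra each with a minimum-index diagonal rule, so
the mesh is conforming and watertight by construction (surface Euler
characteristic 2 is asserted in tests). Cortical and cancellous bone are
encoded in the per-element greyscale field from each element's depth below
the outer surface.

Defaults describe an adult-scale femur consistent with the 93.4 kg
participant the load fixture assumes: length 420 mm, head radius 22 mm,
neck-shaft angle 127 deg, anteversion 15 deg, mid-shaft outer diameter 32 mm
with a 6 mm diaphyseal cortex, and a metaphyseal flare of roughly 1.5x the
shaft diameter at the intertrochanteric level. Greyscale plateaus are 2200
(cortical) and 1400 (cancellous) on the offset 12-bit CT scale whose
segmentation window is 1250-4095; through the material mapping these give a
cortical modulus near 25 GPa. The default 5 mm target edge length produces
about 30k elements - a deliberate desk-scale resolution (a patient-specific
2 mm mesh has ~230k elements); resolution is a parameter, and the acceptance
suite checks that peak stress and head deflection move by less than 25%
between the default and a coarser mesh.

Landmarks are stored as positions, not node indices; the posterior condylar
landmarks in particular are defined on the analytic condylar ellipse so the
posterior condylar axis is exactly parallel to the medial-lateral direction
at construction (snapping them to mesh nodes skews the measured anteversion
by up to half an angular grid spacing). The anatomical frame takes the
superior-inferior axis from knee centre to head centre, orthogonalises the
knee-to-lateral-epicondyle direction against it (Gram-Schmidt; the epicondyle
direction is generally not perpendicular to the mechanical axis), and closes
the right-handed triad with `ap = ml x si`.

## Deformation toolbox

Pathological geometries are made by ramped rigid rotations. The anteversion
warp rotates nodes about the mechanical (head-knee) axis by an angle that
ramps from zero at the condyles to the full rotation proximal to the
lesser-trochanter level; a cosine ramp is used because it is C1-continuous,
avoiding the strain-concentration band a step rotation would imprint. The
neck-shaft warp rotates the head and neck about the anterior-posterior axis
through the neck base, ramped along the neck axis (default span 40 mm). The
total rotation is root-solved on the landmark set (cheap), then applied to
the mesh in 20 increments with an element-inversion check after each; the
warp aborts with a quality report rather than untangling. Because the
mechanical axis passes through both the head and knee centres, the
anteversion warp's axis is invariant and warps compose and invert exactly -
the +20/-20 degree round trip restores node positions to 1e-6 mm. Greyscale
values and patch memberships ride along untouched.

Whether torsion should be confined to the proximal fragment or distributed
along the shaft is not determined by the source description ("gradually");
the distributed (ramped) reading was adopted because it preserves element
quality at severe targets (45 deg anteversion, 115/150 deg neck-shaft).

## The gait-load fixture

The fixture emulates the *outputs* of a neuromusculoskeletal pipeline -
muscle forces and hip/tibiofemoral/patellofemoral contact forces at seven
equally spaced stance instances, expressed in the local femur frame - without
any motion-capture or EMG processing, which are out of scope. Magnitudes are
pinned by configuration:

* hip contact: bimodal stance waveform scaled so its maximum over the seven
  instances is exactly `hip_peak_bw` x body weight (default 2.4 BW, 93.4 kg);
  direction about 8 deg lateral of the mechanical axis in the frontal plane
  (instrumented-implant averages put the stance resultant ~13 deg off the
  shaft axis, passing from the head towards the knee) with a small
  anterior-posterior sweep from braking to propulsion;
* nine muscle groups (gluteus medius/maximus, iliopsoas, vasti, adductors,
  both gastrocnemius heads, short external rotators, tensor fasciae latae)
  with straight lines of action from attachment-patch centroids to fixed
  anatomical via-points and peak forces of 0.25-1.5 BW;
* patellofemoral contact (0.4 BW peak) on the anterior distal femur.

Two properties of real pipeline outputs are emulated explicitly, because the
method comparison is meaningless without them. First, muscle recruitment
resolves the external moments: per instance, nominal muscle magnitudes are
ridge-adjusted (clamped to [0, 6] x nominal, with a 5% baseline tone so every
muscle stays recruitable) until the net moment about the knee approximately
closes; the rotator muscles exist chiefly because nothing else has a moment
arm about the shaft axis. Second, the tibiofemoral contact force closes the
distal load path: it reacts the sum of all other loads, leaving a small
dynamic residual (default 0.05 BW, representing thigh-segment dynamics) that
is exactly what inertia relief absorbs. The resulting load set is therefore
deliberately *not* self-equilibrated - a property asserted in tests. The same
force set is applied to every geometry, matching the source study design, so
on warped geometries the moments re-open slightly.

A small seeded multiplicative jitter (2% s.d.) models step-to-step
variability; everything is bit-reproducible given the seed.

## Boundary conditions

Directions below are local-frame (ML/AP/SI); landmark constraints snap to the
nearest mesh node and the snap distances are recorded on the constraint set.

* **Inertia relief**: no constraints; all loads, residual balanced inertially.
* **Fixed knee**: all translations of the distal condylar surface region
  (distal 5% of femur length) fixed; tibiofemoral and patellofemoral forces
  omitted. Fixing a finite region is the standard reading of "distal femur in
  all six DoF" for solid elements, which carry no rotational DoF.
* **Springs**: grounded 1 N/mm springs on three ~50-node bands (femoral neck,
  epicondyles, knee centre); no Dirichlet rows; all loads. The defaults keep
  the net spring reaction under 2% of the applied load on the synthetic
  femur; stiffness, and hence the method's behaviour, is config-exposed
  because the method is known to be sensitive to it.
* **Isostatic**: exactly six pinned DoF - knee-centre node (3), the
  head-surface node nearest the mechanical-axis exit in ML and AP (so the
  head can deflect only along the mechanical axis), lateral epicondyle in AP.
  The description of the epicondyle direction is contradictory in the source
  (AP in one passage, SI in another); AP is the well-posed default and SI is
  kept as a variant flag, under which rotation about the mechanical axis is
  nearly unrestrained - the acceptance-adjacent tests demonstrate the
  near-singularity rather than guessing the intent away.
* **Mid-shaft**: knee centre (3), epicondyle AP (1), mid-diaphysis ML+AP (2).
* **Biomechanical**: knee centre fixed in 3 translations; the greater
  trochanter reference point, rigid-coupled to its small lateral patch,
  fixed in ML and AP translation and SI rotation (passive thigh soft tissue);
  and the acetabulum surrogate: reference point `p1` at the head centre rides
  an axial slider along the undeformed head-knee axis, linked to the
  articulating head patch through the axial component of the coupling. By
  default the full hip force vector is applied to the bone through the head
  coupling and `p1` is a passive axially-guided tracking point
  (`hip_transmission = "full"`); the alternative routing
  (`hip_transmission = "axial"`) applies the force at `p1` so only the axial
  component reaches the bone and the slider multipliers reproduce the
  transverse components exactly. The full-vector default was chosen because
  the method is defined as incorporating *all* muscle and joint contact
  forces with the femoral head "free to translate and rotate", and because
  experiments showed that pinning the head-patch average transversely (the
  literal distributing-coupling-plus-slider reading) restructures the load
  path and destroys the method's agreement with inertia relief.

## What the benchmark shows, and what it cannot

Under the frozen default conditions the printed physiological bounds hold on
the normal femur: biomechanical maximum resultant head deflection 0.41 mm
(<1 mm), biomechanical peak stress 24.6 MPa (<60 MPa), cortical strains for
the isostatic/inertia-relief/biomechanical methods below ~780 microstrain
(<1100), inertia-relief superior-inferior deflection 0.27 mm (within the
0-3 mm single-legged-stance envelope). The fixed-knee method deflects the
head an order of magnitude more than the benchmark on every geometry, and the
lateral-tension / medial-compression cortical pattern holds for the
inertia-relief and biomechanical methods on the normal, anteverted,
retroverted and coxa vara geometries.

Three ordering claims from patient-scale studies do *not* reproduce robustly
at this scale, and the acceptance tests assert them honestly rather than
papering over them. (1) On the two anteversion geometries the springs
method's rigid drift (driven by the residual moments that re-open when the
normal-geometry force set is applied to a warped bone) slightly exceeds the
fixed-knee deflection (3.3 vs 3.1 mm), because the synthetic femur is stiffer
relative to body weight than a patient model, compressing fixed-knee
deflections into the drift range. (2) With a near-equilibrated fixture all
gentle methods agree with inertia relief to about 1% in the peak-stress
series, so the ranking between the biomechanical and springs methods (nRMSE
0.0035 vs 0.0008) is numerical dust rather than a reproducible ordering; the
wide margins reported at patient scale come from pipeline-specific residuals
and spring sensitivities a synthetic fixture cannot know. For the same
reason the "springs give the lowest peak stress" observation does not
separate from the other gentle methods here (all within ~1 MPa). (3) On the
coxa valga geometry raising the head over the shaft removes the frontal
bending lever, and the lateral-path mean strain sits at zero instead of in
tension.

Passing tests on this synthetic benchmark therefore demonstrate correctness
of the mechanics and the *direction* of boundary-condition artefacts, not the
patient-scale magnitudes: the mesh is 7x coarser than a CT mesh, the pseudo-CT
field has two plateaus instead of a continuous density distribution, muscle
paths are straight lines, cartilage is absent, and the load residuals are a
configured stand-in.

## Numerical notes

* Tetrahedron volumes are kept strictly positive under a fixed node-ordering
  convention; the INP writer emits the same ordering.
* The peak-stress artefact guard (default 5 mm) excludes elements near any
  load-application patch node or Dirichlet-constrained node, identically for
  all methods; comparisons, not absolute extrema, are the object.
* "Absolute principal strain" is `max |principal strain|`; a signed companion
  (the extreme principal strain of largest magnitude) supports the
  tension/compression pattern checks.
* R^2 is computed against the inertia-relief series as truth
  (`1 - SS_res/SS_tot` about the reference mean), not as a symmetric squared
  correlation; nRMSE divides the RMSE by the reference's dynamic range.
  Constant or zero-range references return flagged `NaN`.
* Distributing couplings spread a reference-point force as equal shares plus
  a zero-resultant correction field `omega x (r - rbar)` solved from the
  patch's centroidal inertia; degenerate (collinear or tiny) patches fall
  back to a pseudo-inverse that drops the unresolvable moment component.
* Sphere fitting is algebraic least squares (linear in centre and radius
  offset), exact on noise-free samples and stable on hemispherical coverage.
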