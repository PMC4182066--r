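---
title: "Modelling the retrograde displacement wave of the orbital floor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the retrograde displacement wave of the orbital floor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbishock)
```

## The physical question

Orbital emphysema — air inside the orbital soft tissues — usually
follows a blowout fracture, but the route of the air is debated: is it
pumped in by raised sinus pressure (sneezing, nose blowing), or can it
be *sucked* in by the orbit itself?  The suction hypothesis rests on a
dynamic argument: a blunt strike on the inferior orbital rim first
drives the orbital floor outward into the maxillary sinus, and the
elastic rebound then swings the wall back toward the orbital interior.
If a fracture is present, that retrograde motion reverses the pressure
gradient across the wall and can draw sinus air into the orbit.

`orbishock` implements the complete simulation chain needed to examine
this sequence: synthetic orbit geometry, thin-shell elastodynamics
under an impulsive rim load, and post-processing that detects and
quantifies the outward-then-retrograde wave.

## The synthetic orbit

No usable orbit mesh is publicly deposited, so the geometry module is a
first-class synthetic-data generator.  It emulates an average adult
left orbit as a frustum-like shell: superellipse cross-sections blend
from a rounded rectangle at the rim (half-axes 20 × 17.5 mm, exponent
4) to the circular optic-canal aperture at the apex (radius 2.5 mm,
exponent 2) over a depth of 45 mm.  These dimensions are standard adult
anatomical averages; all are configurable through `orbit_params()`.

Construction details that matter:

* **Arc-length node placement.**  Each cross-section ring is sampled at
  equal arc-length fractions (anchored at the floor/lateral corner),
  not at equal parameter angles; the superellipse parametrization
  otherwise crowds nodes into the corners and leaves the face centres
  coarse.
* **Inferior orbital fissure.**  A slit of 20 × 3 mm is opened along
  the floor/lateral seam in the posterior part of the wall by removing
  whole grid cells, producing a third boundary loop (rim + canal +
  fissure).  `fissure_width = 0` suppresses it.
* **Wall regions and thickness.**  Elements are labelled
  `floor_anterior`, `floor_posterior`, `medial`, `roof`, `lateral` by
  the direction of their column; thickness is per region
  (floor 0.5/1.0, medial 0.3, roof 1.0, lateral 1.5 mm) with a 3 mm
  rim band on the first element row.  The floor is deliberately thicker
  posteriorly than anteriorly, matching the anatomical gradient that is
  held responsible for the anterior predilection of floor fractures.
* **Boundary conditions.**  The apex-aperture ring and the superior rim
  arc (roof plus the upper halves of the medial and lateral rim) are
  fully fixed, standing in for the attachment of the orbital walls to
  the rest of the skull.  The inferior rim is left free: the strike
  acts there, and loading fully constrained nodes would produce no
  motion.  This split is a modelling decision — the skull fixes the
  walls *somewhere* along the rim, and the free inferior band also
  stands in for the compliant frontal wall of the maxillary sinus,
  which is not modelled as a separate panel.
* **Strike nodes and probe.**  Six nodes are selected on the free
  inferior rim, evenly spaced by arc length (a small dynamic program
  minimizes the spacing deviation; on the default mesh the spacing is
  uniform to about 2 %).  The probe node A sits on the anterior floor
  at 25 % depth, midway between the nasolacrimal corner and the
  infraorbital midline, and is recorded in the mesh for
  reproducibility.
* **Jitter.**  Nodes off the boundary loops receive a seeded
  perturbation of at most 5 % of the shortest incident edge, breaking
  structured-mesh symmetry artifacts; `jitter = 0` gives the exact
  structured grid for regression tests.  The construction is
  deterministic for a fixed seed and exactly scale-equivariant.

The default target of 969 elements reproduces the resolution of the
original CT-derived model; the generator lands within 10 % of any
requested count (994 by default after slit removal).

What the generator does **not** emulate: patient-specific wall
curvature and buttresses, the maxillary sinus as a structure, orbital
soft tissue, the periorbita, and any statistical shape variation.
Passing tests on this geometry therefore demonstrate the mechanism and
the solver, not patient-level displacement magnitudes.

## Shell elements

The walls are flat-facet triangles superposing

* a **constant-strain triangle** (CST) membrane field,
* a **discrete Kirchhoff triangle** (DKT) plate-bending field, and
* a small **drilling** stabilization for the rotation about the element
  normal.

The DKT element is built directly from its defining construction: the
rotation field is quadratic over the triangle, pinned at the corners to
the nodal slopes, with the mid-side tangential slope given by the cubic
Hermite edge deflection and the normal slope varying linearly along
each edge.  Curvatures are integrated exactly with the three mid-edge
points.  Bending stiffness scales with t³ and membrane stiffness with
t, and each 18×18 element operator annihilates all six rigid-body
motions to machine precision.

The drilling rotation is tied to the in-plane rotation
½(v,x − u,y) of the membrane field by a penalty of
1e-4 · E t A.  Two choices here are deliberate.  First, the penalty
couples θz to the membrane rotation rather than penalizing θz
differences, so a uniform in-plane spin of a flat patch costs no
energy while a pure drilling spin does — a flat two-element square then
has exactly six zero-energy modes.  Second, the penalty is scaled by
the *membrane* stiffness: a bending-based scale (∝ t³) collapses on
0.3–0.5 mm walls and numerically re-opens the drilling mechanism.

Internally everything is assembled in mm–N–tonne–s, so Young's modulus
enters in MPa and stresses leave in MPa; `material()` converts from SI.
The default material is E = 1.2 GPa — the mean extensometer measurement
on cadaveric orbital-wall samples — with ν = 0.3 and ρ = 1900 kg/m³
(typical cortical bone; neither is part of the measurement) and zero
damping, which keeps the energy checks exact.

Verification is by analytic oracles rather than reference software:
membrane patch test to 1e-8, simply supported plate deflection against
the Navier double-sine series (0.06 % at 32 × 32), plate fundamental
frequency against the Kirchhoff closed form (0.34 % at 16 × 16),
cantilever tip deflection and root stress against beam theory, and
frame indifference under random rotations.

## Mass, time integration and stability

The mass matrix is lumped: each element spreads ρ A t equally over its
three nodes on the translational dofs.  Rotational dofs receive the
nodal mass share scaled by A/12 (units tonne·mm²).  This rotary
inertia is an element-size-based scaling, standard practice in
explicit shell codes: the physically "correct" thin-shell rotary
inertia (∝ t²/12) is so small that rotational frequencies would
control the stable time step without affecting the flexural response.

The strike is a symmetric triangular pulse — the simplest profile
consistent with a force that peaks at 1.3 ms and vanishes at 2.6 ms —
applied as nodal point forces of 2400 N on the six rim nodes along +x
(posterior, along the orbital axis), the canonical frontal blowout
direction.  Both the direction and the per-node force are configurable,
and the pulse knots can be overridden in the run config.

Central differences integrate the free dofs with
dt = cfl_safety × 2/ω_max, where ω_max is estimated by power iteration
on the mass-normalized stiffness (tolerance 0.1 %, verified within 5 %
against a dense eigensolve on a coarse mesh).  The default
cfl_safety = 0.8; the step is then rounded down so snapshots at 1 ms
multiples land exactly on solver steps.  A requested dt above the limit
is refused up front, and a runaway displacement (1000 × mesh diameter)
aborts the run with the step index.  Snapshot velocities use the
central difference over two steps, which makes the recorded energy
balance |W − (T + U)| hold to ~1e-7 of peak work on the default run.
The implicit Newmark average-acceleration integrator (default
dt = 1e-5 s) factorizes its effective stiffness once and serves as the
cross-check: probe traces from both integrators at dt = stable/2 agree
to 0.03 % of peak amplitude.

Rayleigh damping C = αM + βK is available through `material()` but
defaults to zero.

## Wave analysis

The signed wall displacement projects each node's translation onto its
area-weighted normal, which points into the orbital cavity: positive =
inward (toward the orbit), negative = outward (toward the sinus).  The
alternative `orbital_axis` mode projects onto the anteroposterior axis
signed by wall side, reproducing a literal sagittal-axis reading; the
wall-normal default is used for all reported metrics because
inward/outward motion of oblique walls is the quantity of interest.
Which projection produced the original colour maps is ambiguous, so
both are provided and neither is asserted as "the" original.

The retrograde onset is the earliest snapshot at which any floor or
medial-wall node crosses from below −ε to above +ε, with ε = 0.1 mm:
comfortably above integration noise, comfortably below the smallest
physically reported relocation (0.5 mm).  Probe metrics are exact on
the snapshot grid: outward peak max(−s), inward peak max(+s), and their
sum as peak-to-peak.

Surface stresses are recovered per element from the membrane strain and
the centroid curvature as σ = D(ε ± (t/2)κ), with the von Mises
equivalent computed on both fibers.  The fracture threshold is a
configurable von Mises limit, default 80 MPa (the order of cortical
bone tensile strength — the original limit value is not published);
only the *time* of first exceedance in the floor is reported, never
assumed.  Post-fracture mechanics (element removal, contact, air flow)
are out of scope by design.

## The reproduction pipeline

`run_config()` bundles geometry (parameters or a mesh file), material,
load overrides, integration and analysis settings; `run_reproduction()`
executes generate → assemble → integrate → analyze and writes the VTK
snapshot series, probe/energy/per-region CSV traces, the JSON wave
report and a manifest.  Identical configs reproduce byte-identical
reports (the jitter seed is part of the config; no wall-clock enters
the report body).  The report embeds the displacement magnitudes
observed on the original CT-derived model as `reference_observations`,
explicitly labelled non-binding: the synthetic geometry is not that
skull.  A command-line surface is provided as a thin wrapper
(`exec/orbishock`) over these functions.

## Problem sizes and runtime

The default study runs ~1000 elements (~3200 free dofs) for 10 ms of
simulated time, about 28 000 explicit steps — roughly ten seconds on
one core.  Benchmarks use a 32 × 32 plate for deflection, 16 × 16 for
frequency, and a ≤ 200-element orbit for the dense eigensolve oracle;
the full verification suite plus the default run completes in a few
minutes on a single CPU.

## Known limitations

* **Linear kinematics.**  Displacements of several millimetres on a
  40 mm orbit are beyond the strictly linear range; on this synthetic
  geometry the absolute magnitudes come out several times larger than
  the values observed on the CT-derived model (whose stiffer
  environment — surrounding skull, sinus walls — is not present).
  The phenomenology (outward phase during loading, retrograde reversal
  after the pulse, inward peak smaller than outward peak) is the
  meaningful output; millimetre values are qualitative.
* **No fracture.**  Stress exceedance is flagged, not acted on; the
  real event would shed load after 2.6 ms and change the late-phase
  amplitudes.
* **No fluid.**  The pressure-gradient argument that links the
  retrograde wave to air aspiration is interpretive; no air or
  soft-tissue mechanics are computed.
* **Element choice.**  The original commercial solver's exact shell
  formulation is unknown; CST+DKT is the simplest well-validated
  thin-shell element, verified here at benchmark level, but
  element-level equivalence with the original cannot be asserted.
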