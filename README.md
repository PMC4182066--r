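# orbishock

Thin-shell finite-element simulation of an impulsive strike on the bony
orbit, built to study the mechanism behind posttraumatic orbital
emphysema: after a blunt blow to the inferior orbital rim, the orbital
floor first bulges *outward* into the maxillary sinus and then swings
back *inward* — a retrograde ("recurring") displacement wave that can
reverse the pressure gradient across a fractured wall and suck sinus air
into the orbit.

The package is aimed at computational biomechanics users who want a
fully scripted, dependency-light reimplementation of that experiment:
a parametric average-orbit geometry, a verified shell solver, explicit
transient dynamics, and post-processing that quantifies the wave.

## What it computes

* **Synthetic orbit geometry** — a triangulated shell (~969 elements by
  default) of the four orbital walls converging from a rounded-
  rectangular rim to the optic-canal aperture at the apex, with an
  inferior-orbital-fissure slit, per-region wall thickness (floor
  thicker posteriorly than anteriorly), fixed boundary at the apex ring
  and superior rim, and six strike nodes evenly spaced on the free
  inferior rim.
* **Shell finite elements** — flat-facet triangles combining a
  constant-strain membrane (CST) with discrete Kirchhoff plate bending
  (DKT) and a small drilling stabilization; element stiffness
  K = K_m(t) + K_b(t^3) with lumped mass, in an mm–N–tonne–s unit
  system (stresses in MPa).
* **Transient dynamics** — the strike is 6 × 2400 N = 14 400 N along the
  orbital axis, ramping linearly 0 → peak → 0 over (0, 1.3 ms, 2.6 ms);
  the response is integrated over 10 ms (snapshots every 1 ms) by
  central differences at dt = 0.8 × 2/ω_max, or implicit Newmark
  (average acceleration) for cross-checking.
* **Wave analysis** — signed wall displacement s(node, t) = u · n̂ with
  the node normal n̂ pointing into the orbit (positive = inward,
  negative = toward the sinus), retrograde-reversal detection
  (−ε → +ε crossing, ε = 0.1 mm), probe-node outward/inward peaks,
  von Mises surface-stress recovery and fracture-threshold flagging.

Default material: E = 1.2 GPa (measured on orbital-wall bone), ν = 0.3,
ρ = 1900 kg/m³, no damping.

## Worked example

```r
library(orbishock)

mesh <- generate_orbit(orbit_params())
mesh
#> Shell mesh: 532 nodes, 994 triangles
#>   regions: floor_anterior (144), floor_posterior (130), lateral (216), medial (216), roof (288)
#>   fixed nodes: 42; load nodes: 6; probe A: 147

sys  <- assemble(mesh, material())
hist <- integrate_transient(sys, default_strike_load(mesh), time_config())
wave_report(hist, mesh, material())
#> Wave report (wall_normal projection)
#>   peak outward: 47.681 mm at t = 0.001 s (floor_anterior)
#>   peak inward : 14.239 mm at t = 0.004 s (medial)
#>   retrograde reversal onset: 0.002 s (floor_anterior, medial)
#>   probe A: outward 2.861 mm, inward 2.044 mm, peak-to-peak 4.906 mm
#>   first stress exceedance (> 80 MPa): 0.001 s (element 886, floor_posterior)
```

Reading the report: during the load window the floor moves outward
(negative signed displacement, toward the sinus); after the pulse the
motion reverses and an inward-directed wave is detected at 2 ms, with
the inward peak smaller than the outward peak — the qualitative sequence
behind the suction hypothesis.  On this synthetic geometry the absolute
millimetre values are larger than on a CT-derived skull (the model is
linear and lacks the surrounding bone); they should be read as
qualitative, which is why the JSON report also carries the original
model's observations as explicitly non-binding reference fields.

The config-driven pipeline writes the full result set (VTK snapshot
series, probe/energy/per-region CSV, JSON report and manifest):

```r
run_reproduction(run_config(output_dir = "out"))
```

or from a shell via the thin CLI wrapper `exec/orbishock`:

```sh
Rscript exec/orbishock run --out out
Rscript exec/orbishock benchmarks
```

## Verification

`run_benchmarks()` checks the solver against independent analytic
oracles: membrane patch test (≤ 1e-8), simply supported plate deflection
vs the Navier series (≤ 2 %), plate fundamental frequency (≤ 3 %),
harmonic-oscillator period (≤ 0.5 %), undamped energy balance on the
default run (≤ 1 % of peak work), and central-difference vs Newmark
probe traces (≤ 5 % of peak amplitude).

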