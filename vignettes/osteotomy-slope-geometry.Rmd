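---
title: "Methods: wedge-opening geometry, measurement emulation and rank tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wedge-opening geometry, measurement emulation and rank tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owhto)
```

## The geometric model

The proximal tibia is idealised as a square column whose top face is a plane
inclined posteriorly by the initial posterior slope α₀ (10° by default, a
typical plateau slope). A medial open-wedge osteotomy is a complete cut whose
plane makes angle φ (the sagittal plane osteotomy inclination, SPOI) with the
axial plane, hinged laterally: the *true lateral hinge* is the axis in the
cut plane that is parallel to the osteotomy line in the axial view. Opening
the wedge by the correction angle θ is a rigid rotation of the proximal
fragment about that axis.

Assumptions inherited from this idealisation: the cut is complete (no
posterior bony bridge), the hinge is exactly lateral (no posterolateral
obliquity), the fragments are rigid, and soft tissue plays no role. These are
the conditions under which the SPOI–slope relationship can be isolated; on an
anatomic tibia each violated assumption adds its own slope change on top of
the one modelled here.

### Coordinate frame and sign conventions

No standard frame exists for this construction, so the package fixes one:
right-handed, x = medial, y = anterior, z = superior. Then

* the slope line of the plateau is s = (0, cos α₀, sin α₀), rising anteriorly
  for positive slope;
* the true-lateral hinge axis for inclination φ is a = (0, cos φ, sin φ) —
  "true lateral" is exactly the statement that the axis has no x component;
* positive φ descends posteriorly, the same sign convention as the slope, so
  φ = α₀ is the cut parallel to the plateau;
* the fragment motion in `transform_point()` uses the rotation sign that
  elevates the medial side (the wedge opens medially). The measured slope is
  provably invariant to this sign — replacing θ by −θ flips only the
  medial–lateral component of the rotated slope line — so no observable
  quantity depends on it.

### What "the slope" is

The post-correction slope is measured as the **sagittal projection** of the
rotated slope line, atan(d_z/d_y), not the 3D elevation angle asin(d_z).
The two definitions differ once the rotated line acquires a medial–lateral
component (e.g. at φ = 0°, θ = 30° the projection gives 8.68° and the 3D
elevation 8.61°), and only the projection is consistent with slopes read off
lateral radiographs and with the reference grid the package reproduces. This
is also why `run_grid()` produces identical values from the closed form and
from the explicit 3D rotation.

### Closed form and its numerical evaluation

Rotating s about a by θ and projecting gives

α′(θ) = atan[(sin α₀ cos θ + sin φ cos(α₀−φ)(1−cos θ)) /
(cos α₀ cos θ + cos φ cos(α₀−φ)(1−cos θ))].

The implementation evaluates the equivalent regrouped form
sin α₀ + (1 − cos θ)·(sin φ cos(α₀−φ) − sin α₀) (and its cosine
counterpart). The regrouping matters for one reason: when φ = α₀ the two
bracketed increments are *identically* zero in floating point, the
θ-dependence vanishes bit-for-bit, and the function returns α₀ exactly — the
parallel-cut invariance is then an algebraic identity of the code, not an
approximation. Away from that case the form is numerically equivalent to the
textbook one (the backends agree to ~10⁻¹³ degrees; tests require 10⁻⁹).

A second-order expansion of the closed form gives
α′ − α₀ ≈ (θ²/4)·sin(2(φ − α₀)) (angles in radians): slope change is
*quadratic* in the correction angle with sign and magnitude set by φ − α₀.
The tests verify this limit numerically at θ = 0.1° and 0.05°.

The measured slope is independent of the column dimensions (50 × 50 × 100 mm
by default — the values only matter for mesh export and for the noise
baseline), and the default hinge height places the cut at mid-column, which
keeps the cut plane inside the column for every inclination on the grid.

### The planar endpoint model

The same conclusion follows from plane trigonometry. Each slope end-point P
rotates on a circle about its orthogonal projection H onto the hinge axis;
its height above the cut plane is κ = r·sin(θᵢ) before and
κ′ = r·sin(θᵢ + θ) after correction, where θᵢ is the angle of P with the
cut-plane trace in the plane perpendicular to the axis. If θ₁ = θ₂ for the
anterior and posterior end-points, both heights scale identically and the
slope is unchanged; the package verifies against the 3D geometry that
θ₁ = θ₂ holds exactly when φ = α₀ (and that r₁ = r₂ as well on the symmetric
column). The planar construction is taken perpendicular to the hinge axis
through each foot point — the only reading under which the rotation by θ is
planar.

## Emulating the bench experiment

The physical experiment digitizes two pre-drilled end-points (A anterior, B
posterior) on the rotated fragment, n = 10 times per condition, and
reconstructs the slope from the line B→A. The emulator places A and B at the
ends of the top-surface midline, depth 50 mm apart in projection, applies the
exact rigid motion, and adds a two-term noise model:

* **Point noise** `sigma_point` = 0.025 mm per coordinate. The digitizer's
  stated accuracy of ±0.05 mm is read as a ~2-standard-deviation bound of
  Gaussian error, a standard reading of an accuracy specification.
* **Mounting tilt** `sigma_mount` = 0.25° per replicate, applied as a small
  rotation of the measured assembly about the medial–lateral axis, i.e. a
  sagittal seating error of the specimen–jig stack that adds directly to the
  measured slope.

The second term is a modelling choice and deserves its justification. Point
noise alone over a 50 mm baseline perturbs the measured angle by
σ ≈ √2·0.025/50 rad ≈ 0.04°, and a per-replicate error in the *correction
angle* barely registers at all — by the quadratic small-angle law the slope's
sensitivity to θ is at most ~0.08°/° on this grid, so even a 0.25° error in
θ moves the slope by ~0.02°. Replicate scatter of the size this kind of
bench measurement actually shows (tenths of a degree) therefore cannot come
from either source; a seating tilt is the simplest mechanism of the right
size, and with σ = 0.25° the simulated per-cell SDs land in the observed
0.1–0.7° range. The decomposition is one consistent explanation, not a
measurement of the true error budget; the three sources (jig seating,
digitizer, machine angle) are not separable from summary tables.

Noise draws use substreams seeded deterministically from
(seed, SPOI, θ, replicate), so any single cell or replicate regenerates in
isolation and a sub-grid run reproduces the matching cells of a full run
exactly. The tilt is symmetric and enters the angle linearly, and the point
noise is symmetric, so replicate means are unbiased for the noise-free slope
(the tests bound the bias at 0.05° with 1000 replicates).

With both SDs set to zero the emulator collapses onto the virtual grid
bit-for-bit in the parallel column (see the regrouped closed form above) and
to ~10⁻¹³ degrees elsewhere.

What the generator does **not** emulate: printer tolerance and material
compliance, systematic jig bias (all errors are zero-mean), load control of
the correction machine, and the anatomic shape of the tibia. Passing tests
therefore show that the pipeline recovers the geometry under plausible
symmetric measurement error — not that a real bench series would match any
particular cell mean, which is a single physical realization.

## Statistical analysis

The replicate tables are analysed the way small non-normal bench series are:
a Shapiro–Wilk screen per cell (reported, never gating — n = 10 gives the
test little power either way, and a constant cell is degenerate and skipped),
then Kruskal–Wallis rank tests across both margins: across correction angles
5–30° within each SPOI (θ = 0° is the uncut state and is excluded), and
across the four SPOI groups within each correction angle. Raw p-values are
reported per margin without multiplicity adjustment, matching how such
tables are conventionally presented; p below 0.001 prints as "< 0.001".

The H statistic uses mid-ranks and the standard tie-correction divisor
1 − Σ(t³−t)/(N³−N); all-identical data return H = 0, p = 1 by convention
rather than an error (this is exactly the zero-noise parallel margin). The
default p-value is the chi-square upper tail with k − 1 degrees of freedom.
For small samples an exact option enumerates every assignment of the pooled
observations to groups of the observed sizes (capped at total n = 12, i.e.
≤ 9240 assignments).

How good is the chi-square approximation at the sizes used here? For three
balanced groups of three, every tie-free dataset reduces to one of 1680 rank
assignments, so the question has an exhaustive answer: in the
decision-relevant tail (exact p ≤ 0.25) the chi-square p stays within 0.05
of the exact p, while at moderate H the coarse lattice null lets the
discrepancy grow to ~0.1 (the worst case sits near H = 3.2, exact p 0.25 vs
chi-square 0.20). The acceptance suite asserts both facts, and separately
checks type-I calibration at the design actually used (four groups of ten):
the rejection rate at α = 0.05 over 2000 null simulations must lie in
0.05 ± 0.02.

## Validation problem sizes

The test and acceptance suites use: the full 7 × 4 virtual grid; 1000 random
(α₀, φ, θ) triples for three-way backend agreement at 10⁻⁹ degrees; 200
seeded repetitions of the full bench emulation (n = 10) for the rank-test
and scatter calibration — the per-SPOI test is significant in ≥ 90% of seeds
for SPOI 20°, 0°, −10° and non-significant in ≥ 70% for the parallel cut,
and per-cell SDs fall in [0.05°, 1.0°] in ≥ 95% of cells; and 2000 null
simulations for type-I calibration. Trend direction under noise is checked
as the sign of Kendall's τ between cell means and correction angle: with
adjacent true means 0.04–0.11° apart against a 0.11° standard error of a
mean difference, strict cell-by-cell monotonicity is not a property even of
a correctly calibrated emulator, but the direction of the whole sequence is.

## Mesh export

`fragment_meshes()` builds both fragments as 12-triangle hexahedra (every
face is planar by construction), rotates the proximal one about the hinge
line, and `write_stl()` emits binary millimetre STL. At θ = 0 the fragments
tile the intact column, so their volumes sum to width × depth × height
exactly; for θ > 0 the proximal fragment lies on or above the cut plane with
contact only along the hinge edge. Watertightness (every edge shared by
exactly two consistently oriented triangles) is asserted in the tests.

## Known limitations

* The square column isolates the SPOI effect; anatomic tibiae may show
  larger slope changes and the posterolateral-hinge case is parameterized
  (`hinge_axis_override`) but not studied.
* The noise decomposition is a plausible mechanism calibrated to a scatter
  range, not an identified error model.
* The exact Kruskal–Wallis option is limited to total n ≤ 12 by enumeration
  cost.
* Rounding for table display is half-away-from-zero at 0.1°; no grid value
  falls within 0.005° of a rounding boundary, so the tie rule is
  unobservable on the study grid.
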