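---
title: "Methods: volumetric mass reconstruction, muscle estimation and growth fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric mass reconstruction, muscle estimation and growth fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volumass)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices behind them, and what the synthetic
study system does and does not demonstrate.

## The reconstruction model

A specimen is modelled as eight body segments (head, neck, body/torso,
tail, forelimb, thigh, shank, foot; limb segments are bilateral pairs
mirrored across the median plane). Each segment is a stack of planar
cross-section *hoops* placed on skeletal boundary landmarks along a
segment axis. A hoop is either an ellipse (two semi-axes) or an octagon
(eight control radii ordered from dorsal, proceeding right-lateral in
45° steps); octagons are the working profile because eight radial
distances are what skeletal sections actually constrain. Hoops are
resampled to a common ring resolution and lofted by ruled (linear)
interpolation with triangle-fan end caps, which guarantees a watertight
mesh. Air spaces in the head, neck and torso are hoop stacks of their own
with density zero: they displace flesh mass but leave the external volume
untouched, so whole-body density falls below the 1000 kg m⁻³ flesh
density.

Working assumptions, stated explicitly:

* homogeneous flesh at 1000 kg m⁻³ everywhere outside explicit cavities
  (muscle is nearer 1060 kg m⁻³; the ~6% difference is deliberately not
  corrected in segment masses, only in the CFL validation arithmetic);
* linear lofting between sparse hoops — a conservative, reproducible
  reading of how flesh outlines bridge skeletal stations; no splines
  between stations, no skinning, no soft-tissue deformation;
* the frame is right-handed with +x cranial, +y dorsal, +z right-lateral
  and its origin at the right hip joint centre, so COMx > 0 is cranial of
  the hip and COMy < 0 ventral to it.

Mass properties come from exact signed-tetrahedron (divergence-theorem)
integration of the closed mesh — volume, first moment and the full
second-moment tensor — so there is no voxelisation error anywhere in the
pipeline; voxel counting appears only as an *independent oracle* in the
test suite. Composites combine by mass-weighted means and the
parallel-axis theorem. Zero-mass (cavity) parts contribute volume but are
excluded from COM weighting.

## The sensitivity family

Reconstruction uncertainty is bracketed by six rule-based variants of the
initial model. The rules are fixed, not tunable:

* **minimal**: torso hoops drop to the recorded bone-hugging radii
  ("tight to bone"); neck, tail and hindlimb segments scale radially
  ×0.80; every varied hoop is *diamondised* — its four diagonal radii
  ×0.853 — and airspaces are enlarged (radial ×1.2);
* **maximal**: all varied radii ×1.2, airspaces shrunk (radial ×0.8);
* **most cranial / caudal / dorsal / ventral**: per-segment mixtures of
  the maximal and minimal rules (e.g. most cranial = maximal neck+torso
  with minimal tail and hindlimbs) that intentionally bias the COM.

Head and forelimb are never varied: the head is well constrained by
anatomical landmarks and the forelimb is a negligible mass fraction.
Stations (hence lengths) are bit-identical across variants. Two facts
make the rules exactly testable: radial scaling by *f* multiplies any
lofted volume by exactly *f*², and diamondisation multiplies an
alternating-radius octagon's area by exactly the diagonal factor (the
shoelace sum is linear in the diagonal radii), so the minimal non-torso
volume factor is exactly 0.64 × 0.853.

Two points were genuinely open and are package decisions: (i)
diamondisation is applied to the tight-to-bone torso as well as the other
varied segments (switchable via `diamondize_torso`); (ii) "largest/
smallest airspaces" reuse the ×1.2/×0.8 radial factors and follow the
rule of their host segment, the least arbitrary symmetric treatment.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| flesh density | 1000 | kg m⁻³ | homogeneous-model convention |
| muscle density (validation) | 1060 | kg m⁻³ | vertebrate muscle |
| ring resolution `n_ring` | 64 | vertices | see below |
| radial factors min/max | 0.80 / 1.2 | – | fixed sensitivity rules |
| diamond factor | 0.853 | – | diamond-like cross-section |
| extensor coefficients | 0.54 / 0.34 / 0.47 | – | hip/knee/ankle shares of non-bone segment mass in extant Sauria |
| hatchling mass | 5 | kg | assumed mass at age 0 |
| growth asymptote `max_mass` | input, not fitted | kg | imposed apex (the largest specimen's minimal mass in the packaged fixture) |
| tendon radius fraction | 0.01 | of loop radius | "small, thin" insertion; reported separately |

**Ring resolution.** An inscribed ring polygon under-estimates a circular
section by a factor (n/2π)·sin(2π/n): 0.64% at n = 32 but 0.16% at
n = 64. The package default is 64 so that lofted cylinders and frusta
reproduce closed-form volumes well within 0.5% while octagonal profiles
remain *exact* (64 is a multiple of 8, so resampled vertices lie on the
octagon's vertices and edges). Loft volume error converges as O(n⁻²).

## CFL reconstruction

For each caudal vertebra between the sacrum and the tail's transition
point, a closed cross-section loop is drawn through the ordered landmark
ring — transverse-process lateral tip, lateral/ventrolateral arc points,
chevron ventral tip, then back along the chevron and centrum borders.
The "smooth curve" is realised as a periodic cubic spline in cumulative
chord-length parameter (not circular arcs: the reconstruction is
explicitly ellipse-like, not semicircular, and includes a small volume
just below the process tip via spline tangency there). The medial border
tracks the bone outline at a configurable pinch factor, leaving the
M. caudofemoralis brevis territory unfilled (brevis is out of scope).
Loops loft into a watertight solid; mass is volume × density and refers
to *one* muscle belly (set `bilateral = TRUE` for the pair). The tendon
to the fourth trochanter is a thin tube (default 1% of the terminal loop
radius) reported separately — it is deliberately negligible.

`transition_point` is the 1-based index of the first vertebra *excluded*
distally; loops cover vertebrae `1..(transition_point − 1)`.

Maximal-model CFL masses are not re-lofted: they scale the minimal CFL by
the maximal/minimal tail segment mass ratio, which is how the summary
tables define them. The packaged CFL table carries an erratum flag on the
Stan maximal cell (printed 22 kg, irreconcilable with its own recipe);
`load_fixture(8)` flags it and never silently corrects it, and the value
is excluded from acceptance checks.

**Extensor masses.** Bone mass is subtracted at the *model's* homogeneous
1000 kg m⁻³, not a realistic bone density — that is the only convention
consistent with the printed extensor percentages, and it is a convention,
not an anatomical claim.

## Growth fitting

The sigmoid `mass = max_mass/(1 + e^{a(age−b)}) + 5` is linear in
neither constant and, on five-point data sets, multimodal. The fit is
therefore a fixed multi-start grid (a ∈ [−2, −0.01], b ∈ [1, 30], 48×48
by default) followed by Levenberg–Marquardt refinement (Nelder–Mead
fallback); this is deterministic and its refined SS is non-increasing in
grid density. The printed formula's typeset grouping is ambiguous; it is
implemented as `1 + e^{a(age−b)}` because only that form makes *b* the
age at 50% of maximum mass. Growth requires a < 0; the slope is reported
both signed and as |a|. Peak growth rate is the closed form
|a|·max_mass/4 at age b.

The asymptote is an *input*: the packaged fixture imposes the apex
specimen's minimal mass (9502 kg), matching how the growth series is
assembled (per-specimen min/max averages, except the apex specimen where
the minimal estimate is used because of its inflated ribcage
reconstruction — and the same mass anchors the DME cube-law).

Confidence bands are pointwise delta-method bands from the (a, b)
covariance. Because the asymptote and hatchling offset are treated as
known, the band is widest around the steep growth phase and pinches
toward both ends — it does not widen monotonically into extrapolation,
and the implementation reports what the model actually implies.

**Ages.** Only the juvenile's age (12) and two alternatives for the MOR
specimen (14, 16) are printed in the source data; the remaining adult
ages ship in `growth_ages_external.csv` with a provenance column
(`external_histology` for the apex specimen, `external_assumed`
otherwise). Every result that depends on them — notably the absolute
peak growth rate — is conditional on that file and is exposed as an
optional check, not a gating test. The half-mass age bracket
(≈13.1–14.2 yr depending on the MOR age) and the strong single-curve
preference of the AICc/F comparison are the reproducible conclusions.

## The synthetic study system

`generate_skeleton(tyrannosaur_params())` builds an adult-sized
tyrannosaur-like body: femur 1.28 m, GAD 2.5 m, head–tail length
~11.8 m, a deep caudally-weighted barrel torso carrying roughly
three-fifths of the initial volume, 40 caudal vertebrae with the CFL
territory ending at vertebra 16, and torso/head/neck airspaces sized so
the minimal model's cavity fraction is ≈12.5% of external volume. Those
choices were made once, to sit inside the printed plausibility bands
(whole-body max/min mass ratio 1.8–2.0; minimal-model density
840–890 kg m⁻³ vs ≈970 for maximal), and are not revisited by any test.
A 3% per-station radial irregularity (seeded) roughens the profiles.

Two structural choices make the ground truth *analytic* rather than
approximate:

* bones are tessellated cylinders, so every bone volume is πr²L;
* flesh radii are separable (base octagon × per-station scale), which
  keeps every lofted side quad planar; slab areas are then quadratic and
  first moments cubic in the interpolation parameter, so Simpson's rule
  on shoelace areas/moments gives the *exact* volume and COM of the
  lofted solid by a route that never touches the tetrahedron
  accumulation. The test suite uses this as a machine-precision oracle.

The crocodile-like preset (long shallow tail, small process spans) places
its loop landmarks on exact tapering ellipses, so the muscle territory
volume is closed-form and a blind loop-loft reconstruction can be scored
against it; the packaged preset reconstructs it to well within the 5%
validation tolerance.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: vertebral sculpting and asymmetry,
fossil distortion and mounting errors, gastral-basket uncertainty,
investigator subjectivity in hoop placement, or specimen-specific scan
geometry. The package validates the *computational chain*; absolute
masses of real specimens from geometry require the (unavailable) scans,
which is why the acceptance surface combines printed-table arithmetic
with synthetic-geometry properties.

## Numerical choices and degenerate inputs

* Watertightness is checked by edge *index* matching (every directed edge
  once, every undirected edge exactly twice), not coordinate proximity:
  lofting always emits indexed closed meshes, and index matching cannot
  be fooled by coincident vertices.
* Faces with area < 1e−12 m² are dropped with a warning (loft caps can
  emit slivers when a profile radius tapers to ~0).
* Meshes with inward winding are rejected (negative signed volume), and
  lofts orient themselves by flipping all faces if needed — a tie-break
  that keeps every emitted solid positively oriented.
* Cavity containment is a *warning*, not an error, based on sampled ray
  casting of the cavity surface; extreme variants may legitimately pinch
  flesh near a cavity and the analyst should see the diagnostic rather
  than lose the run.
* The GAD metric is stored, not derived from the printed GAD/body-length
  ratio: the ratio is rounded to three figures and reconstructing GAD
  from it shifts GAD-normalised COM cells by up to ±0.3 percentage
  points; the tests document exactly that tolerance.
* Whole-body averages are arithmetic means of the minimal and maximal
  masses. One packaged average cell disagrees with its own min/max pair;
  it is flagged as an erratum in the fixture, and the computation always
  returns the true mean.

## Problem sizes used by the test suite

The suite builds one full-resolution synthetic body (9-hoop torso, ring
resolution 64, ~7 variants), five seeded random solids checked against a
24³-column voxel oracle, a 50-seed noisy growth recovery (σ = 200 kg,
n = 8) and a 200-replicate band-coverage simulation — sizes chosen so the
whole suite runs in seconds while every oracle stays statistically
meaningful.

## Known limitations

* Linear lofting between sparse hoops under-represents curvature between
  stations; the sensitivity family, not the loft, is the error model.
* Homogeneous density ignores regional variation (marrow, integument,
  gut contents); airspaces are the only density structure.
* The extensor coefficient method assumes extant-saurian muscle/segment
  proportions transfer to extinct taxa and deliberately over-assigns all
  non-bone volume to muscle, biasing estimates upward.
* Five-point growth series cannot distinguish subtle model families; the
  AICc/F machinery is honest about that (it prefers the common curve).
* The COM-extreme variants are bounding constructions, not samples from
  a calibrated error distribution; they do not yield statistically valid
  confidence intervals, and the package does not pretend otherwise.
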