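---
title: "Modeling B-DNA from smooth axis curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling B-DNA from smooth axis curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaforge)
```

## The modeling abstraction

dnaforge models a DNA double helix by its *helical axis*: a smooth space
curve threaded through the center of the duplex. Everything else — base-pair
placement, helical twist, the all-atom structure — is derived from that
curve. The abstraction targets mesoscale structural biology: laying out
plasmids, nucleoid fragments or protein-wrapped DNA at the resolution of one
base pair, where the global shape is the scientific question and fine
stereochemistry is delegated to downstream refinement (e.g. molecular
dynamics on the exported PDB).

The pipeline is a composition of four stages:

1. **Axis curve.** A piecewise quadratic/cubic Bézier curve, open or closed
   (`bezier_path()`), or an interpolating curve through coarse-grained bead
   positions (`interpolate_points()`).
2. **Uniform sampling.** Anchor points separated by equal *arc length*, the
   B-DNA rise of 3.4 Å (`uniform_sample()`).
3. **Rotation-minimizing frames.** An orthonormal frame at every anchor,
   transported so that rotation about the tangent is minimized
   (`rmf()`), which makes the unconstrained strand torsion-free at rest.
4. **Base pairs.** An idealized all-atom template per Watson–Crick pair,
   instantiated in each frame after rotation by the twist schedule:
   pair *i* is rotated by θ_i = (i − 1)·2π/10.4 + a_i about the tangent,
   where the a_i are user twist offsets (`twist_schedule()`, `build_dna()`).

## Curve machinery and numerical choices

**Parameterization.** The global parameter u ∈ [0, 1] is split uniformly
across segments; arc-length queries go through a per-segment cumulative
length table (composite 8-point Gauss–Legendre over 64 subintervals per
segment) inverted by monotone interpolation plus three Newton steps. On
smooth Bézier speed functions this reproduces arc lengths to ~1e-9 relative,
comfortably below the 1e-3 Å gap-uniformity the sampler guarantees.

**Tangents.** Bézier derivatives are evaluated analytically; where control
points coincide and the derivative vanishes, a symmetric finite difference
(step 1e-6 in u) is used, and a fully degenerate curve raises a geometry
error naming the segment. A well-defined tangent everywhere is a hard
requirement of the framing stage.

**Open vs. closed sampling.** On open curves the spacing is held exactly at
3.4 Å and a trailing remainder shorter than one rise is dropped — the rise is
a physical constant and should not be stretched to fit the curve. On closed
curves the spacing is adjusted to L/round(L/3.4) so the sampling closes
exactly; correspondingly the default twist pitch of a closed strand is
adjusted to N/round(N/10.4) base pairs per turn so the total twist is an
exact integer number of turns. A circle whose length is not a multiple of
the rise cannot close otherwise; the residual is spread invisibly over the
whole loop rather than concentrated at a seam.

**Adaptive sampling.** For display, the curve is approximated by a polyline
whose consecutive chords turn by at most a threshold angle (default 5°,
configurable). Subdivision is driven by tangent turning per parameter
interval, followed by a repair pass that bisects intervals adjacent to any
remaining offending vertex (including the seam of closed curves).

**Interpolation through beads.** Coarse-grained inputs (one point per
monomer, from worm-like-chain simulation or similar) become a centripetal
Catmull–Rom piecewise cubic: knot spacing proportional to the square root of
chord length, which avoids the cusps and loops uniform parameterization
produces on unevenly spaced beads. Endpoints of open runs use reflected
phantom points; closed runs wrap. The construction is affine-equivariant and
reproduces every input point exactly.

## Frames: why rotation-minimizing, and how

The Frenet frame is unusable here: it is undefined at inflections and twists
wildly with curvature. Instead the frame sequence is built by the
double-reflection method: each transport step reflects the frame through the
bisecting plane of the segment joining consecutive anchors, then reflects
again so the tangent lands on the new tangent. The composition is a rigid
motion that approximates the exact rotation-minimizing transport to high
order at the cost of a few dot products; against a 10× oversampled transport
oracle the accumulated twist error on helical test curves is below 0.1°
(the suite enforces 0.5°).

Two conventions are fixed for reproducibility:

- **Initialization.** The first normal is the projection of global +z onto
  the plane perpendicular to the first tangent (+x when the tangent is
  within 1e-6 of ±z). Deterministic initialization makes every model
  byte-reproducible. The price is that frames are defined in *global*
  coordinates: rotating the input curve rotates the swept shape but not
  necessarily the vertex-level frame phase, so only translations are exactly
  equivariant end to end.
- **Closed-curve seam.** The frames are left strictly rotation-minimizing;
  the angular mismatch between the transported last frame and the first
  frame is *reported* (`seam_deg` attribute), not redistributed. Base-pair
  closure is carried entirely by the adjusted pitch in the twist schedule.
  Planar closed curves have zero holonomy, so their seam mismatch is ~0;
  non-planar loops acquire a writhe-dependent mismatch that the user can
  inspect and, if desired, compensate with twist constraints. User offsets
  applied on a closed strand may reopen the seam; this is documented
  behavior, not prevented.

## Twist constraints

A constraint set is a sparse map from pair index to angular offset
(radians internally, degrees at the CLI). Offsets are interpolated linearly
in *index* between constrained pairs, and held constant before the first and
after the last constraint — so a single constraint re-phases the whole
strand rather than creating a kink. Setting offsets a_p = 0 and
a_q = −(q − p)·2π/10.4 exactly cancels the default twist accumulated between
pairs p and q, locally unwinding the duplex; the suite verifies the net
relative twist is zero to 1e-9. Unwinding can produce chemically strained
structures by design — the tool's role is to reach such intermediates, with
refinement left to MD.

## Base-pair templates

Four templates (AT, TA, CG, GC) are kept in memory and instantiated lazily,
so a model stores one frame, one angle and one pair identifier per base pair
(~140 bytes/bp measured) regardless of length; million-bp strands fit
comfortably in RAM and atoms are generated only during export or on request.

The template geometry is a documented *synthetic idealization* constructed
in code, not a crystallographic average: planar Watson–Crick base rings from
regular-polygon bond geometry (aromatic bond 1.38 Å), C1′–C1′ separation
10.6 Å at 154° azimuth, glycosidic bonds 1.48 Å at 54° to the C1′–C1′
chord, and a schematic cylindrical sugar-phosphate backbone laid out so the
O3′(i)–P(i+1) distance is ~1.6 Å at the canonical 34.6°/3.4 Å step. Atom and
residue naming follows PDB v3 (DA/DT/DC/DG). Consequences, accepted
knowingly: no sequence-dependent geometry (roll, slide, propeller), no
sugar pucker, and O3′–P stretches appear wherever curvature or unwinding
departs from the canonical step. The generic sequence is (ACTG)* on the
leading strand; an explicit sequence is accepted as an extension.

## PDB and mesh output

Chain A holds strand I 5′→3′ in pair order, chain B strand II 5′→3′ in
reverse pair order, residues 1..N on both, TER after each chain — the common
nucleic-acid convention, chosen so viewers and MD packages accept the files.
Coordinates are written at the format's 3-decimal column precision (round
trip ≤ 5e-4 Å); serials wrap modulo 100000 with a warning so indefinitely
long strands still export to a single file.

Simplified representations mirror the three display levels: the anchor
polyline; a helicoidal double ribbon (two strips phase-shifted by π whose
lateral direction follows the twist schedule, so the default ribbon turns
every 10.4 bp and constrained unwinding is visible geometrically); and swept
tubes for disordered linkers (regular polygon swept along RMF frames,
capped when open, welded into a torus when closed). Meshes are consistently
wound and export to Wavefront OBJ or VRML97 (`IndexedFaceSet`, per-vertex
colors in VRML only).

## LoD hierarchy and picking

A binary tree over the pair indices splits each range into equal halves
(left larger by one) and stops at ≤ 10 pairs per leaf; each node stores a
bounding sphere (centroid of its anchors, radius to the farthest anchor,
enlarged at internal nodes to also enclose the child spheres). Distance
classification (atomic within `near`, ribbon to `far`, line beyond;
defaults 500/5000 Å — display tuning, freely configurable) emits an internal
node early only when the nearest- and farthest-point distances of its sphere
fall in the same band, which provably gives every descendant leaf the same
class; the output is therefore *identical* to classifying each leaf by brute
force, which the suite checks on random viewpoints. Ray picking returns the
anchor within the hit radius nearest the ray origin, pruning subtrees whose
inflated spheres miss the ray; 500 random rays per run are compared against
a full linear scan.

## What the synthetic fixtures do and do not show

Test fixtures are generated in code: straight axes (exact arithmetic cases),
four-segment Bézier circles (planarity, closure), interpolated helices
(torsion accumulation), and smoothed random walks with ~70 Å waypoints
(generic smooth curves at the persistence-length scale of DNA). They
exercise every code path at realistic curvature, but they are smooth by
construction: conclusions about near-cusp curves, self-intersecting layouts
or atom-level clashes at severe curvature are out of scope — as is any claim
of chemical accuracy of the idealized templates.

Default problem sizes keep the full suite under a minute while covering the
scaling claims: ~1200-frame strands for hierarchy/oracle comparisons and a
~10⁵-bp build for the lazy-memory check; the same quantities are recomputed
by `scripts/acceptance.R` at the same sizes.

## Known limitations

- B-form parameters only (3.4 Å rise, 10.4 bp/turn defaults); A-/Z-form
  parameter sets would need their own templates and defaults.
- No nicks, mismatches, kinks or interbase stretches; the axis abstraction
  cannot express them.
- Frames are recomputed from scratch on any curve change; there is no
  incremental update (intentional: recomputation is fast and stateless).
- Rotation equivariance holds for the swept shapes but not the vertex-level
  frame phase (deterministic +z initialization, see above).
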