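# dnaforge

All-atom B-DNA models from smooth axis curves.

dnaforge is for structural and computational biologists who need DNA of
arbitrary length and shape — plasmid minicircles, nucleoid fragments,
protein-wrapped loops, backmapped coarse-grained trajectories — at the
resolution of one base pair, without hand-placing atoms. You describe the
*helical axis* as a space curve; dnaforge rebuilds the duplex around it and
exports it as PDB for viewers and molecular-dynamics refinement, or as light
geometric representations (polyline, double ribbon, tubes) for mesoscale
scenes.

## The model

The axis is a piecewise quadratic/cubic Bézier curve **C** (open or closed),
or an interpolating centripetal Catmull–Rom curve through coarse-grained
bead positions. From it:

- a **uniform sampling** S_u places base-pair anchors o_i at equal arc
  length, the B-DNA rise of 3.4 Å;
- a **rotation-minimizing frame sequence** F_u = {(o_i, t_i, n_i)} is
  transported along S_u by the double-reflection method, so the strand at
  rest carries no spurious torsion;
- each base pair is an idealized all-atom Watson–Crick template (AT, TA,
  CG, GC; generic sequence (ACTG)*) instantiated in frame f_i after rotation
  by the **twist schedule**

  θ_i = (i − 1) · 2π / 10.4 + a_i

  about the tangent t_i, i.e. the canonical 10.4 bp/turn helix plus user
  twist offsets a_i, interpolated linearly in index between constrained
  pairs (constant beyond the first/last constraint). Closed strands adjust
  spacing to L/round(L/3.4) and pitch to N/round(N/10.4) so sampling and
  twist both close exactly.

Models are lazy: ~140 bytes per base pair (frames + schedule + sequence;
four shared templates), so millions of base pairs fit in memory and atoms
are generated only at export. A binary bounding-sphere hierarchy over the
anchors (leaves ≤ 10 bp) drives level-of-detail classification
(atomic/ribbon/line by distance) and base-pair ray picking.

## Worked example

```r
library(dnaforge)

axis <- bezier_path(list(rbind(c(0,0,0), c(113,0,0), c(227,0,0), c(340,0,0))))
model <- build_dna(axis)
model
#> <dna_model> 101 bp, open, rise 3.4000 A, 10.4000 bp/turn, 4141 atoms (lazy)
```

A 340 Å axis holds 101 base pairs at the 3.4 Å rise; the 4141 atoms
(41 per pair here) exist only on demand:

```r
head(dna_atoms(model, 1:2)[, c("bp","strand","name","resname","x","y","z")], 3)
#>   bp strand name resname    x         y          z
#> 1  1      1    P      DA -1.9  8.790426 -1.3922667
#> 2  1      1  OP1      DA -2.2 10.074920 -2.1414904
#> 3  1      1  OP2      DA -2.8  8.224221 -2.5143967

export_pdb(model, "model.pdb")
#> ATOM      1  P    DA A   1      -1.900   8.790  -1.392  1.00  0.00           P
```

Chain A is strand I 5′→3′, chain B the antiparallel mate, residues 1..101
each. Local unwinding via twist constraints (angles in radians; degrees at
the CLI): pinning pair 20 and offsetting pair 50 by −30·2π/10.4 cancels the
helical twist between them —

```r
unwound <- build_dna(axis, constraints = list(index = c(20, 50),
                                              offset = c(0, -30 * 2 * pi / 10.4)))
unwound$schedule$angles[50] - unwound$schedule$angles[20]
#> [1] -6.7e-16   # net-untwisted span
```

A 50 Å-radius minicircle closes by pitch adjustment (92 bp at 10.22
bp/turn), and the hierarchy classifies and picks:

```r
mc <- build_dna(circ)   # closed bezier_path of four segments
mc
#> <dna_model> 92 bp, closed, rise 3.4153 A, 10.2222 bp/turn, 3772 atoms (lazy)
#>   frame seam mismatch 0.0000 deg (closure carried by the twist schedule)

h <- build_hierarchy(mc$frames)
classify_lod(h, c(2000, 0, 0), near = 500, far = 5000)
#>   lo hi representation
#> 1  1 92         ribbon
pick_base_pair(h, c(50, 500, 0), c(0, -1, 0), hit_radius = 3)
#> [1] 1
```

### Command line

```sh
exec/dnaforge build curve.yaml --out model.pdb --constraints twists.txt
exec/dnaforge from-points beads.xyz --out axis.yaml --build model.pdb
exec/dnaforge pick curve.yaml --ray 50,500,0,0,-1,0 --hit-radius 3
```

Curve files are YAML (`closed:` flag plus `segments:` as control-point
lists, Å); bead files are xyz text or PDB coordinates; constraint files are
`index angle_deg` lines. Exit codes: 0 success, 2 input error, 3 geometry
error.

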