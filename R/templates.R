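# Idealized base-pair templates (synthetic geometry, built in code).
#
# One all-atom template is kept for each of the four Watson-Crick pairs
# AT, TA, CG, GC, centered on the helix axis with the pair plane in local xy
# and the axis along local z. The geometry is an idealization constructed
# from regular-polygon ring geometry and canonical B-DNA dimensions
# (C1'-C1' separation 10.6 A at 154 deg azimuth, glycosidic bonds 1.48 A at
# 54 deg to the C1'-C1' chord, schematic cylindrical sugar-phosphate
# backbone). It reproduces the pair-level shape of B-DNA, not refined
# stereochemistry: the intended use is shape modeling, with chemical
# refinement delegated to downstream molecular-dynamics tools. Small
# O3'-P stretches between adjacent residues are expected and accepted.

.BOND_AROM <- 1.38   # aromatic ring bond, A
.BOND_CO   <- 1.22   # carbonyl C=O, A
.BOND_CN   <- 1.34   # exocyclic C-N, A
.BOND_CC   <- 1.50   # C-CH3, A
.RHO_C1    <- 5.44   # C1' radius from helix axis, A
.GLY_HALF  <- 77     # half the azimuthal C1'...C1' separation, deg
.BOND_GLY  <- 1.48   # glycosidic N-C1', A
.GLY_TILT  <- 54     # glycosidic bond angle to the C1'-C1' chord, deg

.rot2 <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# hexagon with vertices N1,C2,N3,C4,C5,C6; N1 at the origin, ring center at
# (a, 0); returns a named 6 x 2 matrix
.hexagon_ring <- function() {
  a <- .BOND_AROM
  ang <- deg2rad(c(180, 120, 60, 0, -60, -120))
  V <- cbind(a + a * cos(ang), a * sin(ang))
  rownames(V) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  V
}

# complete a regular n-gon given one edge (e1 -> e2) with the remaining
# vertices on the side away from `away_from`
.polygon_on_edge <- function(e1, e2, n, away_from) {
  s <- sqrt(sum((e2 - e1)^2))
  apo <- s / (2 * tan(pi / n))
  mid <- (e1 + e2) / 2
  u <- mid - away_from
  u <- u / sqrt(sum(u * u))
  ctr <- mid + apo * u
  th1 <- atan2(e1[2] - ctr[2], e1[1] - ctr[1])
  th2 <- atan2(e2[2] - ctr[2], e2[1] - ctr[1])
  dlt <- th2 - th1
  dlt <- atan2(sin(dlt), cos(dlt))  # wrap to (-pi, pi]: +- 2pi/n
  R <- s / (2 * sin(pi / n))
  k <- seq(2, n - 1)
  cbind(ctr[1] + R * cos(th1 + k * dlt), ctr[2] + R * sin(th1 + k * dlt))
}

# exocyclic substituent: extends the external bisector at ring vertex v
.exo <- function(v, nb1, nb2, len) {
  d <- v - (nb1 + nb2) / 2
  v + len * d / sqrt(sum(d * d))
}

# 2D atom layout of one base, aligned so the glycosidic nitrogen sits at the
# origin and the Watson-Crick edge direction is +x; returns named k x 2 matrix
.base2d <- function(base) {
  H <- .hexagon_ring()
  if (base %in% c("A", "G")) {
    pent <- .polygon_on_edge(H["C4", ], H["C5", ], 5L, away_from = c(.BOND_AROM, 0))
    rownames(pent) <- c("N7", "C8", "N9")
    V <- rbind(H, pent)
    if (base == "A") {
      V <- rbind(V, N6 = .exo(V["C6", ], V["N1", ], V["C5", ], .BOND_CN))
    } else {
      V <- rbind(V,
                 O6 = .exo(V["C6", ], V["N1", ], V["C5", ], .BOND_CO),
                 N2 = .exo(V["C2", ], V["N1", ], V["N3", ], .BOND_CN))
    }
    origin <- V["N9", ]
    wc <- V["N1", ]
  } else {
    V <- H
    V <- rbind(V, O2 = .exo(V["C2", ], V["N1", ], V["N3", ], .BOND_CO))
    if (base == "T") {
      V <- rbind(V,
                 O4 = .exo(V["C4", ], V["N3", ], V["C5", ], .BOND_CO),
                 C7 = .exo(V["C5", ], V["C4", ], V["C6", ], .BOND_CC))
    } else {
      V <- rbind(V, N4 = .exo(V["C4", ], V["N3", ], V["C5", ], .BOND_CN))
    }
    origin <- V["N1", ]
    wc <- V["N3", ]
  }
  V <- sweep(V, 2, origin)
  d <- wc - origin
  V %*% t(.rot2(-rad2deg(atan2(d[2], d[1]))))
}

# schematic sugar-phosphate backbone, cylindrical coordinates for strand I:
# (radius A, azimuth offset from the strand's C1' azimuth in deg, z A).
# O3' points toward the 3' neighbor (next pair up the helix for strand I).
.backbone_cyl <- rbind(
  P     = c(8.90, -22, -1.9),
  OP1   = c(10.30, -25, -2.2),
  OP2   = c(8.60, -30, -2.8),
  `O5'` = c(8.60, -16, -1.3),
  `C5'` = c(8.10, -11, -0.8),
  `C4'` = c(7.50,  -6, -0.2),
  `O4'` = c(6.20,  -6, -0.1),
  `C3'` = c(7.70,   0,  0.5),
  `O3'` = c(8.50,   6,  0.3),
  `C2'` = c(6.80,   3,  0.3)
)

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# all atoms of one nucleotide of the pair template; strand 1 is the leading
# strand (5'->3' with increasing pair index), strand 2 its antiparallel mate
.nucleotide_atoms <- function(base, strand) {
  sgn <- if (strand == 1L) 1 else -1
  phi_c1 <- sgn * (-.GLY_HALF)            # C1' azimuth, deg
  # backbone: strand II is the dyad image (rotation by pi about local x)
  bb <- .backbone_cyl
  phi <- deg2rad(if (strand == 1L) phi_c1 + bb[, 2] else phi_c1 - bb[, 2])
  bb_xyz <- cbind(bb[, 1] * cos(phi), bb[, 1] * sin(phi), sgn * bb[, 3])
  c1 <- .RHO_C1 * c(cos(deg2rad(phi_c1)), sin(deg2rad(phi_c1)), 0)
  # glycosidic nitrogen: 1.48 A from C1', tilted toward the helix axis;
  # strand I's C1' sits at -y, its partner's at +y (and vice versa)
  to_partner <- c(0, sgn)
  u2 <- .rot2(sgn * .GLY_TILT) %*% to_partner
  g <- c1 + .BOND_GLY * c(u2, 0)
  g_partner <- g * c(1, -1, 1)             # pair dyad: (x, y, z) -> (x, -y, -z)
  xhat <- normalize(g_partner - g)
  yhat <- sgn * cross3(c(0, 0, 1), xhat)
  B2 <- .base2d(base)
  base_xyz <- sweep(outer(B2[, 1], xhat) + outer(B2[, 2], yhat), 2, g, `+`)
  xyz <- rbind(bb_xyz, c1, base_xyz)
  nm <- c(rownames(.backbone_cyl), "C1'", rownames(B2))
  data.frame(name = nm,
             element = substr(gsub("[^A-Z]", "", nm), 1, 1),
             resname = paste0("D", base),
             strand = strand,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Idealized base-pair templates
#'
#' Returns the four all-atom Watson-Crick pair templates (AT, TA, CG, GC)
#' kept in memory and instantiated at every base-pair anchor. Each template
#' is expressed in the pair's local frame: origin on the helix axis, pair
#' plane approximately local xy, helix axis along local z. Geometry is an
#' idealized synthetic construction (see source comments); atom and residue
#' names follow PDB v3 nucleic-acid nomenclature (DA/DT/DC/DG).
#'
#' @return named list of four data frames with columns `name`, `element`,
#'   `resname`, `strand` (1 = leading strand, 2 = complementary strand),
#'   `x`, `y`, `z` (Angstrom).
#' @export
bp_templates <- function() {
  cache <- .dnaforge_env$templates
  if (!is.null(cache)) return(cache)
  mk <- function(b1) {
    b2 <- .COMPLEMENT[[b1]]
    rbind(.nucleotide_atoms(b1, 1L), .nucleotide_atoms(b2, 2L))
  }
  out <- list(AT = mk("A"), TA = mk("T"), CG = mk("C"), GC = mk("G"))
  .dnaforge_env$templates <- out
  out
}

.dnaforge_env <- new.env(parent = emptyenv())
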