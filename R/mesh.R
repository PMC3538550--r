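# Simplified strand representations as triangle meshes: axis polyline,
# helicoidal double ribbon, swept tubes for disordered linkers; export to
# Wavefront OBJ and VRML97.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix, Angstrom.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param colors optional n x 3 matrix of per-vertex RGB in \[0, 1\].
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, colors = NULL) {
  V <- as_xyz(vertices, "vertices")
  F <- as.matrix(triangles)
  storage.mode(F) <- "integer"
  if (ncol(F) != 3L) stop_input("triangles must have 3 columns")
  if (nrow(F) && (min(F) < 1L || max(F) > nrow(V))) stop_input("triangle index out of range")
  # drop degenerate (zero-area) triangles
  if (nrow(F)) {
    e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    area2 <- rowSums(cross3_rows(e1, e2)^2)
    F <- F[area2 > 1e-24, , drop = FALSE]
  }
  if (!is.null(colors)) {
    colors <- as_xyz(colors, "colors")
    if (nrow(colors) != nrow(V)) stop_input("colors must match vertex count")
  }
  structure(list(vertices = V, triangles = F, colors = colors), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$colors)) "" else ", per-vertex colors"))
  invisible(x)
}

#' Axis polyline representation
#'
#' The coarsest display model: the base-pair anchor points in order; for a
#' closed strand the first point is appended to close the loop.
#'
#' @param frames a `frame_sequence`.
#' @return an n x 3 (or (n+1) x 3 when closed) matrix of points.
#' @export
polyline_rep <- function(frames) {
  stopifnot(inherits(frames, "frame_sequence"))
  P <- frames$origins
  if (nrow(P) < 2L) stop_input("need at least 2 frames")
  if (frames$closed) rbind(P, P[1, ]) else P
}

#' Helicoidal double-ribbon mesh
#'
#' Intermediate display model: two flat ribbons, phase-shifted by pi, whose
#' lateral direction at pair `i` is the frame normal rotated by the schedule
#' angle about the tangent. With the default schedule the ribbon edges
#' complete one turn every `bp_per_turn` pairs, and local unwinding imposed
#' through twist constraints is directly visible in the ribbon.
#'
#' @param frames a `frame_sequence`.
#' @param schedule a `twist_schedule` of matching length.
#' @param width ribbon diameter, Angstrom (default 9); all vertices lie
#'   within `width / 2` of the axis.
#' @return a `triangle_mesh` with `2 * N * 2` vertices per ribbon pair.
#' @export
ribbon_mesh <- function(frames, schedule, width = 9) {
  stopifnot(inherits(frames, "frame_sequence"), inherits(schedule, "twist_schedule"))
  N <- nrow(frames$origins)
  if (N < 2L) stop_input("need at least 2 frames")
  if (length(schedule$angles) != N) stop_input("schedule length != frame count")
  r_in <- width / 6
  r_out <- width / 2
  verts <- matrix(0, 4L * N, 3)
  for (ribbon in 0:1) {
    th <- schedule$angles + ribbon * pi
    u <- frames$n * cos(th) + frames$b * sin(th)
    off <- ribbon * 2L * N
    verts[off + seq_len(N), ] <- frames$origins + r_in * u
    verts[off + N + seq_len(N), ] <- frames$origins + r_out * u
  }
  tri <- list()
  steps <- if (frames$closed) seq_len(N) else seq_len(N - 1L)
  for (ribbon in 0:1) {
    off <- ribbon * 2L * N
    for (i in steps) {
      j <- if (i == N) 1L else i + 1L
      a <- off + i; b <- off + j; c <- off + N + i; d <- off + N + j
      tri[[length(tri) + 1L]] <- rbind(c(a, b, d), c(a, d, c))
    }
  }
  triangle_mesh(verts, do.call(rbind, tri))
}

#' Swept-tube mesh along an axis curve
#'
#' Sweeps a regular polygon along rotation-minimizing frames sampled at
#' `ring_spacing`; disordered protein linkers are modeled this way as
#' fixed-radius tubes. Open tubes are capped with apex fans; closed paths
#' weld the last ring to the first.
#'
#' @param path a `bezier_path`.
#' @param radius tube radius, Angstrom.
#' @param ring_spacing arc-length distance between rings (default 3.4).
#' @param sides polygon sides per ring (default 12, minimum 3).
#' @return a `triangle_mesh`.
#' @export
tube_mesh <- function(path, radius, ring_spacing = 3.4, sides = 12L) {
  stopifnot(inherits(path, "bezier_path"))
  if (!is.finite(radius) || radius <= 0) stop_input("radius must be > 0")
  sides <- as.integer(sides)
  if (sides < 3L) stop_input("sides must be >= 3")
  fr <- rmf(uniform_sample(path, spacing = ring_spacing))
  n <- nrow(fr$origins)
  phi <- 2 * pi * (seq_len(sides) - 1) / sides
  verts <- matrix(0, n * sides, 3)
  for (i in seq_len(n)) {
    ring <- radius * (outer(cos(phi), fr$n[i, ]) + outer(sin(phi), fr$b[i, ]))
    verts[(i - 1L) * sides + seq_len(sides), ] <- sweep(ring, 2, fr$origins[i, ], `+`)
  }
  quad <- function(i, j) {
    # triangles between ring i and ring j, outward winding
    a <- (i - 1L) * sides + seq_len(sides)
    a2 <- (i - 1L) * sides + c(seq_len(sides)[-1L], 1L)
    b <- (j - 1L) * sides + seq_len(sides)
    b2 <- (j - 1L) * sides + c(seq_len(sides)[-1L], 1L)
    rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }
  tri <- do.call(rbind, lapply(seq_len(n - 1L), function(i) quad(i, i + 1L)))
  if (fr$closed) {
    tri <- rbind(tri, quad(n, 1L))
  } else {
    # cap apexes at the end-ring centers
    verts <- rbind(verts, fr$origins[1, ], fr$origins[n, ])
    apex1 <- nrow(verts) - 1L
    apex2 <- nrow(verts)
    r1 <- seq_len(sides)
    r1n <- c(seq_len(sides)[-1L], 1L)
    rn <- (n - 1L) * sides + seq_len(sides)
    rnn <- (n - 1L) * sides + c(seq_len(sides)[-1L], 1L)
    tri <- rbind(tri,
                 cbind(r1n, r1, apex1),    # start cap faces backwards
                 cbind(rn, rnn, apex2))    # end cap faces forwards
  }
  triangle_mesh(verts, tri)
}

#' Export a triangle mesh as OBJ or VRML97
#'
#' OBJ writes `v`/`f` records (per-vertex colors, if present, are dropped
#' with a warning). VRML97 writes a `Shape` with an `IndexedFaceSet` and a
#' per-vertex `Color` node when colors are present.
#'
#' @param mesh a `triangle_mesh`.
#' @param file output path.
#' @param format `"obj"` or `"vrml"`.
#' @return `file`, invisibly.
#' @export
export_mesh <- function(mesh, file, format = c("obj", "vrml")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  V <- mesh$vertices; F <- mesh$triangles
  if (format == "obj") {
    if (!is.null(mesh$colors)) warning("OBJ export drops per-vertex colors")
    lines <- c(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]),
               sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]))
    writeLines(lines, file)
  } else {
    pts <- paste(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), collapse = ", ")
    idx <- paste(sprintf("%d, %d, %d, -1", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
                 collapse = ", ")
    body <- c("#VRML V2.0 utf8",
              "Shape {",
              "  geometry IndexedFaceSet {",
              paste0("    coord Coordinate { point [ ", pts, " ] }"),
              paste0("    coordIndex [ ", idx, " ]"))
    if (!is.null(mesh$colors)) {
      cl <- paste(sprintf("%.4f %.4f %.4f", mesh$colors[, 1], mesh$colors[, 2],
                          mesh$colors[, 3]), collapse = ", ")
      body <- c(body,
                "    colorPerVertex TRUE",
                paste0("    color Color { color [ ", cl, " ] }"))
    }
    body <- c(body, "  }", "}")
    writeLines(body, file)
  }
  invisible(file)
}

#' Read a Wavefront OBJ mesh
#'
#' Minimal importer (`v` and triangular `f` records) used for round-trip
#' verification of exports.
#'
#' @param file path to an OBJ file.
#' @return a `triangle_mesh`.
#' @export
read_obj <- function(file) {
  if (!file.exists(file)) stop_input("OBJ file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  vs <- lines[startsWith(lines, "v ")]
  fs <- lines[startsWith(lines, "f ")]
  if (!length(vs)) stop_input("no vertices in ", file)
  V <- do.call(rbind, lapply(strsplit(vs, "[[:space:]]+"), function(t) as.numeric(t[2:4])))
  F <- do.call(rbind, lapply(strsplit(fs, "[[:space:]]+"), function(t) {
    as.integer(sub("/.*", "", t[2:4]))
  }))
  triangle_mesh(V, F)
}
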