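# All-atom DNA assembly: per-base-pair twist schedule (default B-DNA helix
# plus interpolated user constraints), generic sequence assignment, and lazy
# instantiation of base-pair templates in the frame sequence.

#' Per-base-pair twist schedule
#'
#' The total rotation of pair `i` about its tangent is a default helical term
#' plus a user offset. The default term advances by `2*pi / bp_per_turn` per
#' pair (10.4 bp/turn for B-DNA); for closed strands the pitch is adjusted to
#' `N / round(N / bp_per_turn)` base pairs per turn so the total default
#' twist is an exact integer number of turns and the helix closes seamlessly.
#' User offsets given at selected pairs are interpolated linearly in pair
#' index between constrained pairs and extrapolated as constants before the
#' first and after the last constraint.
#'
#' @param N number of base pairs.
#' @param constraints `NULL`, or a data frame / list with fields `index`
#'   (1-based pair indices, strictly increasing) and `offset` (radians).
#' @param bp_per_turn base pairs per full helical turn (default 10.4).
#' @param closed logical; closed (circular) strand?
#' @return an object of class `twist_schedule`: `angles` (total rotation per
#'   pair, radians), `offsets`, `default`, `bp_per_turn`,
#'   `bp_per_turn_effective`, `closed`.
#' @export
twist_schedule <- function(N, constraints = NULL, bp_per_turn = 10.4, closed = FALSE) {
  N <- as.integer(N)
  if (N < 1L) stop_input("N must be >= 1")
  if (!is.finite(bp_per_turn) || bp_per_turn <= 0) stop_input("bp_per_turn must be > 0")
  offsets <- rep(0, N)
  if (!is.null(constraints) && length(constraints$index)) {
    idx <- as.integer(constraints$index)
    a <- as.numeric(constraints$offset)
    if (length(idx) != length(a)) stop_input("constraints: index and offset lengths differ")
    if (any(idx < 1L | idx > N)) {
      stop_input("twist constraint index out of range [1, ", N, "]: ",
                 paste(idx[idx < 1L | idx > N], collapse = ", "))
    }
    if (is.unsorted(idx, strictly = TRUE)) stop_input("twist constraint indices must be strictly increasing")
    # constant extrapolation outside the constrained range
    xs <- idx; ys <- a
    if (xs[1] > 1L) { xs <- c(1L, xs); ys <- c(a[1], ys) }
    k <- length(idx)
    if (idx[k] < N) { xs <- c(xs, N); ys <- c(ys, a[k]) }
    offsets <- if (length(xs) == 1L) rep(ys, N) else stats::approx(xs, ys, xout = seq_len(N))$y
  }
  bpt_eff <- if (closed) N / max(1, round(N / bp_per_turn)) else bp_per_turn
  dflt <- (seq_len(N) - 1) * 2 * pi / bpt_eff
  structure(list(angles = dflt + offsets, offsets = offsets, default = dflt,
                 bp_per_turn = bp_per_turn, bp_per_turn_effective = bpt_eff,
                 closed = closed),
            class = "twist_schedule")
}

#' Read twist constraints from a text file
#'
#' Plain text, one constraint per line: `index angle_deg`. Angles are
#' converted to radians internally.
#'
#' @param file path to the constraint file.
#' @return a data frame with columns `index` and `offset` (radians).
#' @export
read_twist_constraints <- function(file) {
  if (!file.exists(file)) stop_input("constraint file not found: ", file)
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(data.frame(index = integer(0), offset = numeric(0)))
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad)) stop_input("constraint file ", file, ": expected 'index angle_deg' on line ", bad[1])
  idx <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  deg <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(idx) || anyNA(deg)) stop_input("constraint file ", file, ": non-numeric entry")
  data.frame(index = idx, offset = deg2rad(deg))
}

#' Assign a base-pair sequence
#'
#' With no explicit sequence the generic repeating pattern (ACTG)* is used
#' for the leading strand; an explicit sequence (characters ACGT, length `N`)
#' is accepted as an extension. The pair identifier is the leading base plus
#' its Watson-Crick complement.
#'
#' @param N number of base pairs.
#' @param sequence optional character scalar of length-`N` leading-strand
#'   bases.
#' @return character vector of pair identifiers (`"AT"`, `"TA"`, `"CG"`,
#'   `"GC"`), length `N`.
#' @export
assign_sequence <- function(N, sequence = NULL) {
  N <- as.integer(N)
  if (N < 1L) stop_input("N must be >= 1")
  if (is.null(sequence)) {
    lead <- rep_len(c("A", "C", "T", "G"), N)
  } else {
    lead <- strsplit(toupper(sequence), "")[[1]]
    if (length(lead) != N) stop_input("sequence length ", length(lead), " != N = ", N)
    if (!all(lead %in% names(.COMPLEMENT))) stop_input("sequence may only contain A, C, G, T")
  }
  paste0(lead, .COMPLEMENT[lead])
}

#' Build an all-atom DNA model over an axis curve
#'
#' Composes the pipeline: uniform arc-length sampling at the base-pair rise,
#' rotation-minimizing frames, twist schedule, and sequence assignment.
#' Atom coordinates are not materialized: the model stores one frame, one
#' angle and one pair identifier per base pair plus the four shared
#' templates, so memory stays proportional to the number of base pairs and
#' strands of millions of pairs fit in RAM. Use [dna_atoms()] or
#' [export_pdb()] to instantiate coordinates.
#'
#' @param path a `bezier_path` for the helical axis.
#' @param constraints optional twist constraints (see [twist_schedule()]).
#' @param spacing base-pair rise, Angstrom (default 3.4).
#' @param bp_per_turn base pairs per helical turn (default 10.4).
#' @param sequence optional explicit leading-strand sequence.
#' @param closed logical; defaults to the path's own flag.
#' @return an object of class `dna_model`.
#' @export
build_dna <- function(path, constraints = NULL, spacing = 3.4, bp_per_turn = 10.4,
                      sequence = NULL, closed = path$closed) {
  stopifnot(inherits(path, "bezier_path"))
  sampling <- uniform_sample(path, spacing = spacing)
  frames <- rmf(sampling, closed = closed)
  N <- nrow(frames$origins)
  schedule <- twist_schedule(N, constraints = constraints,
                             bp_per_turn = bp_per_turn, closed = closed)
  pairs <- assign_sequence(N, sequence = sequence)
  structure(list(frames = frames, schedule = schedule, pairs = pairs,
                 closed = closed, spacing = sampling$spacing,
                 n_bp = N),
            class = "dna_model")
}

#' @export
print.dna_model <- function(x, ...) {
  tpl <- bp_templates()
  natoms <- sum(vapply(x$pairs, function(p) nrow(tpl[[p]]), 0L))
  cat(sprintf("<dna_model> %d bp, %s, rise %.4f A, %.4f bp/turn, %d atoms (lazy)\n",
              x$n_bp, if (x$closed) "closed" else "open", x$spacing,
              x$schedule$bp_per_turn_effective, natoms))
  if (x$closed && is.finite(attr(x$frames, "seam_deg"))) {
    cat(sprintf("  frame seam mismatch %.4f deg (closure carried by the twist schedule)\n",
                attr(x$frames, "seam_deg")))
  }
  invisible(x)
}

#' Instantiate a base-pair template in a frame
#'
#' The template's local coordinates are rotated by `theta` about the local z
#' axis (the helix axis), then mapped by the frame's rigid local-to-global
#' transform: local x to the normal, local y to the binormal, local z to the
#' tangent, origin to the frame origin.
#'
#' @param template one of the [bp_templates()] data frames.
#' @param frame a frame list with `o`, `t`, `n`, `b` (see [frame_at()]).
#' @param theta rotation about the tangent, radians.
#' @return the template data frame with `x`, `y`, `z` replaced by global
#'   coordinates.
#' @export
instantiate_base_pair <- function(template, frame, theta = 0) {
  M <- cbind(frame$n, frame$b, frame$t)
  ct <- cos(theta); st <- sin(theta)
  Rz <- matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
  R <- M %*% Rz
  xyz <- as.matrix(template[, c("x", "y", "z")]) %*% t(R)
  out <- template
  out$x <- xyz[, 1] + frame$o[1]
  out$y <- xyz[, 2] + frame$o[2]
  out$z <- xyz[, 3] + frame$o[3]
  out
}

#' Materialize atom coordinates for selected base pairs
#'
#' @param model a `dna_model`.
#' @param indices base-pair indices to instantiate (default all).
#' @return a data frame of atoms with a leading `bp` column.
#' @export
dna_atoms <- function(model, indices = seq_len(model$n_bp)) {
  stopifnot(inherits(model, "dna_model"))
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > model$n_bp)) stop_input("base-pair index out of range")
  tpl <- bp_templates()
  out <- vector("list", length(indices))
  for (j in seq_along(indices)) {
    i <- indices[j]
    at <- instantiate_base_pair(tpl[[model$pairs[i]]], frame_at(model$frames, i),
                                model$schedule$angles[i])
    at <- cbind(bp = i, at)
    out[[j]] <- at
  }
  do.call(rbind, out)
}
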