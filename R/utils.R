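# Internal helpers shared across modules.

# Error signalling: input errors (bad arguments, unreadable files) and
# geometry errors (degenerate curves/frames) carry distinct condition classes
# so the CLI can map them to exit codes 2 and 3.
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("dnaforge_input_error", "error", "condition")))
}

stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("dnaforge_geometry_error", "error", "condition")))
}

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop_geometry("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of two n x 3 matrices
cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# coerce to an n x 3 numeric matrix of finite coordinates
as_xyz <- function(x, what = "points") {
  m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  storage.mode(m) <- "double"
  if (ncol(m) != 3L) stop_input(what, " must have 3 columns (x, y, z)")
  if (!all(is.finite(m))) stop_input(what, " contain non-finite coordinates")
  dimnames(m) <- NULL
  m
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# angle between two vectors, radians, robust near 0 and pi
vec_angle <- function(a, b) {
  atan2(vnorm(cross3(a, b)), sum(a * b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
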