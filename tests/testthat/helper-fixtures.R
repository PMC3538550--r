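# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; random ones take an explicit seed.

# closed near-circle of radius r from four cubic segments with the standard
# circle-approximation control offset k = 4/3 * tan(pi/8)
fixture_circle <- function(r = 50, plane = c("xz", "xy")) {
  plane <- match.arg(plane)
  k <- 0.5522847498307936 * r
  m2 <- function(a, b) if (plane == "xz") cbind(a, 0, b) else cbind(a, b, 0)
  segs <- list(m2(c(r, r, k, 0), c(0, k, r, r)),
               m2(c(0, -k, -r, -r), c(r, r, k, 0)),
               m2(c(-r, -r, -k, 0), c(0, -k, -r, -r)),
               m2(c(0, k, r, r), c(-r, -r, -k, 0)))
  bezier_path(segs, closed = TRUE)
}

fixture_straight <- function(len = 30) {
  bezier_path(list(rbind(c(0, 0, 0), c(len / 3, 0, 0),
                         c(2 * len / 3, 0, 0), c(len, 0, 0))))
}

fixture_helix_points <- function(radius = 10, pitch = 34, turns = 5, per_turn = 24) {
  th <- seq(0, 2 * pi * turns, length.out = turns * per_turn + 1)
  cbind(radius * cos(th), radius * sin(th), pitch * th / (2 * pi))
}

fixture_helix <- function(...) interpolate_points(fixture_helix_points(...))

# smooth random space curve through jittered waypoints, ~70 A apart
fixture_random_smooth <- function(n_points = 20, step = 70, seed = 42) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * n_points), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # correlate consecutive directions to keep the curve smooth
  for (i in 2:n_points) dirs[i, ] <- dirs[i, ] + 2.5 * dirs[i - 1, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- apply(dirs * step, 2, cumsum)
  interpolate_points(pts)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * outer(a, a)
}

# chord-sum arc length between two global parameters (dense polyline oracle)
oracle_arclen <- function(path, u1 = 0, u2 = 1, n = 1e5) {
  uu <- seq(u1, u2, length.out = n)
  sum(sqrt(rowSums(diff(eval_point(path, uu))^2)))
}

# independently coded double-reflection transport of a normal vector
oracle_transport_normal <- function(P, Tg, n0) {
  nn <- n0
  for (i in 2:nrow(P)) {
    v1 <- P[i, ] - P[i - 1, ]; c1 <- sum(v1 * v1)
    tl <- Tg[i - 1, ] - 2 * sum(v1 * Tg[i - 1, ]) / c1 * v1
    nl <- nn - 2 * sum(v1 * nn) / c1 * v1
    v2 <- Tg[i, ] - tl; c2 <- sum(v2 * v2)
    nn <- if (c2 < 1e-24) nl else nl - 2 * sum(v2 * nl) / c2 * v2
    nn <- nn / sqrt(sum(nn * nn))
  }
  nn
}

# signed angle from a to b about unit axis t
signed_angle <- function(a, b, t) {
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  atan2(sum(cr * t), sum(a * b))
}

# brute-force picking over every frame origin (no hierarchy)
oracle_pick <- function(origins, ray_o, ray_d, hit_radius) {
  d <- ray_d / sqrt(sum(ray_d^2))
  best_depth <- Inf; best <- NA_integer_
  for (i in seq_len(nrow(origins))) {
    w <- origins[i, ] - ray_o
    along <- sum(w * d)
    dist <- if (along <= 0) sqrt(sum(w * w)) else sqrt(max(0, sum(w * w) - along^2))
    depth <- sqrt(sum(w * w))
    if (dist <= hit_radius && depth < best_depth - 1e-12) {
      best_depth <- depth; best <- i
    }
  }
  best
}

# brute-force LoD class of every hierarchy leaf
oracle_classify <- function(hierarchy, viewpoint, near, far) {
  leaves <- list()
  walk <- function(nd) {
    if (nd$leaf) { leaves[[length(leaves) + 1L]] <<- nd; return(invisible()) }
    walk(nd$left); walk(nd$right)
  }
  walk(hierarchy$root)
  do.call(rbind, lapply(leaves, function(nd) {
    dmin <- max(0, sqrt(sum((viewpoint - nd$center)^2)) - nd$radius)
    data.frame(lo = nd$lo, hi = nd$hi,
               representation = if (dmin > far) "line" else if (dmin > near) "ribbon" else "atomic",
               stringsAsFactors = FALSE)
  }))
}

# expand a classify_lod result to one class per frame index
expand_classes <- function(cls, n) {
  out <- character(n)
  for (i in seq_len(nrow(cls))) out[cls$lo[i]:cls$hi[i]] <- cls$representation[i]
  out
}

all_leaves <- function(hierarchy) {
  leaves <- list()
  walk <- function(nd) {
    if (nd$leaf) { leaves[[length(leaves) + 1L]] <<- nd; return(invisible()) }
    walk(nd$left); walk(nd$right)
  }
  walk(hierarchy$root)
  leaves
}

rad2deg_test <- function(x) x * 180 / pi
deg2rad_test <- function(x) x * pi / 180
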