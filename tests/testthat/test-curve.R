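# Axis-curve module: evaluation, arc length, adaptive/uniform sampling,
# interpolation through bead positions.

test_that("point evaluation matches closed forms and endpoint interpolation", {
  straight <- fixture_straight(30)
  expect_equal(eval_point(straight, 0.5), c(15, 0, 0))
  expect_equal(eval_point(straight, 0), c(0, 0, 0))
  expect_equal(eval_point(straight, 1), c(30, 0, 0))

  quad <- bezier_path(list(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))))
  expect_equal(eval_point(quad, 0.5), c(1, 0.5, 0))  # (P0 + 2 P1 + P2) / 4

  multi <- fixture_helix(turns = 1)
  expect_equal(eval_point(multi, 0), multi$segments[[1]][1, ])
  last <- multi$segments[[length(multi$segments)]]
  expect_equal(eval_point(multi, 1), last[nrow(last), ])

  expect_error(eval_point(straight, 1.5), class = "dnaforge_input_error")
  expect_error(eval_point(straight, -0.1), class = "dnaforge_input_error")
})

test_that("tangent evaluation: direction, endpoint derivative, degeneracy", {
  straight <- fixture_straight(30)
  for (u in c(0, 0.3, 0.77, 1)) expect_equal(eval_tangent(straight, u), c(1, 0, 0))

  quad <- bezier_path(list(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))))
  expect_equal(eval_tangent(quad, 0.5), c(1, 0, 0))

  P <- rbind(c(0, 0, 0), c(1, 2, 0), c(3, 1, 5), c(4, 4, 4))
  cub <- bezier_path(list(P))
  expect_equal(eval_tangent(cub, 1), (P[4, ] - P[3, ]) / sqrt(sum((P[4, ] - P[3, ])^2)))

  # coincident leading control points: finite-difference fallback still works
  deg <- bezier_path(list(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))))
  expect_equal(eval_tangent(deg, 0), c(1, 0, 0), tolerance = 1e-6)

  # fully degenerate curve has no tangent anywhere
  zero <- bezier_path(list(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))))
  expect_error(eval_tangent(zero, 0.5), class = "dnaforge_geometry_error")
})

test_that("arc length agrees with a dense chord-sum oracle", {
  expect_equal(arc_length(fixture_straight(30)), 30, tolerance = 1e-9)

  # quarter circle approximated by one cubic with the standard control offset
  r <- 10; k <- 0.5522847498307936 * r
  quarter <- bezier_path(list(rbind(c(r, 0, 0), c(r, k, 0), c(k, r, 0), c(0, r, 0))))
  expect_equal(arc_length(quarter), oracle_arclen(quarter), tolerance = 1e-4)

  helix <- fixture_helix(turns = 2)
  expect_equal(arc_length(helix), oracle_arclen(helix), tolerance = 1e-4)

  zero <- bezier_path(list(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))))
  expect_equal(arc_length(zero), 0)
})

test_that("adaptive sampling respects the turn-angle threshold", {
  expect_equal(nrow(adaptive_sample(fixture_straight(30))$points), 2L)

  circ <- fixture_circle(50)
  ad <- adaptive_sample(circ, max_turn_deg = 5)
  ang <- rad2deg_test(max(dnaforge:::.chord_angles(ad$points, TRUE)))
  expect_lte(ang, 5 + 1e-9)
  # emitted points lie exactly on the curve
  expect_equal(ad$points, eval_point(circ, ad$params), tolerance = 1e-12)

  # refinement monotonicity: halving the threshold never decreases the count
  n5 <- nrow(adaptive_sample(circ, 5)$points)
  n25 <- nrow(adaptive_sample(circ, 2.5)$points)
  expect_gte(n25, n5)

  helix <- fixture_helix(turns = 2)
  ad2 <- adaptive_sample(helix, max_turn_deg = 3)
  expect_lte(max(dnaforge:::.chord_angles(ad2$points, FALSE)), deg2rad_test(3) + 1e-9)
})

test_that("uniform sampling places anchors at the base-pair rise", {
  us <- uniform_sample(fixture_straight(34), 3.4)
  expect_equal(nrow(us$points), 11L)
  expect_equal(us$points[, 1], seq(0, 34, by = 3.4), tolerance = 1e-9)

  # arc-length gaps on curved fixtures, checked against the chord-sum oracle
  for (fix in list(fixture_helix(turns = 3), fixture_random_smooth(seed = 7))) {
    us <- uniform_sample(fix)
    gaps <- vapply(seq_len(min(25, nrow(us$points) - 1L)), function(i) {
      oracle_arclen(fix, us$params[i], us$params[i + 1], n = 4000)
    }, numeric(1))
    expect_lt(max(abs(gaps - 3.4)), 1e-3)
    expect_lt(stats::sd(gaps), 1e-3)
  }

  expect_error(uniform_sample(fixture_straight(2)), class = "dnaforge_geometry_error")
})

test_that("closed-curve sampling adjusts spacing to close exactly", {
  r <- 100 / (2 * pi)  # circumference ~100 A
  circ <- fixture_circle(r)
  L <- arc_length(circ)
  us <- uniform_sample(circ)
  expect_equal(nrow(us$points), round(L / 3.4))
  expect_equal(us$spacing, L / round(L / 3.4), tolerance = 1e-12)
  # closure: the wrap gap equals the spacing like every interior gap
  n <- nrow(us$points)
  wrap <- oracle_arclen(circ, us$params[n], 1, n = 4000)
  expect_lt(abs(wrap - us$spacing), 1e-3)
})

test_that("interpolation passes through every bead and is rigid-equivariant", {
  set.seed(11)
  pts <- matrix(cumsum(rnorm(30, sd = 4)), 10, 3)
  ip <- interpolate_points(pts)
  expect_equal(eval_point(ip, (0:9) / 9), pts, tolerance = 1e-9)

  two <- interpolate_points(rbind(c(0, 0, 0), c(5, 5, 0)))
  mid <- eval_point(two, 0.5)
  expect_equal(mid, c(2.5, 2.5, 0), tolerance = 1e-9)

  # collinear inputs stay collinear (affine invariance)
  tt <- 0:9
  col <- interpolate_points(cbind(tt, 2 * tt, -tt))
  smp <- eval_point(col, seq(0, 1, length.out = 50))
  dir <- c(1, 2, -1) / sqrt(6)
  off <- smp - (smp %*% dir) %*% t(dir)
  expect_lt(max(abs(off)), 1e-9)

  # rotation + translation equivariance
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  tr <- c(5, -2, 7)
  ip2 <- interpolate_points(sweep(pts %*% t(R), 2, tr, `+`))
  uu <- seq(0, 1, length.out = 33)
  expect_equal(eval_point(ip2, uu),
               sweep(eval_point(ip, uu) %*% t(R), 2, tr, `+`),
               tolerance = 1e-9)

  expect_error(interpolate_points(rbind(c(0, 0, 0))), class = "dnaforge_input_error")
  expect_error(interpolate_points(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               class = "dnaforge_input_error")

  # closed interpolation joins smoothly through the seam
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- interpolate_points(cbind(20 * cos(th), 20 * sin(th), 0), closed = TRUE)
  expect_true(ring$closed)
  expect_equal(eval_point(ring, 0), c(20, 0, 0), tolerance = 1e-9)
})

test_that("curve files round-trip through read_curve/write_curve", {
  helix <- fixture_helix(turns = 1)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_curve(helix, f)
  back <- read_curve(f)
  expect_equal(back$closed, helix$closed)
  uu <- seq(0, 1, length.out = 20)
  expect_equal(eval_point(back, uu), eval_point(helix, uu), tolerance = 1e-9)
  expect_error(read_curve("does-not-exist.yaml"), class = "dnaforge_input_error")
})

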