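# Twist schedule, sequence assignment, base-pair templates, model assembly.

test_that("default twist advances by 2*pi/10.4 per pair on open strands", {
  ts <- twist_schedule(21)
  expect_equal(ts$angles, (0:20) * 2 * pi / 10.4)
  expect_equal(unique(round(diff(ts$angles), 12)), round(2 * pi / 10.4, 12))
})

test_that("twist constraints interpolate linearly with constant extrapolation", {
  # one constraint propagates everywhere
  ts <- twist_schedule(21, list(index = 11, offset = 0.5))
  expect_equal(ts$offsets, rep(0.5, 21))

  # linear blend between constraints, exact at the constrained indices
  ts <- twist_schedule(21, list(index = c(1, 11), offset = c(0, 1)))
  expect_equal(ts$offsets[6], 0.5)
  expect_equal(ts$offsets[1], 0)
  expect_equal(ts$offsets[11], 1)
  expect_equal(ts$offsets[12:21], rep(1, 10))

  # piecewise linear: second differences vanish strictly between constraints
  ts <- twist_schedule(50, list(index = c(5, 20, 37), offset = c(0.2, -0.4, 1.1)))
  expect_equal(ts$offsets[c(5, 20, 37)], c(0.2, -0.4, 1.1))
  d2 <- diff(diff(ts$offsets[6:19]))
  expect_lt(max(abs(d2)), 1e-12)
  expect_equal(ts$offsets[1:5], rep(0.2, 5))
  expect_equal(ts$offsets[37:50], rep(1.1, 14))

  expect_error(twist_schedule(10, list(index = 11, offset = 1)),
               class = "dnaforge_input_error")
  expect_error(twist_schedule(10, list(index = c(3, 3), offset = c(1, 2))),
               class = "dnaforge_input_error")
})

test_that("closed strands adjust the pitch to an integer number of turns", {
  for (N in c(92, 104, 333)) {
    ts <- twist_schedule(N, closed = TRUE)
    step <- 2 * pi / ts$bp_per_turn_effective
    turns <- N * step / (2 * pi)
    expect_equal(turns, round(turns), tolerance = 1e-12)
    expect_equal(ts$bp_per_turn_effective, N / round(N / 10.4))
    # seam step (pair N back to pair 1, mod 2*pi) equals the interior step
    seam <- (ts$angles[1] - ts$angles[N]) %% (2 * pi)
    expect_equal(seam, step, tolerance = 1e-9)
  }
})

test_that("generic sequence is (ACTG)* and complements are Watson-Crick", {
  expect_equal(assign_sequence(6), c("AT", "CG", "TA", "GC", "AT", "CG"))
  expect_equal(assign_sequence(1), "AT")
  expect_equal(assign_sequence(4, "AATT"), c("AT", "AT", "TA", "TA"))
  expect_error(assign_sequence(4, "AXTT"), class = "dnaforge_input_error")
  expect_error(assign_sequence(3, "AATT"), class = "dnaforge_input_error")
})

test_that("templates hold two complementary PDB v3 nucleotides on the axis", {
  tpl <- bp_templates()
  expect_named(tpl, c("AT", "TA", "CG", "GC"))
  counts <- c(DA = 21L, DT = 20L, DC = 19L, DG = 22L)
  for (pair in names(tpl)) {
    at <- tpl[[pair]]
    expect_setequal(unique(at$strand), 1:2)
    r1 <- at$resname[at$strand == 1][1]
    r2 <- at$resname[at$strand == 2][1]
    expect_equal(r1, paste0("D", substr(pair, 1, 1)))
    expect_equal(r2, paste0("D", substr(pair, 2, 2)))
    expect_equal(sum(at$strand == 1), unname(counts[r1]))
    expect_equal(sum(at$strand == 2), unname(counts[r2]))
    expect_true(all(at$element %in% c("C", "N", "O", "P")))
    # pair plane ~ local xy: base rings straddle z = 0 near the origin
    base <- at[!grepl("'", at$name) & !(at$name %in% c("P", "OP1", "OP2")), ]
    expect_lt(max(abs(base$z)), 1.0)
  }
})

test_that("instantiation is a rigid motion", {
  tpl <- bp_templates()$CG
  id_frame <- list(o = c(0, 0, 0), t = c(0, 0, 1), n = c(1, 0, 0), b = c(0, 1, 0))
  same <- instantiate_base_pair(tpl, id_frame, 0)
  expect_equal(same$x, tpl$x, tolerance = 1e-12)
  expect_equal(same$y, tpl$y, tolerance = 1e-12)
  expect_equal(same$z, tpl$z, tolerance = 1e-12)

  full <- instantiate_base_pair(tpl, id_frame, 2 * pi)
  expect_equal(full$x, tpl$x, tolerance = 1e-9)

  set.seed(9)
  ax <- rnorm(3); t <- ax / sqrt(sum(ax^2))
  n <- initial_normal(t)
  fr <- list(o = rnorm(3, sd = 20), t = t, n = n,
             b = c(t[2] * n[3] - t[3] * n[2], t[3] * n[1] - t[1] * n[3],
                   t[1] * n[2] - t[2] * n[1]))
  moved <- instantiate_base_pair(tpl, fr, 1.23)
  d0 <- stats::dist(cbind(tpl$x, tpl$y, tpl$z))
  d1 <- stats::dist(cbind(moved$x, moved$y, moved$z))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("a straight 340 A axis yields 101 base pairs at 3.4 A rise", {
  model <- build_dna(fixture_straight(340))
  expect_equal(model$n_bp, 101L)
  rises <- sqrt(rowSums(diff(model$frames$origins)^2))
  expect_lt(max(abs(rises - 3.4)), 1e-3)
  # consecutive-pair rotation about the tangent is exactly 2*pi/10.4
  steps <- diff(model$schedule$angles)
  expect_equal(steps, rep(2 * pi / 10.4, 100), tolerance = 1e-12)
  # total atom count equals the sum of template atom counts
  tpl <- bp_templates()
  expect_equal(nrow(dna_atoms(model)),
               sum(vapply(model$pairs, function(p) nrow(tpl[[p]]), 0L)))
})

test_that("local unwinding nets zero relative twist between constrained pairs", {
  p <- 20L; q <- 50L
  constraints <- list(index = c(p, q), offset = c(0, -(q - p) * 2 * pi / 10.4))
  model <- build_dna(fixture_straight(340), constraints = constraints)
  expect_equal(model$schedule$angles[q], model$schedule$angles[p], tolerance = 1e-9)
})

test_that("closed models close by pitch adjustment and stay lazy in memory", {
  circ <- fixture_circle(100 / (2 * pi))
  model <- build_dna(circ)
  N <- model$n_bp
  step <- 2 * pi / model$schedule$bp_per_turn_effective
  seam <- (model$schedule$angles[1] - model$schedule$angles[N]) %% (2 * pi)
  expect_equal(seam, step, tolerance = 1e-9)

  # lazy storage: a 20x longer model stores frames, not atoms
  big <- build_dna(fixture_straight(3400))
  small <- build_dna(fixture_straight(170))
  ratio <- as.numeric(utils::object.size(big)) / as.numeric(utils::object.size(small))
  n_ratio <- big$n_bp / small$n_bp
  expect_lt(ratio, n_ratio * 2)  # scales with frames, no hidden per-atom blowup
})
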