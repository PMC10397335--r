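p_unit <- vicsek_params(L = 1, px_per_unit = 128, N = 2, v0 = 0.05, r = 0.1)

test_that("global order parameter follows the mean unit-velocity vector", {
  expect_equal(order_parameter(rep(0.7, 40)), 1)
  expect_equal(order_parameter(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2, pi / 2, pi / 2)), sqrt(10) / 4)
  expect_error(order_parameter(numeric(0)), "zero agents")
})

test_that("local order averages circles, excluding empty ones", {
  # one center holding a single agent, one holding an antiparallel pair,
  # one empty
  st <- mk_state(x = c(0.2, 0.6, 0.61), y = c(0.2, 0.6, 0.6),
                 theta = c(1.0, 0, pi))
  centers <- rbind(c(25.6, 25.6), c(77, 77), c(110, 20))
  lo <- local_order(st, p_unit, centers, R_px = 6)
  expect_equal(lo$values[1], 1)
  expect_equal(lo$values[2], 0, tolerance = 1e-12)
  expect_true(is.na(lo$values[3]))
  expect_equal(lo$n_agents, c(1L, 2L, 0L))
  expect_equal(lo$mean, 0.5, tolerance = 1e-12)

  expect_warning(empty <- local_order(st, p_unit, rbind(c(110, 20)), 3),
                 "empty")
  expect_true(is.na(empty$mean))
})

test_that("alignment score averages cosines between vectors and agents", {
  # one valid vector (1, 0) at anchor (16, 16); two enclosed agents moving
  # along +y and +x
  fld <- mk_field(matrix(1, 1, 1), matrix(0, 1, 1), grid = 32)
  p <- vicsek_params(L = 0.25, px_per_unit = 128, N = 2, v0 = 0.05, r = 0.1)
  st <- mk_state(x = c(0.12, 0.13), y = c(0.12, 0.13), theta = c(pi / 2, 0))
  expect_equal(alignment_score(fld, st, p, R_px = 10), 0.5)

  par <- mk_state(c(0.12, 0.13), c(0.12, 0.13), c(0, 0))
  expect_equal(alignment_score(fld, par, p, R_px = 10), 1)
  anti <- mk_state(c(0.12, 0.13), c(0.12, 0.13), c(pi, pi))
  expect_equal(alignment_score(fld, anti, p, R_px = 10), -1)

  # no agent inside any circle: undefined, flagged
  away <- mk_state(0.24, 0.24, 0)
  expect_warning(val <- alignment_score(fld, away, p, R_px = 2), "undefined")
  expect_true(is.na(val))
})

test_that("coherence difference compares agent and vector local order", {
  p <- vicsek_params(L = 1, px_per_unit = 128, N = 4, v0 = 0.05, r = 0.1)
  fld <- mk_field(matrix(2, 2, 2), matrix(0.5, 2, 2), grid = 64)
  # one agent sitting on each anchor, all moving along the common vector
  ax <- c(0.25, 0.25, 0.75, 0.75); ay <- c(0.25, 0.75, 0.25, 0.75)
  aligned <- mk_state(ax, ay, rep(atan2(0.5, 2), 4))
  expect_equal(coherence_difference(aligned, fld, p, R_px = 20), 0,
               tolerance = 1e-12)

  # R below the lattice spacing: each circle holds only its own vector, so
  # the PIV-side local order is exactly 1 and D^R = |v_a^{R,SPP} - 1|
  set.seed(9)
  u <- matrix(rnorm(4), 2, 2); v <- matrix(rnorm(4), 2, 2)
  rnd <- mk_field(u, v, grid = 64)
  st <- mk_state(ax, ay, runif(4, 0, 2 * pi))
  spp <- local_order(st, p, cbind(rnd$anchor_x, rnd$anchor_y), R_px = 20)
  expect_equal(coherence_difference(st, rnd, p, R_px = 20),
               abs(spp$mean - 1), tolerance = 1e-12)
})

test_that("characteristic scales: identity, monotonicity, conventions", {
  N <- c(2, 10, 100, 300, 1000)
  expect_true(all(diff(gamma0(N, 615)) < 0))
  expect_true(all(diff(r0(N, 615)) < 0))
  expect_equal(r0(N, 615) * sqrt(pi), gamma0(N, 615))
  expect_equal(r0(300, 615, convention = "grid"), gamma0(300, 615))
  expect_equal(gamma0(1, 615), 615)
})

test_that("metric ranges hold on random fields and states", {
  p <- vicsek_params(L = 1, px_per_unit = 128, N = 25, v0 = 0.05, r = 0.2,
                     eta0 = 2 * pi)
  set.seed(12)
  for (i in 1:20) {
    st <- init_state(p, i)
    u <- matrix(runif(16, -5, 5), 4, 4)
    v <- matrix(runif(16, -5, 5), 4, 4)
    u[sample(16, 3)] <- NA
    fld <- mk_field(u, v)
    R <- runif(1, 5, 80)
    a <- suppressWarnings(alignment_score(fld, st, p, R))
    d <- suppressWarnings(coherence_difference(st, fld, p, R))
    lo <- suppressWarnings(local_order(st, p, cbind(fld$anchor_x, fld$anchor_y), R))
    expect_true(is.na(a) || (a >= -1 - 1e-12 && a <= 1 + 1e-12))
    expect_true(is.na(d) || (d >= 0 && d <= 1 + 1e-12))
    expect_true(is.na(lo$mean) || (lo$mean >= 0 && lo$mean <= 1 + 1e-12))
    expect_true(order_parameter(st) >= 0 && order_parameter(st) <= 1 + 1e-12)
  }
})

test_that("a global rotation of agents and vectors leaves all scores unchanged", {
  p <- vicsek_params(L = 1, px_per_unit = 128, N = 30, v0 = 0.05, r = 0.2,
                     eta0 = 2 * pi)
  st <- init_state(p, 77)
  set.seed(77)
  fld <- mk_field(matrix(runif(16, -4, 4), 4, 4),
                  matrix(runif(16, -4, 4), 4, 4))
  for (phi in c(0.3, 2.0, 4.4)) {
    st2 <- rotate_state(st, phi)
    fld2 <- rotate_field(fld, phi)
    expect_equal(alignment_score(fld2, st2, p, 30),
                 alignment_score(fld, st, p, 30), tolerance = 1e-12)
    expect_equal(order_parameter(st2), order_parameter(st), tolerance = 1e-12)
    expect_equal(coherence_difference(st2, fld2, p, 30),
                 coherence_difference(st, fld, p, 30), tolerance = 1e-10)
    lo1 <- local_order(st, p, cbind(fld$anchor_x, fld$anchor_y), 30)
    lo2 <- local_order(st2, p, cbind(fld$anchor_x, fld$anchor_y), 30)
    expect_equal(lo2$mean, lo1$mean, tolerance = 1e-12)
  }
})

test_that("vectorized alignment score equals the double-loop reference", {
  p <- vicsek_params(L = 1, px_per_unit = 128, N = 20, v0 = 0.05, r = 0.2,
                     eta0 = 2 * pi)
  set.seed(55)
  for (i in 1:50) {
    st <- init_state(p, 1000 + i)
    u <- matrix(runif(9, -4, 4), 3, 3)
    v <- matrix(runif(9, -4, 4), 3, 3)
    if (i %% 3 == 0) u[sample(9, 2)] <- NA
    fld <- mk_field(u, v, grid = 42)
    R <- runif(1, 8, 70)
    expect_equal(suppressWarnings(alignment_score(fld, st, p, R)),
                 ref_alignment(fld, st, p, R), tolerance = 1e-12)
  }
})
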