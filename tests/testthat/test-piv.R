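pp_int <- function(grid, step) piv_params(grid_px = grid, step_px = step,
                                          subpixel = "none", validate = "none")

test_that("normalized cross-correlation matches direct evaluation", {
  set.seed(18)
  A <- matrix(sample.int(256, 64 * 64, replace = TRUE) - 1L, 64, 64)
  expect_equal(ncc(A, A, c(1, 1), 0, 0, 16), 1, tolerance = 1e-12)
  neg <- matrix(255L - A, 64, 64)
  expect_equal(ncc(A, neg, c(1, 1), 0, 0, 16), -1, tolerance = 1e-12)

  # longhand arithmetic on a fixed 4x4 pair
  a <- matrix(c(12, 47, 200, 83, 5, 250, 34, 90,
                160, 22, 77, 143, 9, 61, 188, 30), 4, 4)
  b <- matrix(c(100, 40, 210, 70, 15, 240, 60, 95,
                150, 35, 85, 120, 20, 55, 170, 45), 4, 4)
  expect_equal(ncc(a, b, c(1, 1), 0, 0, 4), 0.945302862033, tolerance = 1e-9)

  flat <- matrix(7L, 8, 8)
  expect_true(is.na(ncc(flat, a, c(1, 1), 0, 0, 4)))
})

test_that("identical frames give zero vectors with unit peak correlation", {
  f <- random_frame(128, 25, seed = 2)
  fld <- piv_field(f, f, pp_int(32, 16))
  ok <- fld$valid
  expect_gt(sum(ok), 5)   # grids with no particle are rightly skipped
  expect_true(all(fld$u[ok] == 0 & fld$v[ok] == 0))
  expect_equal(fld$peak_corr[ok], rep(1, sum(ok)), tolerance = 1e-9)
})

test_that("rigid cyclic shifts are recovered exactly and antisymmetrically", {
  set.seed(31)
  for (i in 1:5) {
    f <- random_frame(256, 100, seed = 100 + i)
    dx <- sample(-16:16, 1); dy <- sample(-16:16, 1)
    g <- cyc_shift(f, dy, dx)
    fwd <- piv_field(f, g, pp_int(64, 32))
    expect_true(any(fwd$valid))
    expect_true(all(fwd$u[fwd$valid] == dx))
    expect_true(all(fwd$v[fwd$valid] == dy))
    rev <- piv_field(g, f, pp_int(64, 32))
    expect_true(all(rev$u[rev$valid] == -dx))
    expect_true(all(rev$v[rev$valid] == -dy))
  }
})

test_that("search argmax equals exhaustive direct-formula evaluation", {
  set.seed(41)
  for (i in 1:10) {
    A <- matrix(sample.int(256, 48 * 48, replace = TRUE) - 1L, 48, 48)
    B <- matrix(sample.int(256, 48 * 48, replace = TRUE) - 1L, 48, 48)
    fld <- piv_field(A, B, pp_int(16, 8))
    for (j in seq_len(nrow(fld))) {
      origin <- c((fld$gy[j] - 1) * 16 + 1, (fld$gx[j] - 1) * 16 + 1)
      ref <- ref_best(A, B, origin, 16, 4)
      expect_identical(c(fld$v[j], fld$u[j]), as.numeric(c(ref$k, ref$l)))
      expect_equal(fld$peak_corr[j], ref$C, tolerance = 1e-9)
    }
    expect_true(all(fld$peak_corr[fld$valid] <= 1 + 1e-9 &
                    fld$peak_corr[fld$valid] >= -1 - 1e-9))
  }
})

test_that("grids without particles at either time produce no vector", {
  rp <- render_params(gamma_img = 128L)
  one <- rasterize_ellipses(80, 80, 0, rp)
  one <- structure(one, class = "piv_frame", t = 0L, bg = 255L, fg = 0L)
  blank <- structure(matrix(255L, 128, 128), class = "piv_frame",
                     t = 1L, bg = 255L, fg = 0L)

  fld <- piv_field(one, one, pp_int(32, 16))
  hit <- fld$gx == 3 & fld$gy == 3   # grid [65..96]^2 holds the particle
  expect_true(all(fld$valid[hit]))
  far <- fld$gx == 1 & fld$gy == 1   # empty template and search region
  expect_false(any(fld$valid[far]))

  # foreground at t but none anywhere at t+1: every grid invalid
  expect_false(any(piv_field(one, blank, pp_int(32, 16))$valid))
  expect_false(any(piv_field(blank, blank, pp_int(32, 16))$valid))
})

test_that("normalized-median validation removes the lone discordant vector", {
  u <- matrix(3, 4, 4); v <- matrix(1, 4, 4)
  clean <- validate_vectors(mk_field(u, v), threshold = 2)
  expect_true(all(clean$valid))

  u2 <- u; v2 <- v
  u2[2, 3] <- -3; v2[2, 3] <- -1    # reversed vector
  fld <- mk_field(u2, v2)
  out <- validate_vectors(fld, threshold = 2)
  bad <- fld$gy == 2 & fld$gx == 3
  expect_false(any(out$valid[bad]))
  expect_true(all(out$valid[!bad]))

  # fewer than 2 valid vectors: untouched
  sparse <- mk_field(matrix(c(1, NA, NA, NA), 2, 2),
                     matrix(c(0, NA, NA, NA), 2, 2))
  expect_identical(validate_vectors(sparse, 2)$valid, sparse$valid)
})

test_that("PIV recovers the true agent displacement after convergence", {
  p <- vicsek_params()   # eta0 = pi/6, 3.7 px/frame
  traj <- simulate_vicsek(p, 151, seed = 8)
  f0 <- render_frame(traj$states[[151]], p)
  f1 <- render_frame(traj$states[[152]], p)
  fld <- piv_field(f0, f1, piv_params())   # gaussian3 + validation defaults
  mag <- mean(sqrt(fld$u[fld$valid]^2 + fld$v[fld$valid]^2))
  expect_lt(abs(mag - 3.7) / 3.7, 0.15)
})

test_that("PIV field CSV round-trips", {
  f <- random_frame(128, 25, seed = 6)
  g <- random_frame(128, 25, seed = 7)
  fld <- piv_field(f, g, piv_params(grid_px = 32, step_px = 16))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_piv_csv(fld, path)
  back <- read_piv_csv(path)
  expect_equal(back$u_px, fld$u)
  expect_equal(back$v_px, fld$v)
  expect_identical(back$valid, fld$valid)
  expect_equal(back$anchor_x_px, fld$anchor_x)
})
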