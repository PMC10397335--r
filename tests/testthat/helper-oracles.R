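# Independent reference implementations and fixture builders used across the
# suite.  Everything here deliberately takes the dumbest correct route
# (all-pixel scans, double loops) so it shares no code path with the package
# internals it checks.

mk_state <- function(x, y, theta, t = 0L) {
  structure(list(t = as.integer(t), x = as.numeric(x), y = as.numeric(y),
                 theta = as.numeric(theta)), class = "agent_state")
}

# Ellipse rasterization oracle: tests every pixel center of the image against
# the nine periodic copies of every ellipse.
ref_raster <- function(cx, cy, theta, rp) {
  G <- rp$gamma_img
  xs <- (1:G) - 0.5
  img <- matrix(rp$bg, G, G)
  a <- rp$major_px / 2
  b <- rp$minor_px / 2
  for (n in seq_along(cx)) {
    ct <- cos(theta[n]); st <- sin(theta[n])
    for (ox in c(-G, 0, G)) for (oy in c(-G, 0, G)) {
      DX <- matrix(xs - (cx[n] + ox), nrow = G, ncol = G, byrow = TRUE)
      DY <- matrix(xs - (cy[n] + oy), nrow = G, ncol = G)
      U <- DX * ct + DY * st
      W <- -DX * st + DY * ct
      img[(U / a)^2 + (W / b)^2 <= 1] <- rp$fg
    }
  }
  storage.mode(img) <- "integer"
  img
}

# Cyclic shift: result[r, c] = img[r - dy, c - dx] (periodic), i.e. content
# moves dy rows down and dx columns right.
cyc_shift <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  out <- unclass(img)[((seq_len(n) - 1L - dy) %% n) + 1L,
                      ((seq_len(m) - 1L - dx) %% m) + 1L]
  attributes(out) <- attributes(img)[c("class", "t", "px_per_unit",
                                       "fg", "bg", "convention")]
  dim(out) <- dim(img)
  out
}

# Exhaustive correlation argmax per grid, using the direct formula via ncc()
# and the documented tie-break (smallest k^2+l^2, then smallest k, then l).
ref_best <- function(A, B, origin, Z, m) {
  best <- NULL
  for (l in -m:m) for (k in -m:m) {
    C <- ncc(A, B, origin, k, l, Z)
    if (is.na(C)) next
    d <- k * k + l * l
    take <- is.null(best) || C > best$C ||
      (C == best$C && (d < best$d ||
        (d == best$d && (k < best$k || (k == best$k && l < best$l)))))
    if (take) best <- list(C = C, k = k, l = l, d = d)
  }
  best
}

# Alignment score by the O(M*N) double loop.
ref_alignment <- function(field, state, params, R) {
  P <- params$L * params$px_per_unit
  tot <- 0; M <- 0L
  for (j in seq_len(nrow(field))) {
    if (!field$valid[j]) next
    vn <- sqrt(field$u[j]^2 + field$v[j]^2)
    if (is.na(vn) || vn == 0) next
    s <- 0; n <- 0L
    for (i in seq_along(state$x)) {
      dx <- abs(state$x[i] * params$px_per_unit - field$anchor_x[j])
      dx <- min(dx, P - dx)
      dy <- abs(state$y[i] * params$px_per_unit - field$anchor_y[j])
      dy <- min(dy, P - dy)
      if (dx * dx + dy * dy <= R^2) {
        s <- s + (field$u[j] * cos(state$theta[i]) +
                  field$v[j] * sin(state$theta[i])) / vn
        n <- n + 1L
      }
    }
    if (n > 0L) { tot <- tot + s / n; M <- M + 1L }
  }
  if (M == 0L) NA_real_ else tot / M
}

# Hand-built PIV field on a regular lattice; u, v given as [gy, gx] matrices.
mk_field <- function(u, v, grid = 32, t = 0L, valid = NULL) {
  ny <- nrow(u); nx <- ncol(u)
  or <- (seq_len(ny) - 1L) * grid
  oc <- (seq_len(nx) - 1L) * grid
  origins <- expand.grid(row0 = or, col0 = oc, KEEP.OUT.ATTRS = FALSE)
  uu <- as.vector(u); vv <- as.vector(v)
  if (is.null(valid)) valid <- !is.na(uu)
  d <- data.frame(gy = match(origins$row0, or), gx = match(origins$col0, oc),
                  anchor_x = origins$col0 + grid / 2,
                  anchor_y = origins$row0 + grid / 2,
                  u = uu, v = vv, peak_corr = 1, valid = valid)
  structure(d, class = c("piv_field", "data.frame"), t = t, grid_px = grid,
            margin_px = as.integer(grid / 2), nx = nx, ny = ny,
            dims = c(ny * grid, nx * grid), subpixel = "none")
}

# Rotate agent headings and PIV vectors by a common angle.
rotate_state <- function(state, phi) {
  mk_state(state$x, state$y, (state$theta + phi) %% (2 * pi), state$t)
}
rotate_field <- function(field, phi) {
  u <- field$u * cos(phi) - field$v * sin(phi)
  v <- field$u * sin(phi) + field$v * cos(phi)
  field$u <- u; field$v <- v
  field
}

# A rendered frame of a random agent state (used as generic textured image).
random_frame <- function(G, n, seed, px_per_unit = 64) {
  p <- vicsek_params(L = G / px_per_unit, px_per_unit = px_per_unit, N = n,
                     v0 = 0.05, r = 0.2, eta0 = 2 * pi)
  render_frame(init_state(p, seed), p)
}

# Small end-to-end configuration: 128 px box, 30 agents, 32 px grids.
cfg_small <- function(eta0 = pi / 6, trials = 1L, steps = 30L,
                      radii = c(12, 30), seed = 7L, ...) {
  experiment_config(
    vicsek = vicsek_params(L = 2, px_per_unit = 64, N = 30, v0 = 0.05,
                           r = 0.3, eta0 = eta0),
    piv = piv_params(grid_px = 32L, step_px = 16L),
    radii = radii, noise_levels = eta0, trials = trials, steps = steps,
    stationary = c(max(0L, steps - 10L), steps), seed = seed, ...)
}
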