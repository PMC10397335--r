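#' Configuration of an end-to-end experiment
#'
#' Bundles every stage's parameters plus replication controls.  Trial
#' \code{i} uses seed \code{seed + i - 1}; the same trial seeds are reused
#' across noise levels (paired design), so identical configurations always
#' reproduce identical tables.
#'
#' @param vicsek a \code{\link{vicsek_params}}.
#' @param render a \code{\link{render_params}} (defaults to the image side
#'   implied by \code{vicsek}).
#' @param piv a \code{\link{piv_params}}.
#' @param radii evaluation radii R, px.
#' @param noise_levels noise amplitudes eta0 to run (radians).
#' @param gammas PIV grid sides for the grid/radius landscape, px.
#' @param trials number of independent initial conditions.
#' @param steps simulated horizon T.
#' @param t_eval time of single-pair evaluations (landscapes use the frame
#'   pair at \code{t_eval - 1} and \code{t_eval}).
#' @param tau recording step: frames are taken every \code{tau} steps.
#' @param stationary \code{c(from, to)} window (steps) for stationary
#'   averages.
#' @param r0_convention radius normalization passed to \code{\link{r0}}.
#' @param seed base seed.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(vicsek = vicsek_params(),
                              render = render_params(gamma_img = vicsek$gamma_img),
                              piv = piv_params(),
                              radii = c(30, 70, 120, 200),
                              noise_levels = pi / 6,
                              gammas = c(36, 72, 108),
                              trials = 1L,
                              steps = 300L,
                              t_eval = steps,
                              tau = 1L,
                              stationary = c(200L, 300L),
                              r0_convention = c("formula", "grid"),
                              seed = 1L) {
  r0_convention <- match.arg(r0_convention)
  stopifnot(trials >= 1, steps >= 1, t_eval >= 1, t_eval <= steps,
            tau >= 1, tau == round(tau),
            length(stationary) == 2, stationary[1] <= stationary[2],
            stationary[2] <= steps)
  structure(list(vicsek = vicsek, render = render, piv = piv, radii = radii,
                 noise_levels = noise_levels, gammas = gammas,
                 trials = as.integer(trials), steps = as.integer(steps),
                 t_eval = as.integer(t_eval), tau = as.integer(tau),
                 stationary = as.integer(stationary),
                 r0_convention = r0_convention, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment_config: %d trial(s), T = %d, tau = %d, base seed %d\n",
              x$trials, x$steps, x$tau, x$seed))
  cat(sprintf("  noise levels: %s; radii (px): %s; r0 convention: %s\n",
              paste(signif(x$noise_levels, 3), collapse = ", "),
              paste(x$radii, collapse = ", "), x$r0_convention))
  print(x$vicsek)
  invisible(x)
}

trial_seed <- function(cfg, trial) cfg$seed + trial - 1L

vparams_at_noise <- function(cfg, eta) {
  p <- cfg$vicsek
  p$eta0 <- eta
  p
}

#' Alignment score and coherence difference over time
#'
#' Runs the full pipeline at one noise level and reports \code{A^R(t)} and
#' \code{D^R(t)} for every configured radius: frames are rendered every
#' \code{tau} steps, PIV is computed for each consecutive recorded pair, and
#' the metrics compare each field against the agent state at the earlier
#' recorded frame.  Degenerate time points (no valid vectors) are recorded as
#' \code{NA}, never zero.
#'
#' @param cfg an \code{\link{experiment_config}} (first noise level is used).
#' @param t_range optional \code{c(from, to)} restricting the pair start
#'   times (default: full horizon).
#' @return data frame with columns \code{t, metric, R_px, value, n_vectors,
#'   eta0, seed}.
#' @export
run_timeseries <- function(cfg, t_range = NULL) {
  eta <- cfg$noise_levels[1]
  if (length(cfg$noise_levels) > 1)
    warning("run_timeseries uses a single noise level; taking the first")
  p <- vparams_at_noise(cfg, eta)
  traj <- simulate_vicsek(p, cfg$steps, cfg$seed)
  rec <- seq.int(0L, cfg$steps, by = cfg$tau)
  starts <- rec[-length(rec)]
  if (!is.null(t_range))
    starts <- starts[starts >= t_range[1] & starts <= t_range[2]]
  rows <- vector("list", length(starts))
  f1 <- NULL; t1_prev <- -1L
  for (i in seq_along(starts)) {
    t0 <- starts[i]; t1 <- t0 + cfg$tau
    f0 <- if (t0 == t1_prev) f1 else render_frame(traj$states[[t0 + 1L]], p, cfg$render)
    f1 <- render_frame(traj$states[[t1 + 1L]], p, cfg$render)
    t1_prev <- t1
    field <- piv_field(f0, f1, cfg$piv)
    st <- traj$states[[t0 + 1L]]
    nvec <- sum(field$valid)
    rows[[i]] <- do.call(rbind, lapply(cfg$radii, function(R) {
      a <- suppressWarnings(alignment_score(field, st, p, R))
      d <- suppressWarnings(coherence_difference(st, field, p, R))
      data.frame(t = t0, metric = c("A_R", "D_R"), R_px = R,
                 value = c(a, d), n_vectors = nvec, eta0 = eta,
                 seed = cfg$seed)
    }))
  }
  do.call(rbind, rows)
}

# Render the (t_eval - 1, t_eval) frame pair of one trial and score A^R for
# one PIV parameterization over the requested radii.
eval_pair_ar <- function(traj, p, cfg, pp, radii) {
  st <- traj$states[[cfg$t_eval]]         # t = t_eval - 1
  f0 <- render_frame(st, p, cfg$render)
  f1 <- render_frame(traj$states[[cfg$t_eval + 1L]], p, cfg$render)
  field <- piv_field(f0, f1, pp)
  vapply(radii, function(R)
    suppressWarnings(alignment_score(field, st, p, R)), numeric(1))
}

#' Alignment-score landscape over grid size and radius
#'
#' For each trial at the configured (typically high) noise level, PIV is run
#' on the frame pair at \code{t_eval} with every grid size in
#' \code{cfg$gammas}, and \code{A^R} is scored at every radius in
#' \code{cfg$radii}; cells are averaged over trials.  Axes are also reported
#' normalized by \code{gamma0(N)} and \code{r0(N)}.
#'
#' @param cfg an \code{\link{experiment_config}}; the first noise level is
#'   used (set it high, e.g. \code{11*pi/6}, for the regime where the
#'   single-particle scales matter).
#' @return data frame with columns \code{gamma_px, R_px, gamma_norm, R_norm,
#'   A_R, n_trials, r0_convention}.
#' @export
run_grid_radius_landscape <- function(cfg) {
  eta <- cfg$noise_levels[1]
  p <- vparams_at_noise(cfg, eta)
  g0 <- gamma0(p$N, p$gamma_img)
  R0 <- r0(p$N, p$gamma_img, cfg$r0_convention)
  acc <- array(0, dim = c(length(cfg$gammas), length(cfg$radii)))
  cnt <- array(0L, dim = dim(acc))
  for (trial in seq_len(cfg$trials)) {
    traj <- simulate_vicsek(p, cfg$t_eval, trial_seed(cfg, trial))
    for (gi in seq_along(cfg$gammas)) {
      gpx <- cfg$gammas[gi]
      pp <- piv_params(grid_px = gpx, step_px = 2L * max(1L, round(gpx / 4)),
                       subpixel = cfg$piv$subpixel, validate = cfg$piv$validate,
                       validation_threshold = cfg$piv$validation_threshold)
      ar <- eval_pair_ar(traj, p, cfg, pp, cfg$radii)
      ok <- !is.na(ar)
      acc[gi, ok] <- acc[gi, ok] + ar[ok]
      cnt[gi, ok] <- cnt[gi, ok] + 1L
    }
  }
  grid <- expand.grid(gi = seq_along(cfg$gammas), ri = seq_along(cfg$radii))
  data.frame(gamma_px = cfg$gammas[grid$gi],
             R_px = cfg$radii[grid$ri],
             gamma_norm = cfg$gammas[grid$gi] / g0,
             R_norm = cfg$radii[grid$ri] / R0,
             A_R = ifelse(cnt[cbind(grid$gi, grid$ri)] > 0,
                          acc[cbind(grid$gi, grid$ri)] /
                            cnt[cbind(grid$gi, grid$ri)], NA_real_),
             n_trials = cnt[cbind(grid$gi, grid$ri)],
             r0_convention = cfg$r0_convention)
}

#' Alignment-score landscape over noise and radius
#'
#' For every noise level and trial, PIV is applied to the frame pair at
#' \code{t_eval} only (late, stationary time) with the configured grid, and
#' \code{A^R} is scored at every radius; cells are averaged over trials.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @return data frame with columns \code{eta0, R_px, R_norm, A_R, n_trials,
#'   r0_convention}.
#' @export
run_noise_radius_landscape <- function(cfg) {
  p0 <- cfg$vicsek
  R0 <- r0(p0$N, p0$gamma_img, cfg$r0_convention)
  out <- list()
  for (eta in cfg$noise_levels) {
    p <- vparams_at_noise(cfg, eta)
    acc <- numeric(length(cfg$radii)); cnt <- integer(length(cfg$radii))
    for (trial in seq_len(cfg$trials)) {
      traj <- simulate_vicsek(p, cfg$t_eval, trial_seed(cfg, trial))
      ar <- eval_pair_ar(traj, p, cfg, cfg$piv, cfg$radii)
      ok <- !is.na(ar)
      acc[ok] <- acc[ok] + ar[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
    out[[length(out) + 1L]] <-
      data.frame(eta0 = eta, R_px = cfg$radii, R_norm = cfg$radii / R0,
                 A_R = ifelse(cnt > 0, acc / cnt, NA_real_),
                 n_trials = cnt, r0_convention = cfg$r0_convention)
  }
  do.call(rbind, out)
}

#' Time-averaged alignment score versus recording step
#'
#' The simulation advances with \code{dt = 1} while frames are recorded every
#' \code{tau} steps; PIV then measures displacement per recorded interval.
#' For each \code{tau}, \code{A^R} is averaged over all recorded pairs inside
#' the stationary window (and over trials).  A warning is raised when the
#' expected displacement \code{tau * v0 * px_per_unit} exceeds the search
#' margin (vectors saturate at the margin).
#'
#' @param cfg an \code{\link{experiment_config}} (first noise level used;
#'   intermediate noise such as \code{pi/2} is the intended regime).
#' @param taus recording steps to evaluate.
#' @return data frame with columns \code{tau, R_px, A_R_mean, n_pairs, eta0}.
#' @export
run_sampling_rate <- function(cfg, taus = c(1L, 2L, 4L)) {
  eta <- cfg$noise_levels[1]
  p <- vparams_at_noise(cfg, eta)
  for (tau in taus)
    if (tau * p$v0 * p$px_per_unit > cfg$piv$margin_px)
      warning(sprintf(
        "tau = %d: expected displacement %.1f px exceeds search margin %d px",
        tau, tau * p$v0 * p$px_per_unit, cfg$piv$margin_px))
  acc <- matrix(0, length(taus), length(cfg$radii))
  cnt <- matrix(0L, length(taus), length(cfg$radii))
  for (trial in seq_len(cfg$trials)) {
    traj <- simulate_vicsek(p, cfg$stationary[2], trial_seed(cfg, trial))
    for (ti in seq_along(taus)) {
      tau <- taus[ti]
      rec <- seq.int(cfg$stationary[1], cfg$stationary[2], by = tau)
      if (length(rec) < 2) next
      f1 <- NULL; tprev <- -1L
      for (i in seq_len(length(rec) - 1L)) {
        t0 <- rec[i]; t1 <- rec[i + 1L]
        f0 <- if (t0 == tprev) f1 else render_frame(traj$states[[t0 + 1L]], p, cfg$render)
        f1 <- render_frame(traj$states[[t1 + 1L]], p, cfg$render)
        tprev <- t1
        field <- piv_field(f0, f1, cfg$piv)
        st <- traj$states[[t0 + 1L]]
        ar <- vapply(cfg$radii, function(R)
          suppressWarnings(alignment_score(field, st, p, R)), numeric(1))
        ok <- !is.na(ar)
        acc[ti, ok] <- acc[ti, ok] + ar[ok]
        cnt[ti, ok] <- cnt[ti, ok] + 1L
      }
    }
  }
  grid <- expand.grid(ti = seq_along(taus), ri = seq_along(cfg$radii))
  data.frame(tau = taus[grid$ti], R_px = cfg$radii[grid$ri],
             A_R_mean = ifelse(cnt[cbind(grid$ti, grid$ri)] > 0,
                               acc[cbind(grid$ti, grid$ri)] /
                                 cnt[cbind(grid$ti, grid$ri)], NA_real_),
             n_pairs = cnt[cbind(grid$ti, grid$ri)], eta0 = eta)
}

#' Locate the order-disorder transition
#'
#' Sweeps the configured noise levels, averages the order parameter
#' \code{v_a} over the stationary window and over trials, and returns the
#' noise amplitude at which the averaged curve crosses 0.5 (linear
#' interpolation between adjacent sweep points).  Purely trajectory-based;
#' no rendering or PIV involved.
#'
#' @param cfg an \code{\link{experiment_config}} whose \code{noise_levels}
#'   span the transition (e.g. \code{seq(pi/2, 3*pi/2, length.out = 7)}).
#' @return an object of class \code{vicsek_transition}: list with
#'   \code{eta_c} and the sweep \code{table}.
#' @export
find_transition <- function(cfg) {
  etas <- sort(cfg$noise_levels)
  if (length(etas) < 2) stop("need at least two noise levels to bracket a crossing")
  w <- cfg$stationary
  va <- vapply(etas, function(eta) {
    p <- vparams_at_noise(cfg, eta)
    mean(vapply(seq_len(cfg$trials), function(trial) {
      traj <- simulate_vicsek(p, w[2], trial_seed(cfg, trial))
      mean(vapply(traj$states[(w[1] + 1L):(w[2] + 1L)], order_parameter,
                  numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  above <- va >= 0.5
  cross <- which(above[-length(above)] & !above[-1])
  if (!length(cross))
    stop(sprintf(
      "no 0.5 crossing in sweep: v_a ranges %.3f (eta0 = %.3f) to %.3f (eta0 = %.3f)",
      va[1], etas[1], va[length(va)], etas[length(etas)]))
  i <- cross[1]
  eta_c <- etas[i] + (va[i] - 0.5) * (etas[i + 1] - etas[i]) / (va[i] - va[i + 1])
  structure(list(eta_c = eta_c,
                 table = data.frame(eta0 = etas, v_a = va,
                                    n_trials = cfg$trials)),
            class = "vicsek_transition")
}

#' @export
print.vicsek_transition <- function(x, ...) {
  cat(sprintf("Order-disorder transition estimate: eta_c = %.3f rad (%.3f pi)\n",
              x$eta_c, x$eta_c / pi))
  print(x$table, row.names = FALSE)
  invisible(x)
}
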