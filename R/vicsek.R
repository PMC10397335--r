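#' Parameters of the Vicsek self-propelled particle model
#'
#' All lengths are in arbitrary simulation units; \code{px_per_unit} converts
#' them to pixels for rendering and PIV, so the image side is
#' \code{gamma_img = round(L * px_per_unit)} pixels.  Defaults reproduce the
#' standard setting used throughout this package: a box of 5 units (615 px),
#' 300 agents moving at 0.03 units/step (3.7 px/frame) that align with
#' neighbors within 0.5 units (61.5 px), plus uniform angular noise of
#' amplitude \code{eta0}.
#'
#' @param L box side length, units.
#' @param px_per_unit pixels per unit.
#' @param N number of agents.
#' @param v0 constant agent speed, units per step.
#' @param r interaction radius, units.
#' @param eta0 angular noise amplitude in radians; each step every agent's new
#'   heading is perturbed by an independent uniform draw in
#'   \code{[-eta0/2, eta0/2]}.  Must lie in \code{[0, 2*pi]}.
#' @param dt time increment per step.
#' @return an object of class \code{vicsek_params}.
#' @examples
#' p <- vicsek_params(N = 100, eta0 = pi)
#' p$gamma_img
#' @export
vicsek_params <- function(L = 5, px_per_unit = 123, N = 300, v0 = 0.03,
                          r = 0.5, eta0 = pi / 6, dt = 1) {
  if (!(is.numeric(L) && length(L) == 1 && L > 0))
    stop("'L' must be a positive number")
  if (!(is.numeric(v0) && length(v0) == 1 && v0 >= 0))
    stop("'v0' must be >= 0")
  if (!(is.numeric(r) && length(r) == 1 && r > 0 && r <= L))
    stop("'r' must satisfy 0 < r <= L")
  if (!(is.numeric(eta0) && length(eta0) == 1 && eta0 >= 0 && eta0 <= 2 * pi))
    stop("'eta0' must lie in [0, 2*pi]")
  if (!(is.numeric(N) && length(N) == 1 && N >= 0 && N == round(N)))
    stop("'N' must be a non-negative integer")
  gamma_img <- as.integer(round(L * px_per_unit))
  if (gamma_img < 1) stop("image side round(L * px_per_unit) must be >= 1 px")
  structure(list(L = L, px_per_unit = px_per_unit, N = as.integer(N),
                 v0 = v0, r = r, eta0 = eta0, dt = dt,
                 gamma_img = gamma_img),
            class = "vicsek_params")
}

#' @export
print.vicsek_params <- function(x, ...) {
  cat(sprintf("Vicsek parameters: N = %d, L = %g units (%d px), v0 = %g (%.2f px/frame)\n",
              x$N, x$L, x$gamma_img, x$v0, x$v0 * x$px_per_unit))
  cat(sprintf("  r = %g units (%.1f px), eta0 = %.4f rad, dt = %g\n",
              x$r, x$r * x$px_per_unit, x$eta0, x$dt))
  invisible(x)
}

# Internal constructor for one time slice of the system.
agent_state <- function(t, x, y, theta) {
  structure(list(t = as.integer(t), x = as.numeric(x), y = as.numeric(y),
                 theta = as.numeric(theta)),
            class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf("agent_state: t = %d, %d agents\n", x$t, length(x$x)))
  invisible(x)
}

#' Random initial condition
#'
#' Positions i.i.d. uniform on the box, headings i.i.d. uniform on
#' \code{[0, 2*pi)}; fully reproducible from \code{seed}.
#'
#' @param params a \code{\link{vicsek_params}} object.
#' @param seed integer seed.
#' @return an \code{agent_state} at \code{t = 0}.
#' @export
init_state <- function(params, seed) {
  stopifnot(inherits(params, "vicsek_params"))
  run_with_seed(seed, function() init_state_impl(params))
}

init_state_impl <- function(params) {
  n <- params$N
  agent_state(0L, runif(n, 0, params$L), runif(n, 0, params$L),
              runif(n, 0, 2 * pi))
}

#' Mean heading of an agent's neighborhood
#'
#' The circular mean of the headings of all agents within distance \code{r}
#' of agent \code{i} (minimum-image convention, self included), computed as
#' the two-argument arctangent of the summed sines and cosines and mapped to
#' \code{[0, 2*pi)}.  If both sums are exactly zero the agent's current
#' heading is returned.
#'
#' This is the reference one-agent implementation (an all-pairs scan); the
#' stepper uses an equivalent cell-list kernel for all agents at once.
#'
#' @param state an \code{agent_state}.
#' @param i agent index (1-based).
#' @param r interaction radius, units.
#' @param L box side, units.
#' @return heading in \code{[0, 2*pi)}.
#' @export
mean_neighbor_angle <- function(state, i, r, L) {
  dx <- state$x - state$x[i]
  dx <- dx - L * round(dx / L)
  dy <- state$y - state$y[i]
  dy <- dy - L * round(dy / L)
  nb <- which(dx^2 + dy^2 <= r^2)
  s <- sum(sin(state$theta[nb]))
  c <- sum(cos(state$theta[nb]))
  if (s == 0 && c == 0) return(state$theta[i] %% (2 * pi))
  atan2(s, c) %% (2 * pi)
}

#' Advance the system by one step
#'
#' Synchronous update: every agent's new heading is the neighborhood mean
#' heading evaluated on the complete time-\code{t} configuration plus an
#' independent uniform noise draw in \code{[-eta0/2, eta0/2]}; every new
#' position is the old position advanced along the \emph{old} heading by
#' \code{v0 * dt}, wrapped periodically.  Noise is drawn from the current R
#' random stream.
#'
#' @param state an \code{agent_state}.
#' @param params a \code{\link{vicsek_params}}.
#' @return the \code{agent_state} at \code{t + 1}.
#' @export
vicsek_step <- function(state, params) {
  n <- length(state$x)
  if (n == 0) return(agent_state(state$t + 1L, numeric(0), numeric(0), numeric(0)))
  th_new <- vm_mean_angles(state$x, state$y, state$theta, params$L, params$r)
  if (params$eta0 > 0)
    th_new <- (th_new + runif(n, -params$eta0 / 2, params$eta0 / 2)) %% (2 * pi)
  x <- (state$x + params$v0 * cos(state$theta) * params$dt) %% params$L
  y <- (state$y + params$v0 * sin(state$theta) * params$dt) %% params$L
  agent_state(state$t + 1L, x, y, th_new)
}

#' Simulate a Vicsek trajectory
#'
#' Runs \code{steps} update steps from a random initial condition; the whole
#' trajectory (initial state included) is reproducible from \code{seed}.
#'
#' @param params a \code{\link{vicsek_params}}.
#' @param steps number of steps \code{T >= 0}.
#' @param seed integer seed.
#' @return an object of class \code{vicsek_trajectory}: a list with
#'   \code{states} (list of \code{agent_state}, \code{t = 0..T}),
#'   \code{params} and \code{seed}.
#' @examples
#' traj <- simulate_vicsek(vicsek_params(N = 50), steps = 10, seed = 1)
#' order_parameter(traj$states[[11]])
#' @export
simulate_vicsek <- function(params, steps, seed) {
  stopifnot(inherits(params, "vicsek_params"),
            is.numeric(steps), length(steps) == 1, steps >= 0,
            steps == round(steps))
  steps <- as.integer(steps)
  states <- vector("list", steps + 1L)
  run_with_seed(seed, function() {
    st <- init_state_impl(params)
    states[[1L]] <<- st
    for (k in seq_len(steps)) {
      st <- vicsek_step(st, params)
      states[[k + 1L]] <<- st
    }
  })
  structure(list(states = states, params = params, seed = seed),
            class = "vicsek_trajectory")
}

#' @export
print.vicsek_trajectory <- function(x, ...) {
  cat(sprintf("Vicsek trajectory: %d agents, t = 0..%d, seed = %s\n",
              x$params$N, length(x$states) - 1L, format(x$seed)))
  cat(sprintf("  final order parameter v_a = %.4f\n",
              order_parameter(x$states[[length(x$states)]])))
  invisible(x)
}

#' @export
summary.vicsek_trajectory <- function(object, ...) {
  va <- vapply(object$states, order_parameter, numeric(1))
  res <- list(params = object$params, steps = length(object$states) - 1L,
              v_a = va)
  class(res) <- "summary.vicsek_trajectory"
  res
}

#' @export
print.summary.vicsek_trajectory <- function(x, ...) {
  print(x$params)
  cat(sprintf("  %d steps; v_a: start %.3f, end %.3f, min %.3f, max %.3f\n",
              x$steps, x$v_a[1], x$v_a[length(x$v_a)], min(x$v_a), max(x$v_a)))
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' One row per agent per time with columns \code{t, agent_id, x_units,
#' y_units, theta_rad}.  \code{read_trajectory_csv} rebuilds a
#' \code{vicsek_trajectory}; supply the \code{params} the file was produced
#' with if downstream rendering/PIV is intended.
#'
#' @param traj a \code{vicsek_trajectory}.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  rows <- lapply(traj$states, function(st)
    data.frame(t = st$t, agent_id = seq_along(st$x),
               x_units = st$x, y_units = st$y, theta_rad = st$theta))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @param params optional \code{\link{vicsek_params}} to attach.
#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, params = NULL) {
  df <- read.csv(path)
  need <- c("t", "agent_id", "x_units", "y_units", "theta_rad")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  states <- lapply(sort(unique(df$t)), function(tt) {
    d <- df[df$t == tt, ]
    d <- d[order(d$agent_id), ]
    agent_state(tt, d$x_units, d$y_units, d$theta_rad)
  })
  structure(list(states = states, params = params, seed = NA_integer_),
            class = "vicsek_trajectory")
}
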