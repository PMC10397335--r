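#' Global order parameter
#'
#' Magnitude of the mean unit-velocity vector over all agents: 1 for perfect
#' global alignment, near 0 for disorder.  Agents move at a common nonzero
#' speed, so unit velocities are \code{(cos theta, sin theta)}.
#'
#' @param state an \code{agent_state}, or a numeric vector of headings.
#' @return value in \code{[0, 1]}.
#' @export
order_parameter <- function(state) {
  th <- if (inherits(state, "agent_state")) state$theta else as.numeric(state)
  if (!length(th)) stop("order parameter undefined for zero agents")
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

# Minimum-image distance helper on a torus of period P (same units both args).
mi_dist2 <- function(ax, ay, cx, cy, P) {
  dx <- abs(ax - cx); dx <- pmin(dx, P - dx)
  dy <- abs(ay - cy); dy <- pmin(dy, P - dy)
  dx * dx + dy * dy
}

#' Local order around a set of centers
#'
#' For each center, the magnitude of the mean unit velocity of the agents
#' within distance \code{R_px} (periodic minimum image, pixel space); empty
#' circles are recorded as \code{NA} and excluded from the mean.  Centers are
#' typically the anchors of the PIV lattice.
#'
#' @param state an \code{agent_state}.
#' @param params the \code{\link{vicsek_params}} (for the pixel scale and
#'   period).
#' @param centers two-column matrix or data frame of center positions, px.
#' @param R_px evaluation radius, px.
#' @return list with \code{values} (per center), \code{n_agents} (per
#'   center) and \code{mean} (over non-empty centers; \code{NA} with a
#'   warning if all centers are empty).
#' @export
local_order <- function(state, params, centers, R_px) {
  stopifnot(R_px > 0)
  centers <- as.matrix(centers)
  P <- params$L * params$px_per_unit
  ax <- state$x * params$px_per_unit
  ay <- state$y * params$px_per_unit
  nc <- nrow(centers)
  vals <- rep(NA_real_, nc)
  nag <- integer(nc)
  for (j in seq_len(nc)) {
    sel <- mi_dist2(ax, ay, centers[j, 1], centers[j, 2], P) <= R_px^2
    nag[j] <- sum(sel)
    if (nag[j] > 0) {
      th <- state$theta[sel]
      vals[j] <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    }
  }
  if (all(is.na(vals))) {
    warning("all centers empty: local order undefined")
    return(list(values = vals, n_agents = nag, mean = NA_real_))
  }
  list(values = vals, n_agents = nag, mean = mean(vals, na.rm = TRUE))
}

#' Alignment score between a PIV field and agent motion
#'
#' For each valid PIV vector, the cosine of the angle between the vector and
#' the velocity of each agent within distance \code{R_px} of its anchor is
#' averaged; the score is the mean of these averages over all participating
#' vectors.  1: agents parallel to nearby vectors; -1: antiparallel; 0: no
#' relation.  Vectors enclosing no agent, and vectors of zero magnitude
#' (direction undefined), are excluded from the outer mean.
#'
#' @param field a \code{\link{piv_field}} at the same time index as
#'   \code{state} (the earlier frame of the PIV pair).
#' @param state the \code{agent_state} at that time.
#' @param params the \code{\link{vicsek_params}}.
#' @param R_px evaluation radius, px.
#' @return value in \code{[-1, 1]}, or \code{NA} (with a warning) if no
#'   vector participates.
#' @export
alignment_score <- function(field, state, params, R_px) {
  stopifnot(R_px > 0)
  P <- params$L * params$px_per_unit
  ax <- state$x * params$px_per_unit
  ay <- state$y * params$px_per_unit
  ct <- cos(state$theta); st <- sin(state$theta)
  ok <- which(field$valid & (field$u^2 + field$v^2) > 0)
  terms <- numeric(0)
  for (j in ok) {
    sel <- mi_dist2(ax, ay, field$anchor_x[j], field$anchor_y[j], P) <= R_px^2
    if (!any(sel)) next
    vn <- sqrt(field$u[j]^2 + field$v[j]^2)
    cosines <- (field$u[j] * ct[sel] + field$v[j] * st[sel]) / vn
    terms <- c(terms, mean(cosines))
  }
  if (!length(terms)) {
    warning("no PIV vector with enclosed agents: alignment score undefined")
    return(NA_real_)
  }
  mean(terms)
}

#' Coherence difference between agents and PIV vectors
#'
#' Absolute difference between the local order of the agents and the local
#' order of the (unit-normalized) valid PIV vectors, both evaluated with the
#' same centers (the valid vectors' anchors) and radius.  Near 0 means PIV
#' vectors and nearby agents are organized alike.
#'
#' @inheritParams alignment_score
#' @return value in \code{[0, 1]}, or \code{NA} if either side is undefined.
#' @export
coherence_difference <- function(state, field, params, R_px) {
  stopifnot(R_px > 0)
  ok <- which(field$valid & (field$u^2 + field$v^2) > 0)
  if (!length(ok)) {
    warning("no valid PIV vectors: coherence difference undefined")
    return(NA_real_)
  }
  cx <- field$anchor_x[ok]; cy <- field$anchor_y[ok]
  spp <- local_order(state, params, cbind(cx, cy), R_px)
  if (is.na(spp$mean)) return(NA_real_)
  P <- params$L * params$px_per_unit
  ang <- atan2(field$v[ok], field$u[ok])
  piv_vals <- vapply(seq_along(ok), function(j) {
    sel <- mi_dist2(cx, cy, cx[j], cy[j], P) <= R_px^2
    th <- ang[sel]
    sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  }, numeric(1))
  abs(spp$mean - mean(piv_vals))
}

#' Characteristic grid size and radius for single-particle occupancy
#'
#' \code{gamma0(N, Gamma) = Gamma / sqrt(N)} is the side of the square grid
#' that contains one agent on average in a \code{Gamma x Gamma} image;
#' \code{r0} is the analogous circle radius, \code{gamma0 / sqrt(pi)} under
#' the uniform-distribution assumption (\code{convention = "formula"}).
#' \code{convention = "grid"} instead equates the radius scale with
#' \code{gamma0} itself, an alternative normalization in circulation for
#' grid-tied radii; results should state which convention was used.
#'
#' @param N agent count.
#' @param Gamma image side, px.
#' @return scale in pixels.
#' @examples
#' gamma0(100, 615)  # 61.5
#' r0(300, 615)      # ~20
#' @export
gamma0 <- function(N, Gamma = 615) {
  stopifnot(all(N >= 1), Gamma > 0)
  Gamma / sqrt(N)
}

#' @param convention radius normalization, see Details.
#' @rdname gamma0
#' @export
r0 <- function(N, Gamma = 615, convention = c("formula", "grid")) {
  convention <- match.arg(convention)
  if (convention == "grid") gamma0(N, Gamma) else gamma0(N, Gamma) / sqrt(pi)
}
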