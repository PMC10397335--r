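#' Rendering parameters
#'
#' Frames are 8-bit grayscale rasters of black oriented ovals on a white
#' background: one filled ellipse per agent, major axis parallel to the
#' agent's heading.  Only two intensity levels are used (no anti-aliasing).
#'
#' @param gamma_img image side in pixels.
#' @param major_px ellipse major-axis length, pixels.
#' @param minor_px ellipse minor-axis length, pixels.
#' @param fg foreground (particle) intensity.
#' @param bg background intensity.
#' @return an object of class \code{render_params}.
#' @export
render_params <- function(gamma_img = 615L, major_px = 8, minor_px = 6,
                          fg = 0L, bg = 255L) {
  stopifnot(gamma_img >= 1, major_px >= minor_px, minor_px > 0,
            fg >= 0, fg < bg, bg <= 255)
  structure(list(gamma_img = as.integer(gamma_img), major_px = major_px,
                 minor_px = minor_px, fg = as.integer(fg),
                 bg = as.integer(bg)),
            class = "render_params")
}

#' Rasterize oriented ellipses into an 8-bit raster
#'
#' Low-level renderer working directly in pixel coordinates.  A pixel is
#' foreground iff its center lies inside some ellipse with semi-axes
#' \code{(major_px/2, minor_px/2)} centered at \code{(cx, cy)} and rotated by
#' \code{theta}; ellipses wrap periodically across the image edges and
#' overlaps union.  Convention: matrix row = y, column = x, origin at the
#' top-left; the pixel in row r, column c (1-based) has center
#' \code{(x, y) = (c - 0.5, r - 0.5)}.
#'
#' @param cx,cy ellipse centers in continuous pixel coordinates,
#'   \code{[0, gamma_img)}.
#' @param theta rotation of the major axis, radians.
#' @param rp a \code{\link{render_params}}.
#' @return integer matrix \code{gamma_img x gamma_img}.
#' @export
rasterize_ellipses <- function(cx, cy, theta, rp) {
  G <- rp$gamma_img
  img <- matrix(rp$bg, G, G)
  a <- rp$major_px / 2
  b <- rp$minor_px / 2
  for (n in seq_along(cx)) {
    cols <- floor(cx[n] - a):ceiling(cx[n] + a + 1)
    rows <- floor(cy[n] - a):ceiling(cy[n] + a + 1)
    dx <- (cols - 0.5) - cx[n]
    dy <- (rows - 0.5) - cy[n]
    ct <- cos(theta[n]); st <- sin(theta[n])
    DX <- matrix(dx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
    DY <- matrix(dy, nrow = length(rows), ncol = length(cols))
    U <- DX * ct + DY * st        # along major axis
    W <- -DX * st + DY * ct       # along minor axis
    ins <- (U / a)^2 + (W / b)^2 <= 1
    if (any(ins)) {
      sel <- which(ins, arr.ind = TRUE)
      rr <- ((rows - 1L) %% G) + 1L
      cc <- ((cols - 1L) %% G) + 1L
      img[cbind(rr[sel[, 1L]], cc[sel[, 2L]])] <- rp$fg
    }
  }
  storage.mode(img) <- "integer"
  img
}

#' Render one agent state as a synthetic microscopy-like frame
#'
#' Converts agent positions from units to pixels
#' (\code{x_px = x * px_per_unit}) and rasterizes one oriented oval per agent
#' (see \code{\link{rasterize_ellipses}}).  Agent centers are kept at
#' continuous (subpixel) coordinates so rasters change smoothly as agents
#' move.
#'
#' @param state an \code{agent_state}.
#' @param params the \code{\link{vicsek_params}} that produced it.
#' @param rp a \code{\link{render_params}}; defaults to the image side implied
#'   by \code{params}.
#' @return an integer matrix of class \code{piv_frame} with attributes
#'   \code{t}, \code{px_per_unit}, \code{fg}, \code{bg} and the coordinate
#'   convention.
#' @export
render_frame <- function(state, params, rp = NULL) {
  if (is.null(rp)) rp <- render_params(gamma_img = params$gamma_img)
  if (length(state$x) &&
      (any(state$x < 0 | state$x >= params$L) ||
       any(state$y < 0 | state$y >= params$L)))
    stop("agent positions outside [0, L): periodic wrap missing upstream")
  img <- rasterize_ellipses(state$x * params$px_per_unit,
                            state$y * params$px_per_unit,
                            state$theta, rp)
  structure(img, class = "piv_frame", t = state$t,
            px_per_unit = params$px_per_unit, fg = rp$fg, bg = rp$bg,
            convention = "row=y,col=x,origin=top-left,center=(c-0.5,r-0.5)")
}

#' @export
print.piv_frame <- function(x, ...) {
  cat(sprintf("piv_frame: %d x %d px, t = %s, %d foreground px\n",
              nrow(x), ncol(x), format(attr(x, "t")),
              sum(unclass(x) == attr(x, "fg"))))
  invisible(x)
}

#' Render a trajectory at a given recording step
#'
#' Frames are rendered at \code{t = 0, tau, 2*tau, ...}; the recording step
#' is stored so downstream PIV reports displacements per recorded interval.
#'
#' @param traj a \code{vicsek_trajectory}.
#' @param rp a \code{\link{render_params}} (default from the trajectory).
#' @param tau recording step, integer \code{>= 1}.
#' @return list of \code{piv_frame}s with attribute \code{tau}.
#' @export
render_sequence <- function(traj, rp = NULL, tau = 1L) {
  stopifnot(tau >= 1, tau == round(tau))
  tau <- as.integer(tau)
  idx <- seq(1L, length(traj$states), by = tau)
  frames <- lapply(idx, function(i) render_frame(traj$states[[i]], traj$params, rp))
  attr(frames, "tau") <- tau
  frames
}

#' Write / read frames as 8-bit grayscale PNG
#'
#' Files are named \code{frame_00000.png, ...} and a JSON sidecar
#' \code{frames.json} records the image side, recording step, pixel scale and
#' coordinate convention.
#'
#' @param frames list of \code{piv_frame}s (e.g. from
#'   \code{\link{render_sequence}}).
#' @param dir output directory (created if missing).
#' @export
write_frames_png <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    png::writePNG(unclass(f) / 255,
                  file.path(dir, sprintf("frame_%05d.png", i - 1L)))
  }
  meta <- list(gamma_img = nrow(frames[[1]]),
               tau = if (is.null(attr(frames, "tau"))) 1L else attr(frames, "tau"),
               px_per_unit = attr(frames[[1]], "px_per_unit"),
               fg = attr(frames[[1]], "fg"), bg = attr(frames[[1]], "bg"),
               convention = attr(frames[[1]], "convention"),
               t = vapply(frames, function(f) as.integer(attr(f, "t")), integer(1)))
  jsonlite::write_json(meta, file.path(dir, "frames.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (!length(files)) stop("no frame_*.png files in ", dir)
  metafile <- file.path(dir, "frames.json")
  meta <- if (file.exists(metafile)) jsonlite::read_json(metafile, simplifyVector = TRUE) else NULL
  frames <- lapply(seq_along(files), function(i) {
    m <- png::readPNG(files[i])
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    img <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    structure(img, class = "piv_frame",
              t = if (!is.null(meta)) meta$t[i] else i - 1L,
              px_per_unit = if (!is.null(meta)) meta$px_per_unit else NA_real_,
              fg = if (!is.null(meta)) meta$fg else 0L,
              bg = if (!is.null(meta)) meta$bg else 255L,
              convention = if (!is.null(meta)) meta$convention else NA_character_)
  })
  attr(frames, "tau") <- if (!is.null(meta)) meta$tau else 1L
  frames
}
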