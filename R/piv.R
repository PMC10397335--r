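#' PIV parameters
#'
#' The image is tiled by square interrogation grids of side \code{grid_px};
#' vectors sit on that lattice (spacing = grid side).  The search zone of a
#' grid is the grid enlarged by \code{step_px} (default: search 96 px for a
#' 64 px grid), i.e. candidate displacements are all integer \code{(k, l)}
#' with \code{|k|, |l| <= margin = step_px / 2}.
#'
#' @param grid_px interrogation grid side, pixels.
#' @param step_px search-zone enlargement, pixels (even); the per-side search
#'   margin is \code{step_px / 2}.
#' @param subpixel \code{"gaussian3"} (three-point Gaussian peak fit per axis)
#'   or \code{"none"} (integer peak).
#' @param validate \code{"normalized_median"} outlier test or \code{"none"}.
#' @param validation_threshold positive threshold of the normalized median
#'   test.
#' @return an object of class \code{piv_params}.
#' @export
piv_params <- function(grid_px = 64L, step_px = 32L,
                       subpixel = c("gaussian3", "none"),
                       validate = c("normalized_median", "none"),
                       validation_threshold = 2) {
  subpixel <- match.arg(subpixel)
  validate <- match.arg(validate)
  stopifnot(grid_px >= 1, step_px >= 2, step_px %% 2 == 0,
            validation_threshold > 0)
  structure(list(grid_px = as.integer(grid_px), step_px = as.integer(step_px),
                 search_px = as.integer(grid_px + step_px),
                 margin_px = as.integer(step_px / 2),
                 subpixel = subpixel, validate = validate,
                 validation_threshold = validation_threshold),
            class = "piv_params")
}

#' Normalized cross-correlation of one grid at one displacement
#'
#' Direct evaluation of the correlation between the \code{Z x Z} patch at
#' \code{origin} in \code{frame_t} and the patch displaced by \code{(k, l)}
#' in \code{frame_t1}: both patches are mean-subtracted, their product summed
#' and normalized by the two patch norms, giving a value in \code{[-1, 1]}.
#' Pixels are accessed periodically.  \code{k} displaces rows (y), \code{l}
#' columns (x).
#'
#' @param frame_t,frame_t1 frames (matrices) of equal size.
#' @param origin \code{c(row, col)} of the grid's top-left pixel, 1-based.
#' @param k,l integer displacement, rows and columns.
#' @param Z grid side, pixels.
#' @return the correlation value, or \code{NA} if either patch is constant
#'   (zero variance: correlation undefined).
#' @export
ncc <- function(frame_t, frame_t1, origin, k, l, Z) {
  A <- unclass(frame_t); B <- unclass(frame_t1)
  ri <- ((origin[1] - 1L + 0:(Z - 1)) %% nrow(A)) + 1L
  ci <- ((origin[2] - 1L + 0:(Z - 1)) %% ncol(A)) + 1L
  rj <- ((origin[1] - 1L + k + 0:(Z - 1)) %% nrow(B)) + 1L
  cj <- ((origin[2] - 1L + l + 0:(Z - 1)) %% ncol(B)) + 1L
  p <- A[ri, ci]; q <- B[rj, cj]
  p <- p - mean(p); q <- q - mean(q)
  den <- sqrt(sum(p^2)) * sqrt(sum(q^2))
  if (den == 0) return(NA_real_)
  sum(p * q) / den
}

# Three-point Gaussian peak interpolation along one axis.  Returns the
# subpixel offset in (-0.5, 0.5), or 0 when the fit is not applicable
# (neighbor missing/undefined, non-positive values, or degenerate curvature).
gauss3_offset <- function(cm, c0, cp) {
  if (!is.finite(cm) || !is.finite(cp) || !is.finite(c0)) return(0)
  if (cm <= 0 || c0 <= 0 || cp <= 0) return(0)
  den <- 2 * (log(cm) - 2 * log(c0) + log(cp))
  if (!is.finite(den) || den >= 0) return(0)
  d <- (log(cm) - log(cp)) / den
  max(-0.5, min(0.5, d))
}

#' Compute a PIV displacement field between two frames
#'
#' For every grid on the lattice: if the grid region at time t or the
#' corresponding search region at time t+1 contains no foreground, the grid
#' is marked invalid and no vector is produced.  Otherwise the normalized
#' cross-correlation is evaluated at every integer displacement within the
#' search margin, the argmax taken (ties broken toward the smallest
#' displacement magnitude, then lexicographically), optionally refined by a
#' three-point Gaussian fit per axis, and finally screened by the
#' normalized-median outlier test if enabled.
#'
#' Vector components: \code{u} along x (columns), \code{v} along y (rows),
#' in pixels per recorded interval.
#'
#' @param frame_t,frame_t1 frames of equal size (\code{piv_frame} or plain
#'   integer matrices).
#' @param pp a \code{\link{piv_params}}.
#' @return an object of class \code{piv_field}: a data frame with columns
#'   \code{gx, gy} (lattice indices), \code{anchor_x, anchor_y} (grid centers,
#'   px), \code{u, v} (displacement, px), \code{peak_corr}, \code{valid};
#'   attributes record the earlier frame's time index, grid size, margin,
#'   lattice shape and frame dimensions.
#' @examples
#' p <- vicsek_params(L = 2, px_per_unit = 64, N = 20, v0 = 0.05)
#' st <- init_state(p, 1)
#' f0 <- render_frame(st, p)
#' f1 <- render_frame(vicsek_step(st, p), p)
#' fld <- piv_field(f0, f1, piv_params(grid_px = 32, step_px = 16))
#' head(fld)
#' @export
piv_field <- function(frame_t, frame_t1, pp = piv_params()) {
  A <- unclass(frame_t); B <- unclass(frame_t1)
  if (!all(dim(A) == dim(B))) stop("frames have different dimensions")
  bg <- attr(frame_t, "bg"); if (is.null(bg)) bg <- 255L
  grid <- pp$grid_px; m <- pp$margin_px
  or <- seq.int(0L, nrow(A) - 1L, by = grid)
  oc <- seq.int(0L, ncol(A) - 1L, by = grid)
  origins <- expand.grid(row0 = or, col0 = oc, KEEP.OUT.ATTRS = FALSE)
  res <- piv_search_cpp(A, B, grid, m, origins$row0, origins$col0, as.integer(bg))
  valid <- res$status == 0L
  u <- as.numeric(res$l)
  v <- as.numeric(res$k)
  if (pp$subpixel == "gaussian3") {
    for (g in which(valid)) {
      v[g] <- v[g] + gauss3_offset(res$ckm[g], res$peak[g], res$ckp[g])
      u[g] <- u[g] + gauss3_offset(res$clm[g], res$peak[g], res$clp[g])
    }
  }
  d <- data.frame(gy = match(origins$row0, or),
                  gx = match(origins$col0, oc),
                  anchor_x = origins$col0 + grid / 2,
                  anchor_y = origins$row0 + grid / 2,
                  u = ifelse(valid, u, NA_real_),
                  v = ifelse(valid, v, NA_real_),
                  peak_corr = res$peak,
                  valid = valid)
  field <- structure(d, class = c("piv_field", "data.frame"),
                     t = attr(frame_t, "t"), grid_px = grid, margin_px = m,
                     nx = length(oc), ny = length(or), dims = dim(A),
                     subpixel = pp$subpixel)
  if (pp$validate == "normalized_median")
    field <- validate_vectors(field, pp$validation_threshold)
  field
}

#' Normalized-median outlier validation
#'
#' Single-pass screen: for every valid vector, the component-wise median of
#' its (up to 8, periodic-wrap) valid lattice neighbors is computed; the
#' vector's residual from that median, normalized by the median neighbor
#' residual plus \code{eps = 0.1} px, must not exceed \code{threshold}.
#' Vectors with fewer than 2 valid neighbors are kept.
#'
#' @param field a \code{\link{piv_field}}.
#' @param threshold positive residual threshold.
#' @param eps stabilizer added to the median residual, px.
#' @return the field with offending vectors flagged invalid.
#' @export
validate_vectors <- function(field, threshold = 2, eps = 0.1) {
  nx <- attr(field, "nx"); ny <- attr(field, "ny")
  valid0 <- field$valid
  if (sum(valid0) < 2L) return(field)
  idx <- matrix(seq_len(nrow(field)), nrow = ny, ncol = nx)  # [gy, gx]
  keep <- valid0
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (j in which(valid0)) {
    gy <- field$gy[j]; gx <- field$gx[j]
    nb <- idx[cbind(((gy - 1L + offs$dy) %% ny) + 1L,
                    ((gx - 1L + offs$dx) %% nx) + 1L)]
    nb <- setdiff(unique(nb), j)
    nb <- nb[valid0[nb]]
    if (length(nb) < 2L) next
    mu <- median(field$u[nb]); mv <- median(field$v[nb])
    resn <- sqrt((field$u[nb] - mu)^2 + (field$v[nb] - mv)^2)
    rj <- sqrt((field$u[j] - mu)^2 + (field$v[j] - mv)^2)
    if (rj / (median(resn) + eps) > threshold) keep[j] <- FALSE
  }
  field$valid <- keep
  field$u[!keep] <- NA_real_
  field$v[!keep] <- NA_real_
  field
}

#' @export
print.piv_field <- function(x, ...) {
  cat(sprintf("PIV field: %d x %d grids of %d px (t = %s), %d/%d valid vectors\n",
              attr(x, "ny"), attr(x, "nx"), attr(x, "grid_px"),
              format(attr(x, "t")), sum(x$valid), nrow(x)))
  if (any(x$valid))
    cat(sprintf("  mean |v| = %.2f px, mean peak corr = %.3f\n",
                mean(sqrt(x$u[x$valid]^2 + x$v[x$valid]^2)),
                mean(x$peak_corr[x$valid])))
  invisible(x)
}

#' Quiver plot of a PIV field
#'
#' Arrows start at grid anchors; the y axis is drawn downwards to match the
#' image convention (row = y, origin top-left).
#'
#' @param x a \code{piv_field}.
#' @param scale arrow magnification.
#' @param ... passed to \code{\link[graphics]{arrows}}.
#' @export
plot.piv_field <- function(x, scale = 3, ...) {
  dims <- attr(x, "dims")
  plot(NA, xlim = c(0, dims[2]), ylim = c(dims[1], 0), asp = 1,
       xlab = "x (px)", ylab = "y (px)", main = "PIV field")
  ok <- x$valid & (x$u^2 + x$v^2) > 0
  if (any(ok))
    arrows(x$anchor_x[ok], x$anchor_y[ok],
           x$anchor_x[ok] + scale * x$u[ok],
           x$anchor_y[ok] + scale * x$v[ok],
           length = 0.05, ...)
  points(x$anchor_x[!x$valid], x$anchor_y[!x$valid], pch = 4, cex = 0.5)
  invisible(x)
}

#' Write / read a PIV field as CSV
#'
#' Columns \code{t, anchor_x_px, anchor_y_px, u_px, v_px, peak_corr, valid}.
#'
#' @param field a \code{piv_field}.
#' @param path file path.
#' @export
write_piv_csv <- function(field, path) {
  tt <- attr(field, "t"); if (is.null(tt)) tt <- NA_integer_
  df <- data.frame(t = tt, anchor_x_px = field$anchor_x,
                   anchor_y_px = field$anchor_y, u_px = field$u,
                   v_px = field$v, peak_corr = field$peak_corr,
                   valid = field$valid)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_piv_csv
#' @export
read_piv_csv <- function(path) {
  read.csv(path)
}
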