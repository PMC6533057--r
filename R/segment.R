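#' Segment the nuclear envelope
#'
#' Reconstructs the nuclear surface from the envelope (rim) channel:
#'
#' 1. a robust center estimate from the intensity-weighted centroid of
#'    above-median signal;
#' 2. per z-slice radial ridge detection -- rays cast from the center at
#'    `n_theta` in-plane angles, the shell ridge located as the
#'    quadratically interpolated intensity maximum along each ray;
#' 3. a robust least-squares ellipsoid fit ([fit_ellipsoid()]) to the
#'    boundary point cloud.
#'
#' Ridge points are accepted only when their peak intensity exceeds
#' `min_peak_frac` of the channel's robust maximum, which drops z-slices
#' outside the nucleus. The fitted surface's residual is reported; the
#' boundary point cloud is retained for oracle cross-checks.
#'
#' @param stack a `nucperi_stack`.
#' @param channel channel holding the rim signal (default `"envelope"`).
#' @param n_theta rays per z-slice (default 24).
#' @param min_points minimum accepted ridge points (default 30); fewer
#'   raises a `nucperi_poor_envelope_fit` error.
#' @param residual_threshold maximum RMS fit residual in um (default 0.25);
#'   above it a `nucperi_poor_envelope_fit` error is raised.
#' @param min_peak_frac minimum ridge peak intensity as a fraction of the
#'   robust (99.9th percentile) channel maximum (default 0.5).
#' @return list of class `nucperi_surface`: `center`, `semiaxes`,
#'   `rotation`, `boundary_points` (n x 3, um), `fit_residual_um`,
#'   `method_tag`.
#' @export
segment_envelope <- function(stack, channel = "envelope", n_theta = 24,
                             min_points = 30, residual_threshold = 0.25,
                             min_peak_frac = 0.5) {
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("stack has no '", channel, "' channel")
  pitch <- stack$voxel_pitch
  d <- dim(img)
  bg <- stats::median(img)
  w <- pmax(img - bg, 0)
  if (sum(w) <= 0) poor_fit_stop("envelope channel carries no signal")
  zc <- axis_coords(d[1], pitch[1])
  yc <- axis_coords(d[2], pitch[2])
  xc <- axis_coords(d[3], pitch[3])
  wz <- apply(w, 1, sum); wy <- apply(w, 2, sum); wx <- apply(w, 3, sum)
  center0 <- c(sum(wz * zc) / sum(wz), sum(wy * yc) / sum(wy),
               sum(wx * xc) / sum(wx))
  robust_max <- stats::quantile(img, 0.999, names = FALSE)
  if (robust_max - bg <= 0) poor_fit_stop("envelope channel is flat")
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  step <- min(pitch[2], pitch[3]) / 2
  r_max <- sqrt((d[2] * pitch[2])^2 + (d[3] * pitch[3])^2) / 2
  r_grid <- seq(step, r_max, by = step)
  pts <- list()
  for (iz in seq_len(d[1])) {
    slice <- img[iz, , ]
    if (max(slice) - bg < min_peak_frac * (robust_max - bg)) next
    for (th in theta) {
      ys <- center0[2] + r_grid * sin(th)
      xs <- center0[3] + r_grid * cos(th)
      v <- bilinear(slice, ys / pitch[2] + 0.5, xs / pitch[3] + 0.5)
      ok <- !is.na(v)
      if (!any(ok)) next
      vi <- v[ok]; ri <- r_grid[ok]
      j <- which.max(vi)
      if (vi[j] - bg < min_peak_frac * (robust_max - bg)) next
      r_peak <- ri[j]
      if (j > 1 && j < length(vi)) {  # quadratic sub-sample refinement
        den <- vi[j - 1] - 2 * vi[j] + vi[j + 1]
        if (den < 0) {
          r_peak <- ri[j] + 0.5 * step * (vi[j - 1] - vi[j + 1]) / den
        }
      }
      pts[[length(pts) + 1]] <- c(zc[iz],
                                  center0[2] + r_peak * sin(th),
                                  center0[3] + r_peak * cos(th))
    }
  }
  if (length(pts) < min_points) {
    poor_fit_stop(sprintf("only %d ridge points found (need >= %d)",
                          length(pts), min_points))
  }
  bp <- do.call(rbind, pts)
  fit <- tryCatch(fit_ellipsoid(bp),
                  error = function(e) poor_fit_stop(conditionMessage(e)))
  if (fit$residual_um > residual_threshold) {
    poor_fit_stop(sprintf("fit residual %.3f um exceeds %.3f um",
                          fit$residual_um, residual_threshold))
  }
  structure(list(center = fit$center, semiaxes = fit$semiaxes,
                 rotation = fit$rotation, boundary_points = bp,
                 fit_residual_um = fit$residual_um,
                 method_tag = "radial_ridge+robust_ellipsoid"),
            class = "nucperi_surface")
}

poor_fit_stop <- function(msg) {
  stop(structure(class = c("nucperi_poor_envelope_fit", "error", "condition"),
                 list(message = paste0("poor_envelope_fit: ", msg),
                      call = NULL)))
}

#' @export
print.nucperi_surface <- function(x, ...) {
  cat(sprintf("nuclear surface: center (%.2f, %.2f, %.2f) um, semi-axes (%.2f, %.2f, %.2f) um, residual %.3f um (%d boundary points)\n",
              x$center[1], x$center[2], x$center[3],
              x$semiaxes[1], x$semiaxes[2], x$semiaxes[3],
              x$fit_residual_um, nrow(x$boundary_points)))
  invisible(x)
}

# Bilinear interpolation on a 2D matrix at fractional (row, col) voxel
# coordinates (voxel-center convention: center of cell (i,j) is (i, j)).
# Returns NA outside the grid.
bilinear <- function(mat, ri, ci) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- rep(NA_real_, length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  if (!any(ok)) return(out)
  r <- ri[ok]; cc <- ci[ok]
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(cc), nc - 1)
  fr <- r - r0; fc <- cc - c0
  v <- (1 - fr) * (1 - fc) * mat[cbind(r0, c0)] +
    fr * (1 - fc) * mat[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * mat[cbind(r0, c0 + 1)] +
    fr * fc * mat[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v
  out
}
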