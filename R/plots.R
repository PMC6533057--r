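#' Quartile boxplot of distance distributions by condition
#'
#' Renders the assay's standard figure: per-condition quartile boxplots of
#' focus-to-periphery distances (median as a thick segment).
#'
#' @param records distance-record data.frame with `condition`.
#' @param ... passed to [graphics::boxplot()].
#' @return invisible boxplot statistics.
#' @export
plot_distance_boxplot <- function(records, ...) {
  conds <- sort(unique(records$condition))
  vals <- lapply(conds, function(cc)
    usable_distances(records[records$condition == cc, ]))
  names(vals) <- conds
  bp <- graphics::boxplot(vals, ylab = "distance to periphery (um)",
                          medlwd = 3, ...)
  invisible(bp)
}

#' MSD curves with standard errors per group
#'
#' @param curves named list of `nucperi_msd` curves (one per group).
#' @param col colors, one per group.
#' @param ... passed to [graphics::plot()].
#' @return invisible NULL.
#' @export
plot_msd <- function(curves, col = seq_along(curves), ...) {
  ymax <- max(vapply(curves, function(cu)
    max(cu$msd_um2 + ifelse(is.na(cu$sem_um2), 0, cu$sem_um2)), 1))
  graphics::plot(NA, xlim = c(0, max(curves[[1]]$lag_s)), ylim = c(0, ymax),
                 xlab = "lag (s)", ylab = "MSD (um^2)", ...)
  for (i in seq_along(curves)) {
    cu <- curves[[i]]
    graphics::lines(cu$lag_s, cu$msd_um2, col = col[i], lwd = 2)
    sem <- ifelse(is.na(cu$sem_um2), 0, cu$sem_um2)
    graphics::arrows(cu$lag_s, cu$msd_um2 - sem, cu$lag_s, cu$msd_um2 + sem,
                     angle = 90, code = 3, length = 0.02, col = col[i])
  }
  if (!is.null(names(curves))) {
    graphics::legend("bottomright", legend = names(curves), col = col,
                     lwd = 2, bty = "n")
  }
  invisible(NULL)
}

#' Trace a 3D track colored by time (2D projection)
#'
#' Mirrors the time-colored track tracings of single-locus imaging: the
#' (y, x) projection of one trajectory, segments colored from early (blue)
#' to late (red).
#'
#' @param traj a trajectory data.frame.
#' @param ... passed to [graphics::plot()].
#' @return invisible NULL.
#' @export
plot_track <- function(traj, ...) {
  ok <- stats::complete.cases(traj[, c("y_um", "x_um")])
  y <- traj$y_um[ok]; x <- traj$x_um[ok]
  n <- length(x)
  cols <- grDevices::hcl.colors(max(n - 1, 1), "Blue-Red")
  graphics::plot(x, y, type = "n", xlab = "x (um)", ylab = "y (um)",
                 asp = 1, ...)
  graphics::segments(x[-n], y[-n], x[-1], y[-1], col = cols, lwd = 2)
  invisible(NULL)
}
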