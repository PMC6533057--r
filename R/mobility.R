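#' Assemble per-frame detections into a trajectory
#'
#' Builds the single-locus track of one cell from time-stamped per-frame
#' focus detections and nucleus centroids. Frames are sorted by time;
#' frames with no accepted focus become gaps (NA positions) and any
#' displacement pair spanning a gap is excluded downstream.
#'
#' @param detections data.frame: frame, t_s, z_um, y_um, x_um (NA rows or
#'   missing frames mark failed detections).
#' @param centroids data.frame: frame, cz_um, cy_um, cx_um (the per-frame
#'   nucleus centroid used for drift correction), or NULL.
#' @param cell_id identifier attached to the trajectory.
#' @return data.frame of class `nucperi_trajectory`: frame, t_s, z_um,
#'   y_um, x_um, cz_um, cy_um, cx_um; attribute `gaps` lists gap frames.
#' @export
build_trajectory <- function(detections, centroids = NULL,
                             cell_id = "cell") {
  req <- c("frame", "t_s", "z_um", "y_um", "x_um")
  if (!all(req %in% names(detections))) {
    stop("detections need columns: ", paste(req, collapse = ", "))
  }
  det <- detections[order(detections$t_s), req]
  if (anyDuplicated(det$t_s)) stop("duplicate timestamps in detections")
  if (!is.null(centroids)) {
    det <- merge(det, centroids[, c("frame", "cz_um", "cy_um", "cx_um")],
                 by = "frame", all.x = TRUE, sort = FALSE)
    det <- det[order(det$t_s), ]
  } else {
    det$cz_um <- det$cy_um <- det$cx_um <- NA_real_
  }
  valid <- stats::complete.cases(det[, c("z_um", "y_um", "x_um")])
  if (sum(valid) < 2) stop("trajectory needs >= 2 valid frames")
  rownames(det) <- NULL
  structure(det, class = c("nucperi_trajectory", "data.frame"),
            cell_id = cell_id, gaps = det$frame[!valid])
}

#' Drift-correct a trajectory
#'
#' Replaces each position by (position - nucleus centroid), removing
#' whole-nucleus motion, and attaches a stationarity score -- the total
#' path length of the centroid (um) -- so callers can also filter for
#' "nearly stationary nuclei" as the original selection did.
#'
#' @param traj a `nucperi_trajectory` with centroid columns present at
#'   every valid frame.
#' @return corrected trajectory; attributes `stationarity_um` (total
#'   centroid displacement) and `drift_corrected = TRUE`.
#' @export
drift_correct <- function(traj) {
  valid <- stats::complete.cases(traj[, c("z_um", "y_um", "x_um")])
  cen <- as.matrix(traj[, c("cz_um", "cy_um", "cx_um")])
  if (any(valid & !stats::complete.cases(cen))) {
    stop("missing nucleus centroid at a valid frame")
  }
  out <- traj
  out$z_um <- traj$z_um - cen[, 1]
  out$y_um <- traj$y_um - cen[, 2]
  out$x_um <- traj$x_um - cen[, 3]
  cc <- cen[stats::complete.cases(cen), , drop = FALSE]
  score <- if (nrow(cc) >= 2) sum(sqrt(rowSums(diff(cc)^2))) else 0
  attr(out, "stationarity_um") <- score
  attr(out, "drift_corrected") <- TRUE
  out
}

# Time-averaged MSD of one track at lags 1..max_lag (frames), using all
# overlapping valid pairs; pairs spanning gaps (NA) are dropped.
msd_track <- function(pos, max_lag) {
  n <- nrow(pos)
  vapply(seq_len(max_lag), function(k) {
    d <- pos[seq_len(n - k) + k, , drop = FALSE] -
      pos[seq_len(n - k), , drop = FALSE]
    sq <- rowSums(d^2)
    if (all(is.na(sq))) NA_real_ else mean(sq, na.rm = TRUE)
  }, 1)
}

#' Ensemble mean-squared displacement across cells
#'
#' Per-track time-averaged MSD at each lag (mean over all overlapping valid
#' pairs of \eqn{|r(t+k\Delta t) - r(t)|^2}), then the unweighted mean and
#' standard error across tracks -- the convention matching error bars that
#' represent the standard error over >= 20 cells. Lags are limited to
#' `max_lag_fraction` of the shortest track.
#'
#' @param trajectories list of `nucperi_trajectory` (or data.frames with
#'   t_s, z_um, y_um, x_um).
#' @param max_lag_fraction usable lag fraction in (0, 1], default 0.5.
#' @param dims 3 for 3D MSD (default), 2 to use only (y, x).
#' @return data.frame of class `nucperi_msd`: lag_s, msd_um2, sem_um2,
#'   n_tracks; attribute `dt_s`.
#' @export
msd_ensemble <- function(trajectories, max_lag_fraction = 0.5, dims = 3) {
  if (length(trajectories) < 1) stop("need >= 1 trajectory")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1) {
    stop("max_lag_fraction must be in (0, 1]")
  }
  lens <- vapply(trajectories, nrow, 1L)
  dt <- diff(trajectories[[1]]$t_s[1:2])
  max_lag <- max(1L, floor(max_lag_fraction * (min(lens) - 1)))
  cols <- if (dims == 3) c("z_um", "y_um", "x_um") else c("y_um", "x_um")
  per_track <- vapply(trajectories, function(tr) {
    msd_track(as.matrix(tr[, cols]), max_lag)
  }, numeric(max_lag))
  per_track <- matrix(per_track, nrow = max_lag)
  msd <- apply(per_track, 1, mean, na.rm = TRUE)
  ntr <- apply(per_track, 1, function(v) sum(!is.na(v)))
  sem <- apply(per_track, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  keep <- ntr > 0
  structure(data.frame(lag_s = (seq_len(max_lag) * dt)[keep],
                       msd_um2 = msd[keep], sem_um2 = sem[keep],
                       n_tracks = ntr[keep]),
            class = c("nucperi_msd", "data.frame"),
            dt_s = dt, dims = dims,
            dropped_lags = sum(!keep))
}

#' Estimate the MSD plateau
#'
#' Default method fits the confined-diffusion saturation form
#' \eqn{MSD(\tau) = P (1 - e^{-\tau/\tau_c})} by nonlinear least squares
#' and returns the plateau P; the fallback (`method = "tail_mean"`) returns
#' the mean of the last third of lags. The fit is declared non-converged
#' when it fails or when the fitted \eqn{\tau_c} exceeds one third of the
#' lag window (the curve is still rising, e.g. free diffusion), in which
#' case callers may fall back to `tail_mean`.
#'
#' @param curve a `nucperi_msd` data.frame (>= 4 lags for the fit).
#' @param method `"exp_fit"` (default) or `"tail_mean"`.
#' @return list: `plateau_um2`, `tau_c_s` (NA for tail_mean), `converged`,
#'   `method`.
#' @export
estimate_plateau <- function(curve, method = c("exp_fit", "tail_mean")) {
  method <- match.arg(method)
  lag <- curve$lag_s
  msd <- curve$msd_um2
  if (method == "tail_mean") {
    k <- max(1L, ceiling(length(lag) / 3))
    tail_idx <- seq(length(lag) - k + 1, length(lag))
    return(list(plateau_um2 = mean(msd[tail_idx]), tau_c_s = NA_real_,
                converged = TRUE, method = method))
  }
  if (length(lag) < 4) stop("exp_fit needs >= 4 lags")
  window <- max(lag)
  if (stats::sd(msd) < 1e-14) {  # constant curve: plateau is that constant
    return(list(plateau_um2 = mean(msd), tau_c_s = 0, converged = TRUE,
                method = method))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      msd ~ P * (1 - exp(-lag / tc)),
      start = list(P = max(msd), tc = lag[2]),
      lower = c(1e-12, 1e-6), upper = c(Inf, 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    k <- max(1L, ceiling(length(lag) / 3))
    tail_idx <- seq(length(lag) - k + 1, length(lag))
    return(list(plateau_um2 = mean(msd[tail_idx]), tau_c_s = NA_real_,
                converged = FALSE, method = "tail_mean_fallback"))
  }
  cf <- stats::coef(fit)
  list(plateau_um2 = unname(cf["P"]), tau_c_s = unname(cf["tc"]),
       converged = unname(cf["tc"]) <= window / 3, method = method)
}

#' Radius of constraint from an MSD plateau
#'
#' Converts the MSD plateau P to the radius Rc of the explored region using
#' the mean squared separation of two independent uniform points:
#' \eqn{E|X-Y|^2 = 6R^2/5} in a ball (3D) and \eqn{R^2} in a disc (2D),
#' so \eqn{Rc = \sqrt{5P/6}} (3D) or \eqn{\sqrt{P}} (2D). The convention is
#' a switch so alternative plateau conventions can be cross-compared.
#'
#' @param plateau_um2 plateau P in um^2 (>= 0).
#' @param dims 2 or 3.
#' @param convention `"uniform_ball"` (default, above) or `"harmonic"`
#'   (plateau = 4R^2/5 variant sometimes used for spring-like confinement).
#' @return Rc in um.
#' @export
radius_of_constraint <- function(plateau_um2, dims = 3,
                                 convention = c("uniform_ball", "harmonic")) {
  convention <- match.arg(convention)
  if (plateau_um2 < 0) stop("plateau must be >= 0")
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  if (convention == "uniform_ball") {
    if (dims == 3) sqrt(5 * plateau_um2 / 6) else sqrt(plateau_um2)
  } else {
    sqrt(5 * plateau_um2 / 4)
  }
}

#' Volume searched by the locus
#'
#' @param rc_um radius of constraint in um (>= 0).
#' @return V = (4/3) pi Rc^3 in um^3.
#' @export
volume_searched <- function(rc_um) {
  if (any(rc_um < 0)) stop("Rc must be >= 0")
  4 / 3 * pi * rc_um^3
}

#' Summarize mobility of one group of tracks
#'
#' Ensemble MSD, plateau, radius of constraint and explored volume for one
#' strain/condition group.
#'
#' @param trajectories list of trajectories (drift-corrected).
#' @param max_lag_fraction see [msd_ensemble()].
#' @param dims 2 or 3.
#' @param convention Rc convention, see [radius_of_constraint()].
#' @return list of class `nucperi_mobility`: `msd` (curve), `plateau_um2`,
#'   `rc_um`, `volume_um3`, `plateau_method`, `converged`, `n_cells`.
#' @export
mobility_summary <- function(trajectories, max_lag_fraction = 0.5, dims = 3,
                             convention = "uniform_ball") {
  curve <- msd_ensemble(trajectories, max_lag_fraction, dims)
  pl <- estimate_plateau(curve)
  rc <- radius_of_constraint(pl$plateau_um2, dims, convention)
  structure(list(msd = curve, plateau_um2 = pl$plateau_um2,
                 rc_um = rc, volume_um3 = volume_searched(rc),
                 plateau_method = pl$method, converged = pl$converged,
                 n_cells = length(trajectories)),
            class = "nucperi_mobility")
}

#' @export
print.nucperi_mobility <- function(x, ...) {
  cat(sprintf("mobility over %d cells: plateau %.4f um^2, Rc %.3f um, V %.3f um^3 (%s%s)\n",
              x$n_cells, x$plateau_um2, x$rc_um, x$volume_um3,
              x$plateau_method,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Compare locus mobility between two groups
#'
#' Per-cell mobility statistic (the plateau of each cell's time-averaged
#' MSD; tail-mean fallback when the saturation fit does not converge)
#' compared by a two-tailed Mann-Whitney test, plus group mobility
#' summaries and the explored-volume fold change V_A / V_B.
#'
#' @param group_a,group_b lists of trajectories.
#' @param max_lag_fraction,dims,convention see [mobility_summary()].
#' @return list of class `nucperi_mobility_comparison`: `summary_a`,
#'   `summary_b`, `per_cell_a`, `per_cell_b`, `test` (a `nucperi_test`),
#'   `volume_fold`, `rc_ratio`, `small_group_warning`.
#' @export
compare_mobility <- function(group_a, group_b, max_lag_fraction = 0.5,
                             dims = 3, convention = "uniform_ball") {
  if (length(group_a) < 1 || length(group_b) < 1) {
    stop("both groups must be non-empty")
  }
  per_cell <- function(group) {
    vapply(group, function(tr) {
      curve <- msd_ensemble(list(tr), max_lag_fraction, dims)
      pl <- estimate_plateau(curve)
      if (!pl$converged) {
        pl <- estimate_plateau(curve, method = "tail_mean")
      }
      pl$plateau_um2
    }, 1)
  }
  pa <- per_cell(group_a)
  pb <- per_cell(group_b)
  sa <- mobility_summary(group_a, max_lag_fraction, dims, convention)
  sb <- mobility_summary(group_b, max_lag_fraction, dims, convention)
  test <- mann_whitney(pa, pb)
  structure(list(summary_a = sa, summary_b = sb,
                 per_cell_a = pa, per_cell_b = pb, test = test,
                 volume_fold = sa$volume_um3 / sb$volume_um3,
                 rc_ratio = sa$rc_um / sb$rc_um,
                 small_group_warning = length(pa) < 3 || length(pb) < 3),
            class = "nucperi_mobility_comparison")
}

#' @export
print.nucperi_mobility_comparison <- function(x, ...) {
  cat(sprintf("group A: Rc %.3f um, V %.3f um^3 (n=%d)\n",
              x$summary_a$rc_um, x$summary_a$volume_um3, x$summary_a$n_cells))
  cat(sprintf("group B: Rc %.3f um, V %.3f um^3 (n=%d)\n",
              x$summary_b$rc_um, x$summary_b$volume_um3, x$summary_b$n_cells))
  cat(sprintf("volume fold A/B: %.2f; Mann-Whitney U = %g, two-tailed p = %.4g\n",
              x$volume_fold, x$test$statistic, x$test$p_two_tailed))
  if (x$small_group_warning) cat("warning: a group has fewer than 3 cells\n")
  invisible(x)
}

#' Extract trajectories of a time-lapse dataset by tracking each frame
#'
#' Runs focus detection on every frame of each time-lapse entry of a
#' manifest and assembles per-cell trajectories. The nucleus centroid of
#' each frame is the intensity-weighted centroid of the envelope channel
#' (used for drift correction). Frames where detection fails become gaps.
#'
#' @param manifest manifest list or path (time-lapse mode).
#' @param psf_sigma PSF sigmas for detection.
#' @param correct_drift apply [drift_correct()] to each track
#'   (default TRUE).
#' @return data.frame in the track-table schema (one row per cell x frame).
#' @export
track_dataset <- function(manifest, psf_sigma = c(0.35, 0.13, 0.13),
                          correct_drift = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  entries <- manifest$entries
  entries <- entries[order(vapply(entries, function(e) e$cell_id, ""))]
  dt <- manifest$frame_interval_s %||% 12
  out <- list()
  for (e in entries) {
    if (!identical(e$type, "timelapse")) next
    n <- length(e$frames)
    det <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) * dt,
                      z_um = NA_real_, y_um = NA_real_, x_um = NA_real_)
    cen <- data.frame(frame = seq_len(n), cz_um = NA_real_,
                      cy_um = NA_real_, cx_um = NA_real_)
    for (f in seq_len(n)) {
      entry_f <- list(cell_id = e$cell_id,
                      voxel_pitch_um = e$voxel_pitch_um,
                      channels = e$frames[[f]]$channels,
                      scale = e$frames[[f]]$scale)
      stack <- read_stack(manifest$dir, entry_f)
      fo <- detect_focus(stack, psf_sigma = psf_sigma)
      if (fo$found) det[f, c("z_um", "y_um", "x_um")] <- fo$position
      cen[f, c("cz_um", "cy_um", "cx_um")] <-
        intensity_centroid(stack, "envelope")
    }
    traj <- build_trajectory(det, cen, cell_id = e$cell_id)
    if (correct_drift) traj <- drift_correct(traj)
    traj$cell_id <- e$cell_id
    traj$condition <- e$condition %||% NA_character_
    out[[length(out) + 1]] <- as.data.frame(traj)
  }
  if (!length(out)) stop("manifest contains no time-lapse entries")
  do.call(rbind, out)
}

# Intensity-weighted centroid of one channel, physical um.
intensity_centroid <- function(stack, channel = "envelope") {
  img <- stack$channels[[channel]]
  pitch <- stack$voxel_pitch
  d <- dim(img)
  w <- pmax(img - stats::median(img), 0)
  tw <- sum(w)
  if (tw <= 0) return(rep(NA_real_, 3))
  c(sum(apply(w, 1, sum) * axis_coords(d[1], pitch[1])),
    sum(apply(w, 2, sum) * axis_coords(d[2], pitch[2])),
    sum(apply(w, 3, sum) * axis_coords(d[3], pitch[3]))) / tw
}

#' Split a track table into per-cell trajectories
#'
#' @param tracks track-table data.frame (see [read_tracks()]).
#' @return named list of trajectories, ordered by cell_id.
#' @export
split_tracks <- function(tracks) {
  ids <- sort(unique(tracks$cell_id))
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$cell_id == id, ]
    tr <- tr[order(tr$t_s), ]
    rownames(tr) <- NULL
    tr
  })
  names(out) <- ids
  out
}
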