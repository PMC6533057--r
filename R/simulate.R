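#' @title Synthetic two-channel nuclear z-stacks with ground truth
#' @description
#' Renders one synthetic still image of a yeast nucleus: channel `envelope`
#' is a Gaussian-profile shell concentrated at the nuclear surface (the
#' Nup49-GFP-like rim), channel `locus` a single PSF-blurred diffraction
#' limited focus. Poisson shot noise followed by additive Gaussian read
#' noise is applied unless `cfg$noise` is FALSE. The returned ground truth
#' carries the exact focus position and the analytic focus-to-surface
#' distance, so downstream measurements can be validated independently.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `stack` (class `nucperi_stack`) and `truth` (list:
#'   `focus_position`, `center`, `semiaxes`, `rotation`, `distance_um`,
#'   `seed`).
#' @export
simulate_nucleus_stack <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  focus <- if (is.character(cfg$focus_position)) {
    sample_focus_position(cfg)
  } else {
    as.numeric(cfg$focus_position)
  }
  env <- render_envelope(cfg)
  loc <- render_focus(cfg, focus)
  if (cfg$noise) {
    env <- add_noise(env, cfg)
    loc <- add_noise(loc, cfg)
  } else {
    env <- env + cfg$background
    loc <- loc + cfg$background
  }
  stack <- new_stack(list(envelope = env, locus = loc), cfg$voxel_pitch,
                     cell_id = "sim")
  d <- point_ellipsoid_distance(focus, cfg$nucleus_center,
                                cfg$nucleus_semiaxes)
  truth <- list(focus_position = focus,
                center = cfg$nucleus_center,
                semiaxes = cfg$nucleus_semiaxes,
                rotation = diag(3),
                distance_um = d$distance,
                inside = d$inside,
                seed = cfg$seed)
  list(stack = stack, truth = truth)
}

# Voxel-center physical coordinates along each axis (um). Voxel i has its
# center at (i - 0.5) * pitch from the stack corner (1-based i).
axis_coords <- function(n, pitch) (seq_len(n) - 0.5) * pitch

# Envelope shell: Gaussian radial profile around the ellipsoid surface,
# sigma = FWHM / 2.355. The profile already represents the optically
# blurred rim; no further PSF convolution is applied.
render_envelope <- function(cfg) {
  sh <- cfg$stack_shape
  zc <- axis_coords(sh[1], cfg$voxel_pitch[1])
  yc <- axis_coords(sh[2], cfg$voxel_pitch[2])
  xc <- axis_coords(sh[3], cfg$voxel_pitch[3])
  pts <- cbind(rep(zc, times = sh[2] * sh[3]),
               rep(rep(yc, each = sh[1]), times = sh[3]),
               rep(xc, each = sh[1] * sh[2]))
  d <- ellipsoid_signed_distance_approx(pts, cfg$nucleus_center,
                                        cfg$nucleus_semiaxes)
  sig <- cfg$shell_thickness / 2.355
  array(cfg$envelope_intensity * exp(-d^2 / (2 * sig^2)), dim = sh)
}

# Diffraction-limited focus: separable anisotropic Gaussian with peak
# amplitude focus_intensity at the focus position.
render_focus <- function(cfg, focus) {
  sh <- cfg$stack_shape
  gz <- exp(-(axis_coords(sh[1], cfg$voxel_pitch[1]) - focus[1])^2 /
              (2 * cfg$psf_sigma[1]^2))
  gy <- exp(-(axis_coords(sh[2], cfg$voxel_pitch[2]) - focus[2])^2 /
              (2 * cfg$psf_sigma[2]^2))
  gx <- exp(-(axis_coords(sh[3], cfg$voxel_pitch[3]) - focus[3])^2 /
              (2 * cfg$psf_sigma[3]^2))
  cfg$focus_intensity * outer(outer(gz, gy), gx)
}

# Poisson shot noise on signal + background, then Gaussian read noise.
add_noise <- function(signal, cfg) {
  n <- length(signal)
  out <- stats::rpois(n, lambda = as.vector(signal) + cfg$background)
  if (cfg$read_noise_sd > 0) {
    out <- out + stats::rnorm(n, 0, cfg$read_noise_sd)
  }
  array(out, dim = dim(signal))
}

#' Simulate a confined-diffusion trajectory
#'
#' Discrete Brownian motion (per-axis increment variance 2*D*dt) confined to
#' a reflecting sphere of radius `confinement_radius` centered on the
#' nucleus center, with optional harmonic tethering toward a peripheral
#' shell. Overshoots past the boundary are specularly reflected across the
#' boundary normal. When the configured frame interval would violate the
#' reflection scheme's step-size validity (D*dt > (R/5)^2), each frame is
#' internally subdivided into the smallest number of sub-steps restoring
#' validity; positions are recorded at the frame interval. With
#' `confinement_radius = Inf` reflection is disabled (free diffusion).
#'
#' @param cfg a [sim_config()] object (`n_frames`, `frame_interval`,
#'   `diffusion_coefficient`, `confinement_radius`, `tether*` fields used).
#' @param start optional (z, y, x) um start position; default: sampled from
#'   the placement law, clipped into the confinement sphere.
#' @param n_substeps override the automatic sub-step count; an explicit
#'   value violating the validity guard D*dt <= (R/5)^2 is an error
#'   demanding a finer time step.
#' @return list with `trajectory` (data.frame: frame, t_s, z_um, y_um, x_um
#'   -- positions in the nucleus frame, um) and `truth` (true_D, true_Rc,
#'   n_substeps).
#' @export
simulate_confined_trajectory <- function(cfg, start = NULL,
                                         n_substeps = NULL) {
  if (cfg$n_frames < 2) stop("n_frames must be >= 2")
  D <- cfg$diffusion_coefficient
  R <- cfg$confinement_radius
  dt_frame <- cfg$frame_interval
  n_sub <- 1L
  if (is.finite(R) && D > 0) {
    n_sub <- max(1L, as.integer(ceiling(D * dt_frame / (R / 5)^2)))
  }
  if (!is.null(n_substeps)) n_sub <- as.integer(n_substeps)
  if (is.finite(R) && D * dt_frame / n_sub > (R / 5)^2 + 1e-12) {
    stop("step size D*dt exceeds (R/5)^2; use a finer time step ",
         "(more sub-steps) to keep the reflection scheme valid")
  }
  dt <- dt_frame / n_sub
  set.seed(cfg$seed)
  ctr <- cfg$nucleus_center
  if (is.null(start)) {
    start <- if (is.character(cfg$focus_position)) {
      sample_focus_position(cfg)
    } else {
      as.numeric(cfg$focus_position)
    }
    # clip into the confinement sphere
    if (is.finite(R)) {
      v <- start - ctr
      r <- sqrt(sum(v^2))
      if (r > R) start <- ctr + v / r * R * 0.99
    }
  }
  n_steps <- (cfg$n_frames - 1L) * n_sub
  sd_step <- sqrt(2 * D * dt)
  steps <- matrix(stats::rnorm(3 * n_steps, 0, sd_step), ncol = 3)
  pos <- matrix(NA_real_, nrow = cfg$n_frames, ncol = 3)
  pos[1, ] <- start
  p <- start - ctr                       # work relative to nucleus center
  a_eff <- min(cfg$nucleus_semiaxes)
  for (s in seq_len(n_steps)) {
    p <- p + steps[s, ]
    if (cfg$tether == "peripheral") {
      r <- sqrt(sum(p^2))
      if (r > 1e-12) {
        depth <- a_eff - r               # current depth below the surface
        p <- p + cfg$tether_stiffness * (depth - cfg$tether_depth) * dt *
          (p / r)
      }
    }
    if (is.finite(R)) {
      for (k in 1:10) {                  # radial specular reflection of the
        r <- sqrt(sum(p^2))              # overshoot; repeat if still outside
        if (r <= R) break
        p <- p * (2 * R - r) / r         # r -> 2R - r (guard keeps r < 2R)
      }
      r <- sqrt(sum(p^2))
      if (r > R) p <- p / r * R          # numeric safety net
    }
    if (s %% n_sub == 0) pos[s / n_sub + 1L, ] <- p + ctr
  }
  traj <- data.frame(frame = seq_len(cfg$n_frames),
                     t_s = (seq_len(cfg$n_frames) - 1) * dt_frame,
                     z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3])
  list(trajectory = traj,
       truth = list(true_D = D, true_Rc = R, n_substeps = n_sub,
                    start = start, seed = cfg$seed))
}

#' Simulate a time-lapse of nuclear stacks
#'
#' Draws one confined-diffusion trajectory, then renders each frame as a
#' two-channel stack with optional whole-nucleus drift applied to both the
#' envelope and the locus. Ground truth carries the per-frame focus
#' position, nucleus centroid and analytic focus-to-surface distance.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `frames` (list of `nucperi_stack`), `trajectory`
#'   (nucleus-frame positions as in [simulate_confined_trajectory()]) and
#'   `truth` (per-frame data.frame: frame, t_s, focus and centroid
#'   coordinates, distance_um; plus true_D, true_Rc).
#' @export
simulate_timelapse <- function(cfg) {
  validate_sim_config(cfg)
  sim <- simulate_confined_trajectory(cfg)
  traj <- sim$trajectory
  n <- cfg$n_frames
  frames <- vector("list", n)
  tr <- data.frame(frame = traj$frame, t_s = traj$t_s,
                   z_um = NA_real_, y_um = NA_real_, x_um = NA_real_,
                   cz_um = NA_real_, cy_um = NA_real_, cx_um = NA_real_,
                   distance_um = NA_real_)
  for (f in seq_len(n)) {
    drift <- (f - 1) * cfg$nucleus_drift_per_frame
    ctr_f <- cfg$nucleus_center + drift
    focus_f <- c(traj$z_um[f], traj$y_um[f], traj$x_um[f]) + drift
    cfg_f <- cfg
    cfg_f$nucleus_center <- ctr_f
    env <- render_envelope(cfg_f)
    loc <- render_focus(cfg_f, focus_f)
    if (cfg$noise) {
      env <- add_noise(env, cfg)
      loc <- add_noise(loc, cfg)
    } else {
      env <- env + cfg$background
      loc <- loc + cfg$background
    }
    frames[[f]] <- new_stack(list(envelope = env, locus = loc),
                             cfg$voxel_pitch,
                             cell_id = sprintf("sim_f%03d", f))
    d <- point_ellipsoid_distance(focus_f, ctr_f, cfg$nucleus_semiaxes)
    tr[f, c("z_um", "y_um", "x_um")] <- focus_f
    tr[f, c("cz_um", "cy_um", "cx_um")] <- ctr_f
    tr$distance_um[f] <- d$distance
  }
  list(frames = frames, trajectory = traj,
       truth = list(per_frame = tr, true_D = cfg$diffusion_coefficient,
                    true_Rc = cfg$confinement_radius, seed = cfg$seed))
}

#' Simulate a ground-truthed population dataset on disk
#'
#' Writes `n_cells` independent stills or time-lapses under `dir`, one TIFF
#' per channel (per frame for time-lapses), plus a JSON manifest (voxel
#' pitch, channel files, frame interval, per-cell seeds, intensity scale
#' factors) and a ground-truth CSV (cell_id, frame, focus coordinates,
#' true distance). Per-cell seeds are derived deterministically from
#' `cfg$seed` so the whole dataset is reproducible from one master seed.
#'
#' @param cfg a [sim_config()] object; `cfg$seed` is the master seed.
#' @param n_cells number of cells (>= 1).
#' @param dir output directory.
#' @param overwrite allow writing into an existing manifest directory.
#' @param condition condition label stored per cell (e.g. a strain name).
#' @return path of the manifest JSON, invisibly; the manifest list as value.
#' @export
simulate_population <- function(cfg, n_cells, dir, overwrite = FALSE,
                                condition = "sim") {
  if (n_cells < 1) stop("n_cells must be >= 1")
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists in '", dir, "'; use overwrite = TRUE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", n_cells)
  truth_rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell_id <- sprintf("cell%04d", i)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    if (cfg$mode == "still") {
      sim <- simulate_nucleus_stack(cfg_i)
      files <- write_stack(sim$stack, file.path(dir, cell_id))
      entries[[i]] <- list(
        cell_id = cell_id, condition = condition, type = "still",
        voxel_pitch_um = cfg$voxel_pitch,
        channels = files$channels, scale = files$scale,
        seed = cfg_i$seed)
      truth_rows[[i]] <- data.frame(
        cell_id = cell_id, frame = 1L,
        z_um = sim$truth$focus_position[1],
        y_um = sim$truth$focus_position[2],
        x_um = sim$truth$focus_position[3],
        cz_um = sim$truth$center[1], cy_um = sim$truth$center[2],
        cx_um = sim$truth$center[3],
        true_distance_um = sim$truth$distance_um)
    } else {
      sim <- simulate_timelapse(cfg_i)
      ch_files <- lapply(seq_along(sim$frames), function(f) {
        write_stack(sim$frames[[f]],
                    file.path(dir, sprintf("%s_f%03d", cell_id, f)))
      })
      entries[[i]] <- list(
        cell_id = cell_id, condition = condition, type = "timelapse",
        voxel_pitch_um = cfg$voxel_pitch,
        frame_interval_s = cfg$frame_interval,
        frames = lapply(ch_files, function(ff)
          list(channels = ff$channels, scale = ff$scale)),
        seed = cfg_i$seed)
      pf <- sim$truth$per_frame
      truth_rows[[i]] <- data.frame(
        cell_id = cell_id, frame = pf$frame,
        z_um = pf$z_um, y_um = pf$y_um, x_um = pf$x_um,
        cz_um = pf$cz_um, cy_um = pf$cy_um, cx_um = pf$cx_um,
        true_distance_um = pf$distance_um)
    }
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(schema_version = 1L,
                   mode = cfg$mode,
                   master_seed = cfg$seed,
                   frame_interval_s = cfg$frame_interval,
                   ground_truth = "ground_truth.csv",
                   entries = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
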