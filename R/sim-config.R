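#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-microscopy and
#' confined-diffusion simulators. Defaults emulate the study's two imaging
#' regimes for a haploid yeast nucleus (~1 um radius):
#'
#' * `mode = "still"`: 28 z-sections at 0.25 um spacing (the still-image
#'   positioning assay);
#' * `mode = "timelapse"`: 20 z-sections at 0.30 um spacing, one stack every
#'   12 s for 5 min (26 frames).
#'
#' The in-plane pixel pitch defaults to 0.1 um. All lengths are um, times
#' seconds, intensities expected photons per voxel. Axis order is (z, y, x)
#' throughout.
#'
#' @param mode "still" or "timelapse"; selects pitch/shape/frame defaults.
#' @param nucleus_center (z, y, x) um; default: the stack's geometric center.
#' @param nucleus_semiaxes (z, y, x) um semi-axes; equal values give a sphere.
#' @param voxel_pitch (z, y, x) um.
#' @param stack_shape integer (n_z, n_y, n_x).
#' @param envelope_intensity expected photons/voxel at the shell peak.
#' @param shell_thickness FWHM (um) of the Gaussian radial profile of the
#'   envelope shell signal, representing the optically blurred nuclear rim.
#' @param focus_position (z, y, x) um, or `"sampled"` to draw it from
#'   `placement`.
#' @param placement radial placement law used when `focus_position` is
#'   sampled: `"uniform"` (uniform in the nuclear volume) or `"peripheral"`
#'   (depth below the surface ~ Exponential(mean `peripheral_depth`),
#'   truncated to the interior).
#' @param peripheral_depth mean depth (um) below the surface for the
#'   peripheral placement law.
#' @param focus_intensity expected photons at the focus peak voxel.
#' @param psf_sigma Gaussian PSF sigmas (z, y, x) um; the widefield default
#'   (0.35, 0.13, 0.13) approximates a GFP-range point-spread function.
#' @param background expected photons/voxel of uniform background.
#' @param read_noise_sd Gaussian read noise sd (photons).
#' @param noise logical; disable to obtain noiseless oracle images.
#' @param n_frames frames in a time-lapse (26 frames = 5 min at 12 s).
#' @param frame_interval seconds between frames.
#' @param diffusion_coefficient D, um^2/s.
#' @param confinement_radius R_true, um: radius of the reflecting sphere
#'   confining the locus (may exceed the nucleus for free-diffusion tests;
#'   `Inf` disables reflection).
#' @param tether `"none"` or `"peripheral"`: adds a harmonic restoring
#'   displacement toward a shell `tether_depth` um below the envelope.
#' @param tether_depth um below the nuclear surface of the tether shell.
#' @param tether_stiffness restoring rate k (1/s); each sub-step applies a
#'   displacement -k * offset * dt along the surface normal.
#' @param nucleus_drift_per_frame (z, y, x) um of whole-nucleus drift added
#'   per frame when rendering time-lapses.
#' @param seed integer RNG seed; identical config + seed reproduces every
#'   voxel and trajectory point exactly.
#' @return object of class `nucperi_config` (a validated list).
#' @export
sim_config <- function(mode = c("still", "timelapse"),
                       nucleus_center = NULL,
                       nucleus_semiaxes = c(1, 1, 1),
                       voxel_pitch = NULL,
                       stack_shape = NULL,
                       envelope_intensity = 200,
                       shell_thickness = 0.25,
                       focus_position = "sampled",
                       placement = c("uniform", "peripheral"),
                       peripheral_depth = 0.1,
                       focus_intensity = 500,
                       psf_sigma = c(0.35, 0.13, 0.13),
                       background = 10,
                       read_noise_sd = 2,
                       noise = TRUE,
                       n_frames = 26,
                       frame_interval = 12,
                       diffusion_coefficient = 0.005,
                       confinement_radius = 0.5,
                       tether = c("none", "peripheral"),
                       tether_depth = 0.1,
                       tether_stiffness = 0.5,
                       nucleus_drift_per_frame = c(0, 0, 0),
                       seed = 1L) {
  mode <- match.arg(mode)
  placement <- match.arg(placement)
  tether <- match.arg(tether)
  if (is.null(voxel_pitch)) {
    voxel_pitch <- if (mode == "still") c(0.25, 0.1, 0.1) else c(0.30, 0.1, 0.1)
  }
  if (is.null(stack_shape)) {
    stack_shape <- if (mode == "still") c(28L, 40L, 40L) else c(20L, 40L, 40L)
  }
  stack_shape <- as.integer(stack_shape)
  extent <- stack_shape * voxel_pitch
  if (is.null(nucleus_center)) nucleus_center <- extent / 2
  cfg <- list(
    mode = mode,
    nucleus_center = as.numeric(nucleus_center),
    nucleus_semiaxes = as.numeric(nucleus_semiaxes),
    voxel_pitch = as.numeric(voxel_pitch),
    stack_shape = stack_shape,
    envelope_intensity = envelope_intensity,
    shell_thickness = shell_thickness,
    focus_position = focus_position,
    placement = placement,
    peripheral_depth = peripheral_depth,
    focus_intensity = focus_intensity,
    psf_sigma = as.numeric(psf_sigma),
    background = background,
    read_noise_sd = read_noise_sd,
    noise = isTRUE(noise),
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    diffusion_coefficient = diffusion_coefficient,
    confinement_radius = confinement_radius,
    tether = tether,
    tether_depth = tether_depth,
    tether_stiffness = tether_stiffness,
    nucleus_drift_per_frame = as.numeric(nucleus_drift_per_frame),
    seed = as.integer(seed)
  )
  class(cfg) <- "nucperi_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(voxel_pitch <= 0)) stop("voxel_pitch must be strictly positive")
    if (any(nucleus_semiaxes <= 0)) stop("nucleus_semiaxes must be positive")
    if (any(psf_sigma <= 0)) stop("psf_sigma must be positive")
    if (any(stack_shape < 1)) stop("stack_shape must be positive")
    if (envelope_intensity <= 0 || focus_intensity <= 0) {
      stop("intensities must be strictly positive")
    }
    if (background < 0 || read_noise_sd < 0) stop("noise levels must be >= 0")
    if (diffusion_coefficient < 0) stop("diffusion_coefficient must be >= 0")
    if (confinement_radius <= 0) stop("confinement_radius must be > 0")
    extent <- stack_shape * voxel_pitch
    margin <- 2 * psf_sigma
    lo <- nucleus_center - nucleus_semiaxes - margin
    hi <- nucleus_center + nucleus_semiaxes + margin
    ax <- c("z", "y", "x")
    bad <- which(lo < 0 | hi > extent)
    if (length(bad)) {
      stop(sprintf(
        paste0("stack does not contain the nucleus plus a 2*psf_sigma ",
               "margin along %s: need [%.3f, %.3f] um inside [0, %.3f] um"),
        paste(ax[bad], collapse = ","), min(lo[bad]), max(hi[bad]),
        min(extent[bad])))
    }
  })
  invisible(cfg)
}

# Per-cell seed derived from a master seed: a fixed multiplicative hash,
# kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + index * 7919) %% 2147483629)
}

# Draw a focus position (z, y, x um) inside the nucleus under a placement
# law. Laws are defined in the unit ball and mapped through the semi-axes,
# so "depth" is exact for spheres and approximate for mild ellipsoids.
sample_focus_position <- function(cfg) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  a_eff <- min(cfg$nucleus_semiaxes)
  r <- if (cfg$placement == "uniform") {
    stats::runif(1)^(1 / 3)
  } else {
    depth <- stats::rexp(1, rate = 1 / cfg$peripheral_depth)
    max(0, 1 - min(depth, a_eff * 0.99) / a_eff)
  }
  cfg$nucleus_center + r * u * cfg$nucleus_semiaxes
}
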