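test_that("identical config and seed reproduce stacks bit for bit", {
  cfg <- quick_still_config(seed = 5)
  a <- simulate_nucleus_stack(cfg)
  b <- simulate_nucleus_stack(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth, b$truth)
  cfg2 <- quick_still_config(seed = 6)
  c2 <- simulate_nucleus_stack(cfg2)
  expect_false(identical(a$stack$channels$locus, c2$stack$channels$locus))
})

test_that("stack must contain the nucleus plus a PSF margin", {
  expect_error(
    sim_config(stack_shape = c(8L, 40L, 40L)),
    "margin along z")
  expect_error(sim_config(voxel_pitch = c(0.25, -0.1, 0.1)), "pitch")
  expect_error(sim_config(nucleus_semiaxes = c(0, 1, 1)), "semiaxes")
})

test_that("ground truth reflects focus placement geometry", {
  # focus at the center of a sphere: true distance R, brightest locus voxel
  # at the voxel containing the center
  cfg <- quick_still_config(seed = 1, noise = FALSE)
  cfg$focus_position <- cfg$nucleus_center
  sim <- simulate_nucleus_stack(cfg)
  expect_equal(sim$truth$distance_um, 0.95, tolerance = 1e-12)
  peak <- arrayInd(which.max(sim$stack$channels$locus),
                   dim(sim$stack$channels$locus))
  ctr_vox <- ceiling(cfg$nucleus_center / cfg$voxel_pitch)
  expect_true(all(abs(peak - ctr_vox) <= 1))

  # focus exactly on the envelope surface: true distance 0
  cfg$focus_position <- cfg$nucleus_center + c(0.95, 0, 0)
  sim0 <- simulate_nucleus_stack(cfg)
  expect_lt(sim0$truth$distance_um, 1e-9)
})

test_that("integrated focus signal matches the PSF normalization", {
  cfg <- quick_still_config(seed = 2, noise = FALSE, background = 0)
  cfg$focus_position <- cfg$nucleus_center + c(0.1, 0.07, -0.05)
  sim <- simulate_nucleus_stack(cfg)
  total <- sum(sim$stack$channels$locus)
  expected <- cfg$focus_intensity * (2 * pi)^1.5 * prod(cfg$psf_sigma) /
    prod(cfg$voxel_pitch)
  expect_equal(total, expected, tolerance = 0.01)
})

test_that("free diffusion reproduces its closed-form statistics", {
  D <- 0.005; dt <- 12
  cfg <- sim_config(mode = "timelapse", confinement_radius = Inf,
                    diffusion_coefficient = D, n_frames = 26, seed = 1)
  cfg$focus_position <- cfg$nucleus_center
  trs <- lapply(1:200, function(i) {
    ci <- cfg; ci$seed <- i
    simulate_confined_trajectory(ci)$trajectory
  })
  incs <- unlist(lapply(trs, function(tr) diff(tr$z_um)))
  expect_equal(var(incs), 2 * D * dt, tolerance = 0.1)
  curve <- msd_ensemble(trs)
  slope <- curve$msd_um2[1] / curve$lag_s[1]
  expect_equal(slope, 6 * D, tolerance = 0.1)
})

test_that("confined diffusion equilibrates to the uniform-ball second moment", {
  # long single track; fine steps so the reflected walk's equilibrium is
  # close to uniform in the ball
  R <- 0.5
  cfg <- sim_config(mode = "timelapse", confinement_radius = R,
                    diffusion_coefficient = 0.005, n_frames = 1e5,
                    frame_interval = 0.25, seed = 5)
  cfg$focus_position <- cfg$nucleus_center
  tr <- simulate_confined_trajectory(cfg)$trajectory
  r2 <- (tr$z_um - cfg$nucleus_center[1])^2 +
    (tr$y_um - cfg$nucleus_center[2])^2 +
    (tr$x_um - cfg$nucleus_center[3])^2
  burn <- -(1:2000)
  expect_equal(mean(r2[burn]), 3 * R^2 / 5, tolerance = 0.02)
  expect_lte(max(sqrt(r2)), R + 1e-9)     # never escapes the sphere
})

test_that("trajectory simulator honors its contracts", {
  cfg <- sim_config(mode = "timelapse", diffusion_coefficient = 0, seed = 3)
  cfg$focus_position <- cfg$nucleus_center + c(0.2, 0, 0)
  tr <- simulate_confined_trajectory(cfg)$trajectory
  expect_equal(nrow(tr), 26)
  expect_true(all(tr$z_um == tr$z_um[1]))  # D = 0: frozen in place

  # explicit sub-step count that violates the guard is refused
  cfg2 <- sim_config(mode = "timelapse", diffusion_coefficient = 0.005,
                     confinement_radius = 0.5, seed = 3)
  expect_error(simulate_confined_trajectory(cfg2, n_substeps = 1),
               "finer time step")
  # the automatic choice satisfies the guard
  sim <- simulate_confined_trajectory(cfg2)
  expect_gte(sim$truth$n_substeps, 6)
  expect_error({
    cfg3 <- cfg2; cfg3$n_frames <- 1L
    simulate_confined_trajectory(cfg3)
  }, "n_frames")
})

test_that("time-lapse covers the imaging regime and encodes drift", {
  cfg <- sim_config(mode = "timelapse", diffusion_coefficient = 0,
                    noise = FALSE, seed = 4,
                    nucleus_drift_per_frame = c(0.05, 0, 0), n_frames = 6)
  cfg$focus_position <- cfg$nucleus_center
  tl <- simulate_timelapse(cfg)
  expect_length(tl$frames, 6)
  pf <- tl$truth$per_frame
  # 26 frames at 12 s span 5 min; here check the time base generally
  expect_equal(pf$t_s, (0:5) * 12)
  full <- sim_config(mode = "timelapse", n_frames = 26)
  expect_equal((full$n_frames - 1) * full$frame_interval, 300)

  # drift moves the raw focus linearly; nucleus-frame track is constant
  expect_equal(diff(pf$z_um), rep(0.05, 5), tolerance = 1e-12)
  rel <- pf$z_um - pf$cz_um
  expect_equal(rel, rep(rel[1], 6), tolerance = 1e-12)

  # zero drift, D = 0: identical focus voxel across frames
  cfg0 <- sim_config(mode = "timelapse", diffusion_coefficient = 0,
                     noise = FALSE, seed = 4, n_frames = 3)
  cfg0$focus_position <- cfg0$nucleus_center + c(0.2, 0.1, 0)
  tl0 <- simulate_timelapse(cfg0)
  peaks <- vapply(tl0$frames, function(st)
    which.max(st$channels$locus), 1L)
  expect_true(all(peaks == peaks[1]))
})

test_that("placement laws separate peripheral from interior populations", {
  cfg_p <- sim_config(placement = "peripheral", seed = 1)
  cfg_u <- sim_config(placement = "uniform", seed = 2)
  draw <- function(cfg, n) {
    set.seed(cfg$seed)
    vapply(seq_len(n), function(i) {
      p <- nucperi:::sample_focus_position(cfg)
      point_ellipsoid_distance(p, cfg$nucleus_center,
                               cfg$nucleus_semiaxes)$distance
    }, 1)
  }
  dp <- draw(cfg_p, 500)
  du <- draw(cfg_u, 500)
  expect_lt(mean(dp), mean(du))
  expect_equal(mean(dp), cfg_p$peripheral_depth, tolerance = 0.25)
  # uniform in a unit ball: mean distance from the surface is R/4
  expect_equal(mean(du), 0.25, tolerance = 0.05)
})

test_that("population datasets are complete and reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- quick_still_config(seed = 77)
  simulate_population(cfg, 5, dir1, condition = "x")
  simulate_population(cfg, 5, dir2, condition = "x")
  man <- read_manifest(file.path(dir1, "manifest.json"))
  expect_length(man$entries, 5)
  truth <- read.csv(file.path(dir1, "ground_truth.csv"))
  expect_equal(nrow(truth), 5)
  expect_identical(readBin(file.path(dir1, "cell0001_locus.tif"), "raw", 1e6),
                   readBin(file.path(dir2, "cell0001_locus.tif"), "raw", 1e6))
  expect_identical(readLines(file.path(dir1, "ground_truth.csv")),
                   readLines(file.path(dir2, "ground_truth.csv")))
  expect_error(simulate_population(cfg, 2, dir1), "overwrite")
})
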