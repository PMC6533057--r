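test_that("noiseless synthetic spots are localized to subvoxel accuracy", {
  offsets <- list(c(0, 0, 0), c(0.31, -0.22, 0.18), c(-0.4, 0.13, -0.07))
  for (off in offsets) {
    cfg <- quick_still_config(seed = 1, noise = FALSE)
    cfg$focus_position <- cfg$nucleus_center + off
    sim <- simulate_nucleus_stack(cfg)
    fo <- detect_focus(sim$stack)
    expect_true(fo$found)
    err <- max(abs(fo$position - sim$truth$focus_position))
    expect_lt(err, 0.5 * max(cfg$voxel_pitch))
  }
})

test_that("a uniform locus channel yields no fabricated focus", {
  cfg <- quick_still_config(seed = 2, noise = FALSE)
  sim <- simulate_nucleus_stack(cfg)
  flat <- sim$stack
  flat$channels$locus <- array(7, dim = dim(flat$channels$locus))
  fo <- detect_focus(flat)
  expect_false(fo$found)
  expect_identical(fo$qc, "no_focus")
  expect_true(all(is.na(fo$position)))
})

test_that("the brighter of two spots wins and both are counted", {
  cfg <- quick_still_config(seed = 3, noise = FALSE)
  p_bright <- cfg$nucleus_center + c(0.3, 0.4, 0)
  p_dim <- cfg$nucleus_center - c(0.3, 0.4, 0)
  sim <- simulate_nucleus_stack(cfg)
  st <- sim$stack
  cfg_dim <- cfg
  cfg_dim$focus_intensity <- cfg$focus_intensity / 5
  st$channels$locus <- nucperi:::render_focus(cfg, p_bright) +
    nucperi:::render_focus(cfg_dim, p_dim) + cfg$background
  fo <- detect_focus(st)
  expect_true(fo$found)
  expect_identical(fo$n_candidates, 2L)
  expect_lt(max(abs(fo$position - p_bright)), 0.5 * max(cfg$voxel_pitch))
})

test_that("quality increases with spot brightness", {
  qual <- vapply(c(30, 100, 400), function(int) {
    cfg <- quick_still_config(seed = 4, focus_intensity = int)
    detect_focus(simulate_nucleus_stack(cfg)$stack)$quality
  }, 1)
  expect_true(all(diff(qual) > 0))
  expect_true(all(qual >= 0 & qual <= 1))
})

test_that("envelope segmentation recovers spheres and ellipsoids", {
  cfg <- sim_config(seed = 5, noise = FALSE)  # sphere R = 1.0 um
  sim <- simulate_nucleus_stack(cfg)
  su <- segment_envelope(sim$stack)
  expect_lt(max(abs(su$semiaxes - 1.0)), max(cfg$voxel_pitch))
  expect_lt(max(abs(su$center - cfg$nucleus_center)), max(cfg$voxel_pitch))

  cfg_e <- sim_config(seed = 6, noise = FALSE,
                      nucleus_semiaxes = c(1.2, 1.0, 0.9))
  sim_e <- simulate_nucleus_stack(cfg_e)
  su_e <- segment_envelope(sim_e$stack)
  rec <- sort(su_e$semiaxes, decreasing = TRUE)
  expect_true(all(abs(rec - c(1.2, 1.0, 0.9)) / c(1.2, 1.0, 0.9) < 0.10))
})

test_that("empty or flat envelope channels raise poor_envelope_fit", {
  cfg <- quick_still_config(seed = 7, noise = FALSE)
  sim <- simulate_nucleus_stack(cfg)
  st <- sim$stack
  st$channels$envelope <- array(0, dim = dim(st$channels$envelope))
  expect_error(segment_envelope(st), class = "nucperi_poor_envelope_fit")
  st$channels$envelope <- array(5, dim = dim(st$channels$envelope))
  expect_error(segment_envelope(st), class = "nucperi_poor_envelope_fit")
})

test_that("2D middle-section mode agrees with 3D in the equatorial plane", {
  cfg <- sim_config(seed = 8, noise = FALSE)
  cfg$focus_position <- cfg$nucleus_center + c(0, 0.5, 0.2)  # equatorial
  sim <- simulate_nucleus_stack(cfg)
  su <- segment_envelope(sim$stack)
  fo <- detect_focus(sim$stack)
  d3 <- distance_to_periphery_3d(fo, su)
  d2 <- distance_to_periphery_2d(sim$stack, fo, su)
  expect_lt(abs(d2$distance_um - d3$distance_um), max(cfg$voxel_pitch))
})

test_that("2D mode errors when k_mid exceeds the stack depth", {
  cfg <- quick_still_config(seed = 9, noise = FALSE)
  sim <- simulate_nucleus_stack(cfg)
  st <- sim$stack
  st$channels <- lapply(st$channels, function(a) a[1:2, , , drop = FALSE])
  expect_error(distance_to_periphery_2d(st, c(1, 1.7, 1.7), k_mid = 3),
               "k_mid")
})

test_that("foci outside the fitted surface clip to zero and are flagged", {
  surface <- list(center = c(2, 2, 2), semiaxes = c(1, 1, 1),
                  rotation = diag(3))
  m <- distance_to_periphery_3d(c(3.5, 2, 2), surface)
  expect_identical(m$distance_um, 0)
  expect_false(m$inside)
  expect_identical(m$qc, "focus_outside_surface")
})

test_that("measure_dataset records every cell, flags failures, reruns identically", {
  dir <- withr::local_tempdir()
  cfg <- quick_still_config(seed = 31)
  simulate_population(cfg, 6, dir, condition = "wt")
  # corrupt one cell's locus channel to a flat image -> no_focus
  man <- read_manifest(file.path(dir, "manifest.json"))
  flat_entry <- man$entries[[3]]
  st <- read_stack(man$dir, flat_entry)
  st$channels$locus <- array(5, dim = dim(st$channels$locus))
  files <- write_stack(st, file.path(dir, flat_entry$cell_id))
  rec <- measure_dataset(file.path(dir, "manifest.json"))
  expect_equal(nrow(rec), 6)
  expect_identical(rec$cell_id, sort(rec$cell_id))
  expect_identical(rec$qc_flags[rec$cell_id == flat_entry$cell_id],
                   "no_focus")
  expect_length(usable_distances(rec), 5)
  rec2 <- measure_dataset(file.path(dir, "manifest.json"))
  expect_identical(rec, rec2)
})

test_that("measured distances track ground truth within a voxel pitch", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, noise = FALSE)
  simulate_population(cfg, 8, dir, condition = "x")
  rec <- measure_dataset(file.path(dir, "manifest.json"))
  truth <- read.csv(file.path(dir, "ground_truth.csv"))
  truth <- truth[order(truth$cell_id), ]
  expect_true(all(abs(rec$distance_um - truth$true_distance_um) <=
                    max(cfg$voxel_pitch)))
})
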