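make_track <- function(pos, dt = 12, cell_id = "c1") {
  n <- nrow(pos)
  det <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) * dt,
                    z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3])
  build_trajectory(det, cell_id = cell_id)
}

test_that("trajectories sort, record gaps and reject bad input", {
  set.seed(1)
  pos <- matrix(rnorm(18), ncol = 3)
  det <- data.frame(frame = 1:6, t_s = (0:5) * 12, z_um = pos[, 1],
                    y_um = pos[, 2], x_um = pos[, 3])
  shuffled <- det[sample(6), ]
  expect_equal(as.data.frame(build_trajectory(shuffled)),
               as.data.frame(build_trajectory(det)))

  det$z_um[3] <- NA
  tr <- build_trajectory(det)
  expect_identical(attr(tr, "gaps"), 3L)

  dup <- det; dup$t_s[2] <- dup$t_s[1]
  expect_error(build_trajectory(dup), "duplicate")
  expect_error(build_trajectory(det[1:1, ]), "2 valid frames")
})

test_that("gaps reduce the number of lag pairs, not the track length", {
  # 26 frames with frame 10 missing: both lag-1 pairs that touch the gap
  # ((9,10) and (10,11)) are excluded, leaving 23 of the 25 pairs
  pos <- matrix(seq_len(78), ncol = 3)
  pos[10, ] <- NA
  msd1 <- nucperi:::msd_track(pos, 1)
  d <- pos[-1, ] - pos[-26, ]
  expect_equal(sum(!is.na(rowSums(d))), 23)
  expect_equal(msd1, mean(rowSums(d^2), na.rm = TRUE))
  expect_equal(msd1, oracle_msd_track(pos, 1), tolerance = 1e-12)
})

test_that("drift correction removes nucleus motion and scores stationarity", {
  n <- 26
  drift <- outer(0:(n - 1), c(0.05, 0, 0))
  fixed_rel <- c(0.3, 0.2, 0.1)
  det <- data.frame(frame = 1:n, t_s = (0:(n - 1)) * 12,
                    z_um = 2 + fixed_rel[1] + drift[, 1],
                    y_um = 2 + fixed_rel[2] + drift[, 2],
                    x_um = 2 + fixed_rel[3] + drift[, 3])
  cen <- data.frame(frame = 1:n, cz_um = 2 + drift[, 1],
                    cy_um = 2 + drift[, 2], cx_um = 2 + drift[, 3])
  tr <- drift_correct(build_trajectory(det, cen))
  curve <- msd_ensemble(list(tr))
  expect_true(all(curve$msd_um2 < 1e-20))  # locus fixed in the nucleus frame
  expect_equal(attr(tr, "stationarity_um"), 0.05 * (n - 1),
               tolerance = 1e-12)

  cen0 <- cen; cen0[, 2:4] <- 2
  tr0 <- drift_correct(build_trajectory(det, cen0))
  expect_equal(attr(tr0, "stationarity_um"), 0)
  expect_equal(tr0$z_um, det$z_um - 2)

  cen_na <- cen; cen_na$cz_um[4] <- NA
  expect_error(drift_correct(build_trajectory(det, cen_na)),
               "missing nucleus centroid")
})

test_that("ensemble MSD equals the brute-force all-pairs oracle", {
  set.seed(42)
  trs <- lapply(1:20, function(i) {
    n <- sample(15:30, 1)
    pos <- matrix(cumsum(rnorm(3 * n, 0, 0.1)), ncol = 3)
    if (i %% 4 == 0) pos[sample(n, 2), ] <- NA  # gaps in some tracks
    make_track(pos, cell_id = sprintf("c%02d", i))
  })
  curve <- msd_ensemble(trs, max_lag_fraction = 0.5)
  max_lag <- length(curve$lag_s)
  per_track <- vapply(trs, function(tr) {
    oracle_msd_track(as.matrix(tr[, c("z_um", "y_um", "x_um")]), max_lag)
  }, numeric(max_lag))
  expect_equal(curve$msd_um2, rowMeans(per_track, na.rm = TRUE),
               tolerance = 1e-12)
  sem <- apply(per_track, 1, function(v)
    sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  expect_equal(curve$sem_um2, sem, tolerance = 1e-12)
})

test_that("deterministic and degenerate motion give closed-form MSDs", {
  pos0 <- matrix(1.5, nrow = 10, ncol = 3)
  c0 <- msd_ensemble(list(make_track(pos0)))
  expect_true(all(c0$msd_um2 == 0))

  delta <- 0.07
  pos <- cbind(delta * (0:19), 0, 0)
  curve <- msd_ensemble(list(make_track(pos)), max_lag_fraction = 0.5)
  k <- seq_along(curve$lag_s)
  expect_equal(curve$msd_um2, (k * delta)^2, tolerance = 1e-12)
})

test_that("plateau estimation recovers the saturating form and flags linear curves", {
  curve <- data.frame(lag_s = seq(12, 150, by = 12))
  curve$msd_um2 <- 0.4 * (1 - exp(-curve$lag_s / 20))
  pl <- estimate_plateau(curve)
  expect_true(pl$converged)
  expect_equal(pl$plateau_um2, 0.4, tolerance = 0.05)
  expect_equal(pl$tau_c_s, 20, tolerance = 0.1)

  const <- data.frame(lag_s = seq(12, 120, by = 12), msd_um2 = 0.25)
  plc <- estimate_plateau(const)
  expect_true(plc$converged)
  expect_equal(plc$plateau_um2, 0.25, tolerance = 1e-9)

  lin <- data.frame(lag_s = seq(12, 150, by = 12))
  lin$msd_um2 <- 0.002 * lin$lag_s
  pll <- estimate_plateau(lin)
  expect_false(pll$converged)

  expect_error(estimate_plateau(curve[1:3, ]), ">= 4 lags")
  tm <- estimate_plateau(curve, method = "tail_mean")
  expect_equal(tm$plateau_um2, mean(curve$msd_um2[9:12]), tolerance = 1e-12)
})

test_that("radius of constraint follows the uniform-ball moment identity", {
  expect_equal(radius_of_constraint(1.2, dims = 3), 1.0, tolerance = 1e-12)
  expect_identical(radius_of_constraint(0), 0)
  expect_equal(radius_of_constraint(0.36, dims = 2), 0.6, tolerance = 1e-12)
  expect_error(radius_of_constraint(-1), ">= 0")

  # Monte-Carlo: mean squared separation of uniform points in a ball of
  # radius R is 6R^2/5, so the estimated Rc recovers R
  set.seed(7)
  R <- 0.8
  n <- 1e5
  draw_ball <- function(n, R) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u * R * runif(n)^(1 / 3)
  }
  x <- draw_ball(n, R); y <- draw_ball(n, R)
  plateau <- mean(rowSums((x - y)^2))
  expect_equal(radius_of_constraint(plateau), R, tolerance = 0.03)
})

test_that("volume identities hold to machine precision", {
  expect_equal(volume_searched(1), 4 / 3 * pi, tolerance = 1e-15)
  expect_identical(volume_searched(0), 0)
  rc_a <- 0.9 * 2.5^(1 / 3); rc_b <- 0.9
  fold <- volume_searched(rc_a) / volume_searched(rc_b)
  expect_equal(fold, 2.5, tolerance = 1e-6)
  expect_equal(fold, (rc_a / rc_b)^3, tolerance = 1e-12)
})

test_that("identical groups compare as indistinguishable", {
  set.seed(9)
  trs <- lapply(1:6, function(i) {
    pos <- matrix(cumsum(rnorm(60, 0, 0.05)), ncol = 3)
    make_track(pos, cell_id = sprintf("c%d", i))
  })
  cmp <- compare_mobility(trs, trs)
  expect_equal(cmp$volume_fold, 1, tolerance = 1e-12)
  expect_gte(cmp$test$p_two_tailed, 0.9)
  expect_equal(cmp$rc_ratio, 1, tolerance = 1e-12)
})

test_that("mobility comparison detects a confinement-radius difference", {
  # power simulation: R_true 0.68 vs 0.50 um, 20 cells each, 26 frames
  run_rep <- function(rep_seed) {
    grp <- function(R, base) {
      lapply(1:20, function(i) {
        cfg <- sim_config(mode = "timelapse", confinement_radius = R,
                          seed = nucperi:::derive_seed(rep_seed, base + i))
        cfg$focus_position <- cfg$nucleus_center
        tr <- simulate_confined_trajectory(cfg)$trajectory
        tr$cell_id <- paste0("c", base + i)
        tr
      })
    }
    cmp <- compare_mobility(grp(0.68, 0), grp(0.50, 1000))
    cmp$test$p_two_tailed < 0.05
  }
  rejections <- vapply(1:100, run_rep, TRUE)
  expect_gte(mean(rejections), 0.9)
})

test_that("estimated Rc does not decrease with the true confinement radius", {
  est_rc <- vapply(c(0.3, 0.4, 0.5, 0.6), function(R) {
    trs <- lapply(1:100, function(i) {
      cfg <- sim_config(mode = "timelapse", confinement_radius = R,
                        seed = nucperi:::derive_seed(55, i))
      cfg$focus_position <- cfg$nucleus_center
      simulate_confined_trajectory(cfg)$trajectory
    })
    pl <- estimate_plateau(msd_ensemble(trs))
    radius_of_constraint(pl$plateau_um2)
  }, 1)
  expect_true(all(diff(est_rc) > 0))
})

test_that("exact Mann-Whitney within mobility comparison matches enumeration", {
  set.seed(3)
  a <- rnorm(3); b <- rnorm(3) + 1
  res <- mann_whitney(a, b)
  expect_equal(res$p_two_tailed, oracle_mw_exact(a, b), tolerance = 1e-12)
})
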