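#' Run the full synthetic positioning + mobility pipeline
#'
#' End-to-end chain on synthetic data, reproducing the two figure-style
#' analyses of the assay from one master seed:
#'
#' 1. **Positioning**: simulates two still populations with different
#'    radial placement laws ("peripheral" vs "uniform" interior), measures
#'    per-cell focus-to-periphery distances, writes the distance table and
#'    quartile summaries, and compares the distributions by z-test.
#' 2. **Mobility**: simulates two time-lapse groups with different
#'    confinement radii, tracks each cell, computes drift-corrected MSD
#'    curves, plateau, Rc and explored volume per group, and compares
#'    groups by two-tailed Mann-Whitney test.
#'
#' Every artifact is a CSV with unit-bearing column names; the effective
#' configuration (including the master seed and derived per-cell seeds) is
#' dumped as JSON next to the outputs. Rerunning with the same seed
#' reproduces every file byte-for-byte.
#'
#' @param dir output directory (created; must be empty of a previous run
#'   unless `overwrite`).
#' @param seed master seed.
#' @param n_cells_still cells per still condition (default 15).
#' @param n_cells_timelapse cells per time-lapse group (default 8).
#' @param rc_a,rc_b true confinement radii (um) of mobility groups A and B
#'   (defaults 0.68 and 0.50).
#' @param mode distance mode, `"3d"` (default) or `"2d"`.
#' @param overwrite overwrite a previous run.
#' @param quiet suppress per-stage messages.
#' @return invisible list of the main results (distance records, z-test,
#'   mobility comparison, file paths).
#' @export
run_pipeline <- function(dir, seed = 1L, n_cells_still = 15,
                         n_cells_timelapse = 8, rc_a = 0.68, rc_b = 0.50,
                         mode = "3d", overwrite = FALSE, quiet = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_per <- sim_config(mode = "still", placement = "peripheral",
                        seed = derive_seed(seed, 101))
  cfg_uni <- sim_config(mode = "still", placement = "uniform",
                        seed = derive_seed(seed, 202))
  say("simulating %d peripheral + %d interior cells", n_cells_still,
      n_cells_still)
  simulate_population(cfg_per, n_cells_still, file.path(dir, "peripheral"),
                      overwrite = overwrite, condition = "peripheral")
  simulate_population(cfg_uni, n_cells_still, file.path(dir, "interior"),
                      overwrite = overwrite, condition = "interior")
  say("measuring distances (%s mode)", mode)
  rec <- rbind(measure_dataset(file.path(dir, "peripheral", "manifest.json"),
                               mode = mode),
               measure_dataset(file.path(dir, "interior", "manifest.json"),
                               mode = mode))
  utils::write.csv(rec, file.path(dir, "distances.csv"), row.names = FALSE)
  qs <- do.call(rbind, lapply(split(rec, rec$condition), function(r) {
    s <- quartile_summary(usable_distances(r))
    data.frame(condition = r$condition[1], n = s$n, min_um = s$min,
               q1_um = s$q1, median_um = s$median, q3_um = s$q3,
               max_um = s$max)
  }))
  utils::write.csv(qs, file.path(dir, "distance_quartiles.csv"),
                   row.names = FALSE)
  ztest <- compare_conditions(rec, test = "z")
  utils::write.csv(ztest, file.path(dir, "distance_test.csv"),
                   row.names = FALSE)
  say("simulating time-lapse groups (Rc %.2f vs %.2f um)", rc_a, rc_b)
  cfg_a <- sim_config(mode = "timelapse", confinement_radius = rc_a,
                      focus_position = c(0, 0, 0), seed = derive_seed(seed, 303))
  cfg_a$focus_position <- cfg_a$nucleus_center
  cfg_b <- sim_config(mode = "timelapse", confinement_radius = rc_b,
                      focus_position = c(0, 0, 0), seed = derive_seed(seed, 404))
  cfg_b$focus_position <- cfg_b$nucleus_center
  simulate_population(cfg_a, n_cells_timelapse, file.path(dir, "groupA"),
                      overwrite = overwrite, condition = "A")
  simulate_population(cfg_b, n_cells_timelapse, file.path(dir, "groupB"),
                      overwrite = overwrite, condition = "B")
  say("tracking time-lapses")
  tracks <- rbind(track_dataset(file.path(dir, "groupA", "manifest.json")),
                  track_dataset(file.path(dir, "groupB", "manifest.json")))
  write_tracks(tracks, file.path(dir, "tracks.csv"))
  ga <- split_tracks(tracks[tracks$condition == "A", ])
  gb <- split_tracks(tracks[tracks$condition == "B", ])
  cmp <- compare_mobility(ga, gb)
  msd_tab <- rbind(cbind(condition = "A", as.data.frame(cmp$summary_a$msd)),
                   cbind(condition = "B", as.data.frame(cmp$summary_b$msd)))
  utils::write.csv(msd_tab, file.path(dir, "msd.csv"), row.names = FALSE)
  summ <- data.frame(
    condition = c("A", "B"),
    n_cells = c(cmp$summary_a$n_cells, cmp$summary_b$n_cells),
    plateau_um2 = c(cmp$summary_a$plateau_um2, cmp$summary_b$plateau_um2),
    rc_um = c(cmp$summary_a$rc_um, cmp$summary_b$rc_um),
    volume_um3 = c(cmp$summary_a$volume_um3, cmp$summary_b$volume_um3),
    converged = c(cmp$summary_a$converged, cmp$summary_b$converged))
  utils::write.csv(summ, file.path(dir, "mobility_summary.csv"),
                   row.names = FALSE)
  mt <- data.frame(method = cmp$test$method, statistic = cmp$test$statistic,
                   p_two_tailed = cmp$test$p_two_tailed,
                   n_a = cmp$test$n_a, n_b = cmp$test$n_b,
                   volume_fold = cmp$volume_fold, rc_ratio = cmp$rc_ratio)
  utils::write.csv(mt, file.path(dir, "mobility_test.csv"),
                   row.names = FALSE)
  eff <- list(seed = seed, n_cells_still = n_cells_still,
              n_cells_timelapse = n_cells_timelapse,
              rc_a = rc_a, rc_b = rc_b, mode = mode,
              package_version = as.character(utils::packageVersion("nucperi")))
  write_config(eff, file.path(dir, "run_config.json"))
  say("done: volume fold A/B = %.2f, Mann-Whitney p = %.3g",
      cmp$volume_fold, cmp$test$p_two_tailed)
  invisible(list(distances = rec, distance_test = ztest,
                 mobility = cmp, dir = dir))
}
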