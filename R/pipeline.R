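#' Pipeline configuration
#'
#' A single JSON file drives the whole pipeline. Top-level keys:
#' `seed` (master seed, deterministically split into per-stage
#' substreams), `out_dir`, `simulate` (roster sizes plus either a
#' `metrics` block of [metric_sim_config()] fields or a `tracks` block of
#' [trajectory_sim_config()] fields and `day_length_s`), `metrics`
#' (`radius`, `max_gap`, `stride`, `window_s`), `model` (`boot`,
#' `include_disease`) and `penmate` (`B`, `direction`, `within_cohort`).
#' Missing keys fall back to package defaults.
#'
#' @param path JSON config file.
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(seed = 1L, out_dir = "calfmove_out",
                   simulate = list(n_cohorts = 1L, calves_per_cohort = 4L,
                                   days_per_housing = 5L, level = "metrics"),
                   metrics = list(radius = 1, max_gap = 60, stride = 10,
                                  window_s = 10),
                   model = list(boot = 0L, include_disease = TRUE),
                   penmate = list(B = 1000L, direction = "lower",
                                  within_cohort = TRUE))
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# per-stage substreams from the master seed, kept < 2^31
stage_seed <- function(seed, stage) {
  offs <- c(roster = 11L, simulate = 23L, analyze = 37L, penmate = 53L)
  (as.integer(seed) * 101L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full simulate-to-penmate pipeline
#'
#' Executes simulate, (for trajectory-level configs) preprocess and
#' metrics, then analyze and penmate, writing each stage's artifact and a
#' machine-readable JSON manifest (seeds, config hash, row counts, stage
#' outputs) into `cfg$out_dir`. Stage boundaries log row counts to
#' stderr so filtering is auditable.
#'
#' @param cfg a `pipeline_config` (or path to one).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("calfmove")),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   stages = list())
  log_stage <- function(...) message("[calfmove] ", sprintf(...))

  sim <- cfg$simulate
  dph <- sim$days_per_housing
  roster <- make_roster(sim$n_cohorts, sim$calves_per_cohort,
                        seed = stage_seed(cfg$seed, "roster"),
                        n_days = 2L * dph)
  write_roster(roster, file.path(out_dir, "roster"))
  log_stage("roster: %d calves, %d cohorts", nrow(roster$calves),
            sim$n_cohorts)

  if (identical(sim$level, "tracks")) {
    panel <- pipeline_tracks_stage(cfg, roster, out_dir, log_stage, manifest)
    manifest <- attr(panel, "manifest")
  } else {
    mcfg_args <- sim$metrics
    if (is.null(mcfg_args)) mcfg_args <- list()
    mcfg <- do.call(metric_sim_config, c(
      list(n_cohorts = sim$n_cohorts,
           calves_per_cohort = sim$calves_per_cohort,
           days_per_housing = dph,
           seed = stage_seed(cfg$seed, "simulate")),
      mcfg_args))
    simout <- simulate_metric_panel(roster, mcfg)
    panel <- simout$panel
    write.csv(simout$truth$individual,
              file.path(out_dir, "sim_truth_individual.csv"),
              row.names = FALSE, quote = FALSE)
    log_stage("simulate (metric level): %d panel rows", nrow(panel))
  }
  write_metric_table(panel, file.path(out_dir, "daily_metrics.csv"))
  manifest$stages$simulate <- list(panel_rows = nrow(panel))

  # analyze: intercept + slope models, repeatability, correlation
  fit0 <- suppressWarnings(
    fit_random_intercept(panel, include_disease = cfg$model$include_disease))
  rep_res <- adjusted_repeatability(fit0, n_boot = cfg$model$boot,
                                    seed = stage_seed(cfg$seed, "analyze"))
  fit1 <- suppressWarnings(
    fit_random_slope(panel, include_disease = cfg$model$include_disease))
  ppc <- personality_plasticity_correlation(fit1)
  write.csv(fit1$individual_effects,
            file.path(out_dir, "individual_effects.csv"),
            row.names = FALSE, quote = FALSE)
  summary_lines <- c(
    sprintf("R = %.4f", rep_res$R),
    if (rep_res$n_boot > 0)
      sprintf("R_ci = [%.4f, %.4f]", rep_res$ci_low, rep_res$ci_high),
    sprintf("intercept_slope_r = %.4f", ppc$r),
    sprintf("intercept_slope_p = %.4g", ppc$p_value))
  writeLines(summary_lines, file.path(out_dir, "analysis_summary.txt"))
  log_stage("analyze: R = %.3f, intercept-slope r = %.3f", rep_res$R, ppc$r)
  manifest$stages$analyze <- list(R = rep_res$R, r = ppc$r)

  # penmate: pair-housing intercepts
  pair_panel <- panel[panel$housing == "pair", , drop = FALSE]
  fit_pair <- suppressWarnings(
    fit_random_intercept(pair_panel,
                         include_disease = cfg$model$include_disease))
  ints <- setNames(fit_pair$individual_effects$intercept_dev,
                   fit_pair$individual_effects$calf_id)
  pm <- permutation_test(ints, roster, B = cfg$penmate$B,
                         seed = stage_seed(cfg$seed, "penmate"),
                         direction = cfg$penmate$direction,
                         within_cohort = cfg$penmate$within_cohort)
  writeLines(sprintf("%.8g", pm$null_cvs),
             file.path(out_dir, "penmate_null_cvs.txt"))
  writeLines(sprintf("metric,housing,observed_cv,p_value,B,seed\n%s,pair,%.6f,%.6g,%d,%d",
                     panel$metric_name[1], pm$observed_cv, pm$p_value, pm$B,
                     pm$seed),
             file.path(out_dir, "penmate_summary.csv"))
  log_stage("penmate: observed CV = %.3f, p = %.3g", pm$observed_cv,
            pm$p_value)
  manifest$stages$penmate <- list(observed_cv = pm$observed_cv,
                                  p_value = pm$p_value)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

pipeline_tracks_stage <- function(cfg, roster, out_dir, log_stage, manifest) {
  sim <- cfg$simulate
  tcfg_args <- sim$tracks
  if (is.null(tcfg_args)) tcfg_args <- list()
  day_len <- if (!is.null(tcfg_args$day_length_s)) tcfg_args$day_length_s else 1200
  tcfg_args$day_length_s <- NULL
  pen_name <- if (!is.null(tcfg_args$pen)) tcfg_args$pen else "group"
  tcfg_args$pen <- NULL
  pen <- if (identical(pen_name, "pair")) pen_pair() else pen_group()
  n_days <- 2L * sim$days_per_housing
  tcfg <- do.call(trajectory_sim_config, c(
    list(pen = pen, duration = day_len * n_days,
         seed = stage_seed(cfg$seed, "simulate")), tcfg_args))
  traj <- simulate_trajectories(roster, tcfg)
  write_trajectory(traj, file.path(out_dir, "trajectories_raw.csv"))
  log_stage("simulate (tracks): %d fixes, %d outside pen after noise",
            nrow(traj), attr(traj, "n_out_of_pen"))

  excl_path <- cfg$exclusions
  iv <- if (!is.null(excl_path)) read_exclusions(excl_path)
        else exclusion_intervals()
  ex <- apply_exclusions(traj, iv, hz = tcfg$hz)
  fp <- filter_out_of_pen(ex$trajectory, pen)
  smoothed <- smooth_moving_average(fp$trajectory, cfg$metrics$window_s)
  rep <- coverage_report(ex$report$total_calf_hours,
                         ex$report$removed_calf_hours, fp$n_removed)
  writeLines(c(sprintf("total_calf_hours,%.6f", rep$total_calf_hours),
               sprintf("removed_calf_hours,%.6f", rep$removed_calf_hours),
               sprintf("removed_fraction,%s", format_percent(rep$removed_fraction)),
               sprintf("out_of_pen_points_removed,%d",
                       rep$out_of_pen_points_removed)),
             file.path(out_dir, "coverage_report.csv"))
  log_stage("preprocess: %d -> %d -> %d fixes (%s removed)",
            nrow(traj), nrow(ex$trajectory), nrow(fp$trajectory),
            format_percent(rep$removed_fraction))

  dd <- daily_distance(smoothed, day_length_s = day_len,
                       max_gap_s = cfg$metrics$max_gap)
  rt <- daily_residence_time(smoothed, radius = cfg$metrics$radius,
                             max_gap = cfg$metrics$max_gap,
                             stride = cfg$metrics$stride,
                             day_length_s = day_len)
  panel <- attach_covariates(rbind(dd, rt), roster,
                             days_per_housing = sim$days_per_housing)
  panel <- panel[panel$metric_name == "distance", , drop = FALSE]
  log_stage("metrics: %d calf-day rows", nrow(panel))
  attr(panel, "manifest") <- manifest
  panel
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write the small worked-example fixtures used in the unit tests
#'
#' Emits the toy inputs the documentation and tests share: a 4-point
#' square track (daily distance 3 m), a 4-reading static-tag placement
#' (CEP 0.1 m), and a 2-pair roster + intercepts for which the
#' permutation null can be enumerated exhaustively.
#'
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  toy_track <- data.frame(calf_id = "toy", t = 0:3,
                          x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  p1 <- file.path(out_dir, "toy_track.csv")
  write.csv(toy_track, p1, row.names = FALSE, quote = FALSE)
  tag <- data.frame(x = c(-0.1, 0.1, -0.3, 0.3), y = c(0, 0, 0, 0))
  p2 <- file.path(out_dir, "toy_static_tag.csv")
  write.csv(tag, p2, row.names = FALSE, quote = FALSE)
  r <- make_roster(1, 4, seed = 1, n_days = 2)
  write_roster(r, file.path(out_dir, "toy_roster"))
  ints <- data.frame(calf_id = r$calves$calf_id,
                     intercept_dev = c(0.0, 0.4, 1.0, 2.5))
  p3 <- file.path(out_dir, "toy_intercepts.csv")
  write.csv(ints, p3, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}
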