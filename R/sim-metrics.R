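#' Configuration for the daily-metric panel simulator
#'
#' Describes the generating model for a per-calf daily movement panel:
#'
#' \deqn{Y = \beta_0 + coh_k + b_{0j} + (\beta_3 + b_{1j}) \cdot housing
#'       + \beta_1 \cdot day + \beta_2 \cdot age + \beta_4 \cdot health + e}
#'
#' with cohort effects i.i.d. normal, per-calf intercept/slope deviations
#' `(b0, b1)` bivariate normal with correlation `cor_intercept_slope`, and
#' i.i.d. Gaussian residuals. In pair housing the *effective* individual
#' intercept is blended towards the pair mean with weight
#' `conformity_weight` (social conformity); group housing is untouched.
#'
#' Defaults are scaled to the daily-distance model of pair-then-group
#' housed dairy calves: housing effect 496.2 m/day and intercept-slope
#' correlation 0.57 are field estimates reused as generator defaults (not
#' ground truth), and the variance defaults
#' (`var_ind_intercept`/`var_resid` = 22500/67500 m2) imply an adjusted
#' repeatability of 0.25. The pair-housing baseline (`intercept`) is a free
#' parameter; 1200 m/day is a plausible value for young calves at 1 Hz
#' tracking.
#'
#' @param n_cohorts,calves_per_cohort design size (defaults 6 x 16).
#' @param days_per_housing tracked days in each housing (default 20).
#' @param fixed_effects named list: `intercept` (pair-housing baseline),
#'   `day` (per observation day), `age` (per day of age), `housing`
#'   (group minus pair), `health_sick`, `health_convalescent`
#'   (vs healthy). Metric units.
#' @param var_cohort,var_ind_intercept,var_ind_slope,var_resid variance
#'   components (metric units squared), all `>= 0`.
#' @param cor_intercept_slope correlation of individual intercept and
#'   housing-slope deviations, in \[-1, 1\].
#' @param conformity_weight pair-housing blending weight `w` in \[0, 1\];
#'   0 = no conformity, 1 = pen-mates share one pair intercept.
#' @param seed integer RNG seed.
#' @return An object of class `metric_sim_config`.
#' @export
metric_sim_config <- function(n_cohorts = 6, calves_per_cohort = 16,
                              days_per_housing = 20,
                              fixed_effects = list(
                                intercept = 1200, day = 5, age = 2,
                                housing = 496.2, health_sick = -150,
                                health_convalescent = -75),
                              var_cohort = 10000,
                              var_ind_intercept = 22500,
                              var_ind_slope = 10000,
                              cor_intercept_slope = 0.57,
                              var_resid = 67500,
                              conformity_weight = 0.5,
                              seed = 1L) {
  needed <- c("intercept", "day", "age", "housing", "health_sick",
              "health_convalescent")
  missing <- setdiff(needed, names(fixed_effects))
  if (length(missing)) stop("fixed_effects missing: ",
                            paste(missing, collapse = ", "))
  if (var_cohort < 0 || var_ind_intercept < 0 || var_ind_slope < 0 ||
      var_resid < 0) stop("variance components must be >= 0")
  if (abs(cor_intercept_slope) > 1) stop("|cor_intercept_slope| must be <= 1")
  if (conformity_weight < 0 || conformity_weight > 1) {
    stop("conformity_weight must be in [0, 1]")
  }
  # implied 2x2 covariance must be PSD: automatic when |rho| <= 1 and
  # variances >= 0, but a zero variance with nonzero rho is degenerate
  cfg <- list(n_cohorts = n_cohorts, calves_per_cohort = calves_per_cohort,
              days_per_housing = days_per_housing,
              fixed_effects = fixed_effects,
              var_cohort = var_cohort,
              var_ind_intercept = var_ind_intercept,
              var_ind_slope = var_ind_slope,
              cor_intercept_slope = cor_intercept_slope,
              var_resid = var_resid,
              conformity_weight = conformity_weight,
              seed = as.integer(seed))
  class(cfg) <- "metric_sim_config"
  cfg
}

#' Simulate a daily movement-metric panel with known ground truth
#'
#' Draws one value per calf-day from the random-slope generating model in
#' [metric_sim_config()]. Days `1..days_per_housing` are pair housing
#' (housing = 0), the remainder group housing (housing = 1); the day index
#' runs continuously across the move. In pair housing the individual
#' intercept is replaced by `(1-w) b0_j + w mean(b0 of the pair)`.
#'
#' @param roster a [make_roster()] roster; its health calendar must cover
#'   `2 * days_per_housing` days and its cohort sizes must match `cfg`.
#' @param cfg a [metric_sim_config()].
#' @param metric_name label for the simulated metric (default "distance").
#' @return A list with `panel` (data.frame: `calf_id`, `date`,
#'   `metric_name`, `value`, `day_of_observation`, `age`, `housing`,
#'   `health`, `cohort_id`) and `truth` (class `sim_truth`: per-calf
#'   `b0`, `b1`, `b0_pair_effective`, per-cohort effects, and the config).
#' @examples
#' r <- make_roster(1, 4, seed = 1, n_days = 10)
#' cfg <- metric_sim_config(n_cohorts = 1, calves_per_cohort = 4,
#'                          days_per_housing = 5, seed = 1)
#' sim <- simulate_metric_panel(r, cfg)
#' head(sim$panel)
#' @export
simulate_metric_panel <- function(roster, cfg, metric_name = "distance") {
  validate_roster(roster)
  stopifnot(inherits(cfg, "metric_sim_config"))
  calves <- roster$calves
  if (nrow(calves) != cfg$n_cohorts * cfg$calves_per_cohort ||
      length(unique(calves$cohort_id)) != cfg$n_cohorts) {
    stop("roster does not match config: expected ", cfg$n_cohorts, " x ",
         cfg$calves_per_cohort, " calves, got ", nrow(calves), " in ",
         length(unique(calves$cohort_id)), " cohorts")
  }
  n_days <- 2L * cfg$days_per_housing
  if (max(roster$health$day) < n_days) {
    stop("roster health calendar covers ", max(roster$health$day),
         " days; need ", n_days)
  }
  set.seed(cfg$seed)
  n <- nrow(calves)
  cohorts <- unique(calves$cohort_id)
  coh_eff <- setNames(rnorm(length(cohorts), 0, sqrt(cfg$var_cohort)),
                      cohorts)
  # bivariate normal individual deviations via Cholesky-style construction
  s0 <- sqrt(cfg$var_ind_intercept)
  s1 <- sqrt(cfg$var_ind_slope)
  rho <- cfg$cor_intercept_slope
  z0 <- rnorm(n); z1 <- rnorm(n)
  b0 <- s0 * z0
  b1 <- s1 * (rho * z0 + sqrt(1 - rho^2) * z1)
  # conformity: blend pair-housing intercept towards the pair mean
  w <- cfg$conformity_weight
  pair_mean <- tapply(b0, calves$pair_id, mean)[calves$pair_id]
  b0_pair <- (1 - w) * b0 + w * pair_mean

  fe <- cfg$fixed_effects
  day <- rep(seq_len(n_days), n)
  idx <- rep(seq_len(n), each = n_days)
  housing <- as.integer(day > cfg$days_per_housing)
  h <- roster$health[roster$health$day <= n_days, ]
  h <- h[order(match(h$calf_id, calves$calf_id), h$day), ]
  if (nrow(h) != n * n_days) stop("health calendar is not one row per calf-day")
  health <- h$health
  health_eff <- ifelse(health == "sick", fe$health_sick,
                       ifelse(health == "convalescent",
                              fe$health_convalescent, 0))
  ind_int <- ifelse(housing == 0L, b0_pair[idx], b0[idx])
  e <- rnorm(n * n_days, 0, sqrt(cfg$var_resid))
  value <- fe$intercept + coh_eff[calves$cohort_id[idx]] + ind_int +
    (fe$housing + b1[idx]) * housing + fe$day * day +
    fe$age * calves$age_at_group_day0[idx] + health_eff + e

  panel <- data.frame(
    calf_id = calves$calf_id[idx],
    date = day,
    metric_name = metric_name,
    value = as.numeric(value),
    day_of_observation = day,
    age = calves$age_at_group_day0[idx],
    housing = ifelse(housing == 0L, "pair", "group"),
    health = health,
    cohort_id = calves$cohort_id[idx],
    stringsAsFactors = FALSE)
  truth <- structure(list(
    individual = data.frame(calf_id = calves$calf_id, b0 = b0, b1 = b1,
                            b0_pair_effective = b0_pair,
                            stringsAsFactors = FALSE),
    cohort = data.frame(cohort_id = cohorts,
                        effect = as.numeric(coh_eff),
                        stringsAsFactors = FALSE),
    config = cfg), class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d calves, %d cohorts; R_true = %.3f, rho = %.2f, w = %.2f\n",
              nrow(x$individual), nrow(x$cohort),
              x$config$var_ind_intercept /
                (x$config$var_ind_intercept + x$config$var_resid),
              x$config$cor_intercept_slope, x$config$conformity_weight))
  invisible(x)
}
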