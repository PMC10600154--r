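# Independent oracles, deliberately written as naive scalar walks /
# double loops so they share no code path with the package internals.

# O(n^2)-flavoured residence time: scalar scan outward from the centre
# fix, skipping outside samples, breaking at the first inside-to-inside
# time gap above max_gap.
oracle_residence <- function(tt, x, y, i, radius = 1, max_gap = 60) {
  n <- length(tt)
  is_in <- function(j) sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2) <= radius
  last <- i
  j <- i + 1L
  while (j <= n) {
    if (is_in(j)) {
      if (tt[j] - tt[last] > max_gap) break
      last <- j
    }
    j <- j + 1L
  }
  t_fwd <- tt[last]
  last <- i
  j <- i - 1L
  while (j >= 1L) {
    if (is_in(j)) {
      if (tt[last] - tt[j] > max_gap) break
      last <- j
    }
    j <- j - 1L
  }
  t_fwd - tt[last]
}

# brute-force centred time-window mean, double loop
oracle_moving_average <- function(tt, v, window_s) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    acc <- 0; k <- 0L
    for (j in seq_along(v)) {
      if (abs(tt[j] - tt[i]) <= window_s / 2) { acc <- acc + v[j]; k <- k + 1L }
    }
    out[i] <- acc / k
  }
  out
}

# exhaustive permutation p-value for a 2-pair (4-calf) cohort: the 4! ID
# permutations induce the 3 distinct pairings uniformly.
oracle_enumerated_p <- function(ints, direction = "lower") {
  stopifnot(length(ints) == 4)
  cv <- function(d) if (mean(d) == 0) 0 else sd(d) / mean(d)
  obs <- cv(abs(c(ints[1] - ints[2], ints[3] - ints[4])))
  pairings <- list(rbind(c(1, 2), c(3, 4)),
                   rbind(c(1, 3), c(2, 4)),
                   rbind(c(1, 4), c(2, 3)))
  nulls <- vapply(pairings, function(p)
    cv(abs(ints[p[, 1]] - ints[p[, 2]])), numeric(1))
  if (direction == "lower") mean(obs <= nulls) else mean(obs >= nulls)
}

# random-walk test track for a single calf
make_random_walk <- function(n, step_sd = 0.5, seed = 1) {
  set.seed(seed)
  as_trajectory(data.frame(
    calf_id = "rw", t = seq_len(n) - 1,
    x = cumsum(rnorm(n, 0, step_sd)),
    y = cumsum(rnorm(n, 0, step_sd))))
}

# small metric panel with unit-scale variances for lmm experiments
unit_panel <- function(seed, r_true = 0.25, rho = 0, var_slope = 0, w = 0,
                       n_cohorts = 6, calves_per_cohort = 16,
                       days_per_housing = 20, var_cohort = 0.1) {
  roster <- make_roster(n_cohorts, calves_per_cohort, seed = seed,
                        n_days = 2L * days_per_housing)
  cfg <- metric_sim_config(
    n_cohorts = n_cohorts, calves_per_cohort = calves_per_cohort,
    days_per_housing = days_per_housing,
    fixed_effects = list(intercept = 10, day = 0.05, age = 0.02,
                         housing = 1, health_sick = -0.5,
                         health_convalescent = -0.25),
    var_cohort = var_cohort, var_ind_intercept = r_true,
    var_ind_slope = var_slope, cor_intercept_slope = rho,
    var_resid = 1 - r_true, conformity_weight = w, seed = seed)
  list(sim = simulate_metric_panel(roster, cfg), roster = roster, cfg = cfg)
}
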