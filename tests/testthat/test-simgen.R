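test_that("make_roster builds paired cohorts with valid ages and health", {
  r <- make_roster(6, 16, seed = 11)
  expect_equal(nrow(r$calves), 96)
  expect_equal(length(unique(r$calves$pair_id)), 48) # 8 pairs/cohort
  expect_true(all(table(r$calves$pair_id) == 2))
  same_cohort <- tapply(r$calves$cohort_id, r$calves$pair_id,
                        function(z) length(unique(z)))
  expect_true(all(same_cohort == 1))
  expect_true(all(r$calves$age_at_group_day0 > 0))
  expect_true(all(r$health$health %in% c("healthy", "sick", "convalescent")))

  r1 <- make_roster(1, 2, seed = 1)
  expect_equal(length(unique(r1$calves$pair_id)), 1)
  expect_equal(length(unique(r1$calves$cohort_id)), 1)

  expect_identical(make_roster(2, 4, seed = 7), make_roster(2, 4, seed = 7))
  expect_error(make_roster(2, 5, seed = 1), "even")
})

test_that("health episodes follow the sick-then-convalescent structure", {
  r <- make_roster(4, 16, seed = 5, n_days = 60, illness_hazard = 0.05)
  h <- r$health
  for (id in unique(h$calf_id)) {
    s <- h$health[h$calf_id == id]
    trans <- paste(s[-length(s)], s[-1])
    # a sick run may only end in convalescent (or record end)
    expect_false(any(trans == "sick healthy"))
    expect_false(any(trans == "healthy convalescent"))
  }
})

test_that("metric panel is deterministic and matches the fixed-effect surface when degenerate", {
  roster <- make_roster(2, 4, seed = 3, n_days = 10)
  fe <- list(intercept = 100, day = 2, age = 1, housing = 50,
             health_sick = -10, health_convalescent = -5)
  cfg <- metric_sim_config(n_cohorts = 2, calves_per_cohort = 4,
                           days_per_housing = 5, fixed_effects = fe,
                           var_cohort = 0, var_ind_intercept = 0,
                           var_ind_slope = 0, cor_intercept_slope = 0,
                           var_resid = 0, conformity_weight = 0, seed = 9)
  sim <- simulate_metric_panel(roster, cfg)
  expected <- with(sim$panel,
    fe$intercept + fe$day * day_of_observation + fe$age * age +
    fe$housing * (housing == "group") +
    fe$health_sick * (health == "sick") +
    fe$health_convalescent * (health == "convalescent"))
  expect_equal(sim$panel$value, expected, tolerance = 1e-12)

  sim2 <- simulate_metric_panel(roster, cfg)
  expect_identical(sim$panel, sim2$panel) # bit-for-bit under same seed
})

test_that("full conformity makes pen-mates share one pair-housing intercept", {
  roster <- make_roster(1, 8, seed = 2, n_days = 4)
  cfg <- metric_sim_config(n_cohorts = 1, calves_per_cohort = 8,
                           days_per_housing = 2, conformity_weight = 1,
                           seed = 4)
  truth <- simulate_metric_panel(roster, cfg)$truth
  eff <- truth$individual$b0_pair_effective
  shared <- tapply(eff, roster$calves$pair_id, function(z) diff(range(z)))
  expect_true(all(shared < 1e-12))
  # and w = 0 leaves intercepts untouched
  cfg0 <- metric_sim_config(n_cohorts = 1, calves_per_cohort = 8,
                            days_per_housing = 2, conformity_weight = 0,
                            seed = 4)
  truth0 <- simulate_metric_panel(roster, cfg0)$truth
  expect_equal(truth0$individual$b0_pair_effective, truth0$individual$b0)
})

test_that("between-calf variance of panel means grows with var_ind_intercept", {
  grid <- c(0.05, 0.5, 2)
  mean_vars <- vapply(grid, function(v) {
    vs <- vapply(1:50, function(s) {
      roster <- make_roster(1, 16, seed = s, n_days = 10)
      cfg <- metric_sim_config(n_cohorts = 1, calves_per_cohort = 16,
                               days_per_housing = 5,
                               var_cohort = 0, var_ind_intercept = v,
                               var_ind_slope = 0, cor_intercept_slope = 0,
                               var_resid = 1, conformity_weight = 0,
                               seed = s)
      p <- simulate_metric_panel(roster, cfg)$panel
      var(tapply(p$value, p$calf_id, mean))
    }, numeric(1))
    mean(vs)
  }, numeric(1))
  expect_true(all(diff(mean_vars) > 0))
})

test_that("config validation rejects bad variance structures", {
  expect_error(metric_sim_config(var_resid = -1), ">= 0")
  expect_error(metric_sim_config(cor_intercept_slope = 1.2), "<= 1")
  expect_error(metric_sim_config(conformity_weight = 2), "\\[0, 1\\]")
  roster <- make_roster(1, 4, seed = 1)
  cfg <- metric_sim_config(n_cohorts = 2, calves_per_cohort = 4, seed = 1)
  expect_error(simulate_metric_panel(roster, cfg), "does not match")
})

test_that("trajectory simulator: rest-only stays put, tracks stay in pen, activity scales distance", {
  roster <- make_roster(1, 2, seed = 1, n_days = 2)
  pen <- pen_group()
  cfg_rest <- trajectory_sim_config(pen, rest_to_move_rate = 0,
                                    sensor_noise_sd = 0, duration = 300,
                                    seed = 5)
  tr <- simulate_trajectories(roster, cfg_rest)
  expect_true(all(tr$x == tr$x[1] & tr$y == tr$y[1]))
  expect_equal(sum(daily_distance(tr, day_length_s = 400)$value), 0)

  cfg <- trajectory_sim_config(pen, sensor_noise_sd = 0.15, duration = 600,
                               rest_to_move_rate = 1 / 30, seed = 6)
  tr2 <- simulate_trajectories(roster, cfg)
  true_xy <- attr(tr2, "true_xy")
  expect_true(all(true_xy$true_x >= pen$x_min & true_xy$true_x <= pen$x_max &
                  true_xy$true_y >= pen$y_min & true_xy$true_y <= pen$y_max))
  expect_identical(simulate_trajectories(roster, cfg),
                   simulate_trajectories(roster, cfg))

  # doubling the activity multiplier increases mean distance across seeds
  dist_for <- function(mult) {
    mean(vapply(1:20, function(s) {
      cfgs <- trajectory_sim_config(pen, sensor_noise_sd = 0,
                                    duration = 400, seed = s)
      ids <- roster$calves$calf_id
      tr <- simulate_trajectories(roster, cfgs,
                                  setNames(rep(mult, 2), ids))
      sum(daily_distance(tr, day_length_s = 500)$value)
    }, numeric(1)))
  }
  expect_gt(dist_for(2), dist_for(1))
})

test_that("trajectory config rejects attraction points outside the pen", {
  expect_error(trajectory_sim_config(pen_pair(),
                                     attraction_points = rbind(c(5, 5))),
               "inside the pen")
})
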