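test_that("daily distance: stationary, straight-line and toy-square cases", {
  stat <- as_trajectory(data.frame(calf_id = "a", t = 0:59,
                                   x = rep(1, 60), y = rep(2, 60)))
  expect_equal(daily_distance(stat)$value, 0)

  line <- as_trajectory(data.frame(calf_id = "a", t = 0:3600,
                                   x = 0:3600, y = rep(0, 3601)))
  expect_equal(daily_distance(line, day_length_s = 4000)$value, 3600)

  sq <- as_trajectory(data.frame(calf_id = "a", t = 0:3,
                                 x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  expect_equal(daily_distance(sq)$value, 3)
})

test_that("daily distance zeroes segments across long gaps and splits days", {
  # 100-s hole between t=59 and t=160: that segment must contribute 0
  tt <- c(0:59, 160:219)
  tr <- as_trajectory(data.frame(calf_id = "a", t = tt,
                                 x = seq_along(tt), y = 0))
  d <- daily_distance(tr, max_gap_s = 60)
  expect_equal(d$value, length(tt) - 2) # 118 unit segments, gap zeroed

  # two days, segment at the boundary belongs to the leading fix's day
  tr2 <- as_trajectory(data.frame(calf_id = "a", t = 0:9, x = 0:9, y = 0))
  d2 <- daily_distance(tr2, day_length_s = 5)
  expect_equal(d2$date, c(1, 2))
  expect_equal(d2$value, c(5, 4)) # fixes 0..4 lead 5 segments, 5..8 lead 4

  # a day with < 2 fixes is omitted
  tr3 <- as_trajectory(data.frame(calf_id = "a", t = c(0, 1, 2, 10),
                                  x = 0:3, y = 0))
  expect_message(d3 <- daily_distance(tr3, day_length_s = 5),
                 "omitting")
  expect_equal(d3$date, 1)
})

test_that("rigid motions leave distance and residence time unchanged", {
  tr <- make_random_walk(300, seed = 3)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(tr$x, tr$y) %*% R
  tr_rot <- as_trajectory(data.frame(calf_id = "rw", t = tr$t,
                                     x = xy[, 1] + 5, y = xy[, 2] - 3))
  expect_equal(daily_distance(tr)$value, daily_distance(tr_rot)$value,
               tolerance = 1e-9)
  for (i in c(1, 57, 150, 300)) {
    expect_equal(residence_time_at(tr, i), residence_time_at(tr_rot, i),
                 tolerance = 1e-9)
  }
})

test_that("residence time: geometry and record-edge cases", {
  # stationary record: residence = full duration at every index
  stat <- as_trajectory(data.frame(calf_id = "a", t = 0:999,
                                   x = 0, y = 0))
  expect_equal(residence_time_at(stat, 500), 999)

  # straight line at 1 m/s, radius 1: neighbours only, no return -> 2 s
  line <- as_trajectory(data.frame(calf_id = "a", t = 0:200, x = 0:200,
                                   y = 0))
  expect_equal(residence_time_at(line, 100), 2)
  expect_equal(residence_time_at(line, 1), 1)   # record edge: one-sided

  expect_error(residence_time_at(line, 0), "out of range")
  expect_error(residence_time_at(line, 202), "out of range")
})

test_that("excursions shorter than max_gap are tolerated, longer ones end the clock", {
  # in circle 0..10, out 11..40 (29 s gap), back 41..50, then away
  tt <- 0:100
  x <- c(rep(0, 11), rep(5, 30), rep(0, 10), rep(9, 50))
  tr <- as_trajectory(data.frame(calf_id = "a", t = tt, x = x, y = 0))
  expect_equal(residence_time_at(tr, 5, radius = 1, max_gap = 60), 50)
  # with max_gap below the 31-s inside-to-inside gap, the clock stops
  expect_equal(residence_time_at(tr, 5, radius = 1, max_gap = 30), 10)
})

test_that("residence time agrees with the scalar-walk oracle on random walks", {
  for (s in 1:10) {
    tr <- make_random_walk(200, step_sd = 0.6, seed = s)
    idx <- seq(1, 200, by = 7)
    got <- vapply(idx, function(i) residence_time_at(tr, i), numeric(1))
    want <- vapply(idx, function(i)
      oracle_residence(tr$t, tr$x, tr$y, i), numeric(1))
    expect_identical(got, want)
  }
})

test_that("increasing radius never decreases residence time", {
  tr <- make_random_walk(300, seed = 9)
  for (i in c(10, 150, 290)) {
    r_small <- residence_time_at(tr, i, radius = 0.5)
    r_big <- residence_time_at(tr, i, radius = 2)
    expect_gte(r_big, r_small)
  }
})

test_that("daily residence time: stationary day, moving line, stride consistency", {
  stat <- as_trajectory(data.frame(calf_id = "a", t = 0:499, x = 0, y = 0))
  expect_equal(daily_residence_time(stat, stride = 1,
                                    day_length_s = 1000)$value, 499)

  # constant speed 0.5 m/s: interior residence ~ 2 * radius / speed = 4 s
  line <- as_trajectory(data.frame(calf_id = "a", t = 0:400,
                                   x = 0.5 * (0:400), y = 0))
  v <- daily_residence_time(line, stride = 1, day_length_s = 500)$value
  expect_equal(v, 4, tolerance = 0.1) # edge effects are O(1/n)

  tr <- make_random_walk(600, step_sd = 0.4, seed = 12)
  v1 <- daily_residence_time(tr, stride = 1, day_length_s = 1000)$value
  v10 <- daily_residence_time(tr, stride = 10, day_length_s = 1000)$value
  expect_lt(abs(v10 - v1) / v1, 0.05)
})

test_that("CEP: worked example, degenerate case, and ceiling(n/2) rule", {
  r <- rbind(c(-0.1, 0), c(0.1, 0), c(-0.3, 0), c(0.3, 0))
  expect_equal(cep(r), 0.1)
  expect_equal(cep(matrix(1, 5, 2)), 0)
  # odd n: 3rd of 5 distances
  r5 <- cbind(c(0, 0, 0, 0, 10), c(1, 2, 3, 4, 0))
  ctr <- colMeans(r5)
  d <- sort(sqrt((r5[, 1] - ctr[1])^2 + (r5[, 2] - ctr[2])^2))
  expect_equal(cep(r5), d[3])
  expect_lte(cep(r5), max(d))
  expect_error(cep(rbind(c(0, 0))), "nrow")
})

test_that("DIST: worked examples", {
  expect_equal(dist_accuracy(rbind(c(0, 0), c(0, 0)), c(0, 0)), 0)
  expect_equal(dist_accuracy(rbind(c(0.1, 0), c(0.3, 0)), c(0, 0)), 0.2)
})

test_that("attach_covariates joins roster fields and housing by day", {
  roster <- make_roster(1, 4, seed = 2, n_days = 10)
  rows <- data.frame(calf_id = rep(roster$calves$calf_id[1:2], each = 10),
                     date = rep(1:10, 2), metric_name = "distance",
                     value = 1)
  panel <- attach_covariates(rows, roster, days_per_housing = 5)
  expect_equal(unique(panel$housing[panel$date <= 5]), "pair")
  expect_equal(unique(panel$housing[panel$date > 5]), "group")
  expect_equal(panel$cohort_id, rep("C01", 20))
  expect_error(attach_covariates(transform(rows, calf_id = "ghost"), roster),
               "absent")
})
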