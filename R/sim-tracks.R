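#' Configuration for the 1 Hz trajectory simulator
#'
#' Movement is a two-state (rest/move) switching process sampled at `hz`.
#' While moving, the calf steps `move_speed / hz` metres per sample towards
#' a randomly chosen attraction point (feeder, trough, lying area) with
#' Gaussian angular jitter, re-targeting on arrival; positions are clipped
#' to the pen boundary. Isotropic Gaussian sensor noise (sd
#' `sensor_noise_sd`, default 0.15 m, the scale of ultra-wideband indoor
#' positioning error) is added afterwards, so noisy fixes can fall outside
#' the pen — deliberately, to exercise the out-of-pen filter.
#'
#' @param pen a [pen_geometry()].
#' @param hz sampling rate, samples per second (default 1).
#' @param rest_to_move_rate,move_to_rest_rate switching rates per second,
#'   `>= 0` (0 disables the transition).
#' @param move_speed movement speed in m/s.
#' @param attraction_points two-column matrix (x, y) of targets; all must
#'   lie inside the pen.
#' @param sensor_noise_sd positioning noise sd in metres, `>= 0`.
#' @param duration recording length in seconds.
#' @param angle_jitter_sd sd of per-step heading jitter in radians
#'   (0 gives straight legs).
#' @param start optional start position `c(x, y)`; default pen centre.
#' @param init_state initial behavioural state, `"rest"` or `"move"`.
#' @param seed integer RNG seed.
#' @return An object of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(pen, hz = 1,
                                  rest_to_move_rate = 1 / 120,
                                  move_to_rest_rate = 1 / 30,
                                  move_speed = 0.5,
                                  attraction_points = NULL,
                                  sensor_noise_sd = 0.15,
                                  duration = 3600,
                                  angle_jitter_sd = 0.3,
                                  start = NULL,
                                  init_state = c("rest", "move"),
                                  seed = 1L) {
  stopifnot(inherits(pen, "pen_geometry"), hz > 0, move_speed > 0,
            duration > 0, sensor_noise_sd >= 0, angle_jitter_sd >= 0)
  if (rest_to_move_rate < 0 || move_to_rest_rate < 0) {
    stop("switching rates must be >= 0")
  }
  if (is.null(attraction_points)) {
    # feeder / trough / lying area: corners-ish plus centre
    attraction_points <- rbind(
      c(pen$x_min + 0.2 * (pen$x_max - pen$x_min),
        pen$y_min + 0.1 * (pen$y_max - pen$y_min)),
      c(pen$x_max - 0.2 * (pen$x_max - pen$x_min),
        pen$y_min + 0.1 * (pen$y_max - pen$y_min)),
      c((pen$x_min + pen$x_max) / 2, pen$y_max - 0.15 * (pen$y_max - pen$y_min)))
  }
  attraction_points <- as.matrix(attraction_points)
  if (ncol(attraction_points) != 2) stop("attraction_points must be n x 2")
  if (!all(points_in_pen(attraction_points[, 1], attraction_points[, 2], pen))) {
    stop("all attraction points must lie inside the pen")
  }
  if (is.null(start)) {
    start <- c((pen$x_min + pen$x_max) / 2, (pen$y_min + pen$y_max) / 2)
  }
  if (!points_in_pen(start[1], start[2], pen)) stop("start must lie inside the pen")
  structure(list(pen = pen, hz = hz,
                 rest_to_move_rate = rest_to_move_rate,
                 move_to_rest_rate = move_to_rest_rate,
                 move_speed = move_speed,
                 attraction_points = attraction_points,
                 sensor_noise_sd = sensor_noise_sd,
                 duration = duration,
                 angle_jitter_sd = angle_jitter_sd,
                 start = start,
                 init_state = match.arg(init_state),
                 seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

#' Simulate noisy positional tracks for a roster of calves
#'
#' Runs the two-state movement model of [trajectory_sim_config()]
#' independently for every calf in the roster. `per_calf_activity`
#' multiplies the rest-to-move rate, so more active calves spend more time
#' in the moving state.
#'
#' @param roster a [make_roster()] roster.
#' @param cfg a [trajectory_sim_config()].
#' @param per_calf_activity optional named numeric vector of positive
#'   multipliers, one per calf (default all 1).
#' @return A trajectory data.frame (`calf_id`, `t`, `x`, `y`, `quality` =
#'   "raw") with attributes `n_out_of_pen` (count of noisy fixes outside
#'   the pen — ground truth for the out-of-pen filter) and `true_xy`
#'   (noise-free positions, guaranteed inside the pen).
#' @export
simulate_trajectories <- function(roster, cfg, per_calf_activity = NULL) {
  validate_roster(roster)
  stopifnot(inherits(cfg, "trajectory_sim_config"))
  ids <- roster$calves$calf_id
  if (is.null(per_calf_activity)) {
    per_calf_activity <- setNames(rep(1, length(ids)), ids)
  }
  if (any(per_calf_activity <= 0)) stop("activity multipliers must be > 0")
  if (!all(ids %in% names(per_calf_activity))) {
    stop("per_calf_activity must name every calf in the roster")
  }
  set.seed(cfg$seed)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- simulate_one_track(ids[i], cfg, per_calf_activity[[ids[i]]])
  }
  traj <- do.call(rbind, out)
  true_xy <- traj[, c("true_x", "true_y")]
  noisy_out <- !points_in_pen(traj$x, traj$y, cfg$pen)
  traj <- traj[, c("calf_id", "t", "x", "y")]
  traj$quality <- "raw"
  attr(traj, "n_out_of_pen") <- sum(noisy_out)
  attr(traj, "true_xy") <- true_xy
  class(traj) <- c("calf_trajectory", "data.frame")
  traj
}

simulate_one_track <- function(id, cfg, activity) {
  n <- floor(cfg$duration * cfg$hz) + 1L
  dt <- 1 / cfg$hz
  p_rm <- 1 - exp(-cfg$rest_to_move_rate * activity * dt)
  p_mr <- 1 - exp(-cfg$move_to_rest_rate * dt)
  step <- cfg$move_speed * dt
  pen <- cfg$pen
  ap <- cfg$attraction_points
  x <- numeric(n); y <- numeric(n)
  x[1] <- cfg$start[1]; y[1] <- cfg$start[2]
  moving <- cfg$init_state == "move"
  target <- ap[sample.int(nrow(ap), 1L), ]
  # pre-draw uniforms and jitter for speed; state loop stays scalar
  u_switch <- runif(n)
  jit <- if (cfg$angle_jitter_sd > 0) rnorm(n, 0, cfg$angle_jitter_sd) else numeric(n)
  for (k in 2:n) {
    if (moving) {
      if (u_switch[k] < p_mr) moving <- FALSE
    } else {
      if (u_switch[k] < p_rm) {
        moving <- TRUE
        target <- ap[sample.int(nrow(ap), 1L), ]
      }
    }
    if (moving) {
      dx <- target[1] - x[k - 1L]; dy <- target[2] - y[k - 1L]
      d <- sqrt(dx^2 + dy^2)
      if (d <= step) { # arrived: re-target
        x[k] <- target[1]; y[k] <- target[2]
        target <- ap[sample.int(nrow(ap), 1L), ]
      } else {
        ang <- atan2(dy, dx) + jit[k]
        x[k] <- x[k - 1L] + step * cos(ang)
        y[k] <- y[k - 1L] + step * sin(ang)
      }
      # reflective behaviour at walls, implemented as clip to boundary
      x[k] <- min(max(x[k], pen$x_min), pen$x_max)
      y[k] <- min(max(y[k], pen$y_min), pen$y_max)
    } else {
      x[k] <- x[k - 1L]; y[k] <- y[k - 1L]
    }
  }
  t <- (seq_len(n) - 1L) * dt
  if (cfg$sensor_noise_sd > 0) {
    nx <- x + rnorm(n, 0, cfg$sensor_noise_sd)
    ny <- y + rnorm(n, 0, cfg$sensor_noise_sd)
  } else { nx <- x; ny <- y }
  data.frame(calf_id = id, t = t, x = nx, y = ny,
             true_x = x, true_y = y, stringsAsFactors = FALSE)
}
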