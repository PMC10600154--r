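#' Assign fixes to observation days
#'
#' Day index is `floor((t - origin) / day_length) + 1`, i.e. calendar days
#' in the local clock with a configurable anchor.
#'
#' @param t time in seconds.
#' @param day_length_s day length in seconds (default 86400).
#' @param origin_s clock offset of day 1 start (default 0).
#' @return integer day index.
#' @export
assign_days <- function(t, day_length_s = 86400, origin_s = 0) {
  as.integer(floor((t - origin_s) / day_length_s)) + 1L
}

#' Daily distance travelled
#'
#' Sums the Euclidean distances between consecutive fixes of each calf,
#' attributing each segment to the day of its leading fix. Segments that
#' span a recording gap longer than `max_gap_s` (e.g. an exclusion
#' interval) contribute 0, so data removal cannot create phantom
#' displacement. Days with fewer than 2 fixes are omitted with a message.
#'
#' @param traj a trajectory, normally smoothed
#'   ([smooth_moving_average()]).
#' @param day_length_s,origin_s day grid, see [assign_days()].
#' @param max_gap_s segments with time step above this contribute 0
#'   (default 60).
#' @return data.frame rows: `calf_id`, `date`, `metric_name` =
#'   "distance", `value` (metres).
#' @examples
#' tr <- as_trajectory(data.frame(calf_id = "a", t = 0:3,
#'                                x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' daily_distance(tr)$value # 3 m
#' @export
daily_distance <- function(traj, day_length_s = 86400, origin_s = 0,
                           max_gap_s = 60) {
  traj <- as_trajectory(traj)
  res <- lapply(split(traj[, c("t", "x", "y")], traj$calf_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    dt <- diff(d$t)
    seg <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    seg[dt > max_gap_s] <- 0
    day <- assign_days(d$t[-nrow(d)], day_length_s, origin_s)
    n_by_day <- table(assign_days(d$t, day_length_s, origin_s))
    few <- names(n_by_day)[n_by_day < 2]
    if (length(few)) message("omitting ", length(few),
                             " day(s) with < 2 fixes")
    v <- tapply(seg, day, sum)
    keep <- !(names(v) %in% few)
    data.frame(date = as.integer(names(v)[keep]),
               value = as.numeric(v[keep]))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(calf_id = character(), date = integer(),
                      metric_name = character(), value = numeric()))
  }
  out <- do.call(rbind, Map(function(id, d) {
    data.frame(calf_id = id, date = d$date, metric_name = "distance",
               value = d$value, stringsAsFactors = FALSE)
  }, names(res), res))
  rownames(out) <- NULL
  out
}

#' Residence time at a single fix
#'
#' The time an animal spends inside a circle of radius `radius` centred on
#' fix `i`, tolerating excursions: scanning forward from `i`, the clock
#' runs until the gap between consecutive inside-circle fixes exceeds
#' `max_gap` seconds (or the record ends); `t_fwd` is the last inside fix
#' before that event. `t_bwd` is defined symmetrically scanning backward.
#' Residence time is `t_fwd - t_bwd`.
#'
#' @param traj trajectory rows for a *single* calf.
#' @param i sample index (1-based) of the centre fix.
#' @param radius circle radius in metres (default 1, roughly 10x the
#'   positioning error).
#' @param max_gap maximum tolerated excursion in seconds (default 60).
#' @return residence time in seconds.
#' @export
residence_time_at <- function(traj, i, radius = 1, max_gap = 60) {
  stopifnot(radius > 0, max_gap >= 0)
  n <- nrow(traj)
  if (i < 1 || i > n) stop("index out of range: ", i, " (n = ", n, ")")
  if (length(unique(traj$calf_id)) > 1) {
    stop("residence_time_at expects a single-calf trajectory")
  }
  d2 <- (traj$x - traj$x[i])^2 + (traj$y - traj$y[i])^2
  inside <- d2 <= radius^2
  ts <- traj$t[inside]
  pos <- sum(inside[seq_len(i)]) # centre fix is always inside (d = 0)
  gaps <- diff(ts)
  # forward: first inter-fix gap > max_gap after the centre
  fwd_break <- which(gaps[seq.int(pos, length.out = length(ts) - pos)] > max_gap)
  t_fwd <- if (length(fwd_break)) ts[pos + fwd_break[1] - 1L] else ts[length(ts)]
  # backward: nearest gap > max_gap before the centre
  if (pos > 1) {
    bwd_break <- which(gaps[seq_len(pos - 1L)] > max_gap)
    t_bwd <- if (length(bwd_break)) ts[max(bwd_break) + 1L] else ts[1]
  } else t_bwd <- ts[1]
  t_fwd - t_bwd
}

#' Daily residence time
#'
#' Mean of [residence_time_at()] over the fixes of each calf-day.
#' `stride` subsamples the centre fixes for tractability (default every
#' 10th fix; stride 1 is the exact reference). Residence windows may
#' extend beyond the day of the centre fix: the statistic is anchored to
#' where the animal *is* during that day.
#'
#' @inheritParams daily_distance
#' @inheritParams residence_time_at
#' @param stride centre-fix subsampling step (default 10).
#' @return data.frame rows: `calf_id`, `date`, `metric_name` =
#'   "residence_time", `value` (seconds).
#' @export
daily_residence_time <- function(traj, radius = 1, max_gap = 60,
                                 stride = 10, day_length_s = 86400,
                                 origin_s = 0) {
  traj <- as_trajectory(traj)
  stopifnot(stride >= 1)
  res <- lapply(split(traj[, c("calf_id", "t", "x", "y")], traj$calf_id),
                function(d) {
    if (nrow(d) == 0) return(NULL)
    day <- assign_days(d$t, day_length_s, origin_s)
    vals <- lapply(split(seq_len(nrow(d)), day), function(idx) {
      centres <- idx[seq(1, length(idx), by = stride)]
      mean(vapply(centres, function(i)
        residence_time_at(d, i, radius, max_gap), numeric(1)))
    })
    data.frame(date = as.integer(names(vals)),
               value = as.numeric(unlist(vals)))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(calf_id = character(), date = integer(),
                      metric_name = character(), value = numeric()))
  }
  out <- do.call(rbind, Map(function(id, d) {
    data.frame(calf_id = id, date = d$date, metric_name = "residence_time",
               value = d$value, stringsAsFactors = FALSE)
  }, names(res), res))
  rownames(out) <- NULL
  out
}

#' Static-tag validation statistics: CEP and DIST
#'
#' `cep()` is the circular error probability: the smallest radius of a
#' circle centred at the *mean reported position* containing at least 50%
#' of the readings — the ceiling(n/2)-th smallest distance to the mean.
#' `dist_accuracy()` is the mean Euclidean distance between the ground
#' truth position and each reading.
#'
#' @param readings two-column matrix or data.frame of (x, y) readings.
#' @param truth ground-truth position `c(x, y)`.
#' @return radius / mean distance in metres.
#' @examples
#' r <- rbind(c(-0.1, 0), c(0.1, 0), c(-0.3, 0), c(0.3, 0))
#' cep(r)                      # 0.1
#' dist_accuracy(r[1:2, ] + 0.2, c(0.2, 0.2)) # mean offset
#' @export
cep <- function(readings) {
  readings <- as.matrix(readings)
  stopifnot(ncol(readings) == 2, nrow(readings) >= 2)
  ctr <- colMeans(readings)
  d <- sqrt((readings[, 1] - ctr[1])^2 + (readings[, 2] - ctr[2])^2)
  sort(d)[ceiling(nrow(readings) / 2)]
}

#' @rdname cep
#' @export
dist_accuracy <- function(readings, truth) {
  readings <- as.matrix(readings)
  stopifnot(ncol(readings) == 2, nrow(readings) >= 1, length(truth) == 2)
  mean(sqrt((readings[, 1] - truth[1])^2 + (readings[, 2] - truth[2])^2))
}

#' Attach design covariates to metric rows
#'
#' Joins roster covariates (cohort, age, per-day health) and the housing
#' label onto metric rows, producing the analysis panel.
#'
#' @param rows output of [daily_distance()] / [daily_residence_time()].
#' @param roster a [make_roster()] roster.
#' @param days_per_housing days 1..`days_per_housing` are labelled
#'   "pair", later days "group".
#' @return the full daily-metric panel data.frame.
#' @export
attach_covariates <- function(rows, roster, days_per_housing = 20) {
  validate_roster(roster)
  calves <- roster$calves
  m <- match(rows$calf_id, calves$calf_id)
  if (anyNA(m)) stop("metric rows contain calves absent from the roster")
  key <- paste(rows$calf_id, rows$date)
  hkey <- paste(roster$health$calf_id, roster$health$day)
  hm <- match(key, hkey)
  data.frame(rows,
             day_of_observation = rows$date,
             age = calves$age_at_group_day0[m],
             housing = ifelse(rows$date <= days_per_housing, "pair", "group"),
             health = ifelse(is.na(hm), "healthy", roster$health$health[hm]),
             cohort_id = calves$cohort_id[m],
             stringsAsFactors = FALSE)
}
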