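#' Trajectory constructor/validator
#'
#' A trajectory is a data.frame with columns `calf_id`, `t` (seconds,
#' strictly increasing within calf), `x`, `y` (metres, finite) and
#' `quality` ("raw" or "smoothed").
#'
#' @param df data.frame with at least `calf_id`, `t`, `x`, `y`.
#' @return The validated trajectory with class `calf_trajectory`.
#' @export
as_trajectory <- function(df) {
  need <- c("calf_id", "t", "x", "y")
  if (!all(need %in% names(df))) {
    stop("trajectory needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(df$quality)) df$quality <- "raw"
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$t))) {
    stop("trajectory coordinates and times must be finite")
  }
  ord <- order(df$calf_id, df$t)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  dup <- unlist(tapply(df$t, df$calf_id, function(tt) c(FALSE, diff(tt) <= 0)),
                use.names = FALSE)
  if (any(dup)) stop("t must be strictly increasing within calf (duplicates?)")
  class(df) <- unique(c("calf_trajectory", class(df)))
  df
}

#' Exclusion-interval table
#'
#' Intervals are half-open `[start, end)` in seconds and may overlap
#' (union semantics): a fix is excluded if it falls in any interval.
#'
#' @param start,end numeric vectors of interval bounds, `end > start`.
#' @param reason optional character vector.
#' @return data.frame of class `exclusion_intervals`.
#' @export
exclusion_intervals <- function(start = numeric(), end = numeric(),
                                reason = NULL) {
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end <= start)) stop("intervals require end > start")
  if (is.null(reason)) reason <- rep("unspecified", length(start))
  structure(data.frame(start = as.numeric(start), end = as.numeric(end),
                       reason = as.character(reason),
                       stringsAsFactors = FALSE),
            class = c("exclusion_intervals", "data.frame"))
}

#' Remove human/vehicle disturbance intervals from a trajectory
#'
#' Drops every fix whose timestamp falls in the union of the half-open
#' exclusion intervals and accumulates the removed recording time.
#'
#' @param traj a trajectory ([as_trajectory()]).
#' @param iv an [exclusion_intervals()] table (empty = no-op).
#' @param hz nominal sampling rate used to convert dropped samples to
#'   calf-hours (default 1).
#' @return list with `trajectory` (retained fixes) and `report` (fields
#'   `total_calf_hours`, `removed_calf_hours`).
#' @export
apply_exclusions <- function(traj, iv = exclusion_intervals(), hz = 1) {
  traj <- as_trajectory(traj)
  total_h <- nrow(traj) / hz / 3600
  if (nrow(iv) == 0) {
    return(list(trajectory = traj,
                report = list(total_calf_hours = total_h,
                              removed_calf_hours = 0)))
  }
  excl <- rep(FALSE, nrow(traj))
  for (r in seq_len(nrow(iv))) {
    excl <- excl | (traj$t >= iv$start[r] & traj$t < iv$end[r])
  }
  out <- traj[!excl, , drop = FALSE]
  rownames(out) <- NULL
  list(trajectory = out,
       report = list(total_calf_hours = total_h,
                     removed_calf_hours = sum(excl) / hz / 3600))
}

#' Drop fixes outside the pen
#'
#' Positioning noise can place a fix outside the physical pen; such points
#' are removed. Boundary points (equality) are retained.
#'
#' @param traj a trajectory.
#' @param pen a [pen_geometry()].
#' @return list with `trajectory` and `n_removed`.
#' @export
filter_out_of_pen <- function(traj, pen) {
  traj <- as_trajectory(traj)
  keep <- points_in_pen(traj$x, traj$y, pen)
  out <- traj[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(trajectory = out, n_removed = sum(!keep))
}

#' Smooth a trajectory with a centred time-window moving average
#'
#' Each coordinate is replaced by the mean over all fixes of the same calf
#' within `window_s / 2` seconds (a centred 10-s window by default, so at
#' 1 Hz up to 11 samples). Windows are truncated at record edges and
#' across gaps: only the fixes actually present are averaged, and nothing
#' is interpolated. Row count and timestamps are preserved;
#' `quality` becomes "smoothed".
#'
#' @param traj a trajectory.
#' @param window_s total window width in seconds (default 10).
#' @return The smoothed trajectory.
#' @export
smooth_moving_average <- function(traj, window_s = 10) {
  traj <- as_trajectory(traj)
  stopifnot(window_s > 0)
  half <- window_s / 2
  parts <- split(seq_len(nrow(traj)), traj$calf_id)
  for (rows in parts) {
    tt <- traj$t[rows]
    # window [t-half, t+half]: cumulative sums + findInterval, O(n log n)
    lo <- findInterval(tt - half, tt, left.open = TRUE) + 1L
    hi <- findInterval(tt + half, tt)
    cx <- c(0, cumsum(traj$x[rows]))
    cy <- c(0, cumsum(traj$y[rows]))
    nwin <- hi - lo + 1L
    traj$x[rows] <- (cx[hi + 1L] - cx[lo]) / nwin
    traj$y[rows] <- (cy[hi + 1L] - cy[lo]) / nwin
  }
  traj$quality <- "smoothed"
  traj
}

#' Coverage report for the cleaning stage
#'
#' @param total_calf_hours,removed_calf_hours recording time before
#'   cleaning and time removed by exclusion intervals, in calf-hours.
#' @param out_of_pen_points_removed count of fixes dropped by the pen
#'   filter.
#' @return list of class `coverage_report`, with `removed_fraction` =
#'   removed/total.
#' @examples
#' r <- coverage_report(85320, 9045)
#' print(r) # removed fraction prints as 10.6%
#' @export
coverage_report <- function(total_calf_hours, removed_calf_hours,
                            out_of_pen_points_removed = 0L) {
  stopifnot(total_calf_hours >= 0, removed_calf_hours >= 0,
            removed_calf_hours <= total_calf_hours)
  structure(list(total_calf_hours = total_calf_hours,
                 removed_calf_hours = removed_calf_hours,
                 removed_fraction = if (total_calf_hours > 0)
                   removed_calf_hours / total_calf_hours else 0,
                 out_of_pen_points_removed = out_of_pen_points_removed),
            class = "coverage_report")
}

#' @rdname coverage_report
#' @param x a `coverage_report`.
#' @param ... unused.
#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s of %s calf-hours removed (%s); %d out-of-pen fixes dropped\n",
              format(x$removed_calf_hours, big.mark = ","),
              format(x$total_calf_hours, big.mark = ","),
              format_percent(x$removed_fraction),
              x$out_of_pen_points_removed))
  invisible(x)
}

#' Format a fraction as a percentage, round-half-up to 1 decimal
#'
#' `format_percent(9045/85320)` prints `"10.6%"`.
#'
#' @param frac fraction in \[0, 1\].
#' @return character scalar like "10.6%".
#' @export
format_percent <- function(frac) {
  sprintf("%.1f%%", floor(frac * 1000 + 0.5) / 10)
}
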