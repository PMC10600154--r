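#' Read and write pipeline files
#'
#' All pipeline artifacts are plain delimited text with headers:
#' trajectories (`calf_id,t,x,y`), exclusion intervals
#' (`start,end,reason`), rosters (a `*_calves.csv` /
#' `*_health.csv` file pair), daily-metric panels and per-individual
#' effects tables. Simulator/pipeline configs are JSON.
#'
#' @param path file path (`prefix` for rosters: two files are written,
#'   `<prefix>_calves.csv` and `<prefix>_health.csv`).
#' @param traj,iv,roster,panel objects to write.
#' @name calfmove-io
NULL

#' @rdname calfmove-io
#' @export
read_trajectory <- function(path) {
  as_trajectory(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname calfmove-io
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj)[, c("calf_id", "t", "x", "y")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calfmove-io
#' @export
read_exclusions <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  exclusion_intervals(d$start, d$end, d$reason)
}

#' @rdname calfmove-io
#' @export
write_exclusions <- function(iv, path) {
  write.csv(as.data.frame(iv), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calfmove-io
#' @export
write_roster <- function(roster, path) {
  validate_roster(roster)
  write.csv(roster$calves, paste0(path, "_calves.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(roster$health, paste0(path, "_health.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calfmove-io
#' @export
read_roster <- function(path) {
  r <- structure(list(
    calves = read.csv(paste0(path, "_calves.csv"), stringsAsFactors = FALSE),
    health = read.csv(paste0(path, "_health.csv"), stringsAsFactors = FALSE)),
    class = "calf_roster")
  validate_roster(r)
  r
}

#' @rdname calfmove-io
#' @export
write_metric_table <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname calfmove-io
#' @export
read_metric_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
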