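#' Generate a cohort/pair roster with ages and health episodes
#'
#' Builds the experimental-design skeleton: calves grouped into cohorts of
#' pair-housed dyads, with per-calf ages and a per-day health status. Ages
#' are drawn from a truncated normal (default mean 36.6 d, sd 4 d,
#' truncated at > 0), matching typical age at the move to group housing.
#' Illness is simulated as sporadic episodes: on any healthy day a calf
#' falls sick with probability `illness_hazard`; an episode is
#' `sick_days` days of "sick" followed by `convalescent_days` days of
#' "convalescent", after which the calf is healthy again.
#'
#' @param n_cohorts number of cohorts.
#' @param calves_per_cohort calves per cohort; must be even so the cohort
#'   tiles into pairs (default 16, i.e. 8 pairs).
#' @param seed integer RNG seed; identical arguments reproduce the roster
#'   bit-for-bit.
#' @param n_days number of tracked days per calf for the health calendar
#'   (default 40 = 20 pair-housing + 20 group-housing days).
#' @param age_mean,age_sd age distribution (days) at day 0 in the group pen.
#' @param illness_hazard daily probability that a healthy calf falls sick.
#' @param sick_days,convalescent_days episode structure in days.
#' @return An object of class `calf_roster`: a list with
#'   `calves` (data.frame: `calf_id`, `cohort_id`, `pair_id`,
#'   `age_at_group_day0`) and `health` (data.frame: `calf_id`, `day`,
#'   `health` in healthy/sick/convalescent).
#' @examples
#' r <- make_roster(2, 4, seed = 7)
#' table(r$calves$cohort_id)
#' @export
make_roster <- function(n_cohorts, calves_per_cohort = 16, seed = 1L,
                        n_days = 40, age_mean = 36.6, age_sd = 4,
                        illness_hazard = 0.01, sick_days = 3,
                        convalescent_days = 3) {
  stopifnot(n_cohorts >= 1, calves_per_cohort >= 2, n_days >= 1)
  if (calves_per_cohort %% 2 != 0) {
    stop("calves_per_cohort must be even: pairs must tile the cohort, got ",
         calves_per_cohort)
  }
  set.seed(as.integer(seed))
  n <- n_cohorts * calves_per_cohort
  cohort_id <- rep(sprintf("C%02d", seq_len(n_cohorts)),
                   each = calves_per_cohort)
  calf_id <- sprintf("%s_calf%02d", cohort_id,
                     rep(seq_len(calves_per_cohort), n_cohorts))
  pair_id <- sprintf("%s_pair%02d", cohort_id,
                     rep(rep(seq_len(calves_per_cohort / 2), each = 2),
                         n_cohorts))
  age <- rnorm(n, age_mean, age_sd)
  while (any(age <= 0)) { # truncation at > 0
    bad <- age <= 0
    age[bad] <- rnorm(sum(bad), age_mean, age_sd)
  }
  calves <- data.frame(calf_id = calf_id, cohort_id = cohort_id,
                       pair_id = pair_id,
                       age_at_group_day0 = age,
                       stringsAsFactors = FALSE)
  health <- simulate_health(calf_id, n_days, illness_hazard,
                            sick_days, convalescent_days)
  structure(list(calves = calves, health = health),
            class = "calf_roster")
}

simulate_health <- function(calf_id, n_days, hazard, sick_days, conv_days) {
  status <- matrix("healthy", nrow = length(calf_id), ncol = n_days)
  for (i in seq_along(calf_id)) {
    d <- 1L
    while (d <= n_days) {
      if (runif(1) < hazard) {
        sick_end <- min(n_days, d + sick_days - 1L)
        status[i, d:sick_end] <- "sick"
        if (sick_end < n_days) {
          conv_end <- min(n_days, sick_end + conv_days)
          status[i, (sick_end + 1L):conv_end] <- "convalescent"
          d <- conv_end + 1L
        } else d <- n_days + 1L
      } else d <- d + 1L
    }
  }
  data.frame(calf_id = rep(calf_id, each = n_days),
             day = rep(seq_len(n_days), length(calf_id)),
             health = as.vector(t(status)),
             stringsAsFactors = FALSE)
}

#' @export
print.calf_roster <- function(x, ...) {
  cat(sprintf("<calf_roster> %d calves, %d cohorts, %d pairs, %d health days\n",
              nrow(x$calves), length(unique(x$calves$cohort_id)),
              length(unique(x$calves$pair_id)),
              max(x$health$day)))
  invisible(x)
}

# pair partner lookup: named vector mate[calf_id]
pair_partners <- function(roster) {
  stopifnot(inherits(roster, "calf_roster"))
  sp <- split(roster$calves$calf_id, roster$calves$pair_id)
  bad <- vapply(sp, length, 1L) != 2L
  if (any(bad)) {
    stop("every pair_id must map to exactly 2 calves; offending: ",
         paste(names(sp)[bad], collapse = ", "))
  }
  mate <- unlist(lapply(sp, function(p) setNames(c(p[2], p[1]), p)))
  names(mate) <- sub("^.*\\.", "", names(mate))
  mate[roster$calves$calf_id]
}

validate_roster <- function(roster) {
  stopifnot(inherits(roster, "calf_roster"))
  invisible(pair_partners(roster))
  same_cohort <- tapply(roster$calves$cohort_id, roster$calves$pair_id,
                        function(z) length(unique(z)) == 1L)
  if (!all(same_cohort)) stop("pair members must share a cohort")
  if (!all(roster$health$health %in% c("healthy", "sick", "convalescent"))) {
    stop("health labels must be healthy/sick/convalescent")
  }
  invisible(roster)
}
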