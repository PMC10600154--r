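#' Coefficient of variation of pen-mate intercept differences
#'
#' For each housed pair, takes the absolute difference of the two
#' pen-mates' intercepts; the statistic is the coefficient of variation
#' `sd(d) / mean(d)` of those absolute differences — a scale-free measure
#' of how *unevenly* similar pairs are. By convention the CV is 0 when
#' all differences are 0.
#'
#' @param intercepts named numeric vector of per-calf intercepts
#'   (typically predicted intercept deviations from a per-housing
#'   random-intercept fit).
#' @param roster a [make_roster()] roster supplying the pairing; every
#'   calf in it must appear in `intercepts`.
#' @return the CV (dimensionless).
#' @examples
#' r <- make_roster(1, 4, seed = 1)
#' penmate_cv(setNames(c(0, 1, 0, 3), r$calves$calf_id), r)
#' @export
penmate_cv <- function(intercepts, roster) {
  validate_roster(roster)
  ids <- roster$calves$calf_id
  if (!all(ids %in% names(intercepts))) {
    stop("unpaired or missing calves: ",
         paste(setdiff(ids, names(intercepts)), collapse = ", "))
  }
  v <- intercepts[ids]
  d <- abs(tapply(as.numeric(v), roster$calves$pair_id,
                  function(z) z[1] - z[2]))
  if (mean(d) == 0) return(0)
  sd(d) / mean(d)
}

#' Pen-mate similarity permutation test
#'
#' Compares the observed [penmate_cv()] with its distribution under
#' random re-pairing: calf intercepts are permuted (within cohort by
#' default, so cohort effects cannot masquerade as pair effects) while
#' the pair structure is held fixed, and the CV recomputed `B` times.
#'
#' With `direction = "lower"` the p-value is the proportion of
#' permutations in which the observed CV is less than or equal to the
#' null CV; `"upper"` gives the opposite tail. The observed pairing is
#' not forced into the null set; `add_one = TRUE` applies the
#' `(k + 1) / (B + 1)` correction (recommended for valid type-I control
#' at small `B`).
#'
#' @inheritParams penmate_cv
#' @param B number of permutations (default 10000).
#' @param seed RNG seed; identical inputs and seed give bit-identical
#'   p-values.
#' @param direction tail, `"lower"` or `"upper"`.
#' @param within_cohort permute within cohorts only (default `TRUE`).
#' @param add_one add-one p-value correction (default `FALSE`, the raw
#'   proportion).
#' @return list of class `penmate_permutation`: `observed_cv`,
#'   `null_cvs`, `p_value`, `B`, `seed`, `direction`.
#' @export
permutation_test <- function(intercepts, roster, B = 10000, seed = 1L,
                             direction = c("lower", "upper"),
                             within_cohort = TRUE, add_one = FALSE) {
  direction <- match.arg(direction)
  stopifnot(B >= 1)
  validate_roster(roster)
  obs <- penmate_cv(intercepts, roster)
  ids <- roster$calves$calf_id
  v <- as.numeric(intercepts[ids])
  pair <- roster$calves$pair_id
  groups <- if (within_cohort) split(seq_along(ids), roster$calves$cohort_id)
            else list(seq_along(ids))
  set.seed(as.integer(seed))
  null_cvs <- vapply(seq_len(B), function(b) {
    perm <- seq_along(ids)
    for (g in groups) perm[g] <- g[sample.int(length(g))]
    d <- abs(tapply(v[perm], pair, function(z) z[1] - z[2]))
    if (mean(d) == 0) 0 else sd(d) / mean(d)
  }, numeric(1))
  k <- if (direction == "lower") sum(obs <= null_cvs) else sum(obs >= null_cvs)
  p <- if (add_one) (k + 1) / (B + 1) else k / B
  structure(list(observed_cv = obs, null_cvs = null_cvs, p_value = p,
                 B = B, seed = seed, direction = direction,
                 within_cohort = within_cohort, add_one = add_one),
            class = "penmate_permutation")
}

#' @export
print.penmate_permutation <- function(x, ...) {
  cat(sprintf("<penmate_permutation> observed CV = %.4f, p = %.4g (%s tail, B = %d)\n",
              x$observed_cv, x$p_value, x$direction, x$B))
  invisible(x)
}
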