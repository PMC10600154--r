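#' Fit the random-intercept movement model
#'
#' REML fit of the personality model: metric value on day of observation,
#' age, housing (0 = pair, 1 = group) and health (reference "healthy"),
#' with crossed-nested random intercepts for cohort and individual,
#'
#' `value ~ day + age + housing + health + (1 | cohort) + (1 | calf)`.
#'
#' The individual intercept variance `V_ind0` captures between-individual
#' (personality) variance; the residual `V_e0` within-individual variance.
#' Fixed-effect p-values use the Wald normal approximation (declared in
#' `metadata$p_method`); at panel sizes of thousands of rows this is
#' indistinguishable from finite-df corrections.
#'
#' @param data a daily-metric panel (columns `calf_id`, `value`,
#'   `day_of_observation`, `age`, `housing`, `health`, `cohort_id`,
#'   `metric_name`).
#' @param metric which `metric_name` to model (default: the only one
#'   present).
#' @param include_disease if `FALSE`, sick/convalescent rows are dropped
#'   (and the health term with them); default `TRUE` keeps them and
#'   controls for health.
#' @param reml use REML (default) or ML.
#' @return An object of class `calf_lmm`: list with `beta` (estimate, se,
#'   z, p per fixed effect), `var_components` (`V_coh`, `V_ind0`, `V_e0`,
#'   plus `V_ind1`, `cov_ind01` for slope models), `individual_effects`
#'   (per-calf predicted deviations), `cohort_effects`, `loglik`, `n_obs`,
#'   `n_individuals`, `singular` flag, `metadata`, and the underlying
#'   `lme4` fit in `model`.
#' @export
fit_random_intercept <- function(data, metric = NULL, include_disease = TRUE,
                                 reml = TRUE) {
  d <- prepare_lmm_data(data, metric, include_disease)
  check_min_individuals(d, 20L)
  fit_calf_lmm(d, slope = FALSE, reml = reml)
}

#' Fit the random-slope (plasticity) movement model
#'
#' As [fit_random_intercept()], but the housing contrast also gets a
#' per-individual random slope with unstructured 2x2 covariance:
#'
#' `value ~ day + age + housing + health + (1 | cohort) + (housing | calf)`.
#'
#' The individual intercept is then the pair-housing personality and the
#' individual slope the plasticity of the housing response.
#'
#' @inheritParams fit_random_intercept
#' @return A `calf_lmm` with `intercept_dev` and `slope_dev` per calf.
#' @export
fit_random_slope <- function(data, metric = NULL, include_disease = TRUE,
                             reml = TRUE) {
  d <- prepare_lmm_data(data, metric, include_disease)
  both <- tapply(d$housing01, d$calf_id, function(h) length(unique(h)) == 2L)
  if (sum(both) < 20L) {
    stop("random-slope model requires both housing levels for >= 20 ",
         "individuals; found ", sum(both))
  }
  fit_calf_lmm(d, slope = TRUE, reml = reml)
}

prepare_lmm_data <- function(data, metric, include_disease) {
  need <- c("calf_id", "value", "day_of_observation", "age", "housing",
            "health", "cohort_id")
  if (!all(need %in% names(data))) {
    stop("panel needs columns ", paste(setdiff(need, names(data)),
                                       collapse = ", "))
  }
  if (!is.null(data$metric_name)) {
    if (is.null(metric)) {
      metric <- unique(data$metric_name)
      if (length(metric) > 1) stop("several metrics present; pick one via `metric`")
    }
    data <- data[data$metric_name == metric, , drop = FALSE]
  }
  if (!nrow(data)) stop("no rows for metric ", metric)
  if (!include_disease) data <- data[data$health == "healthy", , drop = FALSE]
  d <- data.frame(
    value = data$value,
    day = data$day_of_observation,
    age = data$age,
    housing01 = ifelse(data$housing == "group", 1, 0),
    health = factor(data$health,
                    levels = c("healthy", "sick", "convalescent")),
    calf_id = factor(data$calf_id),
    cohort_id = factor(data$cohort_id))
  d$health <- droplevels(d$health)
  d
}

check_min_individuals <- function(d, k) {
  n_per <- table(d$calf_id)
  if (sum(n_per >= 2) < k) {
    stop("need >= 2 observations per individual for >= ", k,
         " individuals; found ", sum(n_per >= 2))
  }
}

fit_calf_lmm <- function(d, slope, reml) {
  rhs <- "day + age"
  # single-housing data (the per-housing pen-mate fits) has no contrast
  if (length(unique(d$housing01)) > 1) rhs <- paste(rhs, "+ housing01")
  if (nlevels(d$health) > 1) rhs <- paste(rhs, "+ health")
  # a single cohort cannot support a cohort random intercept
  has_cohort <- nlevels(d$cohort_id) > 1
  rand <- if (slope) "(housing01 | calf_id)" else "(1 | calf_id)"
  if (has_cohort) rand <- paste("(1 | cohort_id) +", rand)
  form <- as.formula(paste("value ~", rhs, "+", rand))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- tryCatch(
    lme4::lmer(form, data = d, REML = reml, control = ctrl),
    error = function(e) stop("mixed-model fit failed: ",
                             conditionMessage(e), call. = FALSE))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("optimizer did not converge (code ", conv, "): ",
         paste(unlist(fit@optinfo$message), collapse = "; "))
  }
  singular <- lme4::isSingular(fit)
  if (singular) warning("singular fit: a variance component is at zero")

  vc <- lme4::VarCorr(fit)
  v_ind <- vc$calf_id
  var_components <- list(
    V_coh = if (has_cohort) as.numeric(vc$cohort_id[1, 1]) else NA_real_,
    V_ind0 = as.numeric(v_ind[1, 1]),
    V_e0 = attr(vc, "sc")^2)
  if (slope) {
    var_components$V_ind1 <- as.numeric(v_ind[2, 2])
    var_components$cov_ind01 <- as.numeric(v_ind[1, 2])
  }
  cf <- summary(fit)$coefficients
  beta <- data.frame(term = rownames(cf),
                     estimate = cf[, "Estimate"],
                     se = cf[, "Std. Error"],
                     z = cf[, "t value"],
                     p = 2 * pnorm(-abs(cf[, "t value"])),
                     row.names = NULL, stringsAsFactors = FALSE)
  re <- lme4::ranef(fit)
  ind <- re$calf_id
  individual_effects <- data.frame(calf_id = rownames(ind),
                                   intercept_dev = ind[, "(Intercept)"],
                                   stringsAsFactors = FALSE)
  if (slope) individual_effects$slope_dev <- ind[, "housing01"]
  cohort_effects <- if (has_cohort) {
    data.frame(cohort_id = rownames(re$cohort_id),
               effect = re$cohort_id[, "(Intercept)"],
               stringsAsFactors = FALSE)
  } else data.frame(cohort_id = character(), effect = numeric())
  structure(list(beta = beta, var_components = var_components,
                 individual_effects = individual_effects,
                 cohort_effects = cohort_effects,
                 loglik = as.numeric(logLik(fit)),
                 n_obs = nrow(d),
                 n_individuals = nlevels(d$calf_id),
                 singular = singular,
                 model = fit,
                 metadata = list(slope = slope, reml = reml,
                                 p_method = "wald-normal",
                                 housing_coding = "0=pair, 1=group",
                                 health_reference = "healthy")),
            class = "calf_lmm")
}

#' @export
print.calf_lmm <- function(x, ...) {
  cat(sprintf("<calf_lmm> %s model: %d obs, %d individuals%s\n",
              if (x$metadata$slope) "random-slope" else "random-intercept",
              x$n_obs, x$n_individuals,
              if (x$singular) " [singular]" else ""))
  print(x$beta, digits = 4)
  cat("variance components:\n")
  str(x$var_components, give.head = FALSE)
  invisible(x)
}

#' Adjusted repeatability ratio
#'
#' `R = V_ind0 / (V_ind0 + V_e0)`: the fraction of phenotypic variance
#' (after conditioning on the fixed effects) attributable to individual
#' identity. Cohort variance is *excluded* from the denominator;
#' `include_cohort = TRUE` gives the alternative
#' `V_ind0 / (V_ind0 + V_coh + V_e0)`.
#'
#' @param v_ind0,v_e0 individual-intercept and residual variances.
#' @param v_coh cohort variance (used only when `include_cohort`).
#' @param include_cohort include cohort variance in the denominator.
#' @return repeatability in \[0, 1\].
#' @examples
#' repeatability_ratio(1, 3) # 0.25
#' @export
repeatability_ratio <- function(v_ind0, v_e0, v_coh = 0,
                                include_cohort = FALSE) {
  denom <- v_ind0 + v_e0 + if (include_cohort) v_coh else 0
  if (denom == 0) stop("repeatability undefined: V_ind0 + V_e0 = 0")
  v_ind0 / denom
}

#' Adjusted repeatability with parametric-bootstrap CI
#'
#' Computes `R` from a [fit_random_intercept()] fit and a percentile
#' confidence interval by parametric bootstrap: responses are simulated
#' from the fitted model, the model is refitted, and `R` recomputed
#' `n_boot` times.
#'
#' @param fit a `calf_lmm` from [fit_random_intercept()].
#' @param n_boot bootstrap replicates (default 1000; 0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param include_cohort see [repeatability_ratio()].
#' @return list of class `repeatability_result`: `R`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, `boot_R` (the bootstrap draws).
#' @export
adjusted_repeatability <- function(fit, n_boot = 1000, seed = 1L,
                                   conf = 0.95, include_cohort = FALSE) {
  stopifnot(inherits(fit, "calf_lmm"))
  if (isTRUE(fit$metadata$slope)) {
    stop("adjusted repeatability is defined for the random-intercept model")
  }
  vc <- fit$var_components
  R <- repeatability_ratio(vc$V_ind0, vc$V_e0, vc$V_coh, include_cohort)
  ci <- c(NA_real_, NA_real_); boot_R <- numeric(0)
  if (n_boot > 0) {
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    ys <- stats::simulate(fit$model, nsim = n_boot, seed = as.integer(seed))
    boot_R <- vapply(seq_len(n_boot), function(b) {
      rf <- suppressWarnings(suppressMessages(
        lme4::refit(fit$model, ys[[b]], control = ctrl)))
      vcb <- lme4::VarCorr(rf)
      v_coh_b <- if (is.null(vcb$cohort_id)) 0
                 else as.numeric(vcb$cohort_id[1, 1])
      repeatability_ratio(as.numeric(vcb$calf_id[1, 1]), attr(vcb, "sc")^2,
                          v_coh_b, include_cohort)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- as.numeric(quantile(boot_R, c(a, 1 - a), names = FALSE))
    if (R < ci[1] || R > ci[2]) {
      warning("point estimate outside percentile CI (bootstrap noise)")
    }
  }
  structure(list(R = R, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, seed = seed, boot_R = boot_R,
                 include_cohort = include_cohort),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability> R = %.3f", x$R))
  if (x$n_boot > 0) cat(sprintf(" [%.3f, %.3f] (%d bootstraps)",
                                x$ci_low, x$ci_high, x$n_boot))
  cat("\n")
  invisible(x)
}

#' Personality-plasticity (intercept-slope) correlation
#'
#' Pearson correlation between the predicted per-individual intercept
#' deviations (personality) and housing-slope deviations (plasticity)
#' from a random-slope fit, with its test p-value. The model-implied
#' correlation `cov_ind01 / sqrt(V_ind0 * V_ind1)` is reported alongside:
#' predicted (shrunken) effects attenuate the correlation relative to the
#' generating parameter.
#'
#' @param fit a `calf_lmm` from [fit_random_slope()].
#' @return list of class `plasticity_correlation`: `r`, `p_value`, `n`,
#'   `source = "predicted_effects"`, and `r_model`
#'   (`source = "model_parameter"`).
#' @export
personality_plasticity_correlation <- function(fit) {
  stopifnot(inherits(fit, "calf_lmm"))
  if (!isTRUE(fit$metadata$slope)) {
    stop("fit must contain per-individual slopes (use fit_random_slope)")
  }
  eff <- fit$individual_effects
  if (nrow(eff) < 3) stop("need >= 3 individuals for a correlation")
  if (sd(eff$slope_dev) == 0 || sd(eff$intercept_dev) == 0) {
    warning("no between-individual variance in predicted effects; ",
            "correlation undefined")
    ct <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    ct <- cor.test(eff$intercept_dev, eff$slope_dev, method = "pearson")
  }
  vc <- fit$var_components
  denom <- sqrt(vc$V_ind0 * vc$V_ind1)
  r_model <- if (denom > 0) vc$cov_ind01 / denom else NA_real_
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(eff), source = "predicted_effects",
                 r_model = r_model),
            class = "plasticity_correlation")
}

#' @export
print.plasticity_correlation <- function(x, ...) {
  cat(sprintf("<plasticity_correlation> r = %.3f (p = %.2g, n = %d); model parameter %.3f\n",
              x$r, x$p_value, x$n, x$r_model))
  invisible(x)
}

#' Carry-over model: pen-mate personality as a fixed effect
#'
#' On group-housing observations only, refits the random-intercept model
#' with two extra fixed covariates: each calf's own pair-housing predicted
#' intercept and that of its former pen-mate. A non-zero pen-mate
#' coefficient indicates a carry-over of the partner's personality into
#' the new housing.
#'
#' @param group_data daily-metric panel restricted to group housing (an
#'   error is raised if pair rows are present).
#' @param pair_intercepts named numeric vector of pair-housing predicted
#'   intercepts, one per calf (from a pair-housing
#'   [fit_random_intercept()]).
#' @param roster a [make_roster()] roster giving the pairings.
#' @inheritParams fit_random_intercept
#' @return A `calf_lmm`; the rows of `beta` named `own_intercept` and
#'   `penmate_intercept` carry the carry-over coefficients.
#' @export
fit_carryover <- function(group_data, pair_intercepts, roster,
                          metric = NULL, include_disease = TRUE,
                          reml = TRUE) {
  if (any(group_data$housing != "group")) {
    stop("group_data must contain group-housing rows only")
  }
  validate_roster(roster)
  mate <- pair_partners(roster)
  ids <- unique(group_data$calf_id)
  missing_own <- setdiff(ids, names(pair_intercepts))
  missing_mate <- ids[!(mate[ids] %in% names(pair_intercepts))]
  bad <- union(missing_own, missing_mate)
  if (length(bad)) {
    stop("missing pair-housing intercepts for: ", paste(bad, collapse = ", "))
  }
  d <- prepare_lmm_data(group_data, metric, include_disease)
  check_min_individuals(d, 20L)
  d$own_intercept <- as.numeric(pair_intercepts[as.character(d$calf_id)])
  d$penmate_intercept <-
    as.numeric(pair_intercepts[mate[as.character(d$calf_id)]])
  rhs <- "day + age + own_intercept + penmate_intercept"
  if (nlevels(d$health) > 1) rhs <- paste(rhs, "+ health")
  rand <- if (nlevels(d$cohort_id) > 1)
    "(1 | cohort_id) + (1 | calf_id)" else "(1 | calf_id)"
  form <- as.formula(paste("value ~", rhs, "+", rand))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- lme4::lmer(form, data = d, REML = reml, control = ctrl)
  out <- extract_carryover_fit(fit, d)
  out
}

extract_carryover_fit <- function(fit, d) {
  singular <- lme4::isSingular(fit)
  vc <- lme4::VarCorr(fit)
  cf <- summary(fit)$coefficients
  beta <- data.frame(term = rownames(cf),
                     estimate = cf[, "Estimate"],
                     se = cf[, "Std. Error"],
                     z = cf[, "t value"],
                     p = 2 * pnorm(-abs(cf[, "t value"])),
                     row.names = NULL, stringsAsFactors = FALSE)
  re <- lme4::ranef(fit)
  structure(list(beta = beta,
                 var_components = list(
                   V_coh = if (is.null(vc$cohort_id)) NA_real_
                           else as.numeric(vc$cohort_id[1, 1]),
                   V_ind0 = as.numeric(vc$calf_id[1, 1]),
                   V_e0 = attr(vc, "sc")^2),
                 individual_effects = data.frame(
                   calf_id = rownames(re$calf_id),
                   intercept_dev = re$calf_id[, "(Intercept)"],
                   stringsAsFactors = FALSE),
                 cohort_effects = if (is.null(re$cohort_id))
                   data.frame(cohort_id = character(), effect = numeric())
                 else data.frame(
                   cohort_id = rownames(re$cohort_id),
                   effect = re$cohort_id[, "(Intercept)"],
                   stringsAsFactors = FALSE),
                 loglik = as.numeric(logLik(fit)),
                 n_obs = nrow(d),
                 n_individuals = nlevels(d$calf_id),
                 singular = singular,
                 model = fit,
                 metadata = list(slope = FALSE, carryover = TRUE,
                                 p_method = "wald-normal")),
            class = "calf_lmm")
}
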