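#' Utilities from EQ-5D-3L responses
#'
#' Values each scheduled response in an `eq5d` register under a value set.
#' Responses with any missing dimension score `NA` (to be multiply
#' imputed downstream).
#'
#' @param eq5d data.frame with `patient_id`, `visit_month` and the five
#'   dimension columns (levels 1-3 or NA).
#' @param vs a `cea_value_set`.
#' @return data.frame `patient_id`, `visit_month`, `utility`.
#' @export
utilities_from_eq5d <- function(eq5d, vs) {
  code <- eq5d_code(eq5d[, EQ5D_DIMENSIONS])
  data.frame(patient_id = eq5d$patient_id,
             visit_month = eq5d$visit_month,
             utility = value_state(code, vs))
}

# long utility table -> patients x visits matrix (ordered schedule columns)
utility_matrix <- function(util, schedule) {
  ids <- sort(unique(util$patient_id))
  m <- matrix(NA_real_, length(ids), length(schedule),
              dimnames = list(ids, paste0("m", schedule)))
  ri <- match(util$patient_id, ids)
  ci <- match(util$visit_month, schedule)
  keep <- !is.na(ci)
  m[cbind(ri[keep], ci[keep])] <- util$utility[keep]
  m
}

#' Multiple imputation of missing utilities
#'
#' Chained-equations stochastic regression on the utility scale. Each
#' visit's utility is regressed on the analysis covariates (arm, age, sex,
#' diagnosis) and the utilities at the other visits; missing cells are
#' replaced by draws `X beta* + e` where `beta*` is drawn from the
#' approximate posterior of the fitted coefficients and `e` from the
#' residual distribution, cycling over visits `maxit` times per
#' imputation. The contract is that observed cells are never altered, the
#' `m` completed tables differ only at originally missing cells, each
#' table is seed-reproducible, and under MCAR the pooled estimates are
#' unbiased; the algorithm itself is exchangeable for any engine meeting
#' that contract.
#'
#' Cells scheduled after a patient's death are structurally absent (the
#' patient contributes utility 0 from death in the QALY step) and are
#' neither imputed nor counted as missing.
#'
#' @param util long utility table (`patient_id`, `visit_month`, `utility`).
#' @param covariates data.frame with `patient_id` plus complete covariate
#'   columns; factors/characters are expanded to dummies.
#' @param schedule follow-up months, default `c(0, 3, 6, 12, 24)`.
#' @param m number of imputations (default 20).
#' @param seed integer RNG seed.
#' @param maxit chained-equation cycles per imputation.
#' @param death_month optional named vector (by patient id) of death times
#'   in months; visits at or after death are treated as structural zeros.
#' @param on_all_missing what to do with a patient with zero observed
#'   utilities: `"error"` (default), `"exclude"`, or `"mean"` (fill the
#'   baseline with the cohort baseline mean before imputing, logged via a
#'   warning).
#' @return object of class `cea_mi`: list with `tables` (m completed
#'   patients-by-visits matrices), `missing_mask`, `schedule`.
#' @export
impute_missing <- function(util, covariates, schedule = c(0, 3, 6, 12, 24),
                           m = 20L, seed = 1L, maxit = 5L,
                           death_month = NULL,
                           on_all_missing = c("error", "exclude", "mean")) {
  on_all_missing <- match.arg(on_all_missing)
  m <- assert_scalar_int(m, "m")
  U <- utility_matrix(util, schedule)
  ids <- as.integer(rownames(U))

  # structural (post-death) cells: not missing data, excluded from MI
  structural <- matrix(FALSE, nrow(U), ncol(U))
  if (!is.null(death_month)) {
    dm <- death_month[match(ids, as.integer(names(death_month)))]
    structural <- outer(dm, schedule, function(d, s) !is.na(d) & s >= d)
    U[structural] <- NA_real_
  }

  none_obs <- rowSums(!is.na(U) & !structural) == 0L
  if (any(none_obs)) {
    msg <- sprintf("%d patient(s) with zero observed utilities", sum(none_obs))
    if (on_all_missing == "error") abort("%s", msg)
    warning(msg, call. = FALSE)
    if (on_all_missing == "exclude") {
      U <- U[!none_obs, , drop = FALSE]
      structural <- structural[!none_obs, , drop = FALSE]
      ids <- ids[!none_obs]
    } else {
      U[none_obs, 1L] <- mean(U[, 1L], na.rm = TRUE)
    }
  }

  mask <- is.na(U) & !structural
  X <- covariate_design(covariates, ids)

  tables <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(child_seed(seed, k))
    tables[[k]] <- mice_cycle(U, mask, X, maxit)
  }
  structure(list(tables = tables, missing_mask = mask,
                 structural_mask = structural,
                 schedule = schedule, patient_id = ids, m = m),
            class = "cea_mi")
}

# expand covariates (matched to ids) into a numeric design matrix
covariate_design <- function(covariates, ids) {
  cv <- covariates[match(ids, covariates$patient_id), , drop = FALSE]
  if (anyNA(cv$patient_id)) abort("covariates missing for some patients")
  cv$patient_id <- NULL
  if (!ncol(cv)) return(matrix(numeric(0), length(ids), 0L))
  if (anyNA(cv)) abort("covariates must be complete")
  stats::model.matrix(~ ., data = cv)[, -1L, drop = FALSE]
}

# one full chained-equations pass producing a completed matrix
mice_cycle <- function(U, mask, X, maxit) {
  comp <- U
  # initial fill: column means of observed (fallback grand mean)
  for (j in seq_len(ncol(comp))) {
    if (any(mask[, j])) {
      mu <- mean(U[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- mean(U, na.rm = TRUE)
      comp[mask[, j], j] <- mu
    }
  }
  comp[is.na(comp)] <- 0  # structural cells, ignored on output
  for (it in seq_len(maxit)) {
    for (j in seq_len(ncol(comp))) {
      mis <- mask[, j]
      if (!any(mis)) next
      obs <- !is.na(U[, j])
      D <- cbind(1, X, comp[, -j, drop = FALSE])
      fit <- stats::lm.fit(D[obs, , drop = FALSE], U[obs, j])
      keep <- !is.na(fit$coefficients)
      Dk <- D[, keep, drop = FALSE]
      qr_ <- qr(Dk[obs, , drop = FALSE])
      beta <- fit$coefficients[keep]
      df <- max(sum(obs) - sum(keep), 1L)
      sigma <- sqrt(sum(fit$residuals^2) / df)
      # approximate Bayesian draw: sigma* from scaled inv-chisq, beta* ~
      # N(beta, sigma*^2 (D'D)^-1)
      sigma_star <- sigma * sqrt(df / stats::rchisq(1L, df))
      R <- qr.R(qr_)
      z <- stats::rnorm(length(beta))
      beta_star <- beta + backsolve(R, z) * sigma_star
      comp[mis, j] <- Dk[mis, , drop = FALSE] %*% beta_star +
        stats::rnorm(sum(mis), 0, sigma_star)
    }
  }
  comp[!mask & is.na(U)] <- NA_real_  # restore structural cells
  comp[!mask & !is.na(U)] <- U[!mask & !is.na(U)]
  comp
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param est numeric vector of per-imputation point estimates.
#' @param var numeric vector of per-imputation variances (optional).
#' @return list `estimate`, `variance` (within + (1+1/m) between), `m`.
#' @export
pool_rubin <- function(est, var = NULL) {
  m <- length(est)
  q <- mean(est)
  v <- NULL
  if (!is.null(var)) {
    b <- if (m > 1L) stats::var(est) else 0
    v <- mean(var) + (1 + 1 / m) * b
  }
  list(estimate = q, variance = v, m = m)
}

#' Discounted QALYs by trapezoidal area under the utility curve
#'
#' Utility is interpolated linearly between scheduled observations; the
#' area over months 0-12 is year-1 QALYs and over months 12-24 year-2
#' QALYs, the latter discounted as a lump by `1/(1 + rate)`. A patient who
#' dies contributes utility 0 from the death time, with a linear segment
#' from the last observation before death down to 0 at death.
#'
#' @param times_months observation times (strictly increasing, starting at
#'   the baseline visit 0).
#' @param utilities utilities at those times; baseline must be non-missing
#'   (call after imputation).
#' @param death_month optional death time in months.
#' @param discount_rate_effects annual discount rate for second-year
#'   effects (default 0.03).
#' @param horizon_months analysis horizon (24; 12 gives year 1 only).
#' @return list `qaly_year1`, `qaly_year2_undiscounted`,
#'   `qaly_total_discounted`, `discount_rate_effects`.
#' @export
qaly_auc <- function(times_months, utilities, death_month = NA,
                     discount_rate_effects = 0.03, horizon_months = 24) {
  if (length(times_months) != length(utilities))
    abort("schedule/trajectory mismatch")
  if (is.unsorted(times_months, strictly = TRUE))
    abort("observation times must be strictly increasing")
  if (is.na(utilities[1L]) || times_months[1L] != 0)
    abort("baseline utility must be present (impute first)")
  t <- times_months; u <- utilities
  if (!is.na(death_month)) {
    if (any(t < death_month & is.na(u)))
      abort("missing utility before death; impute first")
    keep <- t < death_month
    t <- c(t[keep], death_month); u <- c(u[keep], 0)
    if (death_month < horizon_months) {      # flat zero to horizon
      t <- c(t, horizon_months); u <- c(u, 0)
    }
  } else if (anyNA(u)) {
    abort("missing utility in trajectory; impute first")
  }
  y1 <- trapz_segment(t, u, 0, min(12, horizon_months)) / 12
  y2 <- if (horizon_months > 12) trapz_segment(t, u, 12, horizon_months) / 12
        else 0
  list(qaly_year1 = y1,
       qaly_year2_undiscounted = y2,
       qaly_total_discounted = y1 + y2 / (1 + discount_rate_effects),
       discount_rate_effects = discount_rate_effects)
}

# trapezoid integral of the piecewise-linear curve (t, u) over [a, b];
# curve extended flat at the last observation if it stops before b
trapz_segment <- function(t, u, a, b) {
  if (b <= a) return(0)
  if (max(t) < b) { u <- c(u, u[length(u)]); t <- c(t, b) }
  knots <- sort(unique(c(t, a, b)))
  knots <- knots[knots >= a & knots <= b]
  v <- stats::approx(t, u, xout = knots, rule = 2)$y
  sum(diff(knots) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Per-patient QALYs from completed imputation tables
#'
#' Applies [qaly_auc()] to every patient in every completed table and
#' pools per-patient results over the `m` imputations (Rubin's rules for
#' a mean reduce to averaging).
#'
#' @param mi a `cea_mi` object.
#' @param death_month named vector of death months by patient id (optional).
#' @param discount_rate_effects annual discount rate for year-2 effects.
#' @param horizon_months 24 or 12.
#' @return data.frame `patient_id`, `qaly_year1`, `qaly_year2_undiscounted`,
#'   `qaly_total_discounted` (pooled over imputations).
#' @export
qaly_table <- function(mi, death_month = NULL,
                       discount_rate_effects = 0.03, horizon_months = 24) {
  ids <- mi$patient_id
  dm <- rep(NA_real_, length(ids))
  if (!is.null(death_month))
    dm <- as.numeric(death_month[match(ids, as.integer(names(death_month)))])
  acc <- matrix(0, length(ids), 3L)
  # the trapezoid is linear in the utilities, so complete rows without a
  # death reduce to two fixed weight vectors (fast path for large cohorts)
  s <- mi$schedule
  w1 <- vapply(seq_along(s), function(j)
    trapz_segment(s, as.numeric(seq_along(s) == j),
                  0, min(12, horizon_months)) / 12, numeric(1))
  w2 <- if (horizon_months > 12) vapply(seq_along(s), function(j)
    trapz_segment(s, as.numeric(seq_along(s) == j),
                  12, horizon_months) / 12, numeric(1)) else numeric(length(s))
  for (tab in mi$tables) {
    simple <- is.na(dm) & rowSums(is.na(tab)) == 0L
    if (any(simple)) {
      y1 <- tab[simple, , drop = FALSE] %*% w1
      y2 <- tab[simple, , drop = FALSE] %*% w2
      acc[simple, ] <- acc[simple, ] +
        cbind(y1, y2, y1 + y2 / (1 + discount_rate_effects))
    }
    for (i in which(!simple)) {
      obs <- !is.na(tab[i, ])
      q <- qaly_auc(mi$schedule[obs], tab[i, obs], death_month = dm[i],
                    discount_rate_effects = discount_rate_effects,
                    horizon_months = horizon_months)
      acc[i, ] <- acc[i, ] + c(q$qaly_year1, q$qaly_year2_undiscounted,
                               q$qaly_total_discounted)
    }
  }
  acc <- acc / mi$m
  data.frame(patient_id = ids, qaly_year1 = acc[, 1L],
             qaly_year2_undiscounted = acc[, 2L],
             qaly_total_discounted = acc[, 3L])
}

#' Arm mean utility at a visit, pooled over imputations, bootstrap CI
#'
#' Per-patient utilities are first pooled (averaged) across the completed
#' tables, then the arm mean is bootstrapped over patients with a
#' percentile 95% interval.
#'
#' @param mi a `cea_mi` object.
#' @param patients patients register (for arm membership).
#' @param arm `"intervention"` or `"control"`.
#' @param visit_month scheduled visit.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list `mean`, `ci` (length-2), `n`.
#' @export
group_mean_utility <- function(mi, patients, arm, visit_month,
                               B = 1000L, seed = 1L) {
  j <- match(visit_month, mi$schedule)
  if (is.na(j)) abort("visit %s not in schedule", visit_month)
  pooled <- Reduce(`+`, lapply(mi$tables, function(tb) tb[, j])) / mi$m
  in_arm <- mi$patient_id %in%
    patients$patient_id[patients$arm == arm]
  x <- pooled[in_arm]
  x <- x[!is.na(x)]   # post-death structural cells drop out of visit means
  if (!length(x)) abort("empty arm")
  set.seed(child_seed(seed, j))
  bs <- replicate(B, mean(sample(x, replace = TRUE)))
  list(mean = mean(x),
       ci = unname(stats::quantile(bs, c(0.025, 0.975), type = 6)),
       n = length(x))
}
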