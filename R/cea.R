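#' Analysis specification for one cost-effectiveness comparison
#'
#' One entry of the sensitivity/subgroup harness: which population, value
#' set, discount rates, horizon, perspective and bootstrap settings to
#' use for a single incremental comparison.
#'
#' @param id short unique label.
#' @param population one of `ITT`, `PP`, `complete_case`,
#'   `survivors_only`, `living_alone`, `cohabiting`.
#' @param value_set value-set id (must exist in the harness's value-set
#'   list).
#' @param discount_costs,discount_effects annual rates (fractions) applied
#'   to year-2 amounts.
#' @param horizon_years 1 or 2.
#' @param perspective `societal` (incremental analysis), or `payer` /
#'   `patient` (descriptive totals).
#' @param bootstrap_B replicates (>= 1).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `cea_analysis_spec`.
#' @export
analysis_spec <- function(id, population = "ITT", value_set = "toy",
                          discount_costs = 0.03, discount_effects = 0.03,
                          horizon_years = 2L, perspective = "societal",
                          bootstrap_B = 1000L, seed = 1L) {
  population <- match.arg(population,
    c("ITT", "PP", "complete_case", "survivors_only", "living_alone",
      "cohabiting"))
  perspective <- match.arg(perspective,
                           c("societal", "payer", "patient"))
  if (discount_costs < 0 || discount_effects < 0)
    abort("discount rates must be >= 0")
  if (!horizon_years %in% 1:2) abort("horizon_years must be 1 or 2")
  bootstrap_B <- assert_scalar_int(bootstrap_B, "bootstrap_B")
  structure(list(id = id, population = population, value_set = value_set,
                 discount_costs = discount_costs,
                 discount_effects = discount_effects,
                 horizon_years = as.integer(horizon_years),
                 perspective = perspective, bootstrap_B = bootstrap_B,
                 seed = seed),
            class = "cea_analysis_spec")
}

#' Classify a point on the cost-effectiveness plane
#'
#' `dominant` iff the intervention gains effect at lower cost (dE > 0 and
#' dC < 0); `dominated` iff it loses effect at higher cost (dE < 0 and
#' dC > 0); any other sign combination is a ratio, except dE = 0 where
#' the ICER is undefined (NA, label `undefined`).
#'
#' @param delta_e incremental effect (QALYs).
#' @param delta_c incremental cost (SEK).
#' @return list `label` in \{dominant, dominated, ratio, undefined\} and
#'   `icer` (SEK/QALY, NA unless label is ratio).
#' @export
classify_ce <- function(delta_e, delta_c) {
  if (delta_e > 0 && delta_c < 0)
    list(label = "dominant", icer = NA_real_)
  else if (delta_e < 0 && delta_c > 0)
    list(label = "dominated", icer = NA_real_)
  else if (delta_e == 0)
    list(label = "undefined", icer = NA_real_)
  else list(label = "ratio", icer = delta_c / delta_e)
}

# effect/cost per patient under a spec, from the prepared analysis table
spec_effects_costs <- function(analysis, spec) {
  q <- analysis$qalys[[spec$value_set]]
  if (is.null(q)) abort("unknown value set id: %s", spec$value_set)
  hz <- spec$horizon_years
  E <- if (hz == 1L) q$qaly_year1 else
    q$qaly_year1 + q$qaly_year2_undiscounted / (1 + spec$discount_effects)
  cb <- analysis$bundles
  disc <- 1 / (1 + spec$discount_costs)
  comps <- switch(spec$perspective,
    societal = COST_COMPONENTS,
    payer = c(HEALTHCARE_COMPONENTS, "prescription_drugs"),
    patient = "copay")
  y1 <- rowSums(cb[, paste0(comps, "_y1"), drop = FALSE])
  y2 <- rowSums(cb[, paste0(comps, "_y2"), drop = FALSE])
  C <- if (hz == 1L) y1 else y1 + y2 * disc
  data.frame(patient_id = cb$patient_id,
             arm = analysis$patients$arm[
               match(cb$patient_id, analysis$patients$patient_id)],
             effect = E[match(cb$patient_id, q$patient_id)], cost = C)
}

apply_population <- function(df, patients, population, complete_ids) {
  keep <- switch(population,
    ITT = rep(TRUE, nrow(df)),
    PP = {
      pp <- patients$pp_eligible[match(df$patient_id,
                                       patients$patient_id)]
      df$arm == "control" | (df$arm == "intervention" & pp)
    },
    complete_case = df$patient_id %in% complete_ids,
    survivors_only = is.na(patients$death_day[
      match(df$patient_id, patients$patient_id)]),
    living_alone = patients$living_alone[
      match(df$patient_id, patients$patient_id)],
    cohabiting = !patients$living_alone[
      match(df$patient_id, patients$patient_id)])
  df[keep, , drop = FALSE]
}

#' Incremental cost-effectiveness point estimates
#'
#' Arm mean differences (intervention minus control) in discounted effects
#' and costs under a spec, with dominance classification. Pooling over
#' imputations happens upstream (per-patient QALYs are already pooled), so
#' differencing here operates on pooled per-patient quantities.
#'
#' @param df per-patient data.frame with `arm`, `effect`, `cost` (e.g.
#'   from the harness preparation step).
#' @return object of class `cea_incremental`: list `delta_e`, `delta_c`,
#'   `label`, `icer`, `n`.
#' @export
incremental <- function(df) {
  for (a in c("intervention", "control"))
    if (!sum(df$arm == a)) abort("arm empty after population filter: %s", a)
  de <- mean(df$effect[df$arm == "intervention"]) -
    mean(df$effect[df$arm == "control"])
  dc <- mean(df$cost[df$arm == "intervention"]) -
    mean(df$cost[df$arm == "control"])
  cl <- classify_ce(de, dc)
  structure(list(delta_e = de, delta_c = dc, label = cl$label,
                 icer = cl$icer,
                 n = c(intervention = sum(df$arm == "intervention"),
                       control = sum(df$arm == "control"))),
            class = "cea_incremental")
}

#' Patient-level bootstrap of the incremental results
#'
#' Resamples patients with replacement within arm (arm sizes preserved),
#' recomputes (dE, dC) per replicate and returns the replicate cloud with
#' percentile 95% intervals. Seed-deterministic.
#'
#' @param df per-patient data.frame with `arm`, `effect`, `cost`.
#' @param B number of replicates (>= 100 recommended for CIs).
#' @param seed RNG seed.
#' @return list `replicates` (B x 2 matrix of dE, dC), `ci_e`, `ci_c`
#'   (percentile 95% intervals).
#' @export
bootstrap_ce <- function(df, B = 1000L, seed = 1L) {
  B <- assert_scalar_int(B, "B")
  ii <- which(df$arm == "intervention"); cc <- which(df$arm == "control")
  set.seed(seed)
  Ei <- matrix(df$effect[ii][sample.int(length(ii), length(ii) * B,
                                        replace = TRUE)], ncol = B)
  Ci <- matrix(df$cost[ii][sample.int(length(ii), length(ii) * B,
                                      replace = TRUE)], ncol = B)
  Ec <- matrix(df$effect[cc][sample.int(length(cc), length(cc) * B,
                                        replace = TRUE)], ncol = B)
  Cc <- matrix(df$cost[cc][sample.int(length(cc), length(cc) * B,
                                      replace = TRUE)], ncol = B)
  reps <- cbind(delta_e = colMeans(Ei) - colMeans(Ec),
                delta_c = colMeans(Ci) - colMeans(Cc))
  list(replicates = reps,
       ci_e = unname(stats::quantile(reps[, 1L], c(0.025, 0.975),
                                     type = 6)),
       ci_c = unname(stats::quantile(reps[, 2L], c(0.025, 0.975),
                                     type = 6)))
}

#' Baseline group comparisons
#'
#' Two-sided p-values with the test chosen by declared variable type:
#' Student's t for continuous, Pearson's chi-squared for categorical,
#' Fisher's exact for binary. A categorical variable with an all-zero
#' margin falls back to Fisher's exact test (logged via a message).
#'
#' @param data data.frame including an `arm` column.
#' @param types named character vector mapping variable names to
#'   `"continuous"`, `"categorical"` or `"binary"`.
#' @return data.frame `variable`, `type`, `test`, `p_value`.
#' @export
compare_groups <- function(data, types) {
  if (!all(names(types) %in% names(data)))
    abort("variables absent from data: %s",
          paste(setdiff(names(types), names(data)), collapse = ", "))
  rows <- lapply(names(types), function(v) {
    x <- data[[v]]; g <- data$arm
    tp <- types[[v]]
    if (tp == "continuous") {
      p <- tryCatch(stats::t.test(x ~ g, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
      # constant variable: zero variance, difference exactly 0 -> p = 1
      if (is.na(p) && stats::var(x) == 0) p <- 1
      test <- "t"
    } else {
      tab <- table(factor(g), factor(x))
      if (tp == "binary" || any(rowSums(tab) == 0) ||
          any(colSums(tab) == 0) || any(tab == 0)) {
        if (tp == "categorical")
          message(sprintf("compare_groups: '%s' has an empty cell; %s",
                          v, "falling back to Fisher's exact test"))
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
        test <- "chisq"
      }
    }
    data.frame(variable = v, type = tp, test = test, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prepare the per-patient analysis table for the harness
#'
#' Values EQ-5D responses under each value set, multiply imputes missing
#' utilities, computes per-patient undiscounted year-1/year-2 QALYs
#' (pooled over imputations), prices all resource use into cost bundles
#' and records which patients have complete EQ-5D. Discounting and
#' population filters are applied later, per spec, so one preparation
#' serves the whole harness.
#'
#' @param registers a `cea_registers` bundle.
#' @param value_sets named list of `cea_value_set` objects.
#' @param t a [tariff()].
#' @param rules a [copay_rules()].
#' @param m imputations.
#' @param seed RNG seed for the imputation.
#' @param on_all_missing handling of patients with zero observed
#'   utilities, passed to [impute_missing()]; the pipeline default
#'   `"mean"` keeps such patients in the ITT denominator by seeding their
#'   baseline with the cohort baseline mean (logged via warning).
#' @return object of class `cea_analysis_data`.
#' @export
prepare_analysis <- function(registers, value_sets = list(toy =
                               toy_value_set()),
                             t = tariff(), rules = copay_rules(),
                             m = 20L, seed = 1L,
                             on_all_missing = "mean") {
  pats <- registers$patients
  death_m <- stats::setNames(pats$death_day / 365 * 12, pats$patient_id)
  death_m <- death_m[!is.na(death_m)]
  sched <- registers$design$followup_months %||%
    sort(unique(registers$eq5d$visit_month))
  covars <- pats[, c("patient_id", "arm", "age", "sex", "diagnosis")]
  qalys <- list(); mis <- list()
  for (vn in names(value_sets)) {
    util <- utilities_from_eq5d(registers$eq5d, value_sets[[vn]])
    mi <- impute_missing(util, covars, schedule = sched, m = m,
                         seed = child_seed(seed, match(vn,
                                                       names(value_sets))),
                         death_month = death_m,
                         on_all_missing = on_all_missing)
    # undiscounted year pieces; per-spec discounting applied downstream
    qalys[[vn]] <- qaly_table(mi, death_month = death_m,
                              discount_rate_effects = 0)
    mis[[vn]] <- mi
  }
  bundles <- cost_bundles(registers, t = t, rules = rules,
                          discount_rate_costs = 0)
  eq <- registers$eq5d
  n_visits <- length(sched)
  obs_full <- stats::aggregate(
    !is.na(eq$mobility), by = list(patient_id = eq$patient_id), FUN = sum)
  complete_ids <- obs_full$patient_id[obs_full$x == n_visits]
  structure(list(patients = pats, qalys = qalys, mi = mis,
                 bundles = bundles, complete_ids = complete_ids,
                 value_sets = value_sets),
            class = "cea_analysis_data")
}

#' Run the sensitivity/subgroup harness
#'
#' One incremental result (or descriptive per-arm totals for the payer
#' and patient perspectives) per analysis spec.
#'
#' @param analysis a `cea_analysis_data` from [prepare_analysis()].
#' @param specs list of [analysis_spec()] objects with unique ids.
#' @return data.frame of class `cea_harness_results`, one row per spec:
#'   dE and CI, dC and CI, ICER or dominance label, arm sizes; the
#'   bootstrap replicate clouds are attached as attribute `replicates`
#'   (named list).
#' @export
run_harness <- function(analysis, specs) {
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids)) abort("duplicated spec ids")
  rows <- list(); clouds <- list()
  for (spec in specs) {
    df <- spec_effects_costs(analysis, spec)
    df <- apply_population(df, analysis$patients, spec$population,
                           analysis$complete_ids)
    inc <- incremental(df)
    bs <- bootstrap_ce(df, B = spec$bootstrap_B, seed = spec$seed)
    clouds[[spec$id]] <- bs$replicates
    rows[[spec$id]] <- data.frame(
      id = spec$id, population = spec$population,
      perspective = spec$perspective, value_set = spec$value_set,
      horizon_years = spec$horizon_years,
      discount_costs = spec$discount_costs,
      discount_effects = spec$discount_effects,
      n_intervention = inc$n[["intervention"]],
      n_control = inc$n[["control"]],
      delta_e = inc$delta_e, delta_e_lo = bs$ci_e[1L],
      delta_e_hi = bs$ci_e[2L],
      delta_c = inc$delta_c, delta_c_lo = bs$ci_c[1L],
      delta_c_hi = bs$ci_c[2L],
      icer = inc$icer, label = inc$label,
      mean_cost_intervention = mean(df$cost[df$arm == "intervention"]),
      mean_cost_control = mean(df$cost[df$arm == "control"]),
      total_cost_intervention = sum(df$cost[df$arm == "intervention"]),
      total_cost_control = sum(df$cost[df$arm == "control"]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cea_harness_results", "data.frame"),
            replicates = clouds)
}

#' Default harness mirroring the emulated study's analysis plan
#'
#' Base case (societal, 2 years, 3%/3% discounting, experience-based set)
#' plus the sensitivity analyses (hypothetical value set; 5%/5%
#' discounting; costs 3% / effects 0%; 1-year horizon; per-protocol;
#' complete case), subgroup analyses (survivors only, living alone,
#' cohabiting) and the payer/patient perspective views.
#'
#' @param value_set_main,value_set_alt value-set ids.
#' @param B bootstrap replicates per spec.
#' @param seed RNG seed.
#' @return list of [analysis_spec()] objects.
#' @export
default_harness_specs <- function(value_set_main = "experience",
                                  value_set_alt = "hypothetical",
                                  B = 1000L, seed = 1L) {
  sp <- function(id, k, ...)
    analysis_spec(id, value_set = value_set_main, bootstrap_B = B,
                  seed = child_seed(seed, k), ...)
  list(
    sp("base_case", 1L),
    analysis_spec("alt_value_set", value_set = value_set_alt,
                  bootstrap_B = B, seed = child_seed(seed, 2L)),
    sp("discount_5pct", 3L, discount_costs = 0.05,
       discount_effects = 0.05),
    sp("effects_undiscounted", 4L, discount_effects = 0),
    sp("horizon_1yr", 5L, horizon_years = 1L),
    sp("per_protocol", 6L, population = "PP"),
    sp("complete_case", 7L, population = "complete_case"),
    sp("survivors_only", 8L, population = "survivors_only"),
    sp("living_alone", 9L, population = "living_alone"),
    sp("cohabiting", 10L, population = "cohabiting"),
    sp("payer_perspective", 11L, perspective = "payer"),
    sp("patient_perspective", 12L, perspective = "patient"))
}
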