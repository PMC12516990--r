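#' Demographic characteristics table
#'
#' Per-arm counts/means with between-group p-values from
#' [compare_groups()] (t-test for continuous, chi-squared for
#' categorical, Fisher for binary variables).
#'
#' @param registers a `cea_registers` bundle (both arms required).
#' @return data.frame: `variable`, per-arm summary columns, `p_value`.
#' @export
make_table_demographics <- function(registers) {
  pats <- registers$patients
  need <- c("arm", "age", "sex", "diagnosis", "living_alone")
  miss <- setdiff(need, names(pats))
  if (length(miss))
    abort("missing mandatory demographic column(s): %s",
          paste(miss, collapse = ", "))
  if (length(unique(pats$arm)) < 2L) abort("both arms required")
  types <- c(age = "continuous", sex = "binary",
             diagnosis = "categorical", living_alone = "binary")
  pv <- compare_groups(pats, types)
  fmt <- function(a) {
    x <- pats[pats$arm == a, ]
    c(sprintf("%.1f (%.1f)", mean(x$age), stats::sd(x$age)),
      sprintf("%d (%.1f%%)", sum(x$sex == "female"),
              100 * mean(x$sex == "female")),
      sprintf("%d/%d/%d", sum(x$diagnosis == "CHF"),
              sum(x$diagnosis == "COPD"), sum(x$diagnosis == "both")),
      sprintf("%d (%.1f%%)", sum(x$living_alone),
              100 * mean(x$living_alone)))
  }
  data.frame(
    variable = c("Age, mean (SD)", "Women, n (%)",
                 "Diagnosis CHF/COPD/both, n",
                 "Living alone, n (%)"),
    control = fmt("control"), intervention = fmt("intervention"),
    p_value = round(pv$p_value[match(names(types), pv$variable)], 4))
}

#' Average cost per patient table with bootstrap CIs
#'
#' Mean discounted 2-year cost per component and arm, percentile
#' bootstrap 95% CI, and a Student's t-test p-value per component.
#'
#' @param bundles a `cea_cost_bundles` table.
#' @param patients patients register.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param discount_rate_costs rate for the per-component discounted sums.
#' @return data.frame: `component`, per-arm `mean`, `lo`, `hi`, `p_value`.
#' @export
make_table_costs <- function(bundles, patients, B = 1000L, seed = 1L,
                             discount_rate_costs = 0.03) {
  disc <- 1 / (1 + discount_rate_costs)
  arm <- patients$arm[match(bundles$patient_id, patients$patient_id)]
  rows <- list()
  for (k in seq_along(COST_COMPONENTS)) {
    comp <- COST_COMPONENTS[k]
    y1 <- paste0(comp, "_y1"); y2 <- paste0(comp, "_y2")
    if (!all(c(y1, y2) %in% names(bundles)))
      abort("component missing from bundles: %s", comp)
    x <- bundles[[y1]] + bundles[[y2]] * disc
    set.seed(child_seed(seed, k))
    stat <- lapply(c("control", "intervention"), function(a) {
      v <- x[arm == a]
      bs <- replicate(B, mean(sample(v, replace = TRUE)))
      c(mean = mean(v),
        stats::quantile(bs, c(0.025, 0.975), type = 6))
    })
    p <- if (stats::var(x) == 0) 1 else
      tryCatch(stats::t.test(x[arm == "intervention"],
                             x[arm == "control"],
                             var.equal = TRUE)$p.value,
               error = function(e) NA_real_)
    rows[[comp]] <- data.frame(
      component = comp,
      control_mean = stat[[1L]][1L], control_lo = stat[[1L]][2L],
      control_hi = stat[[1L]][3L],
      intervention_mean = stat[[2L]][1L],
      intervention_lo = stat[[2L]][2L],
      intervention_hi = stat[[2L]][3L], p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- vapply(out, is.numeric, TRUE) & names(out) != "p_value"
  out[num] <- lapply(out[num], round_half_up, digits = 0)
  out$p_value <- round(out$p_value, 4)
  out
}

#' Run configuration
#'
#' Loads a JSON or YAML run config and fills defaults. Recognised keys:
#' `seed`, `n_per_arm`, `horizon_days`, `followup_months`, `m_imputations`,
#' `bootstrap_B`, `out_dir`, `registers_dir` (load instead of generating),
#' `generator` (overrides for [generator_params()]), `tariff`,
#' `copay_rules`, `value_set_files` (named paths read by
#' [read_value_set()]; defaults to the built-in synthetic sets).
#'
#' @param path config file, or `NULL` for all defaults.
#' @return named list of class `cea_run_config`.
#' @export
run_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort("config file not found: %s", path)
    cfg <- if (grepl("[.]ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        abort("yaml package required for YAML configs")
      yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1L, n_per_arm = 110L, horizon_days = 730L,
                   followup_months = c(0, 3, 6, 12, 24),
                   m_imputations = 20L, bootstrap_B = 1000L,
                   out_dir = "cea_output", registers_dir = NULL,
                   generator = list(), tariff = list(),
                   copay_rules = list(), value_set_files = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults[names(cfg)] <- cfg
  structure(defaults, class = "cea_run_config")
}

#' Run the full pipeline from one config
#'
#' Stages: synthesise (or load) registers, prepare the analysis table
#' (valuation, imputation, costing, co-payments), run the harness, and
#' write the report artifacts: demographics and cost tables, harness
#' results, cost-effectiveness plane replicates for the base case,
#' per-arm mean utilities by visit, co-payment summaries, and a JSON run
#' summary with stage log. Deterministic for a fixed (config, seed):
#' rerunning produces byte-identical numeric outputs. Any stage error
#' propagates prefixed with the stage name.
#'
#' @param config a [run_config()] (or path to one).
#' @param quiet suppress stage messages.
#' @return the output directory, invisibly.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- run_config(config)
  log <- list()
  say <- function(stage, fmt, ...) {
    msg <- sprintf(fmt, ...)
    log[[length(log) + 1L]] <<- list(stage = stage, message = msg)
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  regs <- stage("synth", {
    if (!is.null(config$registers_dir)) {
      r <- read_registers(config$registers_dir)
      r$design <- trial_design(
        n_per_arm = max(table(r$patients$arm)),
        horizon_days = config$horizon_days,
        followup_months = config$followup_months, seed = config$seed)
      say("synth", "loaded registers from %s (%d patients)",
          config$registers_dir, nrow(r$patients))
      r
    } else {
      des <- trial_design(n_per_arm = config$n_per_arm,
                          horizon_days = config$horizon_days,
                          followup_months = config$followup_months,
                          seed = config$seed)
      par <- do.call(generator_params, config$generator)
      r <- generate_cohort(des, par)
      say("synth", "generated %d patients, %d care events, %d deaths",
          nrow(r$patients), nrow(r$care_events), nrow(r$deaths))
      write_registers(r, file.path(config$out_dir, "registers"))
      r
    }
  })

  vsets <- stage("valuation", {
    if (is.null(config$value_set_files))
      list(experience = synthetic_value_set("experience"),
           hypothetical = synthetic_value_set("hypothetical"))
    else lapply(config$value_set_files, read_value_set)
  })
  trf <- stage("costing", do.call(tariff, config$tariff))
  rls <- stage("copay", do.call(copay_rules, config$copay_rules))

  analysis <- stage("analysis", {
    a <- prepare_analysis(regs, value_sets = vsets, t = trf, rules = rls,
                          m = config$m_imputations,
                          seed = child_seed(config$seed, 11L))
    n_missing <- sum(analysis_missing <- a$mi[[1L]]$missing_mask)
    say("analysis", "imputed %d missing utility cells (m = %d)",
        n_missing, config$m_imputations)
    a
  })

  specs <- default_harness_specs(B = config$bootstrap_B,
                                 seed = child_seed(config$seed, 12L))
  res <- stage("harness", run_harness(analysis, specs))

  stage("report", {
    outd <- config$out_dir
    wr <- function(df, f) utils::write.csv(
      df, file.path(outd, f), row.names = FALSE, na = "")
    wr(make_table_demographics(regs), "table1_demographics.csv")
    wr(make_table_costs(analysis$bundles, regs$patients,
                        B = config$bootstrap_B,
                        seed = child_seed(config$seed, 13L)),
       "table2_costs.csv")
    res_out <- as.data.frame(res)
    res_out$delta_e <- round(res_out$delta_e, 4)
    res_out$delta_e_lo <- round(res_out$delta_e_lo, 4)
    res_out$delta_e_hi <- round(res_out$delta_e_hi, 4)
    for (cl in c("delta_c", "delta_c_lo", "delta_c_hi", "icer",
                 "mean_cost_intervention", "mean_cost_control",
                 "total_cost_intervention", "total_cost_control"))
      res_out[[cl]] <- round_half_up(res_out[[cl]], 0)
    wr(res_out, "table3_cea.csv")
    reps <- attr(res, "replicates")[["base_case"]]
    wr(data.frame(delta_e = reps[, 1L], delta_c = reps[, 2L]),
       "ce_plane_base_case.csv")
    mu <- do.call(rbind, lapply(
      analysis$mi[[1L]]$schedule, function(v) {
        rbind(
          data.frame(visit_month = v, arm = "control",
                     as.data.frame(group_mean_utility(
                       analysis$mi[[1L]], regs$patients, "control", v,
                       B = config$bootstrap_B,
                       seed = child_seed(config$seed, 14L))[
                         c("mean", "n")])),
          data.frame(visit_month = v, arm = "intervention",
                     as.data.frame(group_mean_utility(
                       analysis$mi[[1L]], regs$patients, "intervention",
                       v, B = config$bootstrap_B,
                       seed = child_seed(config$seed, 14L))[
                         c("mean", "n")])))
      }))
    mu$mean <- round(mu$mean, 4)
    wr(mu, "mean_utility_by_visit.csv")
    led <- copay_ledger(regs, rls)
    wr(patient_perspective_totals(led, regs$patients),
       "copay_by_arm_year.csv")
    base <- res[res$id == "base_case", ]
    summary <- list(
      seed = config$seed, n_patients = nrow(regs$patients),
      base_case = list(delta_e = base$delta_e, delta_c = base$delta_c,
                       label = base$label),
      stages = log)
    jsonlite::write_json(summary, file.path(outd, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("report", "wrote artifacts to %s", outd)
  })
  invisible(config$out_dir)
}
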