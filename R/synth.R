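#' Trial design for the synthetic two-arm register generator
#'
#' Describes a 1:1 randomised two-arm trial stratified by age band
#' (<65 / >=65) and diagnosis (CHF / COPD / both), followed for
#' `horizon_days` with patient-reported EQ-5D-3L at the scheduled months.
#'
#' @param n_per_arm patients per arm (default 110, the size of the trial
#'   the pipeline emulates).
#' @param horizon_days follow-up horizon in days since randomisation
#'   (default 730).
#' @param followup_months strictly increasing visit schedule in months
#'   (default 0, 3, 6, 12, 24).
#' @param seed integer RNG seed; the whole register bundle is a pure
#'   function of (design, params, seed).
#' @return object of class `cea_trial_design`.
#' @export
trial_design <- function(n_per_arm = 110L, horizon_days = 730L,
                         followup_months = c(0, 3, 6, 12, 24), seed = 1L) {
  n_per_arm <- assert_scalar_int(n_per_arm, "n_per_arm")
  horizon_days <- assert_scalar_int(horizon_days, "horizon_days")
  if (is.unsorted(followup_months, strictly = TRUE))
    abort("followup schedule must be strictly increasing")
  structure(list(n_per_arm = n_per_arm, horizon_days = horizon_days,
                 followup_months = followup_months,
                 seed = assert_scalar_int(seed, "seed", positive = FALSE),
                 strata = expand.grid(
                   age_band = c("under65", "65plus"),
                   diagnosis = c("CHF", "COPD", "both"),
                   stringsAsFactors = FALSE)),
            class = "cea_trial_design")
}

#' Generator parameters for the synthetic registers
#'
#' Defaults state the world the pipeline is tested in, mirroring the
#' emulated trial's published marginals where available (cohort age
#' around 70.7, about 46% women, diagnosis mix roughly 38/52/10
#' CHF/COPD/both) and field-plausible values elsewhere; distributional
#' forms are the simplest that support rate-recovery tests (homogeneous
#' Poisson event streams, linear latent utility trajectories).
#'
#' Utility model: latent utility at visit time t (years) is
#' `b_i + slope_arm * t + e_it`, `b_i ~ N(baseline_utility_mean,
#' baseline_utility_sd)`, `e_it ~ N(0, utility_noise_sd)`; the intervention
#' slope is `control_utility_slope + arm_utility_slope_diff` (a positive
#' difference means the intervention declines more slowly). The latent
#' value is truncated to [-0.594, 1] and discretised to the EQ-5D-3L state
#' whose weight under `value_set` is nearest.
#'
#' @param ... overrides of any default listed below.
#' @return object of class `cea_generator_params` (a validated list).
#' @export
generator_params <- function(...) {
  p <- list(
    # demographics (synthetic stand-ins for the emulated cohort marginals)
    age_mean = 70.7, age_sd = 9.5,
    prob_female = 0.464,
    diagnosis_probs = c(CHF = 0.38, COPD = 0.52, both = 0.10),
    prob_living_alone = 0.30,
    labour_participation_prob_by_age = c(under65 = 0.75, `65plus` = 0.045),
    # latent utility trajectory
    baseline_utility_mean = 0.80, baseline_utility_sd = 0.12,
    control_utility_slope = -0.025,        # utility units / year
    arm_utility_slope_diff = 0.024,        # intervention declines slower
    utility_noise_sd = 0.08,
    value_set = NULL,                      # default toy_value_set()
    # missingness per (arm, visit); intervention roughly twice control at
    # post-baseline visits (per-visit levels are placeholders: the source
    # trial reported only the ~2x arm ratio)
    missingness_prob_by_arm_and_visit = list(
      control      = c(`0` = 0.04, `3` = 0.10, `6` = 0.10, `12` = 0.10,
                       `24` = 0.10),
      intervention = c(`0` = 0.04, `3` = 0.19, `6` = 0.19, `12` = 0.19,
                       `24` = 0.19)),
    missingness_mechanism = "MCAR",        # or "MAR"
    mar_utility_beta = -2,                 # logit slope on latent utility
    # annual event rates, control arm; intervention = rate * ratio
    event_rates = list(
      primary_care           = 10.5,
      specialised_outpatient = 6.8,
      inpatient              = 0.55,
      polyclinical           = 0.05,
      dispensations          = 25),
    intervention_rate_ratio = c(
      primary_care = 1.05, specialised_outpatient = 0.80,
      inpatient = 0.70, polyclinical = 1.0, dispensations = 0.95),
    visit_form_probs = c(physician = 0.35, other_hcp = 0.30, group = 0.02,
                         team = 0.05, group_team = 0.03, home = 0.05,
                         indirect = 0.20),
    drg_weight_meanlog = c(specialised_outpatient = -0.35,
                           inpatient = 0.25, polyclinical = -0.1),
    drg_weight_sdlog = 0.45,
    drg_missing_prob = 0.23,               # specialised outpatient only
    inpatient_mean_nights = 4,
    drug_cost_meanlog = 5.6, drug_cost_sdlog = 0.9,  # SEK ex tax / disp.
    drug_payable_fraction = 0.5,           # patient-payable share of price
    sick_leave_rate = 30,                  # days / year, labour participants
    mortality_hazard = 0.06,               # per year
    # intervention delivery (intervention arm only)
    contact_minutes_meanlog = 4.9, contact_minutes_sdlog = 0.35,
    contacts_per_patient = 6,
    prob_health_plan_call = 0.85, prob_platform_use = 0.81)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    abort("unknown generator parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (is.null(p$value_set)) p$value_set <- toy_value_set()
  validate_generator_params(p)
  structure(p, class = "cea_generator_params")
}

validate_generator_params <- function(p) {
  assert_prob(p$prob_female, "prob_female")
  assert_prob(unlist(p$missingness_prob_by_arm_and_visit),
              "missingness_prob_by_arm_and_visit")
  assert_prob(p$drg_missing_prob, "drg_missing_prob")
  assert_prob(p$labour_participation_prob_by_age,
              "labour_participation_prob_by_age")
  assert_nonneg(unlist(p$event_rates), "event_rates")
  assert_nonneg(p$intervention_rate_ratio, "intervention_rate_ratio")
  assert_nonneg(p$mortality_hazard, "mortality_hazard")
  assert_nonneg(p$sick_leave_rate, "sick_leave_rate")
  for (arm in names(p$missingness_prob_by_arm_and_visit)) {
    mp <- p$missingness_prob_by_arm_and_visit[[arm]]
    if (length(mp) > 1L && mp[["0"]] > min(mp[-1L]) + 1e-12)
      abort("baseline missingness must not exceed later visits (%s arm)", arm)
  }
  invisible(p)
}

#' Generate a synthetic trial register bundle
#'
#' Draws a full two-arm cohort and all downstream registers: patients
#' (with stratified 1:1 allocation), EQ-5D-3L responses with
#' arm-differential missingness, care events per stream (homogeneous
#' Poisson within each patient's time alive), drug dispensations,
#' sick-leave absences, intervention contact logs and deaths. Deterministic
#' for a fixed (design, params) pair; deaths truncate all subsequent
#' events and observations; the per-protocol flag marks intervention
#' patients with at least one documented health-plan call and at least one
#' platform use.
#'
#' @param design a [trial_design()].
#' @param params a [generator_params()].
#' @return object of class `cea_registers`: named list of data.frames
#'   `patients`, `eq5d`, `care_events`, `dispensations`, `absences`,
#'   `intervention_log`, `deaths`.
#' @export
generate_cohort <- function(design, params = generator_params()) {
  if (!inherits(design, "cea_trial_design")) abort("not a trial design")
  if (!inherits(params, "cea_generator_params"))
    abort("not generator params")
  validate_generator_params(params)
  p <- params
  n <- 2L * design$n_per_arm
  horizon <- design$horizon_days
  sched <- design$followup_months

  set.seed(child_seed(design$seed, 101L))
  age <- round(stats::rnorm(n, p$age_mean, p$age_sd), 1)
  age <- pmax(age, 30)
  age_band <- ifelse(age < 65, "under65", "65plus")
  sex <- ifelse(stats::runif(n) < p$prob_female, "female", "male")
  diagnosis <- sample(names(p$diagnosis_probs), n, replace = TRUE,
                      prob = p$diagnosis_probs)
  living_alone <- stats::runif(n) < p$prob_living_alone
  labour <- stats::runif(n) <
    p$labour_participation_prob_by_age[age_band]

  # stratified 1:1 allocation: permuted balanced assignment per stratum,
  # odd-stratum leftovers alternate arms so totals stay within |strata|/2
  arm <- character(n)
  stratum <- paste(age_band, diagnosis, sep = ":")
  leftover_flip <- 0L
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    k <- length(idx) %/% 2L
    lab <- c(rep("intervention", k), rep("control", k))
    if (length(idx) %% 2L) {
      lab <- c(lab, if (leftover_flip %% 2L == 0L) "intervention"
               else "control")
      leftover_flip <- leftover_flip + 1L
    }
    arm[idx] <- sample(lab)
  }

  patients <- data.frame(
    patient_id = seq_len(n), arm = arm, age = age, age_band = age_band,
    sex = sex, diagnosis = diagnosis, living_alone = living_alone,
    labour_participant = labour, stringsAsFactors = FALSE)

  # deaths: exponential survival
  set.seed(child_seed(design$seed, 102L))
  death_day <- if (p$mortality_hazard > 0)
    floor(stats::rexp(n, p$mortality_hazard / 365)) else rep(Inf, n)
  death_day[death_day >= horizon] <- NA_real_
  patients$death_day <- death_day
  deaths <- data.frame(patient_id = patients$patient_id[!is.na(death_day)],
                       death_day = death_day[!is.na(death_day)])
  alive_days <- ifelse(is.na(death_day), horizon, death_day)

  # latent utility trajectories and EQ-5D discretisation
  set.seed(child_seed(design$seed, 103L))
  b <- stats::rnorm(n, p$baseline_utility_mean, p$baseline_utility_sd)
  slope <- p$control_utility_slope +
    (arm == "intervention") * p$arm_utility_slope_diff
  visit_day <- round(sched / 12 * 365)
  eq_rows <- list()
  for (j in seq_along(sched)) {
    # questionnaires truncated by death only (the last visit sits at the
    # end of the event horizon)
    alive <- is.na(death_day) | visit_day[j] < death_day
    t_yr <- sched[j] / 12
    latent <- b + slope * t_yr + stats::rnorm(n, 0, p$utility_noise_sd)
    latent <- pmin(pmax(latent, -0.594), 1)
    code <- nearest_state(latent, p$value_set)
    lev <- eq5d_parse(code)
    eq_rows[[j]] <- data.frame(
      patient_id = patients$patient_id[alive],
      visit_month = sched[j], lev[alive, , drop = FALSE],
      latent_utility = latent[alive])
  }
  eq5d <- do.call(rbind, eq_rows)
  eq5d <- eq5d[order(eq5d$patient_id, eq5d$visit_month), ]
  rownames(eq5d) <- NULL

  eq5d <- apply_missingness(
    eq5d, p$missingness_prob_by_arm_and_visit,
    seed = child_seed(design$seed, 104L), patients = patients,
    mechanism = p$missingness_mechanism,
    mar_utility_beta = p$mar_utility_beta)
  eq5d$latent_utility <- NULL

  # care events: homogeneous Poisson per stream over each patient's time
  # alive, uniform event days
  set.seed(child_seed(design$seed, 105L))
  exposure <- alive_days / 365
  ratio <- function(stream)
    ifelse(arm == "intervention", p$intervention_rate_ratio[[stream]], 1)
  ev <- list()
  for (stream in c("primary_care", "specialised_outpatient", "inpatient",
                   "polyclinical")) {
    lam <- p$event_rates[[stream]] * ratio(stream) * exposure
    cnt <- stats::rpois(n, lam)
    pid <- rep(patients$patient_id, cnt)
    day <- floor(stats::runif(sum(cnt)) * rep(alive_days, cnt))
    stream_key <- sub("_care$", "", stream)  # "primary_care" -> "primary"
    e <- data.frame(patient_id = pid, day = day,
                    stream = rep(stream_key, length(pid)),
                    visit_form = rep(NA_character_, length(pid)),
                    drg_weight = rep(NA_real_, length(pid)),
                    nights = rep(0L, length(pid)))
    if (stream == "primary_care") {
      e$visit_form <- sample(names(p$visit_form_probs), nrow(e),
                             replace = TRUE, prob = p$visit_form_probs)
    } else {
      e$drg_weight <- stats::rlnorm(nrow(e),
                                    p$drg_weight_meanlog[[stream]],
                                    p$drg_weight_sdlog)
      if (stream == "specialised_outpatient")
        e$drg_weight[stats::runif(nrow(e)) < p$drg_missing_prob] <- NA_real_
      if (stream == "inpatient")
        e$nights <- 1L + stats::rpois(nrow(e),
                                      p$inpatient_mean_nights - 1)
    }
    ev[[stream]] <- e
  }
  care_events <- do.call(rbind, ev)
  care_events <- care_events[order(care_events$patient_id,
                                   care_events$day), ]
  rownames(care_events) <- NULL

  # dispensations
  set.seed(child_seed(design$seed, 106L))
  cnt <- stats::rpois(n, p$event_rates$dispensations *
                        ratio("dispensations") * exposure)
  cost <- stats::rlnorm(sum(cnt), p$drug_cost_meanlog, p$drug_cost_sdlog)
  dispensations <- data.frame(
    patient_id = rep(patients$patient_id, cnt),
    day = floor(stats::runif(sum(cnt)) * rep(alive_days, cnt)),
    cost_ex_tax = round(cost, 2),
    patient_payable = round(cost * p$drug_payable_fraction, 2))
  dispensations <- dispensations[order(dispensations$patient_id,
                                       dispensations$day), ]
  rownames(dispensations) <- NULL

  # sick-leave / disability absences (labour-market participants only)
  set.seed(child_seed(design$seed, 107L))
  spells <- stats::rpois(n, ifelse(labour, 2, 0) * exposure)
  mean_spell <- p$sick_leave_rate / 2    # days per spell so rate holds
  absences <- data.frame(
    patient_id = rep(patients$patient_id, spells),
    day = floor(stats::runif(sum(spells)) * rep(alive_days, spells)),
    days = 1L + stats::rpois(sum(spells), max(mean_spell - 1, 0)))
  absences <- absences[order(absences$patient_id, absences$day), ]
  rownames(absences) <- NULL

  # intervention delivery logs + per-protocol engagement
  set.seed(child_seed(design$seed, 108L))
  is_int <- arm == "intervention"
  had_call <- is_int & stats::runif(n) < p$prob_health_plan_call
  used_platform <- is_int & stats::runif(n) < p$prob_platform_use
  n_contacts <- ifelse(is_int, stats::rpois(n, p$contacts_per_patient), 0L)
  n_contacts[is_int & had_call & n_contacts == 0L] <- 1L
  pid <- rep(patients$patient_id, n_contacts)
  intervention_log <- data.frame(
    patient_id = pid,
    day = floor(stats::runif(length(pid)) *
                  pmin(rep(alive_days, n_contacts), 183)),
    activity = sample(c("call", "platform_message", "documentation"),
                      length(pid), replace = TRUE,
                      prob = c(0.4, 0.3, 0.3)),
    minutes = round(stats::rlnorm(length(pid), p$contact_minutes_meanlog -
                                    log(p$contacts_per_patient),
                                  p$contact_minutes_sdlog), 1))
  intervention_log <- intervention_log[
    order(intervention_log$patient_id, intervention_log$day), ]
  rownames(intervention_log) <- NULL
  patients$pp_eligible <- had_call & used_platform

  structure(list(patients = patients, eq5d = eq5d,
                 care_events = care_events, dispensations = dispensations,
                 absences = absences, intervention_log = intervention_log,
                 deaths = deaths,
                 design = design),
            class = "cea_registers")
}

#' Mask EQ-5D responses per (arm, visit)
#'
#' Marks whole responses missing (all five dimensions set to NA) with the
#' configured probability for the patient's arm and visit. Under the
#' default MCAR mechanism the mask is independent of health; the MAR
#' switch tilts the probability on the logit scale by
#' `mar_utility_beta * (latent - mean latent)` so that sicker patients
#' respond less, while keeping the same marginal rate approximately.
#' Observed responses are never altered.
#'
#' @param eq5d EQ-5D register (must carry `latent_utility` for MAR).
#' @param probs named list by arm of named per-visit probabilities.
#' @param seed RNG seed.
#' @param patients patients register (arm lookup).
#' @param mechanism `"MCAR"` (default) or `"MAR"`.
#' @param mar_utility_beta logit slope for the MAR mechanism.
#' @return the register with masked rows.
#' @export
apply_missingness <- function(eq5d, probs, seed, patients,
                              mechanism = "MCAR", mar_utility_beta = -2) {
  assert_prob(unlist(probs), "missingness probabilities")
  arm <- patients$arm[match(eq5d$patient_id, patients$patient_id)]
  pr <- numeric(nrow(eq5d))
  for (a in unique(arm)) {
    pa <- probs[[a]]
    if (is.null(pa)) abort("missingness probabilities absent for arm %s", a)
    vis <- as.character(eq5d$visit_month[arm == a])
    if (any(!vis %in% names(pa)))
      abort("missingness probability missing for visit(s): %s",
            paste(setdiff(unique(vis), names(pa)), collapse = ", "))
    pr[arm == a] <- pa[vis]
  }
  if (identical(mechanism, "MAR")) {
    if (is.null(eq5d$latent_utility))
      abort("MAR mechanism needs latent_utility")
    eta <- stats::qlogis(pmin(pmax(pr, 1e-9), 1 - 1e-9)) +
      mar_utility_beta * (eq5d$latent_utility -
                            mean(eq5d$latent_utility))
    pr2 <- stats::plogis(eta)
    pr <- ifelse(pr %in% c(0, 1), pr, pr2)
  }
  set.seed(seed)
  mask <- stats::runif(nrow(eq5d)) < pr
  eq5d[mask, EQ5D_DIMENSIONS] <- NA_integer_
  eq5d
}

#' Write / read a register bundle as delimited text
#'
#' One CSV per register (patients.csv, eq5d.csv, care_events.csv,
#' dispensations.csv, absences.csv, intervention_log.csv, deaths.csv);
#' days are integers since randomisation, missing EQ-5D dimensions are
#' empty fields.
#'
#' @param registers a `cea_registers` bundle.
#' @param dir output directory (created if needed).
#' @return the directory (write) or a `cea_registers` bundle (read).
#' @export
write_registers <- function(registers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "eq5d", "care_events", "dispensations",
               "absences", "intervention_log", "deaths")) {
    utils::write.csv(registers[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' @rdname write_registers
#' @export
read_registers <- function(dir) {
  rd <- function(nm, classes = NA)
    utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                    stringsAsFactors = FALSE, colClasses = classes,
                    na.strings = c("NA", ""))
  out <- list(patients = rd("patients"), eq5d = rd("eq5d"),
              care_events = rd("care_events"),
              dispensations = rd("dispensations"),
              absences = rd("absences"),
              intervention_log = rd("intervention_log"),
              deaths = rd("deaths"))
  structure(out, class = "cea_registers")
}
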