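test_that("stratified 1:1 allocation balances every stratum", {
  regs <- generate_cohort(trial_design(n_per_arm = 110, seed = 1))
  pats <- regs$patients
  expect_equal(nrow(pats), 220L)
  tab <- table(paste(pats$age_band, pats$diagnosis), pats$arm)
  expect_true(all(abs(tab[, "intervention"] - tab[, "control"]) <= 1))
  # leftover alternation keeps overall arm totals near n_per_arm
  expect_lte(abs(sum(pats$arm == "intervention") - 110), 3)
  expect_true(all(pats$arm %in% c("intervention", "control")))
})

test_that("zero mortality hazard yields no deaths and full exposure", {
  regs <- generate_cohort(trial_design(n_per_arm = 30, seed = 2),
                          generator_params(mortality_hazard = 0))
  expect_equal(nrow(regs$deaths), 0L)
  expect_true(all(is.na(regs$patients$death_day)))
  expect_true(all(regs$care_events$day >= 0 &
                    regs$care_events$day < 730))
})

test_that("register bundle is byte-deterministic for a fixed seed", {
  d <- trial_design(n_per_arm = 25, seed = 42)
  a <- generate_cohort(d)
  b <- generate_cohort(d)
  for (nm in c("patients", "eq5d", "care_events", "dispensations",
               "absences", "intervention_log", "deaths"))
    expect_identical(a[[nm]], b[[nm]])
  c_ <- generate_cohort(trial_design(n_per_arm = 25, seed = 43))
  expect_false(identical(a$care_events, c_$care_events))
})

test_that("death truncates all events and observations", {
  regs <- generate_cohort(trial_design(n_per_arm = 60, seed = 7),
                          generator_params(mortality_hazard = 0.4))
  dd <- regs$patients$death_day
  names(dd) <- regs$patients$patient_id
  dead <- !is.na(dd)
  expect_gt(sum(dead), 0)
  ev_death <- dd[as.character(regs$care_events$patient_id)]
  expect_true(all(is.na(ev_death) | regs$care_events$day < ev_death))
  eq_death <- dd[as.character(regs$eq5d$patient_id)]
  visit_day <- round(regs$eq5d$visit_month / 12 * 365)
  expect_true(all(is.na(eq_death) | visit_day < eq_death))
  disp_death <- dd[as.character(regs$dispensations$patient_id)]
  expect_true(all(is.na(disp_death) | regs$dispensations$day < disp_death))
})

test_that("per-protocol flag requires a health-plan call and platform use", {
  regs <- generate_cohort(trial_design(n_per_arm = 200, seed = 5))
  pats <- regs$patients
  expect_true(all(!pats$pp_eligible[pats$arm == "control"]))
  # engagement probabilities 0.85 * 0.81: PP fraction near 0.69
  frac <- mean(pats$pp_eligible[pats$arm == "intervention"])
  expect_gt(frac, 0.55); expect_lt(frac, 0.8)
  # every PP patient has at least one logged contact
  pp_ids <- pats$patient_id[pats$pp_eligible]
  expect_true(all(pp_ids %in% regs$intervention_log$patient_id))
  # control patients never appear in the intervention log
  expect_false(any(regs$intervention_log$patient_id %in%
                     pats$patient_id[pats$arm == "control"]))
})

test_that("missingness is MCAR per (arm, visit) at the nominal rates", {
  n <- 10000L
  regs <- generate_cohort(
    trial_design(n_per_arm = n, seed = 11),
    generator_params(
      mortality_hazard = 0,
      missingness_prob_by_arm_and_visit = list(
        control = c(`0` = 0, `3` = 0.1, `6` = 0.1, `12` = 0.1,
                    `24` = 0.1),
        intervention = c(`0` = 0, `3` = 0.2, `6` = 0.2, `12` = 0.2,
                         `24` = 0.2))))
  eq <- regs$eq5d
  arm <- regs$patients$arm[match(eq$patient_id,
                                 regs$patients$patient_id)]
  for (a in c("control", "intervention")) {
    p <- if (a == "control") 0.1 else 0.2
    at <- arm == a & eq$visit_month > 0
    frac <- mean(is.na(eq$mobility[at]))
    se <- sqrt(p * (1 - p) / sum(at))
    expect_lt(abs(frac - p), 3 * se)   # binomial oracle
    expect_false(any(is.na(eq$mobility[arm == a & eq$visit_month == 0])))
  }
})

test_that("apply_missingness honours degenerate probabilities", {
  regs <- generate_cohort(trial_design(n_per_arm = 20, seed = 3),
                          generator_params(
                            mortality_hazard = 0,
                            missingness_prob_by_arm_and_visit = list(
                              control = c(`0` = 0, `3` = 0, `6` = 0,
                                          `12` = 0, `24` = 0),
                              intervention = c(`0` = 0, `3` = 0, `6` = 0,
                                               `12` = 0, `24` = 0))))
  eq <- regs$eq5d
  zero <- list(control = c(`0` = 0, `3` = 0, `6` = 0, `12` = 0, `24` = 0),
               intervention = c(`0` = 0, `3` = 0, `6` = 0, `12` = 0,
                                `24` = 0))
  expect_identical(apply_missingness(eq, zero, seed = 1,
                                     patients = regs$patients), eq)
  all24 <- lapply(zero, function(x) { x["24"] <- 1; x })
  masked <- apply_missingness(eq, all24, seed = 1,
                              patients = regs$patients)
  expect_true(all(is.na(masked$mobility[masked$visit_month == 24])))
  expect_identical(masked[masked$visit_month < 24, ],
                   eq[eq$visit_month < 24, ])
  # probability missing for a scheduled visit is an error
  expect_error(apply_missingness(eq, lapply(zero, `[`, 1:4), seed = 1,
                                 patients = regs$patients),
               "visit")
})

test_that("parameter validation rejects malformed designs and params", {
  expect_error(trial_design(n_per_arm = 0), "positive")
  expect_error(trial_design(n_per_arm = 2.5), "integer")
  expect_error(trial_design(followup_months = c(0, 6, 3)), "increasing")
  expect_error(generator_params(prob_female = 1.2), "\\[0, 1\\]")
  expect_error(generator_params(
    missingness_prob_by_arm_and_visit = list(
      control = c(`0` = 0.5, `3` = 0.1, `6` = 0.1, `12` = 0.1,
                  `24` = 0.1),
      intervention = c(`0` = 0.04, `3` = 0.1, `6` = 0.1, `12` = 0.1,
                       `24` = 0.1))), "baseline missingness")
  expect_error(generator_params(bogus = 1), "unknown")
})

test_that("arm exchangeability: null generator centres estimates on 0", {
  # with all arm-difference parameters zero the labels are exchangeable;
  # check the mean 24-month utility gap over a modest cohort
  regs <- generate_cohort(
    trial_design(n_per_arm = 4000, seed = 13),
    generator_params(arm_utility_slope_diff = 0, mortality_hazard = 0,
                     intervention_rate_ratio = c(
                       primary_care = 1, specialised_outpatient = 1,
                       inpatient = 1, polyclinical = 1,
                       dispensations = 1),
                     missingness_prob_by_arm_and_visit = list(
                       control = c(`0` = 0, `3` = 0, `6` = 0, `12` = 0,
                                   `24` = 0),
                       intervention = c(`0` = 0, `3` = 0, `6` = 0,
                                        `12` = 0, `24` = 0))))
  u <- utilities_from_eq5d(regs$eq5d, toy_value_set())
  arm <- regs$patients$arm[match(u$patient_id, regs$patients$patient_id)]
  at24 <- u$visit_month == 24
  gap <- mean(u$utility[at24 & arm == "intervention"]) -
    mean(u$utility[at24 & arm == "control"])
  se <- sqrt(var(u$utility[at24]) * 2 / 4000)
  expect_lt(abs(gap), 3 * se)
  ev <- regs$care_events
  earm <- regs$patients$arm[match(ev$patient_id,
                                  regs$patients$patient_id)]
  cnt <- table(earm) / 4000
  expect_lt(abs(cnt[["intervention"]] - cnt[["control"]]),
            3 * sqrt(2 * mean(cnt) / 4000))
})

test_that("registers round-trip through the CSV bundle format", {
  regs <- generate_cohort(trial_design(n_per_arm = 15, seed = 21))
  dir <- withr::local_tempdir()
  write_registers(regs, dir)
  expect_setequal(dir(dir), c("patients.csv", "eq5d.csv",
                              "care_events.csv", "dispensations.csv",
                              "absences.csv", "intervention_log.csv",
                              "deaths.csv"))
  back <- read_registers(dir)
  expect_equal(back$patients$arm, regs$patients$arm)
  expect_equal(back$care_events$day, regs$care_events$day)
  expect_equal(back$eq5d$mobility, regs$eq5d$mobility)
  expect_equal(sum(is.na(back$eq5d$mobility)),
               sum(is.na(regs$eq5d$mobility)))
})

test_that("24-month utility gap matches the analytic generator mean", {
  p <- generator_params(arm_utility_slope_diff = 0.025,
                        mortality_hazard = 0,
                        missingness_prob_by_arm_and_visit = list(
                          control = c(`0` = 0, `3` = 0, `6` = 0,
                                      `12` = 0, `24` = 0),
                          intervention = c(`0` = 0, `3` = 0, `6` = 0,
                                           `12` = 0, `24` = 0)))
  regs <- generate_cohort(trial_design(n_per_arm = 5000, seed = 7), p)
  u <- utilities_from_eq5d(regs$eq5d, p$value_set)
  arm <- regs$patients$arm[match(u$patient_id, regs$patients$patient_id)]
  at24 <- u$visit_month == 24
  gap <- mean(u$utility[at24 & arm == "intervention"]) -
    mean(u$utility[at24 & arm == "control"])
  sd_lat <- sqrt(p$baseline_utility_sd^2 + p$utility_noise_sd^2)
  expected <- oracle_discretised_mean(
    p$baseline_utility_mean + (p$control_utility_slope + 0.025) * 2,
    sd_lat, p$value_set) -
    oracle_discretised_mean(
      p$baseline_utility_mean + p$control_utility_slope * 2,
      sd_lat, p$value_set)
  se <- sqrt(var(u$utility[at24]) * 2 / 5000)
  # empirical gap recovers both the analytic generating-model mean and
  # the nominal slope-difference gap of 0.05 within 3 MC SE
  expect_lt(abs(gap - expected), 3 * se)
  expect_lt(abs(gap - 0.05), 3 * se)
})
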