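test_that("primary-care multipliers price each visit form correctly", {
  t <- tariff(physician_consultation_cost = 1000)
  ev <- function(form) data.frame(stream = "primary", visit_form = form)
  expect_equal(price_primary_event(ev("physician"), t), 1000)
  expect_equal(price_primary_event(ev("other_hcp"), t), 400)
  expect_equal(price_primary_event(ev("group"), t), 400)
  expect_equal(price_primary_event(ev("team"), t), 1500)
  expect_equal(price_primary_event(ev("group_team"), t), 1500)
  expect_equal(price_primary_event(ev("home"), t), 2000)
  expect_equal(price_primary_event(ev("indirect"), t), 1000 / 3)
  # one-third of 999 rounds half-up to 333 at reporting precision
  t999 <- tariff(physician_consultation_cost = 999)
  expect_equal(round_half_up(price_primary_event(ev("indirect"), t999)),
               333)
  expect_error(price_primary_event(ev("house_call"), t), "visit_form")
  expect_error(price_primary_event(
    data.frame(stream = "inpatient", visit_form = "physician"), t),
    "primary")
})

test_that("DRG pricing is weight times point cost, with the fallback", {
  t <- tariff(avg_cost_per_drg_point = 30000,
              specialist_consultation_cost = 2000)
  e <- data.frame(stream = "specialised_outpatient",
                  visit_form = NA_character_, drg_weight = 1.5)
  expect_equal(price_drg_event(e, t), 45000)
  e$drg_weight <- 0
  expect_equal(price_drg_event(e, t), 0)
  # missing weight in specialised outpatient: specialist-consultation
  # fallback with the primary-care multiplier method
  e$drg_weight <- NA
  expect_equal(price_drg_event(e, t), 2000)
  e$visit_form <- "indirect"
  expect_equal(price_drg_event(e, t), 2000 / 3)
  # missing weight on inpatient/polyclinical is a data error
  bad <- data.frame(stream = "inpatient", visit_form = NA,
                    drg_weight = NA, nights = 2)
  expect_error(price_drg_event(bad, t), "data error")
  expect_error(price_drg_event(
    data.frame(stream = "primary", visit_form = "physician",
               drg_weight = 1), t), "DRG")
})

test_that("drug costs sum per patient-year and reject negatives", {
  expect_equal(nrow(price_drugs(data.frame(patient_id = integer(),
                                           day = integer(),
                                           cost_ex_tax = numeric()))), 0L)
  d <- data.frame(patient_id = c(1, 1), day = c(10, 20),
                  cost_ex_tax = c(120.5, 79.5))
  expect_equal(price_drugs(d)$amount, 200)
  d$cost_ex_tax[2] <- -1
  expect_error(price_drugs(d), "negative")
  # brute-force groupby oracle on a random register
  set.seed(31)
  n <- 10000
  d <- data.frame(patient_id = sample(1:50, n, TRUE),
                  day = sample(0:729, n, TRUE),
                  cost_ex_tax = round(runif(n, 1, 500), 2))
  got <- price_drugs(d)
  for (k in sample(nrow(got), 25)) {
    pid <- got$patient_id[k]; yr <- got$year[k]
    sel <- d$patient_id == pid &
      ((yr == 1 & d$day < 365) | (yr == 2 & d$day >= 365))
    expect_equal(got$amount[k], sum(d$cost_ex_tax[sel]))
  }
  expect_equal(sum(got$amount), sum(d$cost_ex_tax))
})

test_that("intervention delivery time is priced at the loaded wage", {
  regs <- tiny_registers()
  t <- tariff(hcp_hourly_wage_with_social_contributions = 500)
  res <- price_intervention(regs$intervention_log, t, regs$patients)
  expect_equal(res$per_patient$amount, c(500, 250))  # 60 and 30 minutes
  expect_equal(res$arm_total, 750)
  zero <- regs$intervention_log[0, ]
  expect_equal(price_intervention(zero, t, regs$patients)$arm_total, 0)
  bad <- regs$intervention_log
  bad$patient_id[1] <- 2   # control patient
  expect_error(price_intervention(bad, t, regs$patients), "control")
})

test_that("productivity loss uses the age band fixed at randomisation", {
  pats <- data.frame(patient_id = 1:3, age = c(54.9, 64.9, 70),
                     labour_participant = c(TRUE, TRUE, TRUE))
  t <- tariff(wage_by_age_band = c(`16-24` = 1, `25-34` = 1, `35-44` = 1,
                                   `45-54` = 45625, `55-64` = 45625,
                                   `65plus` = 99),
              social_contribution_rate = 0.3142,
              days_per_month = 30.41667)
  # 10 days at daily wage 1500 plus 31.42% contributions = 19713
  ab <- data.frame(patient_id = 1, day = 100, days = 10)
  got <- productivity_loss(ab, pats, t)
  expect_equal(round_half_up(got$amount), 19713)
  # age 64.9 at randomisation stays in the 55-64 band all study long,
  # even though a birthday crosses the 65 boundary mid-study
  ab2 <- data.frame(patient_id = 2, day = 700, days = 10)   # ~age 66.8
  expect_equal(productivity_loss(ab2, pats, t)$amount, got$amount)
  # non-participants in the labour market contribute zero
  pats$labour_participant[3] <- FALSE
  ab3 <- data.frame(patient_id = 3, day = 10, days = 10)
  expect_equal(productivity_loss(ab3, pats, t)$amount, 0)
  expect_equal(nrow(productivity_loss(ab3[0, ], pats, t)), 0L)
  expect_error(productivity_loss(
    data.frame(patient_id = 1, day = 730, days = 1), pats, t), "horizon")
})

test_that("bundle assembly: year split, discounting, perspectives", {
  regs <- tiny_registers()
  # single year-2 item of 1030 discounts to 1000 at 3%
  priced <- data.frame(patient_id = 1, component = "primary_care",
                       year = 2L, amount = 1030)
  b <- assemble_bundle(priced, regs, rules = NULL,
                       discount_rate_costs = 0.03)
  expect_equal(b$societal_total_discounted[b$patient_id == 1], 1000)
  expect_equal(b$primary_care_y2[b$patient_id == 1], 1030)
  # all-zero inputs give an all-zero bundle
  b0 <- assemble_bundle(priced[0, ], regs, rules = NULL)
  expect_true(all(b0$societal_total_discounted == 0))
  expect_error(assemble_bundle(
    data.frame(patient_id = 1, component = "primary_care", year = 3L,
               amount = 5), regs, rules = NULL), "year")
})

test_that("full costing run satisfies its conservation invariants", {
  regs <- generate_cohort(trial_design(n_per_arm = 40, seed = 17))
  t <- tariff()
  b <- cost_bundles(regs, t, rules = copay_rules(),
                    discount_rate_costs = 0.03)
  comp_y <- as.matrix(b[, grep("_y[12]$", names(b))])
  expect_true(all(comp_y >= 0))
  # conservation: independent re-summation of every priced stream
  ev <- regs$care_events
  prim <- ev[ev$stream == "primary", ]
  drg <- ev[ev$stream != "primary", ]
  grand <- sum(price_primary_event(prim, t)) +
    sum(price_drg_event(drg, t)) +
    sum(regs$dispensations$cost_ex_tax) +
    sum(productivity_loss(regs$absences, regs$patients, t)$amount) +
    price_intervention(regs$intervention_log, t, regs$patients)$arm_total
  comp_cols <- paste0(rep(c("primary_care", "inpatient",
                            "specialised_outpatient", "polyclinical",
                            "prescription_drugs", "productivity_loss",
                            "intervention_delivery"), each = 2),
                      c("_y1", "_y2"))
  expect_equal(sum(b[, comp_cols]), grand)
  # perspective nesting: payer <= societal when productivity and
  # intervention costs are non-negative
  expect_true(all(b$payer_total_discounted <=
                    b$societal_total_discounted + 1e-9))
  # discounting: r = 0 total >= r > 0 total when year-2 costs positive
  b0 <- cost_bundles(regs, t, rules = NULL, discount_rate_costs = 0)
  expect_true(all(b0$societal_total_discounted >=
                    b$societal_total_discounted - 1e-9))
})

test_that("costing is linear: doubling every event doubles every cost", {
  regs <- generate_cohort(trial_design(n_per_arm = 10, seed = 19))
  dbl <- regs
  bump <- function(df) {
    d2 <- df
    d2$patient_id <- d2$patient_id  # same patients, duplicated rows
    rbind(df, d2)
  }
  dbl$care_events <- bump(regs$care_events)
  dbl$dispensations <- bump(regs$dispensations)
  dbl$absences <- bump(regs$absences)
  dbl$intervention_log <- bump(regs$intervention_log)
  b1 <- cost_bundles(regs, rules = NULL)
  b2 <- cost_bundles(dbl, rules = NULL)
  expect_equal(b2$societal_total_discounted,
               2 * b1$societal_total_discounted)
  expect_equal(b2$payer_total_discounted, 2 * b1$payer_total_discounted)
})
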