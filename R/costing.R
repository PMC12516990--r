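#' Tariff: unit prices, multipliers and wage tables
#'
#' Prices follow the regional costing rules the pipeline emulates:
#' primary-care contacts are priced relative to a physician consultation
#' (other-HCP and group visits 40%, team and group/team visits 150%, home
#' visits 200%, indirect/telephone contacts one third); specialised
#' outpatient, inpatient and polyclinical episodes are priced as DRG
#' weight times the average cost per DRG point, with missing specialised
#' outpatient weights falling back to consultation-multiplier pricing at
#' the specialist consultation price. The monetary unit-price defaults
#' below are placeholders with plausible 2021 magnitudes: the source
#' tariff documents are not reproduced, so real analyses must supply
#' their own values via the config.
#'
#' @param ... overrides of any default field.
#' @return object of class `cea_tariff`.
#' @export
tariff <- function(...) {
  t <- list(
    physician_consultation_cost = 1800,   # SEK, placeholder
    specialist_consultation_cost = 3600,  # SEK, placeholder
    avg_cost_per_drg_point = 27000,       # SEK, placeholder
    multipliers = c(physician = 1, other_hcp = 0.4, group = 0.4,
                    team = 1.5, group_team = 1.5, home = 2,
                    indirect = 1 / 3),
    hcp_hourly_wage_with_social_contributions = 557,  # SEK/h
    wage_by_age_band = c(`16-24` = 26500, `25-34` = 34000,
                         `35-44` = 38900, `45-54` = 40900,
                         `55-64` = 40200, `65plus` = 41000),  # SEK/month
    social_contribution_rate = 0.3142,
    days_per_month = 365 / 12)            # daily wage convention
  over <- list(...)
  unknown <- setdiff(names(over), names(t))
  if (length(unknown))
    abort("unknown tariff field(s): %s", paste(unknown, collapse = ", "))
  t[names(over)] <- over
  amounts <- c(t$physician_consultation_cost,
               t$specialist_consultation_cost, t$avg_cost_per_drg_point,
               t$hcp_hourly_wage_with_social_contributions,
               t$wage_by_age_band)
  if (any(amounts <= 0)) abort("tariff amounts must be > 0")
  structure(t, class = "cea_tariff")
}

#' Price primary-care contacts
#'
#' Applies the consultation multipliers to `physician_consultation_cost`.
#'
#' @param events care-event rows with `stream == "primary"` and a
#'   `visit_form` in the multiplier table.
#' @param t a [tariff()].
#' @param unit_cost consultation unit cost; defaults to the physician
#'   consultation cost (the specialist price is passed here by the
#'   missing-DRG fallback).
#' @return numeric SEK per event.
#' @export
price_primary_event <- function(events, t,
                                unit_cost = t$physician_consultation_cost) {
  if (any(events$stream != "primary"))
    abort("price_primary_event expects primary-care events")
  mult <- t$multipliers[events$visit_form]
  if (anyNA(mult))
    abort("unknown visit_form: %s",
          paste(unique(events$visit_form[is.na(mult)]), collapse = ", "))
  unname(mult * unit_cost)
}

#' Price DRG-weighted episodes
#'
#' Weight times average cost per DRG point. Specialised outpatient
#' episodes with a missing weight fall back to consultation-multiplier
#' pricing at the specialist consultation cost (physician multiplier when
#' no visit form is recorded); a missing weight on inpatient or
#' polyclinical episodes is a data error, since those streams carry
#' complete DRG information.
#'
#' @param events care-event rows with `stream` in `specialised_outpatient`,
#'   `inpatient`, `polyclinical`.
#' @param t a [tariff()].
#' @return numeric SEK per event.
#' @export
price_drg_event <- function(events, t) {
  ok <- events$stream %in% c("specialised_outpatient", "inpatient",
                             "polyclinical")
  if (any(!ok)) abort("price_drg_event expects DRG-costed streams")
  miss <- is.na(events$drg_weight)
  if (any(miss & events$stream != "specialised_outpatient"))
    abort("missing DRG weight on %s episode(s): data error",
          paste(unique(events$stream[miss &
            events$stream != "specialised_outpatient"]), collapse = ", "))
  out <- events$drg_weight * t$avg_cost_per_drg_point
  if (any(miss)) {
    fb <- events[miss, , drop = FALSE]
    fb$stream <- "primary"
    fb$visit_form[is.na(fb$visit_form)] <- "physician"
    out[miss] <- price_primary_event(fb, t,
      unit_cost = t$specialist_consultation_cost)
  }
  out
}

#' Sum dispensed drug costs (ex tax) per patient-year
#'
#' @param dispensations register rows with `patient_id`, `day`,
#'   `cost_ex_tax`.
#' @return data.frame `patient_id`, `year`, `amount` (SEK).
#' @export
price_drugs <- function(dispensations) {
  if (!nrow(dispensations))
    return(data.frame(patient_id = integer(), year = integer(),
                      amount = numeric()))
  if (any(dispensations$cost_ex_tax < 0))
    abort("negative dispensation cost record")
  dt <- data.table::as.data.table(dispensations)
  dt[, year := study_year(day)]
  out <- dt[, list(amount = sum(cost_ex_tax)),
            by = c("patient_id", "year")]
  as.data.frame(out[order(patient_id, year)])
}

#' Price intervention delivery time
#'
#' HCP time in patient-facing meetings, documentation and communication,
#' valued at the mean hourly wage including social contributions.
#'
#' @param intervention_log rows with `patient_id`, `day`, `minutes`.
#' @param t a [tariff()].
#' @param patients patients register; control patients must have no log
#'   entries.
#' @return list `per_patient` (data.frame `patient_id`, `year`, `amount`)
#'   and `arm_total` (SEK).
#' @export
price_intervention <- function(intervention_log, t, patients) {
  if (any(intervention_log$minutes < 0)) abort("minutes must be >= 0")
  ctrl <- patients$patient_id[patients$arm == "control"]
  if (any(intervention_log$patient_id %in% ctrl))
    abort("intervention log entry for control patient")
  if (!nrow(intervention_log))
    return(list(per_patient = data.frame(patient_id = integer(),
                                         year = integer(),
                                         amount = numeric()),
                arm_total = 0))
  dt <- data.table::as.data.table(intervention_log)
  dt[, year := study_year(day)]
  wage <- t$hcp_hourly_wage_with_social_contributions
  pp <- dt[, list(amount = sum(minutes) / 60 * wage),
           by = c("patient_id", "year")]
  list(per_patient = as.data.frame(pp[order(patient_id, year)]),
       arm_total = sum(pp$amount))
}

#' Productivity loss from absenteeism (human capital approach)
#'
#' Absence days times the daily wage for the patient's 10-year age band
#' at randomisation, plus employer social contributions. The age band is
#' fixed at randomisation even if a birthday crosses a band boundary
#' mid-study. Non-participants in the labour market contribute zero.
#'
#' @param absences rows `patient_id`, `day`, `days`.
#' @param patients patients register (`age`, `labour_participant`).
#' @param t a [tariff()] with `wage_by_age_band` (SEK/month) and
#'   `social_contribution_rate`.
#' @param horizon_days records at/after this day are rejected.
#' @return data.frame `patient_id`, `year`, `amount` (SEK).
#' @export
productivity_loss <- function(absences, patients, t, horizon_days = 730L) {
  if (!nrow(absences))
    return(data.frame(patient_id = integer(), year = integer(),
                      amount = numeric()))
  if (any(absences$day < 0 | absences$day >= horizon_days))
    abort("absence record outside study horizon")
  i <- match(absences$patient_id, patients$patient_id)
  if (anyNA(i)) abort("absence for unknown patient")
  band <- wage_band(patients$age[i])
  monthly <- t$wage_by_age_band[band]
  if (anyNA(monthly)) abort("age band not resolvable against wage table")
  daily <- monthly / t$days_per_month
  amount <- absences$days * daily * (1 + t$social_contribution_rate) *
    patients$labour_participant[i]
  dt <- data.table::data.table(patient_id = absences$patient_id,
                               year = study_year(absences$day),
                               amount = unname(amount))
  out <- dt[, list(amount = sum(amount)), by = c("patient_id", "year")]
  as.data.frame(out[order(patient_id, year)])
}

wage_band <- function(age) {
  cut(age, c(-Inf, 25, 35, 45, 55, 65, Inf),
      labels = c("16-24", "25-34", "35-44", "45-54", "55-64", "65plus"),
      right = FALSE)
}

#' Assemble per-patient cost bundles
#'
#' Prices every care event exactly once, adds drug, productivity-loss,
#' intervention-delivery and co-payment streams, splits amounts into study
#' years (events belong to the year of their start day) and computes
#' discounted totals per perspective: societal = healthcare + drugs +
#' productivity loss + intervention delivery; payer = healthcare + drugs;
#' patient = out-of-pocket co-payments. Year-2 amounts enter discounted
#' totals divided by `1 + discount_rate_costs`.
#'
#' @param registers a `cea_registers` bundle.
#' @param t a [tariff()].
#' @param rules a [copay_rules()] (for the patient perspective); `NULL`
#'   omits the patient perspective.
#' @param discount_rate_costs annual discount rate for year-2 costs.
#' @return data.frame of class `cea_cost_bundles`: one row per patient,
#'   columns `<component>_y1`, `<component>_y2` in SEK plus
#'   `societal_total_discounted`, `payer_total_discounted`,
#'   `patient_total_discounted`.
#' @export
cost_bundles <- function(registers, t = tariff(), rules = copay_rules(),
                         discount_rate_costs = 0.03) {
  ev <- registers$care_events
  prim <- ev[ev$stream == "primary", , drop = FALSE]
  drg <- ev[ev$stream != "primary", , drop = FALSE]
  priced <- rbind(
    data.frame(patient_id = prim$patient_id,
               component = "primary_care", year = study_year(prim$day),
               amount = price_primary_event(prim, t)),
    data.frame(patient_id = drg$patient_id,
               component = ifelse(drg$stream == "inpatient", "inpatient",
                           ifelse(drg$stream == "polyclinical",
                                  "polyclinical", "specialised_outpatient")),
               year = study_year(drg$day),
               amount = price_drg_event(drg, t)))

  drugs <- price_drugs(registers$dispensations)
  if (nrow(drugs))
    priced <- rbind(priced, data.frame(patient_id = drugs$patient_id,
                                       component = "prescription_drugs",
                                       year = drugs$year,
                                       amount = drugs$amount))
  prod <- productivity_loss(registers$absences, registers$patients, t,
                            horizon_days =
                              registers$design$horizon_days %||% 730L)
  if (nrow(prod))
    priced <- rbind(priced, data.frame(patient_id = prod$patient_id,
                                       component = "productivity_loss",
                                       year = prod$year,
                                       amount = prod$amount))
  interv <- price_intervention(registers$intervention_log, t,
                               registers$patients)$per_patient
  if (nrow(interv))
    priced <- rbind(priced, data.frame(patient_id = interv$patient_id,
                                       component = "intervention_delivery",
                                       year = interv$year,
                                       amount = interv$amount))
  assemble_bundle(priced, registers, rules, discount_rate_costs)
}

COST_COMPONENTS <- c("primary_care", "inpatient", "specialised_outpatient",
                     "polyclinical", "prescription_drugs",
                     "productivity_loss", "intervention_delivery")
HEALTHCARE_COMPONENTS <- c("primary_care", "inpatient",
                           "specialised_outpatient", "polyclinical")

#' @rdname cost_bundles
#' @param priced long table of priced items (`patient_id`, `component`,
#'   `year` in \{1,2\}, `amount`); every resource-use event must appear
#'   exactly once.
#' @export
assemble_bundle <- function(priced, registers, rules = copay_rules(),
                            discount_rate_costs = 0.03) {
  if (nrow(priced) && any(!priced$year %in% c(1L, 2L)))
    abort("priced item assigned to no valid study year")
  ids <- registers$patients$patient_id
  wide <- matrix(0, length(ids), 2L * length(COST_COMPONENTS),
                 dimnames = list(NULL, paste0(
                   rep(COST_COMPONENTS, each = 2L), c("_y1", "_y2"))))
  if (nrow(priced)) {
    ri <- match(priced$patient_id, ids)
    if (anyNA(ri)) abort("priced item for unknown patient")
    ci <- match(paste0(priced$component, "_y", priced$year),
                colnames(wide))
    if (anyNA(ci)) abort("unknown cost component")
    agg <- rowsum(priced$amount, group = (ci - 1L) * length(ids) + ri)
    cell <- as.integer(rownames(agg))
    wide[cbind((cell - 1L) %% length(ids) + 1L,
               (cell - 1L) %/% length(ids) + 1L)] <- agg[, 1L]
  }
  out <- data.frame(patient_id = ids, wide, check.names = FALSE)
  disc <- 1 / (1 + discount_rate_costs)
  comp_total <- function(components) {
    y1 <- rowSums(out[, paste0(components, "_y1"), drop = FALSE])
    y2 <- rowSums(out[, paste0(components, "_y2"), drop = FALSE])
    y1 + y2 * disc
  }
  out$payer_total_discounted <-
    comp_total(c(HEALTHCARE_COMPONENTS, "prescription_drugs"))
  out$societal_total_discounted <- comp_total(COST_COMPONENTS)
  if (!is.null(rules)) {
    led <- copay_ledger(registers, rules)
    cp <- led$per_patient_year
    cpm <- matrix(0, length(ids), 2L)
    if (nrow(cp)) {
      ri <- match(cp$patient_id, ids)
      cpm[cbind(ri, cp$year)] <- cp$total
    }
    out$copay_y1 <- cpm[, 1L]; out$copay_y2 <- cpm[, 2L]
    out$patient_total_discounted <- cpm[, 1L] + cpm[, 2L] * disc
  }
  structure(out, class = c("cea_cost_bundles", "data.frame"),
            discount_rate_costs = discount_rate_costs)
}
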