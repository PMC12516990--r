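#' Co-payment rules: regional patient fees and ceilings
#'
#' Encodes the high-cost protection rules the pipeline simulates: an
#' annual SEK 1150 ceiling over all publicly provided outpatient
#' encounters, SEK 100 per hospital night capped at SEK 1500 per 30-day
#' consecutive window, a SEK 100 surcharge on primary-care home visits,
#' and an annual SEK 2350 cap on drug-benefit co-payments. Reimbursement
#' periods are assumed to start at randomisation (day 0), so the annual
#' ceilings reset at day 365. Template per-contact fees are placeholders
#' (the regional fee schedule is not reproduced); indirect (telephone)
#' contacts carry no fee.
#'
#' @param ... overrides of any default field.
#' @return object of class `cea_copay_rules`.
#' @export
copay_rules <- function(...) {
  r <- list(
    outpatient_fee_by_type = c(primary = 100, specialised_outpatient = 300,
                               polyclinical = 300, indirect = 0),
    outpatient_annual_ceiling = 1150,
    inpatient_fee_per_night = 100,
    inpatient_window_ceiling = 1500,
    inpatient_window_days = 30L,
    home_visit_surcharge = 100,
    drug_annual_ceiling = 2350,
    reimbursement_period_start = 0L,
    period_days = 365L)
  over <- list(...)
  unknown <- setdiff(names(over), names(r))
  if (length(unknown))
    abort("unknown copay rule(s): %s", paste(unknown, collapse = ", "))
  r[names(over)] <- over
  if (r$inpatient_window_days <= 0) abort("window_days must be > 0")
  if (r$outpatient_annual_ceiling < max(r$outpatient_fee_by_type) ||
      r$inpatient_window_ceiling < r$inpatient_fee_per_night)
    abort("ceilings must be at least the single fee")
  structure(r, class = "cea_copay_rules")
}

copay_period <- function(day, rules) {
  (day - rules$reimbursement_period_start) %/% rules$period_days
}

#' Charge outpatient contacts against the annual ceiling
#'
#' Each contact is charged `min(template fee + home surcharge, remaining
#' ceiling balance)` within its reimbursement period; the balance resets
#' every 365 days from the period start.
#'
#' @param events one patient's outpatient contacts sorted by `day`, with
#'   `stream` (fee key; primary indirect contacts use the `indirect` fee)
#'   and `visit_form`.
#' @param rules a [copay_rules()].
#' @return data.frame ledger: `day`, `fee`, `charged`, `period`,
#'   `balance_after` (cumulative charge within the period).
#' @export
charge_outpatient <- function(events, rules = copay_rules()) {
  if (!nrow(events))
    return(data.frame(day = integer(), fee = numeric(),
                      charged = numeric(), period = integer(),
                      balance_after = numeric()))
  if (is.unsorted(events$day)) abort("events must be sorted by day")
  key <- ifelse(events$stream == "primary" &
                  !is.na(events$visit_form) &
                  events$visit_form == "indirect",
                "indirect", events$stream)
  fee <- rules$outpatient_fee_by_type[key]
  if (anyNA(fee))
    abort("no template fee for contact type(s): %s",
          paste(unique(key[is.na(fee)]), collapse = ", "))
  fee <- unname(fee) +
    rules$home_visit_surcharge * (events$stream == "primary" &
                                    !is.na(events$visit_form) &
                                    events$visit_form == "home")
  period <- copay_period(events$day, rules)
  charged <- numeric(length(fee)); bal <- numeric(length(fee))
  paid <- 0; cur <- period[1L]
  for (i in seq_along(fee)) {
    if (period[i] != cur) { cur <- period[i]; paid <- 0 }
    charged[i] <- min(fee[i], rules$outpatient_annual_ceiling - paid)
    paid <- paid + charged[i]
    bal[i] <- paid
  }
  data.frame(day = events$day, fee = fee, charged = charged,
             period = period, balance_after = bal)
}

#' Charge inpatient nights against the 30-day window ceiling
#'
#' Each night costs the per-night fee unless the active window's charges
#' have reached the window ceiling. A window opens at the first charged
#' night not covered by an open window and spans `inpatient_window_days`
#' consecutive calendar days.
#'
#' @param episodes one patient's admissions: `day` (admission) and
#'   `nights` (non-negative); night k of an episode falls on calendar day
#'   `day + k - 1`.
#' @param rules a [copay_rules()].
#' @return data.frame ledger: one row per night with `night_day`,
#'   `charged`, `window_start`.
#' @export
charge_inpatient <- function(episodes, rules = copay_rules()) {
  if (!nrow(episodes))
    return(data.frame(night_day = integer(), charged = numeric(),
                      window_start = integer()))
  if (any(episodes$nights < 0)) abort("negative nights")
  nights <- sort(unlist(mapply(
    function(d, k) if (k > 0) d + seq_len(k) - 1L else integer(0),
    episodes$day, episodes$nights, SIMPLIFY = FALSE)))
  if (!length(nights))
    return(data.frame(night_day = integer(), charged = numeric(),
                      window_start = integer()))
  charged <- numeric(length(nights))
  win_start <- rep(NA_integer_, length(nights))
  ws <- -Inf; wpaid <- 0
  for (i in seq_along(nights)) {
    d <- nights[i]
    if (d >= ws + rules$inpatient_window_days) { ws <- d; wpaid <- 0 }
    charged[i] <- min(rules$inpatient_fee_per_night,
                      rules$inpatient_window_ceiling - wpaid)
    wpaid <- wpaid + charged[i]
    win_start[i] <- ws
  }
  data.frame(night_day = nights, charged = charged,
             window_start = win_start)
}

#' Charge drug dispensations against the annual benefit cap
#'
#' The patient pays the dispensation's patient-payable amount until the
#' cumulative payment within the reimbursement year reaches the cap;
#' further dispensations that year are free (the graded benefit steps are
#' deliberately not modelled, only the cap).
#'
#' @param dispensations one patient's rows sorted by `day` with
#'   `patient_payable`.
#' @param rules a [copay_rules()].
#' @return data.frame ledger: `day`, `payable`, `charged`, `period`.
#' @export
charge_drugs <- function(dispensations, rules = copay_rules()) {
  if (!nrow(dispensations))
    return(data.frame(day = integer(), payable = numeric(),
                      charged = numeric(), period = integer()))
  if (is.unsorted(dispensations$day)) abort("events must be sorted by day")
  if (any(dispensations$patient_payable < 0))
    abort("patient-payable amounts must be >= 0")
  period <- copay_period(dispensations$day, rules)
  payable <- dispensations$patient_payable
  charged <- numeric(length(payable))
  paid <- 0; cur <- period[1L]
  for (i in seq_along(payable)) {
    if (period[i] != cur) { cur <- period[i]; paid <- 0 }
    charged[i] <- min(payable[i], rules$drug_annual_ceiling - paid)
    paid <- paid + charged[i]
  }
  data.frame(day = dispensations$day, payable = payable,
             charged = charged, period = period)
}

#' Full co-payment ledger for a register bundle
#'
#' Runs the three ceiling engines per patient and aggregates charged
#' amounts by patient and study year.
#'
#' @param registers a `cea_registers` bundle.
#' @param rules a [copay_rules()].
#' @return list `per_patient_year` (data.frame `patient_id`, `year`,
#'   `outpatient`, `inpatient`, `drugs`, `total`) and `audit` (per-event
#'   ledgers by patient).
#' @export
copay_ledger <- function(registers, rules = copay_rules()) {
  ids <- registers$patients$patient_id
  ev <- registers$care_events
  out_ev <- ev[ev$stream %in% c("primary", "specialised_outpatient",
                                "polyclinical"), , drop = FALSE]
  inp <- ev[ev$stream == "inpatient", , drop = FALSE]
  disp <- registers$dispensations
  fid <- function(df) factor(df$patient_id, levels = ids)
  out_by <- split(out_ev[order(out_ev$day), , drop = FALSE],
                  fid(out_ev[order(out_ev$day), , drop = FALSE]))
  inp_by <- split(inp, fid(inp))
  dsp_by <- split(disp[order(disp$day), , drop = FALSE],
                  fid(disp[order(disp$day), , drop = FALSE]))
  rows <- list(); audit <- list()
  for (id in ids) {
    key <- as.character(id)
    lo <- charge_outpatient(out_by[[key]], rules)
    li <- charge_inpatient(inp_by[[key]], rules)
    ld <- charge_drugs(dsp_by[[key]], rules)
    yr_sum <- function(day, x) c(sum(x[study_year(day) == 1L]),
                                 sum(x[study_year(day) == 2L]))
    oy <- yr_sum(lo$day, lo$charged)
    iy <- yr_sum(li$night_day, li$charged)
    dy <- yr_sum(ld$day, ld$charged)
    rows[[as.character(id)]] <- data.frame(
      patient_id = id, year = 1:2, outpatient = oy, inpatient = iy,
      drugs = dy, total = oy + iy + dy)
    audit[[as.character(id)]] <- list(outpatient = lo, inpatient = li,
                                      drugs = ld)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(per_patient_year = per, audit = audit)
}

#' Per-arm, per-year mean co-payments (patient perspective)
#'
#' Arithmetic means over all randomised patients in the arm: deceased
#' patients contribute their charges and stay in the denominator
#' (intention-to-treat symmetry); set `living_only = TRUE` to restrict
#' the denominator to patients alive at the start of each year.
#'
#' @param ledger result of [copay_ledger()].
#' @param patients patients register.
#' @param living_only denominator switch (default FALSE).
#' @return data.frame `arm`, `year`, `mean_copay`, `n`.
#' @export
patient_perspective_totals <- function(ledger, patients,
                                       living_only = FALSE) {
  per <- ledger$per_patient_year
  out <- list()
  for (a in c("control", "intervention")) {
    ids <- patients$patient_id[patients$arm == a]
    if (!length(ids)) abort("empty arm: %s", a)
    for (y in 1:2) {
      den <- ids
      if (living_only) {
        dd <- patients$death_day[match(ids, patients$patient_id)]
        den <- ids[is.na(dd) | dd >= (y - 1L) * 365L]
      }
      x <- per$total[per$patient_id %in% den & per$year == y]
      tot <- sum(x)
      out[[paste(a, y)]] <- data.frame(
        arm = a, year = y, mean_copay = tot / length(den),
        n = length(den))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
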