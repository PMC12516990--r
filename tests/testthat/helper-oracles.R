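# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# engines) so they can arbitrate correctness.

# day-by-day outpatient ceiling simulator: walks the calendar, resets the
# balance at each period boundary, charges events in input order
oracle_outpatient <- function(day, fee, ceiling, period_days = 365L) {
  charged <- numeric(length(day))
  if (!length(day)) return(charged)
  paid <- 0
  current_period <- -1L
  for (i in seq_along(day)) {
    p <- day[i] %/% period_days
    if (p != current_period) {
      paid <- 0
      current_period <- p
    }
    room <- ceiling - paid
    charged[i] <- if (fee[i] <= room) fee[i] else room
    paid <- paid + charged[i]
  }
  charged
}

# day-by-day inpatient window simulator over an explicit calendar grid
oracle_inpatient <- function(night_days, fee = 100, cap = 1500,
                             window = 30L) {
  night_days <- sort(night_days)
  total <- 0
  window_end <- -1L   # last day covered by the open window
  window_paid <- 0
  for (d in night_days) {
    if (d > window_end) {          # night not covered: open a new window
      window_end <- d + window - 1L
      window_paid <- 0
    }
    charge <- min(fee, cap - window_paid)
    window_paid <- window_paid + charge
    total <- total + charge
  }
  total
}

# per-period drug cap simulator
oracle_drugs <- function(day, payable, cap = 2350, period_days = 365L) {
  charged <- numeric(length(day))
  if (!length(day)) return(charged)
  paid_by_period <- list()
  for (i in seq_along(day)) {
    p <- as.character(day[i] %/% period_days)
    paid <- paid_by_period[[p]]
    if (is.null(paid)) paid <- 0
    charged[i] <- min(payable[i], cap - paid)
    paid_by_period[[p]] <- paid + charged[i]
  }
  charged
}

# exact Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# analytic mean of the discretised, truncated utility at one visit:
# latent ~ N(mu, sd), truncated to [-0.594, 1], mapped to the nearest
# unique weight of the value set
oracle_discretised_mean <- function(mu, sd, vs) {
  u <- sort(unique(vs$utility))
  mids <- (head(u, -1) + tail(u, -1)) / 2
  edges <- c(-Inf, mids, Inf)
  p <- diff(pnorm(edges, mu, sd))
  sum(p * u)
}

# analytic between-arm QALY gap for the linear-trajectory generator on the
# default 0/3/6/12/24-month schedule (trapezoid weights hand-derived:
# year 1 month-weights 1.5/3/4.5/3 on visits 0/3/6/12, year 2 6/6 on
# 12/24, each divided by 12 to convert months to years)
oracle_qaly_gap <- function(params, discount_effects = 0.03) {
  sd <- sqrt(params$baseline_utility_sd^2 + params$utility_noise_sd^2)
  vs <- params$value_set
  mu_at <- function(slope, t_months)
    params$baseline_utility_mean + slope * t_months / 12
  s_c <- params$control_utility_slope
  s_i <- s_c + params$arm_utility_slope_diff
  gap <- vapply(c(0, 3, 6, 12, 24), function(t)
    oracle_discretised_mean(mu_at(s_i, t), sd, vs) -
      oracle_discretised_mean(mu_at(s_c, t), sd, vs), numeric(1))
  w1 <- c(1.5, 3, 4.5, 3, 0) / 12
  w2 <- c(0, 0, 0, 6, 6) / 12
  sum(w1 * gap) + sum(w2 * gap) / (1 + discount_effects)
}

# tiny register bundle built by hand (no generator) for unit tests
tiny_registers <- function() {
  patients <- data.frame(
    patient_id = 1:4,
    arm = c("intervention", "control", "intervention", "control"),
    age = c(55, 70, 64.9, 80), age_band = c("under65", "65plus",
                                            "under65", "65plus"),
    sex = c("female", "male", "female", "male"),
    diagnosis = c("CHF", "COPD", "both", "CHF"),
    living_alone = c(TRUE, FALSE, FALSE, TRUE),
    labour_participant = c(TRUE, FALSE, TRUE, FALSE),
    death_day = c(NA, NA, NA, 400),
    pp_eligible = c(TRUE, FALSE, FALSE, FALSE))
  structure(list(
    patients = patients,
    eq5d = data.frame(patient_id = rep(1:4, each = 2),
                      visit_month = rep(c(0, 3), 4),
                      mobility = 1L, self_care = 1L,
                      usual_activities = 1L, pain_discomfort = 2L,
                      anxiety_depression = 1L),
    care_events = data.frame(
      patient_id = c(1, 1, 2, 3, 4),
      day = c(10, 400, 20, 30, 40),
      stream = c("primary", "inpatient", "specialised_outpatient",
                 "primary", "polyclinical"),
      visit_form = c("physician", NA, NA, "home", NA),
      drg_weight = c(NA, 1.2, NA, NA, 0.5),
      nights = c(0L, 3L, 0L, 0L, 0L)),
    dispensations = data.frame(patient_id = c(1, 2), day = c(5, 380),
                               cost_ex_tax = c(120.5, 79.5),
                               patient_payable = c(60, 40)),
    absences = data.frame(patient_id = 1, day = 50, days = 10),
    intervention_log = data.frame(patient_id = c(1, 3), day = c(7, 8),
                                  activity = c("call", "documentation"),
                                  minutes = c(60, 30)),
    deaths = data.frame(patient_id = 4, death_day = 400),
    design = trial_design(n_per_arm = 2, seed = 1)),
    class = "cea_registers")
}

# complete utility table with a known linear trajectory, for MI tests
make_utility_cohort <- function(n, seed, slope = -0.02, base_mean = 0.8,
                                base_sd = 0.1, noise_sd = 0.05,
                                schedule = c(0, 3, 6, 12, 24)) {
  set.seed(seed)
  b <- rnorm(n, base_mean, base_sd)
  long <- do.call(rbind, lapply(schedule, function(s)
    data.frame(patient_id = seq_len(n), visit_month = s,
               utility = b + slope * s / 12 + rnorm(n, 0, noise_sd))))
  covars <- data.frame(patient_id = seq_len(n),
                       arm = rep(c("intervention", "control"),
                                 length.out = n),
                       age = round(runif(n, 50, 90)))
  list(util = long[order(long$patient_id, long$visit_month), ],
       covars = covars, schedule = schedule)
}
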