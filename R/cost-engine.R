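## Cost equations: per-mode travel costs, time costs with the
## parking/service penalty, INR-management time cost, drug-cost payer
## splits, the patient fee schedule with the annual payment ceiling, and
## per-day cost composition for both payers.
##
## Naming note: the source price list overloads symbols (c_x is both the
## taxi travel cost and the daily drug cost; c_t both the hourly time value
## and the travelling time cost). This module uses one name per concept:
## taxi cost, drug_daily, hourly value c_h, travel time cost.

#' Travel cost of a one-way leg
#'
#' Car costs `o_c * d`, taxi `f_t + o_t * d`, walking is free, bus pays the
#' distance-band fare, and ambulance journeys are only ever priced from a
#' reimbursement record. When a reimbursement record exists its
#' patient/society costs override the formula for the whole journey.
#'
#' @param mode Travel mode.
#' @param d One-way distance, km.
#' @param reimbursement Optional list/row with `patient_cost` and
#'   `society_cost` from a reimbursement record.
#' @param params [cost_parameters()].
#' @return `c(patient = , society = )` in EUR for the leg (or, with a
#'   record, for the recorded journey).
#' @examples
#' travel_cost("taxi", 10, params = cost_parameters())   # 5.9 + 1.59 * 10
#' @export
travel_cost <- function(mode, d, reimbursement = NULL,
                        params = cost_parameters()) {
  if (length(mode) != 1L || !mode %in% AF_MODES) {
    stop_af("mode must be one of car/taxi/walking/bus/ambulance", "af_mode_error")
  }
  check_number(d, "d", min = 0, len = 1L)
  if (!is.null(reimbursement)) {
    return(c(patient = as.numeric(reimbursement$patient_cost),
             society = as.numeric(reimbursement$society_cost)))
  }
  patient <- switch(mode,
    car = params$o_c * d,
    taxi = params$f_t + params$o_t * d,
    walking = 0,
    bus = bus_fare(d, params),
    ambulance = stop_af(
      "ambulance journeys are priced only from reimbursement records",
      "af_ambulance_error"))
  c(patient = patient, society = 0)
}

bus_fare <- function(d, params) {
  idx <- vapply(d, function(x) which(params$bus_fares$max_km >= x)[1L],
                integer(1))
  params$bus_fares$fare[idx]
}

#' Time cost of a one-way leg
#'
#' Values the travel time at the wage-coefficient-weighted hourly income.
#' Car and taxi legs add the parking/service time penalty `t_a` to the
#' travel time before valuation (the penalty is a time quantity; adding it
#' outside the product would add hours to euros). Walking, bus and
#' ambulance legs are valued on travel time alone.
#'
#' @param mode Travel mode.
#' @param t_j One-way travel time, hours (vectorised).
#' @param p_a Wage coefficient (1.0 or 0.35).
#' @param c_h Hourly time value, EUR/h.
#' @param params [cost_parameters()].
#' @return Time cost in EUR per leg.
#' @examples
#' time_cost_travel("car", 0.5, 0.35, 12)   # 0.35 * 12 * (0.5 + 0.083)
#' @export
time_cost_travel <- function(mode, t_j, p_a, c_h, params = cost_parameters()) {
  if (any(t_j < 0) || any(p_a < 0) || any(c_h < 0)) {
    stop_af("t_j, p_a and c_h must be non-negative", "af_validation_error")
  }
  mode <- rep_len(mode, max(length(mode), length(t_j)))
  if (!all(mode %in% AF_MODES)) {
    stop_af("unknown travel mode", "af_mode_error")
  }
  penalty <- ifelse(mode %in% c("car", "taxi"), params$t_a, 0)
  p_a * c_h * (t_j + penalty)
}

#' Time cost of INR monitoring
#'
#' Each monitoring visit costs the patient `t_m` hours valued at the
#' wage-coefficient-weighted hourly income: `m * c_h * p_a * t_m`.
#'
#' @param m Number of INR monitoring visits that day (non-negative integer).
#' @param p_a Wage coefficient.
#' @param c_h Hourly time value, EUR/h.
#' @param params [cost_parameters()].
#' @return Time cost in EUR.
#' @export
time_cost_monitoring <- function(m, p_a, c_h, params = cost_parameters()) {
  if (any(m < 0) || any(m != round(m))) {
    stop_af("m must be a non-negative integer count", "af_validation_error")
  }
  m * c_h * p_a * params$t_m
}

#' Daily drug cost split between patient and society
#'
#' Returns the configured daily retail price split. The split should agree
#' with the reimbursement rate (patient share = 1 - rate: 60% for warfarin's
#' basic 40% rate, 35% for the DOACs' lower special 65% rate);
#' [cost_parameters()] warns when the configured split deviates by more than
#' the tolerance.
#'
#' @param arm `"warfarin"` or `"doac"`.
#' @param params [cost_parameters()].
#' @return `c(patient = , society = )` in EUR/day.
#' @export
drug_daily_cost <- function(arm, params = cost_parameters()) {
  if (!arm %in% c("warfarin", "doac")) {
    stop_af("arm must be 'warfarin' or 'doac'", "af_validation_error")
  }
  params$drug_daily[[arm]]
}

## nominal (pre-ceiling) patient fee per contact
fee_schedule <- function(kind, home, params) {
  fifelse(kind == "primary_visit", params$primary_visit_fee,
  fifelse(kind == "specialised_visit", params$specialised_visit_fee,
  fifelse(kind == "emergency_visit", params$emergency_visit_fee,
  fifelse(kind %in% WARD_KINDS, params$ward_day_fee,
  fifelse(kind == "inr" & home, params$home_inr_patient_fee, 0)))))
}

#' Patient fee for one contact under the payment ceiling
#'
#' Charges the nominal fee for the contact kind, capped by the annual
#' payment ceiling on cumulative patient fees: the part exceeding the
#' ceiling is rerouted to public healthcare expenditure. The ceiling state
#' must be advanced in date order.
#'
#' @param contact A list/row with `kind`, `date` and optionally `home`
#'   (home INR measurement).
#' @param ceiling_state State from a previous call, or `NULL` to start a
#'   fresh year.
#' @param params [cost_parameters()].
#' @return A list with `fee_patient`, `overflow` (EUR rerouted to
#'   healthcare) and the advanced `state`.
#' @examples
#' st <- list(cumulative = 680, last_date = as.Date("2018-01-01"))
#' patient_fee(list(kind = "specialised_visit", date = as.Date("2018-02-01")),
#'             st)  # patient pays 3.0, healthcare absorbs 38.2
#' @export
patient_fee <- function(contact, ceiling_state = NULL,
                        params = cost_parameters()) {
  if (is.null(ceiling_state)) {
    ceiling_state <- list(cumulative = 0, last_date = as.Date("1900-01-01"))
  }
  if (!is.null(contact$date) &&
      as.Date(contact$date) < ceiling_state$last_date) {
    stop_af("contacts must be fee-processed in date order (ceiling is order-dependent)",
            "af_order_error")
  }
  home <- isTRUE(contact$home)
  nominal <- fee_schedule(contact$kind, home, params)
  room <- max(params$payment_ceiling - ceiling_state$cumulative, 0)
  fee_patient <- min(nominal, room)
  overflow <- nominal - fee_patient
  list(fee_patient = fee_patient, overflow = overflow,
       state = list(cumulative = ceiling_state$cumulative + fee_patient,
                    last_date = if (is.null(contact$date))
                      ceiling_state$last_date else as.Date(contact$date)))
}

#' Apply the fee schedule and payment ceiling to a contact table
#'
#' Adds `fee_patient` and `fee_overflow` columns, processing each patient's
#' contacts in date order against the annual ceiling.
#'
#' @param contacts Contact table.
#' @param params [cost_parameters()].
#' @return The contact table with fee columns added.
#' @export
process_fees <- function(contacts, params = cost_parameters()) {
  contacts <- as.data.table(contacts)
  if (nrow(contacts) == 0L) {
    contacts[, `:=`(fee_patient = numeric(0), fee_overflow = numeric(0))]
    return(contacts)
  }
  if (!"home" %in% names(contacts)) contacts[, home := FALSE]
  setorder(contacts, patient_id, date, id)
  contacts[, nominal := fee_schedule(kind, home, params)]
  contacts[, fee_patient := {
    before <- cumsum(nominal) - nominal
    pmin(nominal, pmax(params$payment_ceiling - before, 0))
  }, by = patient_id]
  contacts[, fee_overflow := nominal - fee_patient]
  contacts[, nominal := NULL]
  contacts[]
}

#' Compose one patient-day cost record
#'
#' Combines the day's INR monitoring time cost, direct therapy cost (daily
#' drug price plus ceiling-processed fees), travelling time cost and travel
#' cost into the patient-side daily total, and the day's healthcare-side
#' components (visit/ward accounting costs, society drug cost, society
#' travel reimbursement, INR monitoring cost, fee overflow, phone and
#' home-INR service costs) into the healthcare daily total.
#'
#' @param patient One-row patient (list or `data.table` row) with `arm`,
#'   `hourly_income` and `wage_coef`.
#' @param journeys Resolved journeys of that patient-day (possibly empty).
#' @param contacts Fee-processed contacts of that patient-day (possibly
#'   empty); must carry `fee_patient`/`fee_overflow` (see [process_fees()]).
#' @param reimbursements Reimbursement records of that patient-day.
#' @param params [cost_parameters()].
#' @param date The day (required when both tables are empty).
#' @return A one-row `data.table`: `c_m`, `c_a`, `c_t`, `c_d`,
#'   `c_p = c_m + c_a + c_t + c_d`, the healthcare components `e_p`, `e_s`,
#'   `w_p`, `w_s`, `d_h`, `k`, `inr_cost`, `other_society` and
#'   `healthcare_total`, plus bookkeeping columns.
#' @export
compose_daily <- function(patient, journeys = NULL, contacts = NULL,
                          reimbursements = NULL, params = cost_parameters(),
                          date = NULL) {
  journeys <- if (is.null(journeys)) data.table() else as.data.table(journeys)
  contacts <- if (is.null(contacts)) data.table() else as.data.table(contacts)
  reimb <- if (is.null(reimbursements)) data.table() else
    as.data.table(reimbursements)
  pid <- patient$id %||% NA_integer_
  dates <- c(if (nrow(journeys)) unique(journeys$date),
             if (nrow(contacts)) unique(contacts$date))
  pids <- c(if (nrow(journeys)) unique(journeys$patient_id),
            if (nrow(contacts)) unique(contacts$patient_id))
  if (length(unique(dates)) > 1L || length(unique(pids)) > 1L ||
      (length(pids) > 0L && !is.na(pid) && any(pids != pid))) {
    stop_af("journeys and contacts must share one patient and one date",
            "af_validation_error")
  }
  if (is.null(date)) date <- if (length(dates)) as.Date(dates[1L]) else NA
  if (nrow(contacts) > 0L && !"fee_patient" %in% names(contacts)) {
    stop_af("contacts lack fee columns; run process_fees() first",
            "af_validation_error")
  }

  dd <- drug_daily_cost(patient$arm, params)
  m <- if (nrow(contacts)) sum(contacts$kind == "inr") else 0L
  c_m <- time_cost_monitoring(m, patient$wage_coef, patient$hourly_income,
                              params)
  fees <- if (nrow(contacts)) sum(contacts$fee_patient) else 0
  overflow <- if (nrow(contacts)) sum(contacts$fee_overflow) else 0
  c_a <- dd[["patient"]] + fees

  c_t <- 0; c_d <- 0
  if (nrow(journeys) > 0L) {
    leg_time <- time_cost_travel(journeys$mode, journeys$travel_time_h,
                                 patient$wage_coef, patient$hourly_income,
                                 params)
    c_t <- sum(journeys$legs * leg_time)
    free <- journeys[from_reimbursement == FALSE]
    if (nrow(free) > 0L) {
      c_d <- sum(vapply(seq_len(nrow(free)), function(i) {
        free$legs[i] *
          travel_cost(free$mode[i], free$distance_km[i], NULL, params)[["patient"]]
      }, numeric(1)))
    }
  }
  k <- 0
  if (nrow(reimb) > 0L) {
    c_d <- c_d + sum(reimb$patient_cost)
    k <- sum(reimb$society_cost)
  }

  sum_cost <- function(kinds) {
    if (!nrow(contacts)) 0 else
      sum(contacts$healthcare_unit_cost[contacts$kind %in% kinds &
                                          contacts$kind != "phone"])
  }
  e_p <- sum_cost("primary_visit")
  e_s <- sum_cost(c("specialised_visit", "emergency_visit"))
  w_p <- sum_cost("primary_ward_day")
  w_s <- sum_cost("specialised_ward_day")
  phone_cost <- if (nrow(contacts))
    sum(contacts$healthcare_unit_cost[contacts$kind == "phone"]) else 0
  home_extra <- if (nrow(contacts))
    sum(contacts$kind == "inr" & (contacts$home %in% TRUE)) *
      params$home_inr_society_extra else 0
  inr_cost <- m * params$inr_unit_cost
  other_society <- phone_cost + overflow + home_extra

  data.table(
    patient_id = pid, date = as.Date(date),
    n_inr = m, c_m = c_m, c_a = c_a, c_t = c_t, c_d = c_d,
    c_p = c_m + c_a + c_t + c_d,
    drug_patient = dd[["patient"]], fees_patient = fees,
    e_p = e_p, e_s = e_s, w_p = w_p, w_s = w_s,
    d_h = dd[["society"]], k = k, inr_cost = inr_cost,
    other_society = other_society,
    healthcare_total = e_p + e_s + w_p + w_s + dd[["society"]] + k +
      inr_cost + other_society)
}

#' Daily cost records for a whole cohort (vectorised)
#'
#' Batch equivalent of calling [compose_daily()] on every active patient-day
#' (a day with at least one contact, journey or reimbursement record).
#' Inactive days carry only drug costs and are added analytically at annual
#' aggregation (see [per_patient_annual()]), keeping the record table at
#' active-day size.
#'
#' @param patients Patient table (selected cohort).
#' @param contacts Filtered, fee-processed or raw contact table (fees are
#'   processed here if the fee columns are missing).
#' @param journeys Resolved journey table.
#' @param reimbursements Reimbursement-record table.
#' @param params [cost_parameters()].
#' @return A `data.table` of daily cost records (one row per active
#'   patient-day) with the columns of [compose_daily()].
#' @export
compute_daily_costs <- function(patients, contacts, journeys,
                                reimbursements = NULL,
                                params = cost_parameters()) {
  patients <- as.data.table(patients)
  contacts <- as.data.table(contacts)
  journeys <- as.data.table(journeys)
  reimb <- if (is.null(reimbursements)) data.table(
    patient_id = integer(0), date = as.Date(character(0)),
    patient_cost = numeric(0), society_cost = numeric(0)) else
    as.data.table(reimbursements)
  if (nrow(contacts) > 0L && !"fee_patient" %in% names(contacts)) {
    contacts <- process_fees(contacts, params)
  }
  reimb <- reimb[patient_id %in% patients$id]

  pday <- unique(rbind(
    if (nrow(contacts)) contacts[, .(patient_id, date)],
    if (nrow(journeys)) journeys[, .(patient_id, date)],
    if (nrow(reimb)) reimb[, .(patient_id, date)]))
  if (is.null(pday) || nrow(pday) == 0L) {
    return(compose_daily(list(arm = "warfarin", wage_coef = 1,
                              hourly_income = 0, id = NA_integer_),
                         params = params, date = NA)[0L])
  }

  cagg <- if (nrow(contacts)) contacts[, .(
    n_inr = sum(kind == "inr"),
    fees_patient = sum(fee_patient),
    overflow = sum(fee_overflow),
    e_p = sum(healthcare_unit_cost[kind == "primary_visit"]),
    e_s = sum(healthcare_unit_cost[kind %in% c("specialised_visit",
                                               "emergency_visit")]),
    w_p = sum(healthcare_unit_cost[kind == "primary_ward_day"]),
    w_s = sum(healthcare_unit_cost[kind == "specialised_ward_day"]),
    phone_cost = sum(healthcare_unit_cost[kind == "phone"]),
    home_extra = sum(kind == "inr" & (home %in% TRUE)) *
      params$home_inr_society_extra),
    by = .(patient_id, date)] else NULL

  jagg <- NULL
  if (nrow(journeys) > 0L) {
    jt <- merge(journeys,
                patients[, .(patient_id = id, wage_coef, hourly_income)],
                by = "patient_id", sort = FALSE)
    jt[, leg_time_cost := time_cost_travel(mode, travel_time_h, wage_coef,
                                           hourly_income, params)]
    jt[, leg_travel_cost := fifelse(
      from_reimbursement, 0,
      fifelse(mode == "car", params$o_c * distance_km,
      fifelse(mode == "taxi", params$f_t + params$o_t * distance_km,
      fifelse(mode == "bus", bus_fare(distance_km, params), 0))))]
    jagg <- jt[, .(c_t = sum(legs * leg_time_cost),
                   c_d_formula = sum(legs * leg_travel_cost)),
               by = .(patient_id, date)]
  }
  ragg <- if (nrow(reimb)) reimb[, .(reimb_patient = sum(patient_cost),
                                     k = sum(society_cost)),
                                 by = .(patient_id, date)] else NULL

  daily <- pday
  for (tab in list(cagg, jagg, ragg)) {
    if (!is.null(tab)) daily <- merge(daily, tab, by = c("patient_id", "date"),
                                      all.x = TRUE, sort = FALSE)
  }
  for (col in setdiff(names(daily), c("patient_id", "date"))) {
    set(daily, which(is.na(daily[[col]])), col, 0)
  }
  for (col in c("n_inr", "fees_patient", "overflow", "e_p", "e_s", "w_p",
                "w_s", "phone_cost", "home_extra", "c_t", "c_d_formula",
                "reimb_patient", "k")) {
    if (!col %in% names(daily)) daily[, (col) := 0]
  }
  daily <- merge(daily,
                 patients[, .(patient_id = id, arm, wage_coef, hourly_income)],
                 by = "patient_id", sort = FALSE)
  dp <- vapply(params$drug_daily, `[[`, numeric(1), "patient")
  ds <- vapply(params$drug_daily, `[[`, numeric(1), "society")
  daily[, `:=`(
    c_m = time_cost_monitoring(n_inr, wage_coef, hourly_income, params),
    drug_patient = dp[arm],
    d_h = ds[arm])]
  daily[, `:=`(
    c_a = drug_patient + fees_patient,
    c_d = c_d_formula + reimb_patient,
    inr_cost = n_inr * params$inr_unit_cost,
    other_society = phone_cost + overflow + home_extra)]
  daily[, c_p := c_m + c_a + c_t + c_d]
  daily[, healthcare_total := e_p + e_s + w_p + w_s + d_h + k + inr_cost +
          other_society]
  setorder(daily, patient_id, date)
  daily[, .(patient_id, date, n_inr, c_m, c_a, c_t, c_d, c_p, drug_patient,
            fees_patient, e_p, e_s, w_p, w_s, d_h, k, inr_cost, other_society,
            healthcare_total)]
}
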