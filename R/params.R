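#' Fixed cost-model parameters
#'
#' Bundles every fixed unit price and time constant of the cost model: the
#' INR monitoring time loss, the parking/service time penalty, per-kilometre
#' vehicle operating costs, taxi and bus fares, daily anticoagulant prices
#' for both payers, the patient fee schedule, the EUR 31 per-visit INR cost
#' borne by the healthcare service, and the EUR 683 annual payment ceiling on
#' patient fees. Defaults follow the Finnish 2017-2018 price level used
#' throughout the model.
#'
#' @param t_m Time loss per INR monitoring visit, hours.
#' @param t_a Parking time (car) or service time (taxi) penalty per leg, hours.
#' @param o_c Car operating cost, EUR/km.
#' @param o_t Taxi operating cost, EUR/km.
#' @param f_t Taxi fixed charge, EUR per leg.
#' @param bus_fares `data.frame` with columns `max_km` (ordered, last `Inf`)
#'   and `fare` (EUR); the fare of the first band whose `max_km` is >= the
#'   one-way distance applies per leg. The three default fares are fixed;
#'   the distance thresholds are a modelling choice.
#' @param drug_daily Named list `warfarin`/`doac`, each `c(patient=, society=)`
#'   daily drug cost in EUR. DOAC default is the apixaban-like price point
#'   (0.95 / 1.76); 1.00 / 1.87 is the alternative.
#' @param reimbursement_rate Named vector: Kela drug reimbursement rate by
#'   therapy (basic 40% for warfarin, lower special 65% for DOACs). Used only
#'   for the consistency check on `drug_daily`.
#' @param primary_visit_fee Patient fee for a primary healthcare visit, EUR
#'   (11.4 nurse / 20.6 physician; default physician).
#' @param specialised_visit_fee Patient fee for a specialised healthcare
#'   visit, EUR.
#' @param emergency_visit_fee Patient fee for an urgent emergency visit, EUR
#'   (charged at the specialised level).
#' @param ward_day_fee Patient fee per inpatient ward day (both care levels),
#'   EUR.
#' @param inr_unit_cost Healthcare cost per INR monitoring visit (blood test +
#'   personnel), EUR.
#' @param payment_ceiling Annual cap on ceiling-eligible patient fees, EUR.
#'   Fees beyond the cap shift to public healthcare expenditure.
#' @param home_inr_patient_fee Fixed home-care service fee charged to the
#'   patient for an INR measurement taken at home, EUR (local fee; not
#'   nationally fixed).
#' @param home_inr_society_extra Home-care visit cost borne by the healthcare
#'   service on top of `inr_unit_cost` for a home INR measurement, EUR.
#' @param wage_age_threshold Age (years) at which the hourly wage coefficient
#'   drops from 1.0 (working age) to 0.35 (retired).
#' @param drug_split_tolerance Allowed deviation between the configured
#'   patient share of the retail drug price and `1 - reimbursement_rate`
#'   before a warning is emitted.
#'
#' @return An object of class `af_cost_parameters` (a validated list).
#' @examples
#' p <- cost_parameters()
#' p$payment_ceiling
#' @export
cost_parameters <- function(t_m = 0.5,
                            t_a = 0.083,
                            o_c = 0.43,
                            o_t = 1.59,
                            f_t = 5.9,
                            bus_fares = data.frame(
                              max_km = c(15, 40, Inf),
                              fare = c(2.00, 3.80, 5.00)),
                            drug_daily = list(
                              warfarin = c(patient = 0.08, society = 0.05),
                              doac = c(patient = 0.95, society = 1.76)),
                            reimbursement_rate = c(warfarin = 0.40,
                                                   doac = 0.65),
                            primary_visit_fee = 20.6,
                            specialised_visit_fee = 41.2,
                            emergency_visit_fee = 41.2,
                            ward_day_fee = 48.9,
                            inr_unit_cost = 31,
                            payment_ceiling = 683,
                            home_inr_patient_fee = 12.0,
                            home_inr_society_extra = 45.0,
                            wage_age_threshold = 65,
                            drug_split_tolerance = 0.02) {
  p <- list(t_m = t_m, t_a = t_a, o_c = o_c, o_t = o_t, f_t = f_t,
            bus_fares = bus_fares, drug_daily = drug_daily,
            reimbursement_rate = reimbursement_rate,
            primary_visit_fee = primary_visit_fee,
            specialised_visit_fee = specialised_visit_fee,
            emergency_visit_fee = emergency_visit_fee,
            ward_day_fee = ward_day_fee,
            inr_unit_cost = inr_unit_cost,
            payment_ceiling = payment_ceiling,
            home_inr_patient_fee = home_inr_patient_fee,
            home_inr_society_extra = home_inr_society_extra,
            wage_age_threshold = wage_age_threshold,
            drug_split_tolerance = drug_split_tolerance)
  class(p) <- "af_cost_parameters"
  validate_cost_parameters(p)
}

validate_cost_parameters <- function(p) {
  for (f in c("t_m", "t_a", "o_c", "o_t", "f_t", "primary_visit_fee",
              "specialised_visit_fee", "emergency_visit_fee", "ward_day_fee",
              "inr_unit_cost", "payment_ceiling", "home_inr_patient_fee",
              "home_inr_society_extra", "wage_age_threshold")) {
    check_number(p[[f]], f, min = 0, len = 1L)
  }
  bf <- p$bus_fares
  if (!is.data.frame(bf) || !all(c("max_km", "fare") %in% names(bf)) ||
      nrow(bf) < 1L) {
    stop_af("field 'bus_fares' must be a data.frame(max_km, fare)",
            "af_validation_error")
  }
  if (is.unsorted(bf$max_km, strictly = TRUE) ||
      !is.infinite(bf$max_km[nrow(bf)])) {
    stop_af("field 'bus_fares' bands must be strictly increasing and end at Inf",
            "af_validation_error")
  }
  check_number(bf$fare, "bus_fares$fare", min = 0)
  for (a in c("warfarin", "doac")) {
    dd <- p$drug_daily[[a]]
    check_number(dd, paste0("drug_daily$", a), min = 0, len = 2L)
    if (!all(c("patient", "society") %in% names(dd))) {
      stop_af(sprintf("field 'drug_daily$%s' needs patient and society parts", a),
              "af_validation_error")
    }
    check_number(p$reimbursement_rate[[a]],
                 paste0("reimbursement_rate$", a), min = 0, max = 1, len = 1L)
    tot <- sum(dd)
    if (tot > 0) {
      share <- dd[["patient"]] / tot
      expected <- 1 - p$reimbursement_rate[[a]]
      if (abs(share - expected) > p$drug_split_tolerance) {
        warning(sprintf(
          "%s drug split: patient share %.3f deviates from 1 - reimbursement rate (%.3f) by more than %.2f",
          a, share, expected, p$drug_split_tolerance), call. = FALSE)
      }
    }
  }
  p
}

#' @export
print.af_cost_parameters <- function(x, ...) {
  cat("<af_cost_parameters>\n")
  cat(sprintf("  t_m %.3f h, t_a %.3f h, o_c %.2f EUR/km, o_t %.2f EUR/km, f_t %.2f EUR\n",
              x$t_m, x$t_a, x$o_c, x$o_t, x$f_t))
  cat(sprintf("  fees: primary %.1f, specialised %.1f, ward/day %.1f, ceiling %.0f EUR\n",
              x$primary_visit_fee, x$specialised_visit_fee, x$ward_day_fee,
              x$payment_ceiling))
  cat(sprintf("  drugs EUR/day: warfarin %.2f/%.2f, doac %.2f/%.2f (patient/society)\n",
              x$drug_daily$warfarin[["patient"]], x$drug_daily$warfarin[["society"]],
              x$drug_daily$doac[["patient"]], x$drug_daily$doac[["society"]]))
  invisible(x)
}

#' Read cost parameters from a YAML or JSON file
#'
#' Scalar fields override the defaults of [cost_parameters()]; `bus_fares`
#' may be given as a list of `{max_km, fare}` records and `drug_daily` as a
#' mapping of therapy to `{patient, society}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` parameter file.
#' @return An `af_cost_parameters` object.
#' @export
read_cost_parameters <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_af("the 'yaml' package is required to read YAML parameter files",
              "af_validation_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$bus_fares)) {
    bf <- as.data.frame(raw$bus_fares)
    bf$max_km[is.character(bf$max_km) | is.na(bf$max_km)] <- Inf
    bf$max_km <- as.numeric(bf$max_km)
    args$bus_fares <- bf
  }
  if (!is.null(raw$drug_daily)) {
    args$drug_daily <- lapply(raw$drug_daily, function(d) unlist(d))
  }
  do.call(cost_parameters, args)
}
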