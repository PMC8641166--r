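## Cohort selection (inclusion/attrition rules) and AF-contact filtering.

WARD_KINDS <- c("primary_ward_day", "specialised_ward_day")
AF_CONTACT_KINDS <- c("inr", "primary_visit", "specialised_visit",
                      "primary_ward_day", "specialised_ward_day", "phone",
                      "emergency_visit")

#' Hourly wage coefficient by age
#'
#' Lost working time of a working-age patient is valued at the full hourly
#' gross wage; the lost leisure time of a retired patient at 35% of it. The
#' boundary sits at 65 years (a 65-year-old counts as retired); the
#' threshold is configurable because price lists have printed it both ways.
#'
#' @param age Age in years (vectorised, >= 0).
#' @param threshold Retirement age boundary, default 65.
#' @return 1.0 below the threshold, 0.35 at or above it.
#' @examples
#' wage_coefficient(c(64, 65, 90))
#' @export
wage_coefficient <- function(age, threshold = 65) {
  if (!is.numeric(age) || anyNA(age) || any(age < 0)) {
    stop_af("age must be non-negative and non-missing", "af_validation_error")
  }
  ifelse(age < threshold, 1.0, 0.35)
}

#' Apply the study inclusion rules to a raw patient table
#'
#' Retains patients who are not in a nursing home, have an AF diagnosis
#' before the window start, reside in-district, are alive at the window end,
#' hold one continuous anticoagulant prescription covering the window plus
#' the 60 days before it, and never switch therapy in that span. Rules are
#' applied in that order and each exclusion is counted once, so the counts
#' plus the included total partition the input.
#'
#' @param patients Patient table (see [generate_cohort()]); single-interval
#'   prescriptions may be carried as `rx_drug`/`rx_start`/`rx_end` columns.
#' @param prescriptions Optional long prescriptions table
#'   (`patient_id`, `drug`, `start`, `end`) overriding the patient columns;
#'   needed to represent multi-interval or switching histories.
#' @param window Study window, default [af_study_window()].
#' @param gap_days Tolerated gap (days) between consecutive prescription
#'   intervals of the same drug before continuity is considered broken.
#'   Default 0 (the strictest reading of "continuous").
#' @return A list with `warfarin` and `doac` patient tables (disjoint) and
#'   `attrition`, a named vector of per-rule exclusion counts plus
#'   `included`.
#' @export
select_cohort <- function(patients, prescriptions = NULL,
                          window = af_study_window(), gap_days = 0) {
  patients <- as.data.table(patients)
  rules <- c("nursing_home", "no_prior_af_diagnosis", "out_of_district",
             "deceased", "no_continuous_prescription", "therapy_switch")
  attrition <- setNames(integer(length(rules)), rules)
  if (nrow(patients) == 0L) {
    return(list(warfarin = patients, doac = patients,
                attrition = c(attrition, included = 0L)))
  }
  if (is.null(prescriptions)) {
    if (!all(c("rx_drug", "rx_start", "rx_end") %in% names(patients))) {
      stop_af("need either a prescriptions table or rx_* patient columns",
              "af_validation_error")
    }
    prescriptions <- patients[, .(patient_id = id, drug = rx_drug,
                                  start = rx_start, end = rx_end)]
  }
  prescriptions <- as.data.table(prescriptions)

  span_start <- window$start - 60L
  span_end <- window$end
  rx <- prescriptions[end >= span_start & start <= span_end]

  ## contradictory data: overlapping prescriptions for different drug classes
  if (nrow(rx) > 1L) {
    setorder(rx, patient_id, start)
    bad <- rx[, {
      ok <- TRUE
      if (.N > 1L) {
        for (i in 2:.N) {
          if (start[i] <= end[i - 1L] && drug[i] != drug[i - 1L]) ok <- FALSE
        }
      }
      .(ok = ok)
    }, by = patient_id][ok == FALSE]
    if (nrow(bad) > 0L) {
      stop_af(sprintf(
        "overlapping contradictory prescriptions for patient(s) %s",
        paste(head(bad$patient_id, 5L), collapse = ", ")),
        "af_data_integrity_error")
    }
  }

  keep <- rep(TRUE, nrow(patients))
  drop_rule <- function(keep, flag, rule) {
    hit <- keep & flag
    attrition[rule] <<- sum(hit)
    keep & !flag
  }
  keep <- drop_rule(keep, isTRUE_vec(patients$nursing_home), "nursing_home")
  keep <- drop_rule(keep, !(patients$af_diagnosis_date < window$start),
                    "no_prior_af_diagnosis")
  keep <- drop_rule(keep, !isTRUE_vec(patients$in_district), "out_of_district")
  keep <- drop_rule(keep, !isTRUE_vec(patients$alive_at_end), "deceased")

  ## continuity: the union of anticoagulant intervals (any drug) must cover
  ## [start-60, end]; switching between covered drugs is rule 6's business
  cov <- rx[, .(covered = covers_span(start, end, span_start, span_end,
                                      gap_days),
                n_drugs = uniqueN(drug)), by = patient_id]
  covered <- patients$id %in% cov[covered == TRUE]$patient_id
  keep <- drop_rule(keep, !covered, "no_continuous_prescription")
  switched <- patients$id %in% cov[n_drugs > 1L]$patient_id
  keep <- drop_rule(keep, switched, "therapy_switch")

  sel <- patients[keep]
  drug_of <- rx[data.table(patient_id = sel$id), on = "patient_id",
                mult = "first"]$drug
  out <- list(warfarin = sel[drug_of == "warfarin"],
              doac = sel[drug_of == "doac"],
              attrition = c(attrition, included = sum(keep)))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

## does the union of prescription intervals (allowing gap_days between
## consecutive ones) cover [span_start, span_end]?
covers_span <- function(start, end, span_start, span_end, gap_days) {
  o <- order(start)
  s <- start[o]; e <- end[o]
  if (s[1L] > span_start) return(FALSE)
  reach <- e[1L]
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      if (as.numeric(s[i] - reach) > gap_days + 1) break
      reach <- max(reach, e[i])
    }
  }
  reach >= span_end
}

#' Filter contacts to AF-related events
#'
#' Keeps all INR monitorings and every contact whose primary diagnosis is AF
#' or gastrointestinal bleeding. Ischemic stroke and intracerebral
#' haemorrhage contacts are kept only when their episode (same patient and
#' diagnosis, dates within one day of each other) contains both an urgent
#' visit and at least one inpatient ward day. Everything else is dropped.
#' The filter is a pure function and idempotent.
#'
#' @param contacts Contact table.
#' @return The filtered contact table (same columns).
#' @export
filter_af_contacts <- function(contacts) {
  contacts <- as.data.table(contacts)
  if (nrow(contacts) == 0L) return(contacts)
  keep_basic <- contacts$diagnosis_class %in% c("af", "gi_bleed") |
    contacts$kind == "inr"
  strict <- contacts$diagnosis_class %in%
    c("ischemic_stroke", "intracerebral_haemorrhage") & !keep_basic
  keep <- keep_basic
  if (any(strict)) {
    ep <- contacts[strict, .(patient_id, diagnosis_class, date, kind, urgent)]
    ep[, row := which(strict)]
    setorder(ep, patient_id, diagnosis_class, date)
    ep[, gap := c(0, pmax(as.numeric(diff(date)), 0)),
       by = .(patient_id, diagnosis_class)]
    ep[, episode := cumsum(gap > 1), by = .(patient_id, diagnosis_class)]
    ep[, `:=`(has_urgent = any(urgent | kind == "emergency_visit"),
              has_ward = any(kind %in% WARD_KINDS)),
       by = .(patient_id, diagnosis_class, episode)]
    keep[ep$row] <- ep$has_urgent & ep$has_ward
  }
  contacts[keep]
}
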