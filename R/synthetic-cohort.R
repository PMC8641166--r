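#' Generate a synthetic two-arm anticoagulation cohort
#'
#' Draws patients for both therapy arms with the configured age, sex, income
#' and urban-residence structure. Home nodes are assigned by inverse-CDF
#' matching: each patient draws a target distance-to-laboratory from the
#' lognormal implied by the configured moments and is placed at the network
#' node whose nearest-laboratory distance is closest to it, coupling the
#' urban flag to the short-distance end of the same draw. Every patient
#' carries a single anticoagulant prescription interval and the selection
#' traits (`nursing_home`, `in_district`, `alive_at_end`) driven by the
#' optional attrition shares.
#'
#' @param config An [cohort_config()] object.
#' @param geo An [geography()] object from [generate_geography()].
#' @return A `data.table` of patients (one row each) with home node, nearest
#'   facility ids, hourly income `c_h`, wage coefficient `p_a`, prescription
#'   interval and selection traits.
#' @examples
#' geo <- generate_geography(geography_config(n_nodes = 60, n_labs = 3,
#'                                            n_health_centres = 2, seed = 2))
#' pats <- generate_cohort(cohort_config(n_warfarin = 20, n_doac = 5,
#'                                       seed = 2), geo)
#' table(pats$arm)
#' @export
generate_cohort <- function(config, geo) {
  stopifnot(inherits(config, "af_cohort_config"), inherits(geo, "af_geography"))
  validate_cohort_config(config)
  with_stream(config$seed, "cohort", build_cohort(config, geo))
}

build_cohort <- function(cfg, geo) {
  n <- cfg$n_warfarin + cfg$n_doac
  empty <- data.table(
    id = integer(0), arm = character(0), age = numeric(0), sex = character(0),
    home_node = integer(0), urban = logical(0), hourly_income = numeric(0),
    wage_coef = numeric(0), dist_lab_km = numeric(0),
    nearest_lab = integer(0), nearest_hc = integer(0), hospital = integer(0),
    af_diagnosis_date = as.Date(character(0)), nursing_home = logical(0),
    in_district = logical(0), alive_at_end = logical(0),
    rx_drug = character(0), rx_start = as.Date(character(0)),
    rx_end = as.Date(character(0)))
  if (n == 0L) return(empty)

  win <- af_study_window()
  arm <- rep(c("warfarin", "doac"), c(cfg$n_warfarin, cfg$n_doac))
  age <- pmax(18, rnorm(n, cfg$age_mean[arm], cfg$age_sd[arm]))
  sex <- ifelse(runif(n) < cfg$female_share[arm], "F", "M")
  income <- pmax(0.5, rnorm(n, cfg$income_mean[arm], cfg$income_sd[arm]))

  ## distance-to-lab draw; urban flag coupled to the short-distance tail
  lp <- lnorm_pars(attr(geo, "dist_lab_mean") %||% 5.5,
                   attr(geo, "dist_lab_sd") %||% 7.6)
  q <- runif(n)
  target_d <- qlnorm(q, lp$meanlog, lp$sdlog)
  urban <- q < cfg$urban_share[arm]

  nd <- geo$nodes$dist_lab_km
  ord <- order(nd)
  sorted <- nd[ord]
  pos <- findInterval(target_d, sorted, all.inside = TRUE)
  ## nearest of the two bracketing node distances
  use_upper <- (pos < length(sorted)) &
    (abs(sorted[pmin(pos + 1L, length(sorted))] - target_d) <
       abs(sorted[pos] - target_d))
  pos <- pos + as.integer(use_upper)
  home_idx <- ord[pos]

  hosp <- geo$facilities[kind == "hospital"]$id[1L]
  patients <- data.table(
    id = seq_len(n), arm = arm, age = age, sex = sex,
    home_node = geo$nodes$id[home_idx], urban = urban,
    hourly_income = income,
    wage_coef = wage_coefficient(age),
    dist_lab_km = nd[home_idx],
    nearest_lab = geo$nodes$nearest_lab[home_idx],
    nearest_hc = geo$nodes$nearest_hc[home_idx],
    hospital = hosp,
    af_diagnosis_date = win$start - sample(30:3000, n, replace = TRUE),
    nursing_home = runif(n) < cfg$attrition$nursing_home,
    in_district = runif(n) >= cfg$attrition$out_of_district,
    alive_at_end = runif(n) >= cfg$attrition$deceased,
    rx_drug = arm,
    rx_start = win$start - 60L - sample(0:900, n, replace = TRUE),
    rx_end = win$end + sample(0:180, n, replace = TRUE))
  ## late starters fail the 60-day continuity rule
  late <- runif(n) < cfg$attrition$late_rx
  patients[late, rx_start := win$start - sample(0:59, sum(late), replace = TRUE)]
  ## switchers: truncate the first prescription mid-window (the other drug's
  ## interval is added by callers needing an explicit prescriptions table)
  sw <- runif(n) < cfg$attrition$switch
  patients[sw, rx_end := win$start + sample(30:300, sum(sw), replace = TRUE)]
  patients[sw, rx_drug := arm[sw]]
  setattr(patients, "switch_flag", sw)
  patients[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate synthetic AF-related healthcare contacts
#'
#' Draws one year of dated contacts per patient: INR monitorings (evenly
#' spaced with jitter, the routine-monitoring pattern), primary and
#' specialised visits, phone consultations, inpatient ward stays (consecutive
#' dates) and urgent complication episodes, which always pair an urgent
#' emergency visit with at least one specialised ward day on consecutive
#' dates. A configurable share of non-AF noise contacts
#' (`diagnosis_class = "other"`) exercises the diagnosis filter downstream.
#'
#' @param patients Patient table from [generate_cohort()].
#' @param config The [cohort_config()] used to generate them.
#' @return A `data.table` of contacts with kind, date, diagnosis class,
#'   facility, urgency, home-INR flag and healthcare unit cost.
#' @export
generate_contacts <- function(patients, config) {
  stopifnot(inherits(config, "af_cohort_config"))
  validate_cohort_config(config)
  if (nrow(patients) > 0 && !all(patients$arm %in% c("warfarin", "doac"))) {
    stop_af("patient arm must be 'warfarin' or 'doac'", "af_validation_error")
  }
  with_stream(config$seed, "contacts", build_contacts(patients, config))
}

## expand per-patient counts into dated rows
expand_counts <- function(patients, counts, dater) {
  idx <- rep(seq_len(nrow(patients)), counts)
  if (length(idx) == 0L) return(NULL)
  data.table(patient_id = patients$id[idx],
             arm = patients$arm[idx],
             day = dater(counts)[["day"]],
             row = idx)
}

build_contacts <- function(patients, cfg) {
  win <- af_study_window()
  n <- nrow(patients)
  empty <- data.table(
    id = integer(0), patient_id = integer(0), date = as.Date(character(0)),
    kind = character(0), urgent = logical(0), diagnosis_class = character(0),
    facility_id = integer(0), home = logical(0), healthcare_unit_cost = numeric(0))
  if (n == 0L) return(empty)
  out <- list()

  ## per-patient counts drawn arm-wise (mean/sd differ only by arm)
  draw_counts <- function(mean_by_arm, sd_by_arm) {
    cnt <- integer(n)
    for (a in c("warfarin", "doac")) {
      ia <- which(patients$arm == a)
      cnt[ia] <- rcount(length(ia), mean_by_arm[[a]], sd_by_arm[[a]])
    }
    cnt
  }

  ## INR monitorings: evenly spaced with jitter
  m <- draw_counts(cfg$inr_mean, cfg$inr_sd)
  idx <- rep(seq_len(n), m)
  if (length(idx)) {
    gap <- 365 / m[idx]
    j <- sequence(m)
    day <- round(gap * (j - 0.5) + rnorm(length(idx), 0, gap * 0.2))
    day <- pmin(pmax(day, 0), 364)
    out$inr <- data.table(
      patient_id = patients$id[idx], day = day, kind = "inr",
      urgent = FALSE, diagnosis_class = "af",
      facility_id = patients$nearest_lab[idx],
      home = runif(length(idx)) < cfg$home_inr_share,
      healthcare_unit_cost = 0)
  }

  ## visit-type contacts
  vr <- cfg$visit_rates
  fac_for <- function(kind, idx) {
    switch(kind,
           primary_visit = patients$nearest_hc[idx],
           phone = patients$nearest_hc[idx],
           primary_ward_day = patients$nearest_hc[idx],
           patients$hospital[idx])
  }
  for (kind in names(vr)) {
    cnt <- draw_counts(vr[[kind]]$mean, vr[[kind]]$sd)
    idx <- rep(seq_len(n), cnt)
    if (!length(idx)) next
    if (grepl("ward_day", kind)) {
      ## one contiguous stay per patient: start day + consecutive days
      start <- sample(0:250, n, replace = TRUE)
      j <- sequence(cnt)
      day <- pmin(start[idx] + j - 1L, 364L)
    } else {
      day <- sample(0:364, length(idx), replace = TRUE)
    }
    out[[kind]] <- data.table(
      patient_id = patients$id[idx], day = day, kind = kind,
      urgent = FALSE, diagnosis_class = "af",
      facility_id = fac_for(kind, idx), home = FALSE,
      healthcare_unit_cost = rlnorm2(length(idx), cfg$unit_costs[[kind]],
                                     cfg$unit_cost_cv))
  }

  ## urgent complication episodes: emergency visit + >= 1 ward day,
  ## consecutive dates at the hospital
  for (comp in names(cfg$complication_probs)) {
    hit <- runif(n) < cfg$complication_probs[[comp]][patients$arm]
    if (!any(hit)) next
    hidx <- which(hit)
    t0 <- sample(0:350, length(hidx), replace = TRUE)
    stay <- 1L + rpois(length(hidx), 2)
    ev <- data.table(
      patient_id = patients$id[hidx], day = t0, kind = "emergency_visit",
      urgent = TRUE, diagnosis_class = comp,
      facility_id = patients$hospital[hidx], home = FALSE,
      healthcare_unit_cost = rlnorm2(length(hidx),
                                     cfg$unit_costs$emergency_visit,
                                     cfg$unit_cost_cv))
    widx <- rep(seq_along(hidx), stay)
    wd <- data.table(
      patient_id = patients$id[hidx][widx],
      day = pmin(t0[widx] + sequence(stay) - 1L, 364L),
      kind = "specialised_ward_day", urgent = FALSE, diagnosis_class = comp,
      facility_id = patients$hospital[hidx][widx], home = FALSE,
      healthcare_unit_cost = rlnorm2(length(widx),
                                     cfg$unit_costs$specialised_ward_day,
                                     cfg$unit_cost_cv))
    out[[paste0("comp_", comp)]] <- rbind(ev, wd)
  }

  ## non-AF noise contacts, dropped by the diagnosis filter
  if (cfg$other_contact_rate > 0) {
    cnt <- rcount(n, cfg$other_contact_rate, cfg$other_contact_rate * 1.5)
    idx <- rep(seq_len(n), cnt)
    if (length(idx)) {
      kinds <- sample(c("primary_visit", "phone"), length(idx), replace = TRUE)
      out$other <- data.table(
        patient_id = patients$id[idx], day = sample(0:364, length(idx), TRUE),
        kind = kinds, urgent = FALSE, diagnosis_class = "other",
        facility_id = patients$nearest_hc[idx], home = FALSE,
        healthcare_unit_cost = rlnorm2(length(idx), cfg$unit_costs$primary_visit,
                                       cfg$unit_cost_cv))
    }
  }

  contacts <- rbindlist(out, use.names = TRUE)
  if (nrow(contacts) == 0L) return(empty)
  contacts[, date := win$start + day]
  contacts[, day := NULL]
  setorder(contacts, patient_id, date, kind)
  contacts[, id := seq_len(.N)]
  setcolorder(contacts, c("id", "patient_id", "date", "kind", "urgent",
                          "diagnosis_class", "facility_id", "home",
                          "healthcare_unit_cost"))
  contacts[]
}

rlnorm2 <- function(n, mean, cv) {
  if (mean <= 0) return(numeric(n))
  lp <- lnorm_pars(mean, mean * cv)
  rlnorm(n, lp$meanlog, lp$sdlog)
}

#' Generate partial travel-reimbursement records
#'
#' Samples roughly `kela_coverage` of travel-eligible contacts (everything
#' except phone consultations and home INR measurements) into reimbursement
#' records, dominated by taxi journeys; urgent emergency contacts receive an
#' ambulance record with probability `ambulance_record_prob`. Each record
#' splits the journey cost into a patient share (capped at the EUR 25
#' deductible) and a society share. `kela_coverage = 0` yields no records at
#' all; `kela_coverage = 1` covers every eligible contact.
#'
#' @param contacts Contact table from [generate_contacts()].
#' @param config The [cohort_config()] used to generate them.
#' @return A `data.table` of records: `contact_id`, `patient_id`, `date`,
#'   `mode`, `patient_cost`, `society_cost`.
#' @export
generate_reimbursements <- function(contacts, config) {
  stopifnot(inherits(config, "af_cohort_config"))
  validate_cohort_config(config)
  with_stream(config$seed, "reimbursements",
              build_reimbursements(contacts, config))
}

build_reimbursements <- function(contacts, cfg) {
  empty <- data.table(contact_id = integer(0), patient_id = integer(0),
                      date = as.Date(character(0)), mode = character(0),
                      patient_cost = numeric(0), society_cost = numeric(0))
  eligible <- contacts[kind != "phone" & !home]
  if (nrow(eligible) == 0L || cfg$kela_coverage == 0) return(empty)
  p <- ifelse(eligible$urgent,
              pmax(cfg$kela_coverage, cfg$ambulance_record_prob),
              cfg$kela_coverage)
  take <- runif(nrow(eligible)) < p
  rec <- eligible[take, .(contact_id = id, patient_id, date, urgent)]
  if (nrow(rec) == 0L) return(empty)
  rec[, mode := ifelse(urgent, "ambulance",
                       sample(c("taxi", "car", "bus"), .N, replace = TRUE,
                              prob = c(0.92, 0.075, 0.005)))]
  d <- rlnorm2(nrow(rec), 15, 0.8)  # journey length proxy, km
  total <- fifelse(rec$mode == "ambulance", rgamma(nrow(rec), 4, scale = 50),
                   fifelse(rec$mode == "taxi", 5.9 + 1.59 * d,
                           fifelse(rec$mode == "car", 0.43 * d, 3.8)))
  rec[, patient_cost := pmin(total, 25)]
  rec[, society_cost := pmax(total - 25, 0)]
  rec[, urgent := NULL]
  rec[]
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `patients.csv`, `contacts.csv`, `reimbursements.csv`,
#' `facilities.csv`, `network_nodes.csv`, `network_edges.csv` and
#' `bus_stops.csv` (dates ISO-8601, distances km, money EUR).
#'
#' @param sim A list with elements `patients`, `contacts`, `reimbursements`
#'   and `geography` (as returned by [af_simulate()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(sim$patients, file.path(dir, "patients.csv"))
  fwrite(sim$contacts, file.path(dir, "contacts.csv"))
  fwrite(sim$reimbursements, file.path(dir, "reimbursements.csv"))
  fwrite(sim$geography$facilities, file.path(dir, "facilities.csv"))
  fwrite(sim$geography$nodes, file.path(dir, "network_nodes.csv"))
  fwrite(sim$geography$edges, file.path(dir, "network_edges.csv"))
  fwrite(data.table(node = sim$geography$bus_stops),
         file.path(dir, "bus_stops.csv"))
  invisible(dir)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_geography()], [generate_cohort()],
#' [generate_contacts()] and [generate_reimbursements()].
#'
#' @param cohort_cfg An [cohort_config()].
#' @param geo_cfg An [geography_config()].
#' @param seed Optional seed overriding both configs' seeds.
#' @return A list: `geography`, `patients`, `contacts`, `reimbursements`.
#' @export
af_simulate <- function(cohort_cfg = cohort_config(),
                        geo_cfg = geography_config(),
                        seed = NULL) {
  if (!is.null(seed)) {
    cohort_cfg$seed <- seed
    geo_cfg$seed <- seed
  }
  geo <- generate_geography(geo_cfg)
  patients <- generate_cohort(cohort_cfg, geo)
  contacts <- generate_contacts(patients, cohort_cfg)
  reimb <- generate_reimbursements(contacts, cohort_cfg)
  list(geography = geo, patients = patients, contacts = contacts,
       reimbursements = reimb)
}
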