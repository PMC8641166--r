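## Travel-mode assignment (rule classifier with reimbursement-record
## precedence) and the daily trip limiter collapsing each patient-day's
## contacts into at most two roundtrips (four one-way legs).

#' Assign a travel mode to a journey
#'
#' Rule-based classifier applied when no reimbursement record fixes the mode.
#' Precedence: (1) a reimbursement-recorded mode always wins; (2) ambulance
#' requires an urgent visit backed by an ambulance record (a consequence of
#' rule 1); (3) taxi for patients aged 90 or over; (4) walking when the
#' one-way distance is at most 1.25 km below age 80, or at most 0.25 km at
#' ages 80-89; (5) bus when the distance exceeds 1.25 km, the destination is
#' bus-accessible, the nearest stop is within 0.25 km and the patient is
#' under 80; (6) private car otherwise. Total over the valid domain and
#' vectorised.
#'
#' @param age Patient age, years.
#' @param one_way_distance One-way journey distance, km.
#' @param dest_bus_accessible Is the destination reachable by bus?
#' @param stop_distance Network distance to the nearest bus stop, km
#'   (`Inf` when there are no stops).
#' @param urgent Is the journey an urgent emergency visit?
#' @param reimbursement_mode Mode recorded in a reimbursement record, or
#'   `NA`/`NULL` when none exists.
#' @return Character vector of modes.
#' @examples
#' assign_travel_mode(92, 0.5, FALSE, Inf)              # taxi
#' assign_travel_mode(70, 1.0, FALSE, Inf)              # walking
#' assign_travel_mode(70, 5, TRUE, 0.2)                 # bus
#' @export
assign_travel_mode <- function(age, one_way_distance, dest_bus_accessible,
                               stop_distance, urgent = FALSE,
                               reimbursement_mode = NULL) {
  n <- max(length(age), length(one_way_distance))
  age <- rep_len(age, n)
  d <- rep_len(one_way_distance, n)
  busok <- rep_len(as.logical(dest_bus_accessible), n)
  stopd <- rep_len(stop_distance, n)
  if (is.null(reimbursement_mode)) reimbursement_mode <- NA_character_
  rm_ <- rep_len(as.character(reimbursement_mode), n)
  if (any(age < 18, na.rm = TRUE) || any(d < 0, na.rm = TRUE)) {
    stop_af("age must be >= 18 and distance >= 0", "af_validation_error")
  }
  bad <- !is.na(rm_) & !(rm_ %in% AF_MODES)
  if (any(bad)) {
    stop_af(sprintf("unknown reimbursement mode '%s'", rm_[bad][1L]),
            "af_mode_error")
  }
  mode <- rep("car", n)
  mode[age >= 90] <- "taxi"
  walk <- (d <= 1.25 & age < 80) | (d <= 0.25 & age >= 80 & age < 90)
  mode[walk & age < 90] <- "walking"
  bus <- d > 1.25 & busok & stopd <= 0.25 & age < 80
  mode[bus & !walk & age < 90] <- "bus"
  mode[!is.na(rm_)] <- rm_[!is.na(rm_)]
  mode
}

## Ward-stay annotation: consecutive ward-day contacts of one patient at one
## care level form a stay; flag entry/exit days, and mark every contact that
## falls strictly inside a stay (trips are suppressed there).
annotate_ward_stays <- function(contacts) {
  contacts <- as.data.table(contacts)
  contacts[, is_ward := kind %in% WARD_KINDS]
  contacts[, `:=`(ward_entry = FALSE, ward_exit = FALSE, in_stay = FALSE)]
  if (!any(contacts$is_ward)) return(contacts)
  wd <- unique(contacts[is_ward == TRUE, .(patient_id, kind, facility_id, date)])
  setorder(wd, patient_id, kind, facility_id, date)
  wd[, gap := c(2, as.numeric(diff(date))), by = .(patient_id, kind, facility_id)]
  wd[, stay_id := cumsum(gap > 1)]
  stays <- wd[, .(start = min(date), end = max(date),
                  patient_id = patient_id[1L], kind = kind[1L],
                  facility_id = facility_id[1L]), by = stay_id]
  ## entry/exit flags on ward-day contacts
  contacts[stays, on = .(patient_id, kind, facility_id, date = start),
           ward_entry := TRUE]
  contacts[stays, on = .(patient_id, kind, facility_id, date = end),
           ward_exit := TRUE]
  ## any contact dated inside some stay of the patient (inclusive)
  inside <- contacts[stays, on = .(patient_id, date >= start, date <= end),
                     which = TRUE, nomatch = NULL]
  contacts[unique(inside), in_stay := TRUE]
  contacts[]
}

## care-level anchor of a trip-generating contact
contact_level <- function(kind) {
  fifelse(kind %in% c("specialised_visit", "emergency_visit",
                      "specialised_ward_day"), "specialised",
          fifelse(kind %in% c("primary_visit", "primary_ward_day"), "primary",
                  fifelse(kind == "inr", "inr", "none")))
}

## Core limiter for one patient-day of annotated contacts. Returns journey
## stubs (purpose, facility, legs, urgent). Cap: 4 one-way legs.
plan_one_day <- function(dc) {
  stubs <- list()
  ward <- dc[is_ward == TRUE]
  out_kinds <- dc[is_ward == FALSE & kind != "phone" & !(home %in% TRUE)]
  in_stay_day <- any(dc$in_stay) || nrow(ward) > 0L

  if (nrow(ward) > 0L) {
    ## one-way legs on stay boundaries only
    tr <- unique(ward[ward_entry | ward_exit,
                      .(facility_id, kind,
                        legs_n = as.integer(ward_entry) + as.integer(ward_exit))])
    if (nrow(tr) > 0L) {
      stubs$ward <- data.table(purpose = "ward", facility_id = tr$facility_id,
                               legs = tr$legs_n, urgent = FALSE)
    }
    ## outpatient/INR at a *different* care level than the ward still needs a
    ## roundtrip (if the patient is not mid-stay the whole day there is a
    ## transition anyway; Table-2 reading, see vignette). Same level: chained.
    if (nrow(out_kinds) > 0L && any(ward$ward_entry | ward$ward_exit)) {
      ## INR during an inpatient stay never generates a trip; outpatient
      ## visits at the ward's own care level are chained into its legs
      wl <- unique(contact_level(ward$kind))
      ol <- unique(contact_level(out_kinds$kind))
      extra <- setdiff(ol, c(wl, "inr"))
      if (length(extra) > 0L) {
        lv <- extra[1L]
        anchor <- out_kinds[contact_level(kind) == lv][1L]
        stubs$out <- data.table(
          purpose = if (lv == "inr") "inr" else lv,
          facility_id = if (lv == "inr") NA_integer_ else anchor$facility_id,
          legs = 2L, urgent = anchor$urgent)
      }
    }
  } else if (!in_stay_day && nrow(out_kinds) > 0L) {
    lv <- contact_level(out_kinds$kind)
    has_p <- "primary" %in% lv
    has_s <- "specialised" %in% lv
    inr_fac <- unique(out_kinds[lv == "inr"]$facility_id)
    if (has_p && has_s) {
      a_p <- out_kinds[lv == "primary"][1L]
      a_s <- out_kinds[lv == "specialised"][1L]
      stubs$p <- data.table(purpose = "primary", facility_id = a_p$facility_id,
                            legs = 2L, urgent = a_p$urgent)
      stubs$s <- data.table(purpose = "specialised", facility_id = a_s$facility_id,
                            legs = 2L, urgent = a_s$urgent)
    } else if (has_s) {
      a_s <- out_kinds[lv == "specialised"][1L]
      stubs$s <- data.table(purpose = "specialised", facility_id = a_s$facility_id,
                            legs = 2L, urgent = a_s$urgent)
    } else if (has_p) {
      a_p <- out_kinds[lv == "primary"][1L]
      stubs$p <- data.table(purpose = "primary", facility_id = a_p$facility_id,
                            legs = 2L, urgent = a_p$urgent)
    } else if (length(inr_fac) > 0L) {
      ## INR-only day: one roundtrip per distinct location, max two
      k <- min(length(inr_fac), 2L)
      stubs$i <- data.table(purpose = "inr",
                            facility_id = rep(NA_integer_, k),
                            legs = rep(2L, k), urgent = FALSE)
    }
  }
  st <- rbindlist(stubs)
  if (nrow(st) == 0L) return(st)
  ## hard cap: at most 4 one-way legs per day, roundtrips first
  st <- st[order(-legs)]
  cum <- cumsum(st$legs)
  over <- which(cum > 4L)
  if (length(over) > 0L) {
    first_over <- over[1L]
    room <- 4L - if (first_over > 1L) cum[first_over - 1L] else 0L
    st <- st[seq_len(first_over)]
    st$legs[first_over] <- room
    st <- st[legs > 0L]
  }
  st
}

#' Daily trip plan for one patient-day
#'
#' Collapses the contacts of one patient on one date into journey stubs
#' under the daily trip limiter: contacts during an inpatient stay generate
#' no trip, stay boundaries generate one-way legs, any combination of
#' INR/outpatient contacts at one care level generates a single roundtrip,
#' combinations spanning primary and specialised care two roundtrips, with a
#' hard cap of two roundtrips (four one-way legs) per day. Phone
#' consultations and home INR measurements never generate trips.
#'
#' @param day_contacts Contacts of a single patient on a single date. Ward
#'   stay flags are derived from the rows given; when the day is part of a
#'   longer stay, pass contacts annotated over the full stream (the pipeline
#'   does this) so mid-stay days are recognised.
#' @return A `data.table` of journey stubs: `purpose` (`"inr"`, `"primary"`,
#'   `"specialised"`, `"ward"`), `facility_id` (`NA` for INR, routed to the
#'   closest laboratory later), `legs` (1 one-way, 2 roundtrip), `urgent`.
#' @examples
#' d <- data.table::data.table(
#'   patient_id = 1L, date = as.Date("2017-07-01"),
#'   kind = c("inr", "primary_visit"), facility_id = c(4L, 2L),
#'   urgent = FALSE, home = FALSE)
#' daily_trip_plan(d)
#' @export
daily_trip_plan <- function(day_contacts) {
  dc <- as.data.table(day_contacts)
  if (nrow(dc) == 0L) {
    return(data.table(purpose = character(0), facility_id = integer(0),
                      legs = integer(0), urgent = logical(0)))
  }
  if (uniqueN(dc$patient_id) > 1L || uniqueN(dc$date) > 1L) {
    stop_af("day_contacts must belong to one patient and one date",
            "af_validation_error")
  }
  if (!"home" %in% names(dc)) dc[, home := FALSE]
  if (!all(c("is_ward", "ward_entry", "ward_exit", "in_stay") %in% names(dc))) {
    dc <- annotate_ward_stays(dc)
  }
  plan_one_day(dc)
}

## All patient-days at once (annotates ward stays over the full stream).
## The common case -- no ward involvement -- is vectorised; ward days go
## through the same plan_one_day() core as the exported single-day API.
trip_plan <- function(contacts) {
  contacts <- annotate_ward_stays(contacts)
  if (!"home" %in% names(contacts)) contacts[, home := FALSE]
  empty <- data.table(patient_id = integer(0), date = as.Date(character(0)),
                      purpose = character(0), facility_id = integer(0),
                      legs = integer(0), urgent = logical(0))
  if (nrow(contacts) == 0L) return(empty)

  wd_days <- unique(contacts[is_ward | in_stay, .(patient_id, date)])
  plain <- contacts[!wd_days, on = .(patient_id, date)][
    kind != "phone" & !(home %in% TRUE)]

  out <- list()
  if (nrow(plain) > 0L) {
    plain[, level := contact_level(kind)]
    smry <- plain[, {
      has_p <- any(level == "primary")
      has_s <- any(level == "specialised")
      inr_fac <- unique(facility_id[level == "inr"])
      .(has_p = has_p, has_s = has_s,
        n_inr_loc = length(inr_fac),
        p_fac = if (has_p) facility_id[level == "primary"][1L] else NA_integer_,
        s_fac = if (has_s) facility_id[level == "specialised"][1L] else NA_integer_,
        p_urgent = any(urgent[level == "primary"]),
        s_urgent = any(urgent[level == "specialised"]))
    }, by = .(patient_id, date)]
    out$primary <- smry[has_p == TRUE,
                        .(patient_id, date, purpose = "primary",
                          facility_id = p_fac, legs = 2L, urgent = p_urgent)]
    out$spec <- smry[has_s == TRUE,
                     .(patient_id, date, purpose = "specialised",
                       facility_id = s_fac, legs = 2L, urgent = s_urgent)]
    ## INR-only days: one roundtrip per distinct location, capped at two
    inr_only <- smry[has_p == FALSE & has_s == FALSE & n_inr_loc > 0L]
    if (nrow(inr_only) > 0L) {
      reps <- pmin(inr_only$n_inr_loc, 2L)
      idx <- rep(seq_len(nrow(inr_only)), reps)
      out$inr <- inr_only[idx, .(patient_id, date, purpose = "inr",
                                 facility_id = NA_integer_, legs = 2L,
                                 urgent = FALSE)]
    }
  }
  if (nrow(wd_days) > 0L) {
    wards <- contacts[wd_days, on = .(patient_id, date)]
    out$ward <- wards[, plan_one_day(.SD), by = .(patient_id, date)]
  }
  stubs <- rbind(rbindlist(out, use.names = TRUE), empty, fill = TRUE)
  setorder(stubs, patient_id, date)
  stubs[]
}

#' Resolve journey stubs into routed journeys
#'
#' Routes each stub from the patient's home: INR stubs to the closest
#' laboratory, everything else to the contact's recorded facility. The car
#' fastest-route distance serves as the appointment distance for the mode
#' rules; the journey then takes its own mode's time-optimal route (walking
#' at 4 km/h, bus capped at 30 km/h plus the walked stop-access time). A
#' reimbursement record on the same patient-day fixes the mode. Journeys to
#' unreachable facilities are dropped with a warning.
#'
#' @param stubs Journey stubs (from [daily_trip_plan()] or the pipeline),
#'   with `patient_id` and `date` columns.
#' @param geo An [geography()] object.
#' @param patients Patient table.
#' @param reimbursements Optional reimbursement-record table.
#' @return A `data.table` of journeys: mode, legs, one-way `distance_km` and
#'   `travel_time_h`, `from_reimbursement` flag.
#' @export
resolve_journeys <- function(stubs, geo, patients,
                             reimbursements = NULL) {
  stubs <- as.data.table(stubs)
  patients <- as.data.table(patients)
  if (nrow(stubs) == 0L) {
    return(data.table(patient_id = integer(0), date = as.Date(character(0)),
                      purpose = character(0), facility_id = integer(0),
                      mode = character(0), legs = integer(0),
                      distance_km = numeric(0), travel_time_h = numeric(0),
                      from_reimbursement = logical(0)))
  }
  j <- merge(stubs,
             patients[, .(patient_id = id, age, home_node)],
             by = "patient_id", sort = FALSE)

  ## destination nodes: INR stubs go to the closest laboratory
  labt <- closest_lab_table(geo, unique(j$home_node))
  j <- merge(j, labt[, .(home_node, lab_id)], by = "home_node", sort = FALSE)
  j[purpose == "inr", facility_id := lab_id]
  fac <- geo$facilities[, .(facility_id = id, fac_node = node,
                            fac_bus = bus_accessible)]
  j <- merge(j, fac, by = "facility_id", all.x = TRUE, sort = FALSE)
  missing_fac <- is.na(j$fac_node)
  if (any(missing_fac)) {
    warning(sprintf("%d journey(s) dropped: unknown facility", sum(missing_fac)),
            call. = FALSE)
    j <- j[!missing_fac]
  }

  ## route matrices over unique origins x unique destinations, per mode
  od <- unique(j[, .(home_node, fac_node)])
  uo <- unique(od$home_node)
  ut <- unique(od$fac_node)
  routes <- rbindlist(lapply(c("car", "walking", "bus"), function(m) {
    rm_ <- route_matrix(geo, uo, ut, m)
    ij <- cbind(match(od$home_node, uo),
                match(as.character(od$fac_node), colnames(rm_$time)))
    data.table(home_node = od$home_node, fac_node = od$fac_node, profile = m,
               time_h = rm_$time[ij], dist_km = rm_$dist[ij])
  }))
  rcar <- routes[profile == "car"]
  unreachable <- rcar[is.infinite(time_h)]
  if (nrow(unreachable) > 0L) {
    j <- j[!unreachable, on = .(home_node, fac_node)]
    warning(sprintf("%d journey(s) dropped: facility unreachable",
                    nrow(unreachable)), call. = FALSE)
    if (nrow(j) == 0L) return(j)
  }
  j <- merge(j, rcar[, .(home_node, fac_node, car_time = time_h,
                         car_dist = dist_km)],
             by = c("home_node", "fac_node"), sort = FALSE)
  j <- merge(j, routes[profile == "walking",
                       .(home_node, fac_node, walk_time = time_h,
                         walk_dist = dist_km)],
             by = c("home_node", "fac_node"), sort = FALSE)
  j <- merge(j, routes[profile == "bus",
                       .(home_node, fac_node, bus_time = time_h,
                         bus_dist = dist_km)],
             by = c("home_node", "fac_node"), sort = FALSE)

  ## bus stop access + reimbursement-recorded modes
  stopd <- data.table(home_node = unique(j$home_node))
  stopd[, stop_km := bus_access_distance(geo, home_node)]
  j <- merge(j, stopd, by = "home_node", sort = FALSE)
  if (!is.null(reimbursements) && nrow(reimbursements) > 0L) {
    rb <- as.data.table(reimbursements)[, .(mode = mode[1L]),
                                        by = .(patient_id, date)]
    j <- merge(j, rb, by = c("patient_id", "date"), all.x = TRUE, sort = FALSE)
    setnames(j, "mode", "reimb_mode")
  } else {
    j[, reimb_mode := NA_character_]
  }

  j[, mode := assign_travel_mode(age, car_dist, fac_bus, stop_km,
                                 urgent = urgent,
                                 reimbursement_mode = reimb_mode)]
  j[, `:=`(
    distance_km = fifelse(mode == "walking", walk_dist,
                          fifelse(mode == "bus", bus_dist, car_dist)),
    travel_time_h = fifelse(mode == "walking", walk_time,
                            fifelse(mode == "bus", bus_time + stop_km / 4,
                                    car_time)))]
  j[, from_reimbursement := !is.na(reimb_mode)]
  j[, .(patient_id, date, purpose, facility_id, mode, legs,
        distance_km, travel_time_h, urgent, from_reimbursement)]
}
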