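test_that("travel mode rules follow the selection table", {
  # taxi from age 90 regardless of distance
  expect_equal(assign_travel_mode(92, 0.5, FALSE, Inf), "taxi")
  expect_equal(assign_travel_mode(90, 30, TRUE, 0.1), "taxi")
  # walking bands
  expect_equal(assign_travel_mode(70, 1.0, FALSE, Inf), "walking")
  expect_equal(assign_travel_mode(79.9, 1.25, FALSE, Inf), "walking")
  expect_equal(assign_travel_mode(85, 0.2, FALSE, Inf), "walking")
  expect_equal(assign_travel_mode(85, 0.5, TRUE, 0.1), "car")
  # bus requires distance > 1.25, accessible destination, close stop, age < 80
  expect_equal(assign_travel_mode(70, 5, TRUE, 0.2), "bus")
  expect_equal(assign_travel_mode(70, 5, TRUE, 0.4), "car")
  expect_equal(assign_travel_mode(70, 5, FALSE, 0.2), "car")
  expect_equal(assign_travel_mode(82, 5, TRUE, 0.2), "car")
  # default car
  expect_equal(assign_travel_mode(70, 2, FALSE, Inf), "car")
})

test_that("reimbursement-recorded modes take precedence", {
  expect_equal(assign_travel_mode(92, 0.5, FALSE, Inf,
                                  reimbursement_mode = "bus"), "bus")
  expect_equal(assign_travel_mode(70, 1.0, FALSE, Inf, urgent = TRUE,
                                  reimbursement_mode = "ambulance"),
               "ambulance")
  # vectorised mixed input
  got <- assign_travel_mode(c(92, 70, 70), c(0.5, 1.0, 5), c(FALSE, FALSE, TRUE),
                            c(Inf, Inf, 0.2),
                            reimbursement_mode = c(NA, "taxi", NA))
  expect_equal(got, c("taxi", "taxi", "bus"))
  expect_error(assign_travel_mode(70, 1, FALSE, Inf,
                                  reimbursement_mode = "horse"),
               class = "af_mode_error")
  expect_error(assign_travel_mode(15, 1, FALSE, Inf),
               class = "af_validation_error")
})

test_that("mode assignment is total over a random valid domain", {
  set.seed(42)
  n <- 500
  got <- assign_travel_mode(
    age = runif(n, 18, 105), one_way_distance = runif(n, 0, 80),
    dest_bus_accessible = runif(n) < 0.5, stop_distance = runif(n, 0, 2),
    urgent = FALSE)
  expect_true(all(got %in% c("car", "taxi", "walking", "bus")))
})

day <- as.Date("2017-07-10")
dc <- function(kinds, facility_id = 2L, dates = day, urgent = FALSE,
               home = FALSE) {
  make_contacts(1L, dates, kinds, facility_id = facility_id, urgent = urgent,
                home = home)
}

test_that("daily trip plan maps contact combinations to trip counts", {
  # single INR: one roundtrip to the (later-resolved) laboratory
  p <- daily_trip_plan(dc("inr"))
  expect_equal(nrow(p), 1L)
  expect_equal(p$legs, 2L)
  expect_equal(p$purpose, "inr")
  expect_true(is.na(p$facility_id))

  # three INR at the same laboratory: still one roundtrip
  p <- daily_trip_plan(dc(rep("inr", 3)))
  expect_equal(sum(p$legs), 2L)

  # INR + primary visit: one roundtrip, anchored at the visit facility
  p <- daily_trip_plan(dc(c("inr", "primary_visit")))
  expect_equal(nrow(p), 1L)
  expect_equal(p$purpose, "primary")

  # INR + specialised visit: one roundtrip (lab available at the hospital)
  p <- daily_trip_plan(dc(c("inr", "specialised_visit")))
  expect_equal(sum(p$legs), 2L)
  expect_equal(p$purpose, "specialised")

  # primary + INR + specialised: two roundtrips
  p <- daily_trip_plan(dc(c("primary_visit", "inr", "specialised_visit"),
                          facility_id = c(2L, 4L, 3L)))
  expect_equal(nrow(p), 2L)
  expect_equal(sum(p$legs), 4L)

  # phone-only day: no trips; home INR: no trips
  expect_equal(nrow(daily_trip_plan(dc("phone"))), 0L)
  expect_equal(nrow(daily_trip_plan(dc("inr", home = TRUE))), 0L)
})

test_that("ward stays suppress and bound trips", {
  # INR during a one-day ward stay: the stay generates its legs, INR none
  p <- daily_trip_plan(dc(c("inr", "specialised_ward_day")))
  expect_equal(unique(p$purpose), "ward")
  # single-day stay = entry + exit: two one-way legs
  expect_equal(sum(p$legs), 2L)

  # mid-stay day of a 3-day stay: no trips at all, even with an INR
  contacts <- rbind(
    make_contacts(1L, day + 0:2, rep("specialised_ward_day", 3)),
    make_contacts(1L, day + 1, "inr"))
  contacts[, id := seq_len(.N)]
  ann <- afcost:::annotate_ward_stays(contacts)
  expect_equal(nrow(daily_trip_plan(ann[date == day + 1])), 0L)
  # first day: one-way in; last day: one-way out
  expect_equal(daily_trip_plan(ann[date == day])$legs, 1L)
  expect_equal(daily_trip_plan(ann[date == day + 2])$legs, 1L)

  # primary visit on the first day of a 2-day specialised stay:
  # roundtrip (primary) + one-way (ward entry)
  contacts2 <- rbind(
    make_contacts(1L, day + 0:1, rep("specialised_ward_day", 2),
                  facility_id = 3L),
    make_contacts(1L, day, "primary_visit", facility_id = 2L))
  contacts2[, id := seq_len(.N)]
  ann2 <- afcost:::annotate_ward_stays(contacts2)
  p <- daily_trip_plan(ann2[date == day])
  expect_setequal(p$purpose, c("ward", "primary"))
  expect_equal(sum(p$legs), 3L)
  # a one-day stay books both the entry and the exit leg
  p1 <- daily_trip_plan(dc(c("primary_visit", "specialised_ward_day"),
                           facility_id = c(2L, 3L)))
  expect_equal(sum(p1$legs), 4L)
})

test_that("no adversarial day exceeds two roundtrips", {
  set.seed(99)
  kinds <- c("inr", "primary_visit", "specialised_visit", "emergency_visit",
             "phone", "primary_ward_day", "specialised_ward_day")
  for (i in 1:50) {
    k <- sample(kinds, sample(1:10, 1), replace = TRUE)
    p <- daily_trip_plan(dc(k, facility_id = sample(2:5, length(k), TRUE)))
    expect_lte(sum(p$legs), 4L)
  }
})

test_that("journeys resolve to the right destinations and modes", {
  # line network: home(1) -- lab(2) -- hospital(3)
  nodes <- data.table(id = 1:3, x = c(0, 2, 12), y = 0)
  edges <- data.table(from = c(1L, 2L), to = c(2L, 3L),
                      length_km = c(2, 10), speed_limit = c(50, 80))
  fac <- data.table(id = 1:3, kind = c("lab", "hospital", "health_centre"),
                    node = c(2L, 3L, 2L), bus_accessible = TRUE)
  geo <- geography(nodes, edges, fac, bus_stops = 1L)
  pats <- data.table(id = 1L, arm = "warfarin", age = 70,
                     hourly_income = 12, wage_coef = 0.35, home_node = 1L)
  stubs <- data.table(patient_id = 1L, date = day,
                      purpose = c("inr", "specialised"),
                      facility_id = c(NA_integer_, 2L),
                      legs = c(2L, 2L), urgent = FALSE)
  j <- resolve_journeys(stubs, geo, pats)
  expect_equal(nrow(j), 2L)
  inr_j <- j[purpose == "inr"]
  expect_equal(inr_j$facility_id, 1L)      # the closest laboratory
  expect_equal(inr_j$distance_km, 2)
  expect_equal(inr_j$mode, "bus")          # 2 km > 1.25, stop at home, age 70
  spec_j <- j[purpose == "specialised"]
  expect_equal(spec_j$distance_km, 12)
  expect_equal(spec_j$mode, "bus")
  # bus time includes the stop-access walk (0 km here)
  expect_equal(inr_j$travel_time_h, 2 / 30)

  # a reimbursement record fixes the mode
  reimb <- data.table(patient_id = 1L, date = day, mode = "taxi",
                      patient_cost = 25, society_cost = 10)
  j2 <- resolve_journeys(stubs, geo, pats, reimb)
  expect_true(all(j2$mode == "taxi"))
  expect_true(all(j2$from_reimbursement))

  # zero stubs resolve to zero journeys
  expect_equal(nrow(resolve_journeys(stubs[0], geo, pats)), 0L)
})
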