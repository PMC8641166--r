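params <- cost_parameters()
day <- as.Date("2017-08-01")

test_that("per-mode travel costs follow the fare equations", {
  expect_equal(unname(travel_cost("walking", 7, params = params)), c(0, 0))
  expect_equal(travel_cost("taxi", 10, params = params)[["patient"]],
               5.9 + 1.59 * 10)  # 21.8
  expect_equal(travel_cost("car", 0, params = params)[["patient"]], 0)
  expect_equal(travel_cost("car", 12.5, params = params)[["patient"]],
               0.43 * 12.5)
  # bus fare bands
  expect_equal(travel_cost("bus", 10, params = params)[["patient"]], 2.00)
  expect_equal(travel_cost("bus", 20, params = params)[["patient"]], 3.80)
  expect_equal(travel_cost("bus", 50, params = params)[["patient"]], 5.00)
  # ambulance only from records
  expect_error(travel_cost("ambulance", 10, params = params),
               class = "af_ambulance_error")
  rec <- list(patient_cost = 25, society_cost = 130)
  expect_equal(unname(travel_cost("ambulance", 10, rec, params)), c(25, 130))
  # a record overrides the formula for any mode
  expect_equal(travel_cost("taxi", 10, rec, params)[["patient"]], 25)
})

test_that("time costs value travel time with the car/taxi penalty", {
  expect_equal(time_cost_travel("car", 0.5, 0.35, 12, params),
               0.35 * 12 * (0.5 + 0.083))  # 2.4486
  expect_equal(time_cost_travel("walking", 0, 0.35, 12, params), 0)
  expect_equal(time_cost_travel("bus", 1, 1.0, 12, params), 12)
  expect_equal(time_cost_travel("ambulance", 0.25, 1.0, 20, params), 5)
  expect_error(time_cost_travel("car", -1, 0.35, 12, params),
               class = "af_validation_error")
})

test_that("INR monitoring time cost is m * c_h * p_a * t_m", {
  expect_equal(time_cost_monitoring(0, 0.35, 12, params), 0)
  expect_equal(time_cost_monitoring(1, 0.35, 12, params), 2.1)
  expect_equal(time_cost_monitoring(2, 0.35, 12, params),
               2 * time_cost_monitoring(1, 0.35, 12, params))
  expect_error(time_cost_monitoring(1.5, 0.35, 12, params),
               class = "af_validation_error")
})

test_that("drug splits and payer conservation", {
  expect_equal(unname(drug_daily_cost("warfarin", params)), c(0.08, 0.05))
  expect_equal(unname(drug_daily_cost("doac", params)), c(0.95, 1.76))
  for (a in c("warfarin", "doac")) {
    dd <- drug_daily_cost(a, params)
    expect_equal(sum(dd), dd[["patient"]] + dd[["society"]])
  }
  expect_error(drug_daily_cost("heparin", params),
               class = "af_validation_error")
})

test_that("payment ceiling reroutes overflow in date order", {
  st <- list(cumulative = 680, last_date = day)
  got <- patient_fee(list(kind = "specialised_visit", date = day + 1), st,
                     params)
  expect_equal(got$fee_patient, 3.0)
  expect_equal(got$overflow, 41.2 - 3.0)
  expect_equal(got$state$cumulative, 683)
  # saturated cap
  nxt <- patient_fee(list(kind = "primary_visit", date = day + 2),
                     got$state, params)
  expect_equal(nxt$fee_patient, 0)
  expect_equal(nxt$overflow, 20.6)
  # first primary visit pays the nominal physician fee
  first <- patient_fee(list(kind = "primary_visit", date = day), NULL, params)
  expect_equal(first$fee_patient, 20.6)
  # order dependence is enforced
  expect_error(patient_fee(list(kind = "inr", date = day - 5), got$state,
                           params),
               class = "af_order_error")
})

test_that("batch fee processing conserves nominal fees under the cap", {
  # 20 ward days at 48.9 = 978 nominal: patient pays exactly the ceiling
  contacts <- make_contacts(1L, day + 0:19, rep("primary_ward_day", 20))
  out <- process_fees(contacts, params)
  expect_equal(sum(out$fee_patient), 683)
  expect_equal(sum(out$fee_patient) + sum(out$fee_overflow), 20 * 48.9)
  expect_true(all(cumsum(out$fee_patient) <= 683 + 1e-9))
  # INR visits are free, home INR pays the home-care fee
  inr <- process_fees(make_contacts(2L, day, "inr"), params)
  expect_equal(inr$fee_patient, 0)
  home <- process_fees(make_contacts(2L, day, "inr", home = TRUE), params)
  expect_equal(home$fee_patient, params$home_inr_patient_fee)
})

test_that("compose_daily reproduces the hand-chained INR day", {
  pat <- test_patient(age = 70)  # retired? no: 70 >= 65 -> 0.35
  expect_equal(pat$wage_coef, 0.35)
  contacts <- process_fees(make_contacts(1L, day, "inr"), params)
  journeys <- data.table(patient_id = 1L, date = day, purpose = "inr",
                         facility_id = 1L, mode = "walking", legs = 2L,
                         distance_km = 1, travel_time_h = 0.25,
                         urgent = FALSE, from_reimbursement = FALSE)
  rec <- compose_daily(pat, journeys, contacts, params = params)
  expect_equal(rec$c_m, 2.1)                    # 1 * 12 * 0.35 * 0.5
  expect_equal(rec$c_t, 0.35 * 12 * 2 * 0.25)   # 2.1
  expect_equal(rec$c_d, 0)
  expect_equal(rec$inr_cost, 31)
  expect_equal(rec$c_a, 0.08)                   # drug only, INR fee-free
  expect_equal(rec$c_p, rec$c_m + rec$c_a + rec$c_t + rec$c_d)
})

test_that("a no-contact day accrues only drug costs; 365 of them add up", {
  pat <- test_patient(arm = "warfarin")
  rec <- compose_daily(pat, params = params, date = day)
  expect_equal(rec$c_p, 0.08)
  expect_equal(rec$healthcare_total, 0.05)
  expect_equal(rec$c_m + rec$c_t + rec$c_d, 0)
  # 365 no-contact days: society drug cost 18.25
  daily <- rbindlist(lapply(0:364, function(i)
    compose_daily(pat, params = params, date = day + i)))
  expect_equal(sum(daily$healthcare_total), 365 * 0.05)  # 18.25
  expect_equal(sum(daily$c_p), 365 * 0.08)
})

test_that("compose_daily rejects mixed patients or dates", {
  pat <- test_patient()
  c1 <- process_fees(make_contacts(1L, day, "inr"), params)
  c2 <- process_fees(make_contacts(2L, day, "inr"), params)
  expect_error(compose_daily(pat, contacts = rbind(c1, c2), params = params),
               class = "af_validation_error")
  cc <- process_fees(make_contacts(1L, c(day, day + 1), rep("inr", 2)), params)
  expect_error(compose_daily(pat, contacts = cc, params = params),
               class = "af_validation_error")
  expect_error(compose_daily(pat, contacts = make_contacts(1L, day, "inr"),
                             params = params),
               "process_fees", class = "af_validation_error")
})

test_that("batch daily costs equal composing day by day", {
  sim <- af_simulate(cohort_config(n_warfarin = 12, n_doac = 4, seed = 21,
                                   other_contact_rate = 0),
                     geography_config(n_nodes = 80, n_labs = 4,
                                      n_health_centres = 3, seed = 21))
  contacts <- process_fees(filter_af_contacts(sim$contacts), params)
  stubs <- afcost:::trip_plan(contacts)
  journeys <- resolve_journeys(stubs, sim$geography, sim$patients,
                               sim$reimbursements)
  batch <- compute_daily_costs(sim$patients, contacts, journeys,
                               sim$reimbursements, params)
  for (i in sample.int(nrow(batch), min(25, nrow(batch)))) {
    pid <- batch$patient_id[i]
    d <- batch$date[i]
    one <- compose_daily(
      as.list(sim$patients[id == pid]),
      journeys[patient_id == pid & date == d],
      contacts[patient_id == pid & date == d],
      sim$reimbursements[patient_id == pid & date == d],
      params)
    for (col in c("c_m", "c_a", "c_t", "c_d", "c_p", "healthcare_total")) {
      expect_equal(batch[[col]][i], one[[col]], tolerance = 1e-10,
                   info = sprintf("%s patient %d %s", col, pid, format(d)))
    }
  }
  # Eq additivity is exact on every row
  expect_equal(batch$c_p, batch$c_m + batch$c_a + batch$c_t + batch$c_d)
  expect_true(all(batch[, .(c_m, c_a, c_t, c_d, e_p, e_s, w_p, w_s, d_h, k,
                            inr_cost, other_society)] >= 0))
})

test_that("travel and time costs are monotone in distance for car and taxi", {
  d <- seq(0, 60, by = 2.5)
  for (m in c("car", "taxi")) {
    costs <- vapply(d, function(x)
      travel_cost(m, x, params = params)[["patient"]], numeric(1))
    expect_true(all(diff(costs) >= 0))
    tc <- time_cost_travel(rep(m, length(d)), d / 50, 1, 12, params)
    expect_true(all(diff(tc) >= 0))
  }
})
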