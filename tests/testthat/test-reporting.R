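params <- cost_parameters()
day <- as.Date("2017-08-01")

## small deterministic daily table for two patients
toy_daily <- function() {
  rbind(
    data.table(patient_id = 1L, date = day + 0:1, n_inr = 1L,
               c_m = 2.1, c_a = 0.08, c_t = 1.0, c_d = 0.5,
               c_p = 2.1 + 0.08 + 1.0 + 0.5,
               drug_patient = 0.08, fees_patient = 0,
               e_p = 0, e_s = 0, w_p = 0, w_s = 0, d_h = 0.05, k = 0,
               inr_cost = 31, other_society = 0,
               healthcare_total = 31.05),
    data.table(patient_id = 2L, date = day, n_inr = 0L,
               c_m = 0, c_a = 20.95, c_t = 0, c_d = 0, c_p = 20.95,
               drug_patient = 0.95, fees_patient = 20,
               e_p = 50, e_s = 0, w_p = 0, w_s = 0, d_h = 1.76, k = 10,
               inr_cost = 0, other_society = 0,
               healthcare_total = 61.76))
}

test_that("per-patient totals are exact sums with duplicate detection", {
  tot <- per_patient_annual(toy_daily())
  expect_equal(nrow(tot), 2L)
  p1 <- tot[patient_id == 1L]
  expect_equal(p1$patient_total, 2 * 3.68)
  expect_equal(p1$time_cost, 2 * (2.1 + 1.0))
  expect_equal(p1$travel_cost, 2 * 0.5)
  expect_equal(p1$inr_monitoring, 62)
  expect_equal(p1$patient_total,
               p1$time_cost + p1$travel_cost + p1$fees + p1$drug_patient)
  expect_equal(p1$combined_total, p1$patient_total + p1$healthcare_total)
  dup <- rbind(toy_daily(), toy_daily()[1])
  expect_error(per_patient_annual(dup), class = "af_validation_error")
})

test_that("inactive days accrue drug costs and zero-activity patients appear", {
  pats <- data.table(id = 1:3, arm = c("warfarin", "doac", "warfarin"))
  tot <- per_patient_annual(toy_daily(), pats, params, window_days = 365L)
  expect_equal(nrow(tot), 3L)
  # patient 3 has no records: pure drug costs
  p3 <- tot[patient_id == 3L]
  expect_equal(p3$patient_total, 365 * 0.08)
  expect_equal(p3$healthcare_total, 365 * 0.05)
  # patient 1 had 2 active days
  p1 <- tot[patient_id == 1L]
  expect_equal(p1$drug_patient, 365 * 0.08)
  expect_equal(p1$drug_society, 365 * 0.05)
})

test_that("group averages include zero-activity patients", {
  pats <- data.table(id = 1:3, arm = c("warfarin", "warfarin", "warfarin"))
  daily <- toy_daily()[patient_id == 1L]
  tot <- per_patient_annual(daily, pats, params)
  ga <- group_average(tot, arm = "warfarin")
  expect_equal(ga$s, 3L)
  expect_equal(ga$r_p, mean(tot$patient_total))
  expect_error(group_average(tot[0]), class = "af_validation_error")
  # one patient: the mean is that patient's totals
  one <- group_average(tot[patient_id == 1L])
  expect_equal(one$r_p, tot[patient_id == 1L]$patient_total)
  # two patients 100 and 300 average to 200
  t2 <- copy(tot[1:2])[, patient_total := c(100, 300)]
  expect_equal(group_average(t2)$r_p, 200)
})

test_that("identical groups compare with zero difference and p = 1", {
  pats <- data.table(id = 1:40, arm = rep(c("warfarin", "doac"), each = 20))
  set.seed(1)
  daily <- data.table(
    patient_id = rep(1:40, each = 2), date = rep(c(day, day + 1), 40),
    n_inr = 1L, c_m = 2, c_a = 1, c_t = 1, c_d = 1, c_p = 5,
    drug_patient = 0.5, fees_patient = 0.5, e_p = 10, e_s = 0, w_p = 0,
    w_s = 0, d_h = 1, k = 0, inr_cost = 31, other_society = 0,
    healthcare_total = 42)
  tot <- per_patient_annual(daily)
  tot <- merge(tot, pats[, .(patient_id = id, arm)], by = "patient_id")
  tab <- cost_table(group_summary(tot[arm == "warfarin"]),
                    group_summary(tot[arm == "doac"]))
  expect_true(all(abs(tab$difference) < 1e-12))
  expect_true(all(tab$p_value > 0.999))
  expect_equal(tab$difference, tab$warfarin_mean - tab$doac_mean)
  # Welch-t variant is also available and agrees on the null here
  tab_t <- cost_table(group_summary(tot[arm == "warfarin"]),
                      group_summary(tot[arm == "doac"]), p_method = "t")
  expect_true(all(tab_t$p_value > 0.999))
})

test_that("CI half-width shrinks like 1/sqrt(s)", {
  set.seed(7)
  x <- rnorm(6400, 100, 30)
  mk <- function(n) {
    data.table(patient_id = seq_len(n), patient_total = x[seq_len(n)],
               healthcare_total = 1, combined_total = 1 + x[seq_len(n)],
               time_travel_cost = 0, time_cost = 0, travel_cost = 0,
               fees = 0, drug_patient = 0, inr_monitoring = 0,
               primary_visit_cost = 0, specialised_visit_cost = 0,
               primary_ward_cost = 0, specialised_ward_cost = 0,
               drug_society = 0, society_travel_cost = 0, other_society = 0)
  }
  hw <- vapply(c(400, 1600, 6400), function(n) {
    s <- group_summary(mk(n))
    row <- s[component == "patient_total"]
    (row$ci_hi - row$ci_lo) / 2
  }, numeric(1))
  expect_equal(hw[1] / hw[2], 2, tolerance = 0.15)
  expect_equal(hw[2] / hw[3], 2, tolerance = 0.15)
})

test_that("utilisation table caps travel counts at visit counts", {
  sim <- af_simulate(cohort_config(n_warfarin = 30, n_doac = 10, seed = 13,
                                   other_contact_rate = 0),
                     geography_config(n_nodes = 100, n_labs = 4,
                                      n_health_centres = 3, seed = 13))
  contacts <- filter_af_contacts(sim$contacts)
  stubs <- afcost:::trip_plan(contacts)
  journeys <- resolve_journeys(stubs, sim$geography, sim$patients,
                               sim$reimbursements)
  ut <- utilisation_table(sim$patients, contacts, journeys, sim$geography)
  visits_w <- ut[arm == "warfarin" & variable == "visits"]$mean
  trips_w <- ut[arm == "warfarin" & variable == "travel_count"]$mean
  inr_w <- ut[arm == "warfarin" & variable == "inr"]$mean
  expect_lte(trips_w, visits_w)
  expect_gt(visits_w, inr_w - 1e-9)  # visits include INR contacts
  # empty contact stream: all-zero counts
  ut0 <- utilisation_table(sim$patients, contacts[0], journeys[0])
  expect_true(all(ut0[variable %in% c("visits", "inr", "travel_count")]$mean == 0))
})

test_that("report regeneration is byte-identical", {
  pats <- data.table(id = 1:10, arm = rep(c("warfarin", "doac"), 5))
  daily <- toy_daily()
  tot <- per_patient_annual(daily, pats, params)
  tab <- cost_table(group_summary(tot[arm == "warfarin"]),
                    group_summary(tot[arm == "doac"]))
  d1 <- tempfile(); d2 <- tempfile()
  write_cost_report(d1, tab)
  write_cost_report(d2, tab)
  f1 <- file.path(d1, "cost_table.csv"); f2 <- file.path(d2, "cost_table.csv")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(file.path(d1, "report.md")),
                   readLines(file.path(d2, "report.md")))
  unlink(c(d1, d2), recursive = TRUE)
})
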