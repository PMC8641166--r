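#' Synthetic cohort configuration
#'
#' Describes the statistical world the synthetic registry generator emulates:
#' a two-arm anticoagulation cohort with the published group sizes, age and
#' income moments, INR monitoring and visit rates, complication
#' probabilities, and the ~5% coverage of travel-reimbursement records.
#' Per-arm vectors are named `c(warfarin =, doac =)`. Count distributions
#' are negative binomial parameterised by `(mean, sd)` pairs (the published
#' utilisation table reports SD > mean throughout); a pair with
#' `sd^2 <= mean` falls back to Poisson.
#'
#' @param n_warfarin,n_doac Arm sizes (>= 0; 0 gives an empty arm).
#' @param age_mean,age_sd Age moments (years) per arm.
#' @param female_share Share of women per arm.
#' @param inr_mean,inr_sd Annual INR monitoring count moments per arm.
#' @param visit_rates Named list of `(mean, sd)` pairs per contact type and
#'   arm; see defaults for the shape.
#' @param complication_probs Named list per complication of per-arm annual
#'   event probabilities.
#' @param income_mean,income_sd Postal-area hourly income moments (EUR/h)
#'   per arm.
#' @param urban_share Share of patients with an urban residence per arm.
#' @param kela_coverage Share of eligible contacts carrying a
#'   travel-reimbursement record.
#' @param ambulance_record_prob Probability that an urgent emergency contact
#'   carries an ambulance reimbursement record (forced to 0 when
#'   `kela_coverage` is 0 so zero coverage really means no records).
#' @param home_inr_share Share of INR measurements taken at the patient's
#'   home (no travel; home-care fees apply).
#' @param other_contact_rate Annual rate of non-AF noise contacts (dropped by
#'   [filter_af_contacts()]).
#' @param unit_costs Named list of mean healthcare unit costs (EUR) per
#'   contact kind, drawn lognormally with coefficient of variation
#'   `unit_cost_cv`.
#' @param unit_cost_cv Coefficient of variation of healthcare unit costs.
#' @param attrition Named list of shares of generated patients given an
#'   exclusion trait (`nursing_home`, `out_of_district`, `deceased`,
#'   `late_rx`, `switch`); all default 0 so the default world passes
#'   selection intact.
#' @param seed Integer seed; all generator randomness flows from it through
#'   named child streams.
#' @return An object of class `af_cohort_config`.
#' @export
cohort_config <- function(n_warfarin = 3171L,
                          n_doac = 829L,
                          age_mean = c(warfarin = 76.0, doac = 72.7),
                          age_sd = c(warfarin = 9.2, doac = 9.8),
                          female_share = c(warfarin = 0.468, doac = 0.472),
                          inr_mean = c(warfarin = 17.5, doac = 0.1),
                          inr_sd = c(warfarin = 9.9, doac = 0.9),
                          visit_rates = list(
                            primary_visit = list(mean = c(warfarin = 0.2, doac = 0.2),
                                                 sd = c(warfarin = 0.8, doac = 0.8)),
                            specialised_visit = list(mean = c(warfarin = 0.2, doac = 0.3),
                                                     sd = c(warfarin = 0.7, doac = 0.9)),
                            primary_ward_day = list(mean = c(warfarin = 0.2, doac = 0.2),
                                                    sd = c(warfarin = 2.7, doac = 2.4)),
                            specialised_ward_day = list(mean = c(warfarin = 0.1, doac = 0.2),
                                                        sd = c(warfarin = 1.0, doac = 1.2)),
                            phone = list(mean = c(warfarin = 0.3, doac = 0.3),
                                         sd = c(warfarin = 0.7, doac = 0.7))),
                          complication_probs = list(
                            ischemic_stroke = c(warfarin = 0.005, doac = 0.005),
                            intracerebral_haemorrhage = c(warfarin = 0.0035, doac = 0.0),
                            gi_bleed = c(warfarin = 0.024, doac = 0.008)),
                          income_mean = c(warfarin = 12.0, doac = 12.3),
                          income_sd = c(warfarin = 1.0, doac = 1.2),
                          urban_share = c(warfarin = 0.723, doac = 0.685),
                          kela_coverage = 0.05,
                          ambulance_record_prob = 0.9,
                          home_inr_share = 0.02,
                          other_contact_rate = 0.5,
                          unit_costs = list(primary_visit = 65,
                                            specialised_visit = 300,
                                            emergency_visit = 300,
                                            primary_ward_day = 60,
                                            specialised_ward_day = 750,
                                            phone = 15),
                          unit_cost_cv = 0.6,
                          attrition = list(nursing_home = 0,
                                           out_of_district = 0,
                                           deceased = 0,
                                           late_rx = 0,
                                           switch = 0),
                          seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "af_cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  check_number(cfg$n_warfarin, "n_warfarin", min = 0, len = 1L)
  check_number(cfg$n_doac, "n_doac", min = 0, len = 1L)
  for (f in c("age_mean", "age_sd", "inr_mean", "inr_sd",
              "income_mean", "income_sd")) {
    check_number(cfg[[f]], f, min = 0, len = 2L)
    if (!all(c("warfarin", "doac") %in% names(cfg[[f]]))) {
      stop_af(sprintf("field '%s' must be named c(warfarin=, doac=)", f),
              "af_validation_error")
    }
  }
  for (f in c("female_share", "urban_share")) {
    check_number(cfg[[f]], f, min = 0, max = 1, len = 2L)
  }
  check_number(cfg$kela_coverage, "kela_coverage", min = 0, max = 1, len = 1L)
  check_number(cfg$ambulance_record_prob, "ambulance_record_prob",
               min = 0, max = 1, len = 1L)
  check_number(cfg$home_inr_share, "home_inr_share", min = 0, max = 1, len = 1L)
  check_number(cfg$other_contact_rate, "other_contact_rate", min = 0, len = 1L)
  for (k in names(cfg$visit_rates)) {
    check_number(cfg$visit_rates[[k]]$mean, paste0("visit_rates$", k, "$mean"),
                 min = 0, len = 2L)
    check_number(cfg$visit_rates[[k]]$sd, paste0("visit_rates$", k, "$sd"),
                 min = 0, len = 2L)
  }
  for (k in names(cfg$complication_probs)) {
    check_number(cfg$complication_probs[[k]],
                 paste0("complication_probs$", k), min = 0, max = 1, len = 2L)
  }
  for (k in names(cfg$attrition)) {
    check_number(cfg$attrition[[k]], paste0("attrition$", k),
                 min = 0, max = 1, len = 1L)
  }
  check_number(cfg$seed, "seed", len = 1L)
  cfg
}

#' Synthetic geography configuration
#'
#' The synthetic region is a set of town clusters over a square extent. Each
#' cluster is a handful of radial road "spokes"; satellite nodes sit on a
#' spoke at radial distances drawn as stratified quantiles of a lognormal
#' matched to the target distance-to-laboratory moments, so network distance
#' to the cluster centre equals the drawn radius. Laboratories and health
#' centres sit at cluster centres (laboratories are mainly co-located with
#' health stations), the single hospital at the centre node nearest the
#' regional centroid. Cluster centres are joined by a minimum spanning tree
#' of trunk roads.
#'
#' @param n_nodes Total node count (>= number of town centres).
#' @param n_labs Number of INR laboratories (>= 1).
#' @param n_health_centres Number of primary-care health centres.
#' @param bus_stop_density Probability that a satellite node hosts a bus
#'   stop (every cluster centre hosts one).
#' @param speed_limit_range `c(min, max)` km/h; edge speed limits grow with
#'   edge length inside this range.
#' @param extent Side of the square region, km.
#' @param dist_lab_mean,dist_lab_sd Target mean/SD (km) of the
#'   distance-to-nearest-laboratory distribution over candidate home nodes.
#' @param n_spokes Radial roads per town cluster.
#' @param seed Integer seed.
#' @return An object of class `af_geography_config`.
#' @export
geography_config <- function(n_nodes = 900L,
                             n_labs = 27L,
                             n_health_centres = 23L,
                             bus_stop_density = 0.3,
                             speed_limit_range = c(40, 100),
                             extent = 100,
                             dist_lab_mean = 5.5,
                             dist_lab_sd = 7.6,
                             n_spokes = 3L,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "af_geography_config"
  validate_geography_config(cfg)
}

validate_geography_config <- function(cfg) {
  check_number(cfg$n_nodes, "n_nodes", min = 1, len = 1L)
  check_number(cfg$n_labs, "n_labs", min = 1, len = 1L)
  check_number(cfg$n_health_centres, "n_health_centres", min = 0, len = 1L)
  check_number(cfg$bus_stop_density, "bus_stop_density", min = 0, max = 1, len = 1L)
  check_number(cfg$speed_limit_range, "speed_limit_range", min = 1, len = 2L)
  check_number(cfg$extent, "extent", min = 1, len = 1L)
  check_number(cfg$dist_lab_mean, "dist_lab_mean", min = 0.01, len = 1L)
  check_number(cfg$dist_lab_sd, "dist_lab_sd", min = 0.01, len = 1L)
  check_number(cfg$n_spokes, "n_spokes", min = 1, len = 1L)
  check_number(cfg$seed, "seed", len = 1L)
  n_centres <- max(cfg$n_labs, cfg$n_health_centres, 1)
  if (cfg$n_nodes < n_centres) {
    stop_af(sprintf(
      "field 'n_nodes' (%d) too small for %d facility town centres",
      cfg$n_nodes, n_centres), "af_validation_error")
  }
  cfg
}
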