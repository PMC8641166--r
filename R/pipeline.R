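#' Run the full cost-model pipeline
#'
#' Chains every stage: synthetic data generation, cohort selection,
#' AF-contact filtering, trip planning, journey routing and mode
#' assignment, daily cost composition, annual aggregation and the two-arm
#' comparison tables.
#'
#' @param cohort_cfg An [cohort_config()].
#' @param geo_cfg An [geography_config()].
#' @param params [cost_parameters()].
#' @param seed Optional seed overriding both configs.
#' @param p_method p-value method for [cost_table()].
#' @return A list: `geography`, `patients`, `contacts` (filtered),
#'   `reimbursements`, `cohort` (selected arms + attrition), `journeys`,
#'   `daily`, `totals` (per patient), `cost_table`, `utilisation`,
#'   `group_averages`.
#' @examples
#' \donttest{
#' res <- af_run(cohort_config(n_warfarin = 40, n_doac = 10, seed = 3),
#'               geography_config(n_nodes = 80, n_labs = 4,
#'                                n_health_centres = 3, seed = 3))
#' res$cost_table[res$cost_table$component == "patient_total", ]
#' }
#' @export
af_run <- function(cohort_cfg = cohort_config(),
                   geo_cfg = geography_config(),
                   params = cost_parameters(),
                   seed = NULL,
                   p_method = "z") {
  if (!is.null(seed)) {
    cohort_cfg$seed <- seed
    geo_cfg$seed <- seed
  }
  sim <- af_simulate(cohort_cfg, geo_cfg)
  sel <- select_cohort(sim$patients)
  cohort <- rbind(sel$warfarin, sel$doac)
  contacts <- filter_af_contacts(sim$contacts[patient_id %in% cohort$id])
  contacts <- process_fees(contacts, params)
  reimb <- sim$reimbursements[patient_id %in% cohort$id &
                                contact_id %in% contacts$id]

  stubs <- trip_plan(contacts)
  journeys <- resolve_journeys(stubs, sim$geography, cohort, reimb)
  daily <- compute_daily_costs(cohort, contacts, journeys, reimb, params)
  totals <- per_patient_annual(daily, cohort, params,
                               window_days = af_study_window()$days)
  warf <- totals[arm == "warfarin"]
  doac <- totals[arm == "doac"]
  ct <- if (nrow(warf) > 0L && nrow(doac) > 0L) {
    cost_table(group_summary(warf), group_summary(doac), p_method = p_method)
  } else NULL
  util <- utilisation_table(cohort, contacts, journeys, sim$geography)
  list(geography = sim$geography, patients = sim$patients,
       contacts = contacts, reimbursements = reimb,
       cohort = sel, journeys = journeys, daily = daily, totals = totals,
       cost_table = ct, utilisation = util,
       group_averages = list(
         warfarin = if (nrow(warf)) group_average(warf) else NULL,
         doac = if (nrow(doac)) group_average(doac) else NULL))
}

#' Command-line interface
#'
#' Thin wrapper exposing `simulate`, `route`, `run` and `report`
#' subcommands, e.g.
#' `Rscript -e 'afcost::afcost_cli()' run --seed 1 --out results/`.
#' Configs may be supplied as YAML/JSON files whose fields override the
#' defaults of [cohort_config()], [geography_config()] and
#' [cost_parameters()].
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return Exit status, invisibly.
#' @export
afcost_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: afcost <simulate|route|run> [options]",
    "  simulate --seed N --out DIR [--config FILE] [--geo FILE]",
    "  route    --from NODE --to NODE --mode MODE [--geo FILE] [--seed N]",
    "  run      --seed N --out DIR [--config FILE] [--geo FILE] [--params FILE]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- parse_cli_opts(args[-1L])
  seed <- as.integer(opts$seed %||% 1L)
  read_cfg <- function(path, ctor) {
    if (is.null(path)) return(ctor())
    raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
      jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(ctor, raw)
  }
  ccfg <- read_cfg(opts$config, cohort_config)
  gcfg <- read_cfg(opts$geo, geography_config)
  if (cmd == "simulate") {
    sim <- af_simulate(ccfg, gcfg, seed = seed)
    write_synthetic_data(sim, opts$out %||% ".")
    message(sprintf("wrote synthetic data for %d patients to %s",
                    nrow(sim$patients), opts$out %||% "."))
  } else if (cmd == "route") {
    geo <- generate_geography(gcfg)
    r <- fastest_route(geo, as.integer(opts$from), as.integer(opts$to),
                       opts$mode %||% "car")
    message(sprintf("%.2f km, %.3f h", r$distance_km, r$travel_time_h))
  } else if (cmd == "run") {
    params <- if (is.null(opts$params)) cost_parameters() else
      read_cost_parameters(opts$params)
    res <- af_run(ccfg, gcfg, params, seed = seed)
    out <- opts$out %||% "."
    write_cost_report(out, res$cost_table, res$utilisation,
                      res$cohort$attrition)
    fwrite(res$daily, file.path(out, "daily_costs.csv"))
    message(sprintf("report written to %s", out))
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
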