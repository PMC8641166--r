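library(data.table)

## ---- independent routing oracle -------------------------------------------
## Exhaustive enumeration of all simple paths (plain-R DFS, no igraph):
## the oracle against which fastest_route() is checked.

oracle_speed_cap <- function(mode) {
  switch(mode, walking = 4, bus = 30, Inf)
}

brute_force_fastest <- function(nodes, edges, origin, dest, mode) {
  cap <- oracle_speed_cap(mode)
  adj <- vector("list", max(nodes$id))
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    t <- edges$length_km[i] / min(edges$speed_limit[i], cap)
    adj[[a]] <- rbind(adj[[a]], c(b, t, edges$length_km[i]))
    adj[[b]] <- rbind(adj[[b]], c(a, t, edges$length_km[i]))
  }
  best <- list(time = Inf, dist = Inf)
  visited <- rep(FALSE, max(nodes$id))
  dfs <- function(v, t_acc, d_acc) {
    if (v == dest) {
      if (t_acc < best$time) best <<- list(time = t_acc, dist = d_acc)
      return(invisible())
    }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (!is.null(nb)) {
      for (i in seq_len(nrow(nb))) {
        w <- nb[i, 1]
        if (!visited[w]) dfs(w, t_acc + nb[i, 2], d_acc + nb[i, 3])
      }
    }
    visited[v] <<- FALSE
  }
  if (origin == dest) return(list(time = 0, dist = 0))
  dfs(origin, 0, 0)
  best
}

## random connected geography: spanning tree + extra edges
random_test_geography <- function(n, extra_edges = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- data.table(id = seq_len(n), x = runif(n, 0, 20), y = runif(n, 0, 20))
  edges <- data.table(from = integer(0), to = integer(0))
  if (n > 1L) {
    to <- 2:n
    from <- vapply(to, function(v) sample.int(v - 1L, 1L), integer(1))
    edges <- data.table(from = from, to = to)
    for (i in seq_len(extra_edges)) {
      p <- sample.int(n, 2L)
      if (p[1] != p[2] &&
          !any((edges$from == min(p) & edges$to == max(p)) |
               (edges$from == max(p) & edges$to == min(p)))) {
        edges <- rbind(edges, data.table(from = p[1], to = p[2]))
      }
    }
  }
  edges[, length_km := round(runif(.N, 0.5, 30), 2)]
  edges[, speed_limit := sample(c(40, 60, 80, 100), .N, replace = TRUE)]
  facilities <- data.table(
    id = 1:2, kind = c("lab", "hospital"),
    node = c(1L, n), bus_accessible = TRUE)
  geography(nodes, edges, facilities, bus_stops = integer(0))
}

## two-node geography with one edge: the minimal hand-checkable network
two_node_geography <- function(length_km = 10, speed_limit = 50) {
  geography(
    nodes = data.table(id = 1:2, x = c(0, length_km), y = 0),
    edges = data.table(from = 1L, to = 2L, length_km = length_km,
                       speed_limit = speed_limit),
    facilities = data.table(id = 1:2, kind = c("lab", "hospital"),
                            node = c(1L, 2L), bus_accessible = TRUE),
    bus_stops = integer(0))
}

## a patient row as the cost engine expects it
test_patient <- function(id = 1L, arm = "warfarin", age = 70,
                         hourly_income = 12, home_node = 1L) {
  list(id = id, arm = arm, age = age, hourly_income = hourly_income,
       wage_coef = wage_coefficient(age), home_node = home_node)
}

## contact rows with defaults
make_contacts <- function(patient_id, dates, kinds, facility_id = 2L,
                          diagnosis_class = "af", urgent = FALSE,
                          home = FALSE, unit_cost = 100) {
  n <- max(length(dates), length(kinds))
  data.table(
    id = seq_len(n), patient_id = patient_id, date = as.Date(dates),
    kind = rep_len(kinds, n), urgent = rep_len(urgent, n),
    diagnosis_class = rep_len(diagnosis_class, n),
    facility_id = rep_len(facility_id, n), home = rep_len(home, n),
    healthcare_unit_cost = rep_len(unit_cost, n))
}

## the published annual comparison table (EUR), used as a reporting fixture
reference_cost_table <- function() {
  rbindlist(list(
    list("healthcare_total",       805.2, 1118.7, 927.3, 1150.9, -122.1),
    list("patient_total",          296.7,  256.3, 406.5,  132.8, -109.8),
    list("combined_total",        1102.0, 1272.2, 1333.8, 1250.8, -231.8),
    list("time_travel_cost",       195.6,  221.8,  17.5,   61.5,  178.1),
    list("time_cost",               79.5,   84.4,   3.3,   11.2,   76.2),
    list("travel_cost",            118.2,  168.1,  14.3,   52.4,  103.9),
    list("fees",                    74.0,  155.0,  29.2,   88.0,   44.8),
    list("drug_patient",            27.0,    0.0, 359.8,   10.4, -332.8),
    list("inr_monitoring",         519.2,  296.2,   4.3,   14.1,  514.9),
    list("primary_visit_cost",      12.7,   51.7,  16.6,   47.5,   -3.9),
    list("specialised_visit_cost",  61.1,  303.9, 100.3,  608.5,  -39.2),
    list("primary_ward_cost",       12.2,  130.2,  13.9,  122.4,   -1.7),
    list("specialised_ward_cost",   78.6,  706.7,  88.4,  781.0,   -9.8),
    list("drug_society",            18.0,    0.0, 668.2,   19.4, -650.2),
    list("society_travel_cost",     99.3,  305.4,  26.5,  110.8,   72.8)
  ))[, setNames(.SD, c("component", "warfarin_mean", "warfarin_sd",
                       "doac_mean", "doac_sd", "difference"))]
}
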