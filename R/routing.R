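## Road-network geography and fastest-route analysis.
##
## The geography is an undirected road graph (edge lengths in km, speed
## limits in km/h) plus facility placements (INR laboratories, health
## centres, one central hospital) and bus stops. Routing minimises travel
## time, where the speed on an edge is min(speed limit, mode cap):
## walking 4 km/h flat, bus 30 km/h flat, car/taxi/ambulance drive at the
## speed limit. This stands in for the origin-destination cost-matrix
## network analysis used on the real road network.

AF_MODES <- c("car", "taxi", "walking", "bus", "ambulance")

mode_speed_cap <- function(mode) {
  caps <- c(car = Inf, taxi = Inf, ambulance = Inf, bus = 30, walking = 4)
  if (!mode %in% names(caps)) {
    stop_af(sprintf("unknown travel mode '%s'", mode), "af_mode_error")
  }
  caps[[mode]]
}

#' Construct a geography object
#'
#' @param nodes `data.frame` with columns `id` (integer), `x`, `y` (planar
#'   km coordinates).
#' @param edges `data.frame` with columns `from`, `to` (node ids),
#'   `length_km` (> 0) and `speed_limit` (km/h, > 0); undirected.
#' @param facilities `data.frame` with columns `id`, `kind` (one of `"lab"`,
#'   `"health_centre"`, `"hospital"`), `node`, `bus_accessible` (logical).
#'   Exactly one hospital; at least one laboratory.
#' @param bus_stops Integer vector of node ids hosting a bus stop (may be
#'   empty).
#' @return An object of class `af_geography`.
#' @export
geography <- function(nodes, edges, facilities, bus_stops = integer(0)) {
  nodes <- as.data.table(nodes)
  edges <- as.data.table(edges)
  facilities <- as.data.table(facilities)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("from", "to", "length_km", "speed_limit") %in% names(edges)),
            all(c("id", "kind", "node", "bus_accessible") %in% names(facilities)))
  if (nrow(edges) > 0 && (any(edges$length_km <= 0) || any(edges$speed_limit <= 0))) {
    stop_af("edge lengths and speed limits must be positive", "af_validation_error")
  }
  if (!all(facilities$kind %in% c("lab", "health_centre", "hospital"))) {
    stop_af("facility kind must be lab, health_centre or hospital",
            "af_validation_error")
  }
  if (sum(facilities$kind == "hospital") != 1L) {
    stop_af("geography must contain exactly one hospital", "af_validation_error")
  }
  if (sum(facilities$kind == "lab") < 1L) {
    stop_af("geography must contain at least one laboratory", "af_validation_error")
  }
  if (!all(facilities$node %in% nodes$id) ||
      !all(c(edges$from, edges$to) %in% nodes$id) ||
      !all(bus_stops %in% nodes$id)) {
    stop_af("facility, edge or bus-stop node ids missing from node table",
            "af_validation_error")
  }
  g <- igraph::graph_from_data_frame(
    edges[, .(from = as.character(from), to = as.character(to),
              length_km, speed_limit)],
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  if (nrow(nodes) > 1L && igraph::components(g)$no != 1L) {
    stop_af("road network must be connected", "af_validation_error")
  }
  structure(list(nodes = nodes, edges = edges, facilities = facilities,
                 bus_stops = as.integer(bus_stops), graph = g),
            class = "af_geography")
}

#' @export
print.af_geography <- function(x, ...) {
  cat(sprintf("<af_geography> %d nodes, %d edges, %d labs, %d health centres, %d bus stops\n",
              nrow(x$nodes), nrow(x$edges), sum(x$facilities$kind == "lab"),
              sum(x$facilities$kind == "health_centre"), length(x$bus_stops)))
  invisible(x)
}

edge_time_weights <- function(geo, mode) {
  cap <- mode_speed_cap(mode)
  len <- igraph::E(geo$graph)$length_km
  spd <- pmin(igraph::E(geo$graph)$speed_limit, cap)
  len / spd
}

node_index <- function(geo, node) {
  idx <- match(as.character(node), igraph::V(geo$graph)$name)
  if (anyNA(idx)) {
    stop_af(sprintf("node(s) %s not in geography",
                    paste(node[is.na(idx)], collapse = ", ")),
            "af_validation_error")
  }
  idx
}

#' Fastest route between two network nodes
#'
#' Minimises total travel time over paths, with per-edge speed
#' `min(speed limit, mode cap)`; walking is capped at 4 km/h and bus at
#' 30 km/h, while car, taxi and ambulance drive at the speed limit. The
#' returned distance is measured along the time-optimal path. Parking and
#' service time penalties are *not* included here (they are applied per leg
#' by the cost engine).
#'
#' @param geo An [geography()] object.
#' @param origin,destination Node ids.
#' @param mode One of `"car"`, `"taxi"`, `"walking"`, `"bus"`, `"ambulance"`.
#' @return A list of class `af_route` with `distance_km`, `travel_time_h`
#'   and `path` (node id sequence).
#' @examples
#' geo <- generate_geography(geography_config(n_nodes = 30, seed = 7))
#' fastest_route(geo, geo$nodes$id[1], geo$nodes$id[5], "car")
#' @export
fastest_route <- function(geo, origin, destination, mode) {
  stopifnot(inherits(geo, "af_geography"))
  oi <- node_index(geo, origin)
  di <- node_index(geo, destination)
  if (oi == di) {
    return(structure(list(distance_km = 0, travel_time_h = 0,
                          path = as.integer(origin)), class = "af_route"))
  }
  w <- edge_time_weights(geo, mode)
  sp <- suppressWarnings(igraph::shortest_paths(
    geo$graph, from = oi, to = di, weights = w, output = "both"))
  if (length(sp$vpath[[1]]) == 0L) {
    stop_af(sprintf("nodes %s and %s are not connected", origin, destination),
            "af_unreachable_error")
  }
  eids <- sp$epath[[1]]
  structure(list(
    distance_km = sum(igraph::E(geo$graph)$length_km[eids]),
    travel_time_h = sum(w[eids]),
    path = as.integer(igraph::V(geo$graph)$name[sp$vpath[[1]]])),
    class = "af_route")
}

#' @export
print.af_route <- function(x, ...) {
  cat(sprintf("<af_route> %.2f km, %.3f h, %d nodes\n",
              x$distance_km, x$travel_time_h, length(x$path)))
  invisible(x)
}

## Batched routing: time and along-path distance from each origin to each
## target under one mode profile. One shortest_paths() call per unique origin.
route_matrix <- function(geo, origins, targets, mode) {
  w <- edge_time_weights(geo, mode)
  len <- igraph::E(geo$graph)$length_km
  uo <- unique(origins)
  ti <- node_index(geo, targets)
  tm <- matrix(Inf, length(uo), length(targets),
               dimnames = list(as.character(uo), as.character(targets)))
  dm <- tm
  for (i in seq_along(uo)) {
    oi <- node_index(geo, uo[i])
    sp <- suppressWarnings(igraph::shortest_paths(
      geo$graph, from = oi, to = ti, weights = w, output = "epath"))
    for (j in seq_along(ti)) {
      eids <- sp$epath[[j]]
      if (oi == ti[j]) {
        tm[i, j] <- 0; dm[i, j] <- 0
      } else if (length(eids) > 0L) {
        tm[i, j] <- sum(w[eids]); dm[i, j] <- sum(len[eids])
      }
    }
  }
  list(time = tm[as.character(origins), , drop = FALSE],
       dist = dm[as.character(origins), , drop = FALSE])
}

#' Closest INR laboratory from a home node
#'
#' The comparison metric is the car-profile fastest travel time (time is the
#' route optimisation criterion throughout the model); ties are broken by the
#' lowest facility id.
#'
#' @inheritParams fastest_route
#' @param home_node Node id of the patient's residence.
#' @return A list with `facility` (one-row `data.table`) and `route`
#'   (the car-profile [fastest_route()] result).
#' @export
closest_laboratory <- function(geo, home_node) {
  stopifnot(inherits(geo, "af_geography"))
  labs <- geo$facilities[kind == "lab"]
  if (nrow(labs) == 0L) stop_af("geography has no laboratories", "af_validation_error")
  labs <- labs[order(id)]
  rm_ <- route_matrix(geo, home_node, labs$node, "car")
  times <- rm_$time[1L, ]
  if (all(is.infinite(times))) {
    stop_af("no laboratory reachable from home node", "af_unreachable_error")
  }
  best <- which.min(times)  # first minimum = lowest facility id after ordering
  list(facility = labs[best],
       route = fastest_route(geo, home_node, labs$node[best], "car"))
}

## Vectorised variant used by the pipeline: nearest-lab facility id, node and
## car time/distance for each home node.
closest_lab_table <- function(geo, home_nodes) {
  labs <- geo$facilities[kind == "lab"][order(id)]
  uh <- unique(home_nodes)
  rm_ <- route_matrix(geo, uh, labs$node, "car")
  best <- apply(rm_$time, 1L, which.min)
  data.table(home_node = uh,
             lab_id = labs$id[best],
             lab_node = labs$node[best],
             lab_time_h = rm_$time[cbind(seq_along(uh), best)],
             lab_dist_km = rm_$dist[cbind(seq_along(uh), best)])
}

#' Network distance to the nearest bus stop
#'
#' Shortest network *distance* (km, not time) from a home node to the nearest
#' bus stop; `Inf` when the geography has no stops.
#'
#' @inheritParams closest_laboratory
#' @return Distance in km (vectorised over `home_node`).
#' @export
bus_access_distance <- function(geo, home_node) {
  stopifnot(inherits(geo, "af_geography"))
  if (length(geo$bus_stops) == 0L) return(rep(Inf, length(home_node)))
  d <- igraph::distances(geo$graph,
                         v = node_index(geo, home_node),
                         to = node_index(geo, geo$bus_stops),
                         weights = igraph::E(geo$graph)$length_km)
  unname(apply(d, 1L, min))
}
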