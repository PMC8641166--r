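#' Generate a synthetic road-network geography
#'
#' Builds the town-cluster road network described in [geography_config()]:
#' cluster centres over the square extent, satellite nodes on radial spokes
#' whose radii are stratified lognormal quantiles matched to the target
#' distance-to-laboratory moments, trunk roads joining cluster centres via a
#' minimum spanning tree, laboratories/health centres at centres and the
#' hospital at the centre nearest the regional centroid. The node table
#' carries the derived columns `dist_lab_km`, `nearest_lab` and `nearest_hc`
#' used by the cohort generator and the utilisation report.
#'
#' @param config An [geography_config()] object.
#' @return An [geography()] object.
#' @examples
#' geo <- generate_geography(geography_config(n_nodes = 60, n_labs = 3,
#'                                            n_health_centres = 2, seed = 2))
#' geo
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "af_geography_config"))
  validate_geography_config(config)
  geo <- with_stream(config$seed, "geography", build_geography(config))
  attr(geo, "dist_lab_mean") <- config$dist_lab_mean
  attr(geo, "dist_lab_sd") <- config$dist_lab_sd
  geo
}

build_geography <- function(cfg) {
  nc <- as.integer(max(cfg$n_labs, cfg$n_health_centres, 1))
  n_sat <- as.integer(cfg$n_nodes) - nc
  lp <- lnorm_pars(cfg$dist_lab_mean, cfg$dist_lab_sd)

  ## town centres, away from the border
  cx <- runif(nc, 0.08, 0.92) * cfg$extent
  cy <- runif(nc, 0.08, 0.92) * cfg$extent

  ## satellite radii: stratified conditional means of the target lognormal
  ## (one node per probability stratum). Midpoint quantiles would bias the
  ## sample mean low under the heavy right tail; the conditional stratum
  ## mean E[X | q_{i-1} < F(X) <= q_i] keeps the node-distance mean on
  ## target, which the cohort generator's inverse-CDF matching inherits.
  radii <- numeric(0)
  if (n_sat > 0L) {
    zlo <- qnorm((seq_len(n_sat) - 1) / n_sat)
    zhi <- qnorm(seq_len(n_sat) / n_sat)
    m_raw <- exp(lp$meanlog + lp$sdlog^2 / 2)
    radii <- n_sat * m_raw * (pnorm(lp$sdlog - zlo) - pnorm(lp$sdlog - zhi))
    radii <- pmin(radii, 1.5 * cfg$extent)
    if (n_sat > 1L) radii <- sample(radii)  # sample(x) misbehaves at length 1
    cluster <- rep_len(seq_len(nc), n_sat)
    spoke <- (sample.int(cfg$n_spokes, n_sat, replace = TRUE))
  }

  nodes <- data.table(id = seq_len(nc), x = cx, y = cy,
                      cluster = seq_len(nc), radius = 0)
  edges_list <- list()
  if (n_sat > 0L) {
    angles <- matrix(runif(nc * cfg$n_spokes, 0, 2 * pi), nc, cfg$n_spokes)
    sat <- data.table(id = nc + seq_len(n_sat), cluster = cluster,
                      spoke = spoke, radius = radii)
    sat[, `:=`(x = cx[cluster] + radius * cos(angles[cbind(cluster, spoke)]),
               y = cy[cluster] + radius * sin(angles[cbind(cluster, spoke)]))]
    ## chain each spoke outward: consecutive radii, innermost to the centre
    setorder(sat, cluster, spoke, radius)
    sat[, prev_id := shift(id), by = .(cluster, spoke)]
    sat[, prev_radius := shift(radius, fill = 0), by = .(cluster, spoke)]
    sat[is.na(prev_id), prev_id := cluster]
    edges_list$spokes <- sat[, .(from = prev_id, to = id,
                                 length_km = pmax(radius - prev_radius, 0.05))]
    nodes <- rbind(nodes, sat[, .(id, x, y, cluster, radius)])
    setorder(nodes, id)
  }

  ## trunk roads: MST over centres
  if (nc > 1L) {
    dmat <- as.matrix(stats::dist(cbind(cx, cy)))
    gfull <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                 weighted = TRUE)
    mst <- igraph::mst(gfull)
    el <- igraph::as_edgelist(mst, names = FALSE)
    edges_list$trunk <- data.table(from = el[, 1L], to = el[, 2L],
                                   length_km = igraph::E(mst)$weight)
  }
  edges <- rbindlist(edges_list)
  if (nrow(edges) == 0L && nrow(nodes) > 1L) {
    stop_af("degenerate geography: no edges generated", "af_validation_error")
  }
  ## speed limits grow with edge length (urban streets vs trunk roads)
  sl <- ifelse(edges$length_km < 2, 40,
               ifelse(edges$length_km < 10, 60,
                      ifelse(edges$length_km < 30, 80, 100)))
  edges[, speed_limit := pmin(pmax(sl, cfg$speed_limit_range[1]),
                              cfg$speed_limit_range[2])]

  ## facilities: labs and health centres at centres, hospital nearest centroid
  lab_nodes <- seq_len(cfg$n_labs)
  hc_nodes <- if (cfg$n_health_centres > 0) seq_len(cfg$n_health_centres) else integer(0)
  centroid <- c(mean(nodes$x), mean(nodes$y))
  hosp_node <- which.min((cx - centroid[1])^2 + (cy - centroid[2])^2)
  facilities <- rbind(
    data.table(id = seq_along(lab_nodes), kind = "lab", node = lab_nodes),
    if (length(hc_nodes)) data.table(id = length(lab_nodes) + seq_along(hc_nodes),
                                     kind = "health_centre", node = hc_nodes),
    data.table(id = length(lab_nodes) + length(hc_nodes) + 1L,
               kind = "hospital", node = hosp_node))
  facilities[, bus_accessible := TRUE]  # facilities sit at town centres

  ## bus stops: all centres plus a share of satellites
  stops <- seq_len(nc)
  if (n_sat > 0L && cfg$bus_stop_density > 0) {
    extra <- nodes$id[nodes$id > nc][
      rbinom(n_sat, 1L, cfg$bus_stop_density) == 1L]
    stops <- sort(c(stops, extra))
  }

  geo <- geography(nodes[, .(id, x, y)], edges, facilities, stops)

  ## derived columns: network distance (km) to nearest lab / health centre
  wlen <- igraph::E(geo$graph)$length_km
  dlab <- igraph::distances(geo$graph, v = node_index(geo, nodes$id),
                            to = node_index(geo, lab_nodes), weights = wlen)
  geo$nodes[, dist_lab_km := apply(dlab, 1L, min)]
  geo$nodes[, nearest_lab := facilities[kind == "lab"]$id[apply(dlab, 1L, which.min)]]
  if (length(hc_nodes)) {
    dhc <- igraph::distances(geo$graph, v = node_index(geo, nodes$id),
                             to = node_index(geo, hc_nodes), weights = wlen)
    geo$nodes[, nearest_hc := facilities[kind == "health_centre"]$id[apply(dhc, 1L, which.min)]]
  } else {
    geo$nodes[, nearest_hc := NA_integer_]
  }
  geo
}
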