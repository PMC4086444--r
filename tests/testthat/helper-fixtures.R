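# Fixture builders and independent oracles used across the suite.

R_EARTH <- 6371000

# areas strung along a meridian at given km marks (1 deg lat = pi*R/180 m)
line_city <- function(km = c(0, 1, 3, 7), pop = rep(10, length(km)),
                      ids = sprintf("L%d", seq_along(km))) {
  location_table(data.frame(
    area_id = ids,
    lat = km * 1000 / (pi * R_EARTH / 180),
    lon = 0,
    population = pop,
    stringsAsFactors = FALSE))
}

# dense single-cluster city (every area in the urban core)
urban_city <- function(n, seed, ...) {
  generate_city(city_spec(n_areas = n, seed = seed, urban_fraction = 1, ...))
}

mk_problem <- function(city, k, s, epsilon, variant = "revised") {
  nm <- nearest_neighbors(city, k)
  suppressWarnings(deid_problem(city, nm, s, epsilon, variant))
}

# hand-built transition matrix for audit / relocation tests
tm_from_entries <- function(origin, dest, prob) {
  structure(list(entries = data.frame(origin_id = origin, dest_id = dest,
                                      probability = prob,
                                      stringsAsFactors = FALSE),
                 objective_m = NA_real_, status = "optimal", meta = list()),
            class = "transition_matrix")
}

identity_tm <- function(locations) {
  tm_from_entries(locations$area_id, locations$area_id,
                  rep(1, nrow(locations)))
}

# independently coded spherical-law-of-cosines distance (oracle)
slc_m <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  x <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R_EARTH * acos(pmin(1, pmax(-1, x)))
}

# brute-force nearest-k from the all-pairs distance matrix (oracle)
brute_knn <- function(locations, k) {
  n <- nrow(locations)
  loc <- locations[order(locations$area_id), ]
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_m(loc$lat[i], loc$lon[i], loc$lat[j], loc$lon[j]))
  diag(d) <- 0
  do.call(rbind, lapply(seq_len(n), function(i) {
    o <- order(d[i, ], loc$area_id)[seq_len(k)]
    data.frame(origin_id = loc$area_id[i], dest_id = loc$area_id[o],
               distance_m = d[i, o], stringsAsFactors = FALSE)
  }))
}

expect_rel_equal <- function(a, b, tol = 1e-6) {
  expect_lte(abs(a - b), tol * max(1, abs(a), abs(b)))
}
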