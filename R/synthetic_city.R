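#' Specify a synthetic city
#'
#' Describes a fixture geography with the statistical structure of a real
#' small-area postal geography: a dense urban core of moderately populated
#' codes surrounded by a sparse periphery of tiny-population codes.  The
#' defaults target an overall median area population of about 10 with a long
#' right tail, so that almost every area holds fewer people than a typical
#' patient cohort — the regime in which the classic de-identification LP
#' breaks down and the revised model is needed.
#'
#' @param n_areas Number of areas (`>= 2`); default 1000.
#' @param bbox Named numeric vector `c(lat_min, lat_max, lon_min, lon_max)`;
#'   default an Ottawa-sized box.
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @param urban_fraction Share of areas placed inside the dense core
#'   (default 0.7).
#' @param core_fraction Side length of the core box as a fraction of each
#'   bbox side, centered (default 0.12).
#' @param urban_median Median of the heavy-tailed (log-normal) urban
#'   population draw before the +1 shift (default 16; must be `>= 1`).
#' @param urban_sdlog Log-scale spread of the urban draw (default 0.9).
#' @param rural_mean Mean of the Poisson rural population draw before the
#'   +1 shift (default 1.5).
#' @return A `city_spec` list.
#' @export
city_spec <- function(n_areas = 1000,
                      bbox = c(lat_min = 45.0, lat_max = 45.6,
                               lon_min = -76.4, lon_max = -75.2),
                      seed = 1L,
                      urban_fraction = 0.7, core_fraction = 0.12,
                      urban_median = 16, urban_sdlog = 0.9,
                      rural_mean = 1.5) {
  if (n_areas < 2) stop("n_areas must be >= 2")
  need <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(need %in% names(bbox))) stop("bbox must name ", paste(need, collapse = ", "))
  if (bbox[["lat_max"]] <= bbox[["lat_min"]] ||
      bbox[["lon_max"]] <= bbox[["lon_min"]])
    stop("bbox is degenerate")
  if (urban_median < 1) stop("target median population below 1 is infeasible")
  if (urban_fraction < 0 || urban_fraction > 1)
    stop("urban_fraction must be in [0, 1]")
  if (rural_mean < 0) stop("rural_mean must be >= 0")
  structure(list(n_areas = as.integer(n_areas), bbox = bbox,
                 seed = as.integer(seed), urban_fraction = urban_fraction,
                 core_fraction = core_fraction, urban_median = urban_median,
                 urban_sdlog = urban_sdlog, rural_mean = rural_mean),
            class = "city_spec")
}

with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Generate a synthetic city
#'
#' Draws `urban_fraction` of the areas uniformly inside the central core box
#' with populations `1 + floor(lognormal)` (median about `urban_median`),
#' and the rest uniformly over the whole bounding box with populations
#' `1 + Poisson(rural_mean)` (mostly 1–5 people).  Identical specs produce
#' identical tables.
#'
#' @param spec A [city_spec()].
#' @return A [location_table()] with area ids `A00001`, `A00002`, ...
#' @export
generate_city <- function(spec) {
  stopifnot(inherits(spec, "city_spec"))
  b <- spec$bbox
  n_urb <- round(spec$urban_fraction * spec$n_areas)
  n_rur <- spec$n_areas - n_urb
  latc <- (b[["lat_min"]] + b[["lat_max"]]) / 2
  lonc <- (b[["lon_min"]] + b[["lon_max"]]) / 2
  dlat <- (b[["lat_max"]] - b[["lat_min"]]) * spec$core_fraction / 2
  dlon <- (b[["lon_max"]] - b[["lon_min"]]) * spec$core_fraction / 2
  with_preserved_rng({
    set.seed(spec$seed)
    lat <- c(stats::runif(n_urb, latc - dlat, latc + dlat),
             stats::runif(n_rur, b[["lat_min"]], b[["lat_max"]]))
    lon <- c(stats::runif(n_urb, lonc - dlon, lonc + dlon),
             stats::runif(n_rur, b[["lon_min"]], b[["lon_max"]]))
    pop <- c(1 + floor(stats::rlnorm(n_urb, log(spec$urban_median),
                                     spec$urban_sdlog)),
             1 + stats::rpois(n_rur, spec$rural_mean))
    location_table(data.frame(
      area_id = sprintf("A%05d", seq_len(spec$n_areas)),
      lat = lat, lon = lon, population = pop, stringsAsFactors = FALSE))
  })
}

#' Sample a patient cohort from a city
#'
#' Draws `s` distinct residents uniformly from the population universe, so
#' origin counts follow the population-weighted (multivariate
#' hypergeometric) law with expectation \eqn{s\, n_i / N}, and no origin can
#' receive more patients than it has residents.
#'
#' @param locations A [location_table()].
#' @param s Number of patients (`1 <= s <= N`).
#' @param seed Integer seed; deterministic per seed.
#' @return A [patient_list()] with ids `P0001`, `P0002`, ...
#' @export
sample_patients <- function(locations, s, seed) {
  stopifnot(inherits(locations, "location_table"))
  N <- total_population(locations)
  if (s < 1 || s != round(s)) stop("s must be a positive integer")
  if (s > N) stop("more patients than people: s = ", s, " > N = ", N)
  with_preserved_rng({
    set.seed(as.integer(seed))
    persons <- rep(locations$area_id, locations$population)
    origins <- sample(persons, s)
    patient_list(data.frame(
      patient_id = sprintf("P%05d", seq_len(s)),
      area_id = origins, stringsAsFactors = FALSE), locations)
  })
}
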