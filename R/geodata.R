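#' Construct a validated location table
#'
#' A location table is the universe of areal units (postal/ZIP codes or
#' similar) among which patients may be relocated.  Each area is represented
#' by its centroid and its resident population count \eqn{n_i}; the total
#' population \eqn{N = \sum_i n_i} is derived.
#'
#' @param x A data frame with columns `area_id`, `lat`, `lon`, `population`.
#' @return An object of class `location_table` (a data frame) with attribute
#'   `N`, the total population.
#' @details Validation enforces: unique `area_id`; `population >= 1` for every
#'   area; latitudes in \eqn{[-90, 90]} and longitudes in \eqn{(-180, 180]}.
#'   Population counts must be whole numbers.
#' @seealso [load_locations()], [nearest_neighbors()]
#' @export
location_table <- function(x) {
  x <- as.data.frame(x)
  req <- c("area_id", "lat", "lon", "population")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("location table is missing column(s): ", paste(miss, collapse = ", "))
  x <- x[, req]
  x$area_id <- as.character(x$area_id)
  if (nrow(x) < 1) stop("location table has no rows")
  if (anyDuplicated(x$area_id))
    stop("duplicate area_id values: ",
         paste(unique(x$area_id[duplicated(x$area_id)]), collapse = ", "))
  if (any(!is.finite(x$lat)) || any(x$lat < -90) || any(x$lat > 90))
    stop("lat out of range [-90, 90]")
  if (any(!is.finite(x$lon)) || any(x$lon <= -180) || any(x$lon > 180))
    stop("lon out of range (-180, 180]")
  if (any(!is.finite(x$population)) || any(x$population < 1))
    stop("population must be >= 1 for every area")
  if (any(x$population != round(x$population)))
    stop("population must be a whole number")
  x$population <- as.numeric(x$population)
  rownames(x) <- NULL
  structure(x, N = sum(x$population),
            class = c("location_table", "data.frame"))
}

#' Total population of a location table
#'
#' @param locations A [location_table()].
#' @return The integer-valued total population \eqn{N}.
#' @export
total_population <- function(locations) {
  sum(as.data.frame(locations)$population)
}

#' @export
print.location_table <- function(x, ...) {
  cat(sprintf("<location_table> %d areas, N = %s people\n",
              nrow(x), format(total_population(x), big.mark = ",")))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Read a location table from delimited text
#'
#' @param path Path to a delimited text file with a header.
#' @param sep Field delimiter (default comma).
#' @param columns Named character vector mapping the required names
#'   `area_id`, `lat`, `lon`, `population` to the column names used in the
#'   file, for files with non-standard headers.
#' @return A validated [location_table()].
#' @export
load_locations <- function(path, sep = ",",
                           columns = c(area_id = "area_id", lat = "lat",
                                       lon = "lon", population = "population")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df <- data.frame(area_id = raw[[columns[["area_id"]]]],
                   lat = raw[[columns[["lat"]]]],
                   lon = raw[[columns[["lon"]]]],
                   population = raw[[columns[["population"]]]],
                   stringsAsFactors = FALSE)
  location_table(df)
}

#' Write a location table as CSV
#'
#' @param locations A [location_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locations <- function(locations, path) {
  utils::write.csv(as.data.frame(locations), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Great-circle (Haversine) distance in meters
#'
#' Shortest "as-the-crow-flies" distance between points on a sphere of radius
#' 6,371,000 m (mean Earth radius); ellipsoidal effects are ignored.
#' Vectorized over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84 centroids).
#' @return Distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 180), all(abs(lon2) <= 180))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .earth_radius_m)
}

.earth_radius_m <- 6371000

# All-pairs Haversine distance matrix for a location table (meters).
# Exact zeros on the diagonal.
distance_matrix <- function(locations) {
  p <- cbind(locations$lon, locations$lat)
  d <- geosphere::distm(p, p,
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = .earth_radius_m))
  diag(d) <- 0
  dimnames(d) <- list(locations$area_id, locations$area_id)
  d
}

#' Nearest-k neighbor map
#'
#' For every origin area, the ordered set \eqn{B_i} of its `k` nearest areas
#' by great-circle distance.  The origin itself is always a member of its own
#' neighbor set (it is trivially nearest, at distance 0) and counts toward
#' `k`, so patients may remain in place.  Ties at equal distance are broken by
#' ascending `area_id` so the map is deterministic.
#'
#' @param locations A [location_table()].
#' @param k Number of destinations per origin, self included (`k >= 1`).
#'   Values above the number of areas are clamped with a warning.
#' @return A `neighbor_map`: a data frame with columns `origin_id`, `dest_id`,
#'   `distance_m`, sorted by origin then distance (ties by `dest_id`), with
#'   attribute `k` (the effective neighborhood size).  The result depends only
#'   on the set of areas, not on the row order of `locations`.
#' @export
nearest_neighbors <- function(locations, k) {
  stopifnot(inherits(locations, "location_table"), length(k) == 1, k >= 1)
  k <- as.integer(k)
  n <- nrow(locations)
  if (k > n) {
    warning("k = ", k, " exceeds the number of areas (", n, "); clamped")
    k <- n
  }
  ord <- order(locations$area_id)
  locations <- locations[ord, ]
  d <- distance_matrix(locations)
  ids <- locations$area_id
  res <- lapply(seq_len(n), function(i) {
    o <- order(d[i, ], ids)[seq_len(k)]
    data.frame(origin_id = ids[i], dest_id = ids[o], distance_m = d[i, o],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, k = k, class = c("neighbor_map", "data.frame"))
}

#' @export
print.neighbor_map <- function(x, ...) {
  cat(sprintf("<neighbor_map> %d origins x k = %d destinations\n",
              length(unique(x$origin_id)), attr(x, "k")))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write a neighbor map as CSV
#'
#' Columns `origin_id,dest_id,distance_m`, sorted by origin then distance.
#'
#' @param neighbors A `neighbor_map` from [nearest_neighbors()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_neighbor_map <- function(neighbors, path) {
  utils::write.csv(as.data.frame(neighbors), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
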