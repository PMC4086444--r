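#' Construct a validated patient list
#'
#' @param x A data frame with columns `patient_id` and `area_id` (the
#'   patient's true origin area).
#' @param locations Optional [location_table()]; when supplied, every origin
#'   must exist in it.
#' @return A `patient_list` data frame; its row count is the patient count
#'   \eqn{s}.
#' @export
patient_list <- function(x, locations = NULL) {
  x <- as.data.frame(x)
  req <- c("patient_id", "area_id")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("patient list is missing column(s): ", paste(miss, collapse = ", "))
  x <- x[, req]
  x$patient_id <- as.character(x$patient_id)
  x$area_id <- as.character(x$area_id)
  if (nrow(x) < 1) stop("patient list has no rows")
  if (anyDuplicated(x$patient_id))
    stop("duplicate patient_id values")
  if (!is.null(locations)) {
    bad <- setdiff(unique(x$area_id), locations$area_id)
    if (length(bad))
      stop("patient origin(s) absent from the location table: ",
           paste(bad, collapse = ", "))
  }
  rownames(x) <- NULL
  structure(x, class = c("patient_list", "data.frame"))
}

#' Read a patient list from CSV
#'
#' @param path CSV with header `patient_id,area_id`.
#' @param locations Optional [location_table()] for origin validation.
#' @param sep Field delimiter.
#' @return A [patient_list()].
#' @export
load_patients <- function(path, locations = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  patient_list(utils::read.table(path, sep = sep, header = TRUE,
                                 stringsAsFactors = FALSE), locations)
}

#' Write a patient list as CSV
#'
#' @param patients A [patient_list()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(as.data.frame(patients), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# deterministic 31-bit string hash (polynomial, base 31); keeps per-origin
# substreams independent of which other origins are present
.string_seed <- function(root, id) {
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 31 + b) %% 2147483647
  as.integer((root + h) %% 2147483647)
}

#' Stochastically relocate patients with a solved transition matrix
#'
#' For each origin area `i` holding \eqn{s_i} patients, destination counts
#' are drawn from Multinomial\eqn{(s_i, \{P_{ij}\})} and the origin's
#' patients — shuffled uniformly, since patients are exchangeable — are
#' assigned to destinations in the matrix's stored order.  Patient ids and
#' the total count are preserved; only `area_id` changes.
#'
#' @param patients A [patient_list()].
#' @param P A `transition_matrix` with status `"optimal"` containing a row
#'   for every patient origin.
#' @param seed Integer root seed.  Each origin draws from its own substream
#'   keyed by `area_id`, so results for one origin do not depend on which
#'   other origins are present.  The caller's RNG state is left untouched.
#' @return A new `patient_list` with randomized `area_id`, in the input's
#'   row order.
#' @export
relocate <- function(patients, P, seed) {
  stopifnot(inherits(patients, "patient_list"),
            inherits(P, "transition_matrix"))
  if (P$status != "optimal" || is.null(P$entries))
    stop("relocation requires an optimal transition matrix")
  e <- P$entries
  origins <- unique(patients$area_id)
  missing <- setdiff(origins, unique(e$origin_id))
  if (length(missing))
    stop("origin(s) missing from the transition matrix: ",
         paste(missing, collapse = ", "))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })

  out <- patients$area_id
  for (o in sort(origins)) {
    rows <- which(patients$area_id == o)
    prow <- e[e$origin_id == o, ]
    prob <- prow$probability / sum(prow$probability)
    set.seed(.string_seed(seed, o))
    counts <- as.vector(stats::rmultinom(1, length(rows), prob))
    shuffled <- rows[sample.int(length(rows))]
    out[shuffled] <- rep(prow$dest_id, counts)
  }
  res <- data.frame(patient_id = patients$patient_id, area_id = out,
                    stringsAsFactors = FALSE)
  structure(res, class = c("patient_list", "data.frame"))
}
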