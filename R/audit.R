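#' Re-identification probability of one (origin, destination) pair
#'
#' Evaluates, from first principles, the probability that a record disclosed
#' in area `j` is traced back to a specific individual of origin area `i`:
#' \deqn{r_{ij} = \min(s/n_i, 1)\; \frac{n_i P_{ij}}{\sum_k n_k P_{kj}}.}
#' The cap \eqn{\min(s/n_i, 1)} reflects that the number of patients truly
#' from `i` cannot exceed its population.  The quantity is scale-invariant in
#' column `j`: rescaling all incoming probabilities leaves it unchanged.
#'
#' @param P A `transition_matrix` with status `"optimal"` (or any
#'   row-stochastic matrix read via [read_transition_matrix()]).
#' @param locations The [location_table()] the matrix was built from.
#' @param s Patient count.
#' @param i,j Area ids (origin and destination).
#' @return The probability in \eqn{[0, 1]}, or `NA` when destination `j`
#'   receives no transition mass (a destination no one maps to poses no risk;
#'   such pairs are excluded from audit maxima rather than scored 0/0).
#' @export
reidentification_probability <- function(P, locations, s, i, j) {
  stopifnot(inherits(P, "transition_matrix"), !is.null(P$entries))
  e <- P$entries
  pop <- stats::setNames(locations$population, locations$area_id)
  if (is.na(pop[i]) || is.na(pop[j])) stop("unknown area id")
  col <- e[e$dest_id == j, ]
  mass <- sum(pop[col$origin_id] * col$probability)
  if (mass <= 0) return(NA_real_)
  pij <- sum(col$probability[col$origin_id == i])
  min(s / pop[[i]], 1) * pop[[i]] * pij / mass
}

#' Audit a transition matrix against the risk threshold
#'
#' Recomputes every pair's re-identification probability from first
#' principles rather than trusting LP feasibility, so solver tolerance
#' violations and pruning bugs are caught.  The audit passes when the maximum
#' over all pairs with positive incoming column mass is at most
#' \eqn{\epsilon + 10^{-6}}.
#'
#' @param P A `transition_matrix` with status `"optimal"`.
#' @param problem The [deid_problem()] the matrix solves (supplies locations,
#'   `s` and `epsilon`).
#' @return An `audit_report`: data frame `risks` (`origin_id`, `dest_id`,
#'   `risk`), `max_risk`, `epsilon`, logical `pass`, and
#'   `zero_mass_destinations` (destinations skipped for lack of incoming
#'   mass).
#' @export
audit <- function(P, problem) {
  stopifnot(inherits(P, "transition_matrix"), inherits(problem, "deid_problem"))
  if (P$status != "optimal" || is.null(P$entries))
    stop("only an optimal transition matrix can be audited")
  e <- P$entries
  loc <- problem$locations
  ids <- loc$area_id
  if (!all(e$origin_id %in% ids) || !all(e$dest_id %in% ids))
    stop("transition matrix refers to areas absent from the problem's ",
         "location table")
  rs <- tapply(e$probability, e$origin_id, sum)
  if (any(abs(rs - 1) > 1e-4))
    stop("transition matrix is not row-stochastic")
  pop <- stats::setNames(loc$population, ids)
  s <- problem$s

  mass <- tapply(pop[e$origin_id] * e$probability, e$dest_id, sum)
  colmass <- as.vector(mass[e$dest_id])
  risk <- ifelse(colmass > 0,
                 pmin(s / pop[e$origin_id], 1) *
                   pop[e$origin_id] * e$probability / colmass,
                 NA_real_)
  risks <- data.frame(origin_id = e$origin_id, dest_id = e$dest_id,
                      risk = risk, stringsAsFactors = FALSE)
  ok <- !is.na(risk)
  max_risk <- if (any(ok)) max(risk[ok]) else NA_real_
  pass <- !is.na(max_risk) && max_risk <= problem$epsilon + 1e-6
  structure(list(risks = risks, max_risk = max_risk,
                 epsilon = problem$epsilon, pass = pass,
                 zero_mass_destinations =
                   sort(names(mass)[mass <= 0])),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> max risk %.6f vs epsilon %g: %s\n",
              x$max_risk, x$epsilon, if (x$pass) "PASS" else "FAIL"))
  if (length(x$zero_mass_destinations))
    cat("  skipped zero-mass destinations:",
        length(x$zero_mass_destinations), "\n")
  invisible(x)
}

#' Write an audit report
#'
#' Per-pair risks to `path` as CSV (`origin_id,dest_id,risk`); summary
#' (max risk, epsilon, pass, skipped destinations) to
#' `paste0(path, ".summary.json")`.
#'
#' @param report An `audit_report` from [audit()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(report, path) {
  stopifnot(inherits(report, "audit_report"))
  utils::write.csv(report$risks, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(max_risk = report$max_risk, epsilon = report$epsilon,
         pass = report$pass,
         zero_mass_destinations = report$zero_mass_destinations),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
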