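#' Specify a de-identification problem instance
#'
#' Bundles everything needed to build the linear program: the area universe,
#' the sparsified destination sets, the patient count \eqn{s}, the risk
#' threshold \eqn{\epsilon}, and the model variant.
#'
#' @param locations A [location_table()].
#' @param neighbors A `neighbor_map` over the same areas
#'   (see [nearest_neighbors()]).
#' @param s Positive integer number of patients to be disclosed.
#' @param epsilon Risk threshold \eqn{\epsilon > 0}: the disclosed dataset
#'   must not allow any location to be traced to a specific individual with
#'   probability above \eqn{\epsilon}.  Values above 1 are permitted (they
#'   arise when exploring the classic model's feasibility limits) but draw a
#'   warning, since a bound above 1 offers no protection.
#' @param variant `"revised"` (default) uses the per-origin risk coefficient
#'   \eqn{\nu_i = \min(s, n_i)/(N\epsilon)}, which keeps small-population
#'   areas feasible; `"wcmb"` uses the classic constant \eqn{\nu = s/(N\epsilon)}.
#' @return An object of class `deid_problem`.
#' @export
deid_problem <- function(locations, neighbors, s, epsilon,
                         variant = c("revised", "wcmb")) {
  variant <- match.arg(variant)
  stopifnot(inherits(locations, "location_table"),
            inherits(neighbors, "neighbor_map"))
  if (!setequal(unique(neighbors$origin_id), locations$area_id))
    stop("neighbor map origins do not match the location table")
  if (length(s) != 1 || !is.finite(s) || s < 1 || s != round(s))
    stop("s must be a positive integer")
  if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0")
  if (epsilon > 1)
    warning("epsilon > 1 is impractical: the re-identification probability ",
            "bound exceeds 1")
  N <- total_population(locations)
  if (variant == "revised" && epsilon < 1 && s > N)
    warning("s exceeds the total population N; the model is only meaningful ",
            "for s <= N")
  structure(list(locations = locations, neighbors = neighbors,
                 s = as.numeric(s), epsilon = epsilon, variant = variant),
            class = "deid_problem")
}

#' @export
print.deid_problem <- function(x, ...) {
  cat(sprintf("<deid_problem> %s variant | %d areas (N = %s) | s = %d | epsilon = %g | k = %d\n",
              x$variant, nrow(x$locations),
              format(total_population(x$locations), big.mark = ","),
              as.integer(x$s), x$epsilon, attr(x$neighbors, "k")))
  invisible(x)
}

#' Risk-constraint coefficient \eqn{\nu}
#'
#' The coefficient multiplying the transition probability in the
#' re-identification constraint.  The classic model uses the constant
#' \eqn{\nu = s/(N\epsilon)} for every origin; the revised model replaces
#' \eqn{s} by \eqn{\min(s, n_i)}, reflecting that at most \eqn{n_i} of the
#' \eqn{s} patients can truly originate from an area of population \eqn{n_i}.
#' Consequently the revised coefficient never exceeds the classic one.
#'
#' @param variant `"wcmb"` or `"revised"`.
#' @param s Patient count.
#' @param N Total population.
#' @param epsilon Risk threshold.
#' @param n_i Origin population(s); vectorized.  Ignored by `"wcmb"` (but may
#'   still be supplied).
#' @return \eqn{\nu} (dimensionless), one value per `n_i`.
#' @export
risk_coefficient <- function(variant = c("revised", "wcmb"), s, N, epsilon,
                             n_i = NULL) {
  variant <- match.arg(variant)
  stopifnot(s > 0, N > 0, epsilon > 0)
  if (variant == "wcmb") {
    v <- s / (N * epsilon)
    if (!is.null(n_i)) v <- rep(v, length(n_i))
    v
  } else {
    if (is.null(n_i)) stop("the revised coefficient requires n_i")
    stopifnot(all(n_i > 0))
    pmin(s, n_i) / (N * epsilon)
  }
}

#' Redundancy function g of the origin population
#'
#' \eqn{g(n_i) = n_i/N - \nu_i} with \eqn{\nu_i = \min(s, n_i)/(N\epsilon)}:
#' the coefficient of the origin's own transition probability after the risk
#' constraint is rearranged so all other coefficients are non-negative.
#' Piecewise: \eqn{(n_i/N)(1 - 1/\epsilon)} for \eqn{n_i \le s} and
#' \eqn{(n_i - s/\epsilon)/N} for \eqn{n_i > s}; continuous at \eqn{n_i = s}.
#' For \eqn{\epsilon < 1} it attains its minimum \eqn{(s/N)(1 - 1/\epsilon)}
#' at \eqn{n_i = s} and crosses zero at \eqn{n_i = s/\epsilon}; a
#' non-negative value means every coefficient of the constraint is
#' non-negative, so the constraint is redundant and can be dropped.
#'
#' @param n_i Origin population(s); vectorized.
#' @param s Patient count.
#' @param N Total population.
#' @param epsilon Risk threshold.
#' @return \eqn{g(n_i)}, dimensionless.
#' @export
g_function <- function(n_i, s, N, epsilon) {
  stopifnot(all(n_i >= 1), s > 0, N > 0, epsilon > 0)
  n_i / N - pmin(s, n_i) / (N * epsilon)
}

#' Is an origin's risk constraint redundant?
#'
#' TRUE when \eqn{n_i \ge s/\epsilon}: the rearranged constraint then has
#' only non-negative coefficients, so it holds automatically for any
#' non-negative transition probabilities and can be left out without changing
#' the model.  The same rule is safe for both variants because the revised
#' coefficient never exceeds the classic one.
#'
#' @inheritParams g_function
#' @return Logical, one value per `n_i`.
#' @export
is_redundant_risk_constraint <- function(n_i, s, epsilon) {
  stopifnot(all(n_i > 0), s > 0, epsilon > 0)
  n_i * epsilon >= s
}

#' Analytic LP dimensions for a nearest-k instance
#'
#' Counting convention: one decision variable per (origin, destination) pair
#' with the destination in the origin's neighbor set; one row-sum equality
#' per origin plus one risk inequality per variable; non-negativity is a
#' variable bound, not a counted constraint.  Hence
#' `variables = n_areas * min(k, n_areas)` and
#' `constraints = n_areas + variables`.
#'
#' @param n_areas Number of areas \eqn{|A|}.
#' @param k Neighborhood size (default: full transitions, `k = n_areas`).
#' @return Named numeric vector with elements `variables` and `constraints`.
#' @export
lp_size <- function(n_areas, k = n_areas) {
  stopifnot(n_areas >= 1, k >= 1)
  k <- min(k, n_areas)
  v <- as.numeric(n_areas) * k
  c(variables = v, constraints = n_areas + v)
}

#' Build the de-identification linear program
#'
#' Materializes the objective and constraint matrices for a [deid_problem()].
#' The objective minimizes the expected displacement
#' \eqn{\sum_{i}\sum_{j \in B_i} (n_i/N)\, d_{ij}\, P_{ij}} (meters).
#' Constraints: each origin's transition probabilities sum to one, and for
#' every retained pair \eqn{(i, j)} the risk inequality
#' \eqn{\sum_{k: j \in B_k} (n_k/N) P_{kj} - \nu_i P_{ij} \ge 0}.  The column
#' sum ranges only over origins whose neighbor set contains \eqn{j}; other
#' \eqn{P_{kj}} do not exist as variables under nearest-k sparsification.
#'
#' @param problem A [deid_problem()].
#' @param prune If `TRUE` (default), risk constraints of origins with
#'   \eqn{n_i \ge s/\epsilon} are omitted as redundant and recorded; the
#'   pruned and unpruned programs have identical feasible sets.
#' @return An object of class `lp_spec`: a list with the variable index
#'   (`vars`: `origin_id`, `dest_id`), objective coefficients `c` (meters,
#'   expectation-weighted), sparse equality block (`A_eq`, `b_eq`), sparse
#'   `>=` inequality block (`A_ge`, `b_ge = 0`), `pruned_origins`,
#'   `n_variables`, `n_constraints` (built) and `n_constraints_unpruned`
#'   (counting convention of [lp_size()]), plus the instance parameters.
#' @export
build_lp <- function(problem, prune = TRUE) {
  stopifnot(inherits(problem, "deid_problem"))
  nm <- problem$neighbors
  if (nrow(nm) == 0) stop("empty neighbor map")
  loc <- problem$locations
  N <- total_population(loc)
  s <- problem$s
  eps <- problem$epsilon

  oi <- match(nm$origin_id, loc$area_id)
  di <- match(nm$dest_id, loc$area_id)
  if (anyNA(oi) || anyNA(di))
    stop("neighbor map refers to areas absent from the location table")
  pop <- loc$population
  nv <- nrow(nm)
  n_areas <- nrow(loc)

  cvec <- pop[oi] / N * nm$distance_m

  origin_levels <- sort(unique(nm$origin_id))
  row_of_origin <- match(nm$origin_id, origin_levels)
  A_eq <- Matrix::sparseMatrix(i = row_of_origin, j = seq_len(nv), x = 1,
                               dims = c(length(origin_levels), nv))

  nu <- risk_coefficient(problem$variant, s, N, eps, n_i = pop)
  redundant <- is_redundant_risk_constraint(pop, s, eps)
  keep <- if (prune) !redundant[oi] else rep(TRUE, nv)
  kept <- which(keep)
  r <- length(kept)

  # risk row for variable v = (i, j): (column-mass row of j) - nu_i * e_v
  W <- Matrix::sparseMatrix(i = di, j = seq_len(nv), x = pop[oi] / N,
                            dims = c(n_areas, nv))
  if (r > 0) {
    Tsel <- Matrix::sparseMatrix(i = seq_len(r), j = di[kept], x = 1,
                                 dims = c(r, n_areas))
    E <- Matrix::sparseMatrix(i = seq_len(r), j = kept, x = nu[oi[kept]],
                              dims = c(r, nv))
    A_ge <- Tsel %*% W - E
  } else {
    A_ge <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(0, nv))
  }

  structure(list(
    vars = data.frame(origin_id = nm$origin_id, dest_id = nm$dest_id,
                      stringsAsFactors = FALSE),
    c = cvec,
    A_eq = A_eq, b_eq = rep(1, length(origin_levels)),
    A_ge = A_ge, b_ge = rep(0, r),
    risk_rows = data.frame(origin_id = nm$origin_id[kept],
                           dest_id = nm$dest_id[kept],
                           stringsAsFactors = FALSE),
    pruned_origins = loc$area_id[redundant & prune],
    n_variables = nv,
    n_constraints = length(origin_levels) + r,
    n_constraints_unpruned = length(origin_levels) + nv,
    s = s, epsilon = eps, variant = problem$variant, N = N,
    area_ids = loc$area_id, populations = pop
  ), class = "lp_spec")
}

#' @export
print.lp_spec <- function(x, ...) {
  cat(sprintf(
    "<lp_spec> %s | %d variables | %d constraints built (%d unpruned; %d origins pruned)\n",
    x$variant, x$n_variables, x$n_constraints, x$n_constraints_unpruned,
    length(x$pruned_origins)))
  invisible(x)
}

#' Export an LP in sparse triplet form for inspection
#'
#' Writes `triplets.csv` (`row,col,coef`), `rows.csv` (`row,sense,rhs`) and
#' `config.txt` (key-value instance parameters) under `dir`.  Equality rows
#' come first, then the retained risk rows.
#'
#' @param spec An `lp_spec` from [build_lp()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_lp <- function(spec, dir) {
  stopifnot(inherits(spec, "lp_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eq <- Matrix::summary(methods::as(spec$A_eq, "TsparseMatrix"))
  ge <- Matrix::summary(methods::as(spec$A_ge, "TsparseMatrix"))
  n_eq <- nrow(spec$A_eq)
  trip <- rbind(
    data.frame(row = eq$i, col = eq$j, coef = eq$x),
    data.frame(row = ge$i + n_eq, col = ge$j, coef = ge$x))
  trip <- trip[order(trip$row, trip$col), ]
  utils::write.csv(trip, file.path(dir, "triplets.csv"), row.names = FALSE,
                   quote = FALSE)
  rows <- rbind(
    data.frame(row = seq_len(n_eq), sense = "=", rhs = spec$b_eq),
    if (nrow(spec$A_ge) > 0)
      data.frame(row = n_eq + seq_len(nrow(spec$A_ge)), sense = ">=",
                 rhs = spec$b_ge))
  utils::write.csv(rows, file.path(dir, "rows.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(c(paste0("variant=", spec$variant),
               paste0("s=", format(spec$s)),
               paste0("epsilon=", format(spec$epsilon)),
               paste0("N=", format(spec$N)),
               paste0("variables=", spec$n_variables),
               paste0("constraints=", spec$n_constraints),
               paste0("constraints_unpruned=", spec$n_constraints_unpruned),
               paste0("pruned_origins=", length(spec$pruned_origins))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
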