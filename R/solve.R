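#' Solve a de-identification LP
#'
#' Minimizes the expected-displacement objective of an `lp_spec` and returns
#' the transition matrix.  Infeasibility is a legitimate, reported outcome
#' (status `"infeasible"`), not an error: the classic model is expected to be
#' infeasible on small-population geographies at practical risk thresholds.
#'
#' @param spec An `lp_spec` from [build_lp()].
#' @param backend `"highs"` (default) solves the sparse program with the
#'   HiGHS solver through a `python`/SciPy subprocess; `"dense"` uses the
#'   package's own dense two-phase simplex, practical only for small
#'   instances (a few hundred variables) but free of external processes.
#' @param tolerance Relative feasibility/cleanup tolerance (default `1e-6`).
#'   Entries in `[-tolerance, tolerance)` are clipped to zero (tiny positive
#'   values are solver noise, not transition mass) and rows renormalized on
#'   return.
#' @param python Path of the python interpreter for the `"highs"` backend.
#' @return An object of class `transition_matrix`: sparse `entries`
#'   (`origin_id`, `dest_id`, `probability`), `objective_m` (expected
#'   displacement in meters, recomputed from the returned solution),
#'   `status` in `optimal`, `infeasible`, `unbounded`, `numeric_failure`,
#'   and run metadata.
#' @details Only the objective value is contract-bound: degenerate optima may
#'   assign transition mass differently between backends or solver versions
#'   while achieving the same expected displacement.
#' @export
solve_lp <- function(spec, backend = c("highs", "dense"), tolerance = 1e-6,
                     python = Sys.which("python")) {
  stopifnot(inherits(spec, "lp_spec"))
  backend <- match.arg(backend)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(backend,
                highs = solve_backend_highs(spec, python),
                dense = solve_backend_dense(spec))
  elapsed <- proc.time()[["elapsed"]] - t0

  meta <- list(variant = spec$variant, epsilon = spec$epsilon, s = spec$s,
               backend = backend, tolerance = tolerance,
               solve_seconds = elapsed)
  if (res$status != "optimal") {
    return(structure(list(entries = NULL, objective_m = NA_real_,
                          status = res$status, meta = meta),
                     class = "transition_matrix"))
  }
  x <- res$x
  if (any(x < -tolerance))
    return(structure(list(entries = NULL, objective_m = NA_real_,
                          status = "numeric_failure", meta = meta),
                     class = "transition_matrix"))
  # entries below the tolerance are solver dust: they carry no real
  # transition mass but make audit ratios of dust over dust equal 1
  x[x < tolerance] <- 0
  # renormalize each origin's row to an exact unit sum
  rs <- as.vector(tapply(x, spec$vars$origin_id, sum)[spec$vars$origin_id])
  if (any(abs(rs - 1) > 1e-4))
    return(structure(list(entries = NULL, objective_m = NA_real_,
                          status = "numeric_failure", meta = meta),
                     class = "transition_matrix"))
  x <- x / rs
  objective <- sum(spec$c * x)
  if (is.finite(res$objective) && abs(res$objective) > 0 &&
      abs(objective - res$objective) > 1e-6 * max(1, abs(res$objective)))
    warning("recomputed objective deviates from the solver report by more ",
            "than the relative tolerance")
  keep <- x > 0
  entries <- data.frame(origin_id = spec$vars$origin_id[keep],
                        dest_id = spec$vars$dest_id[keep],
                        probability = x[keep], stringsAsFactors = FALSE)
  structure(list(entries = entries, objective_m = objective,
                 status = "optimal", meta = meta),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  if (x$status == "optimal") {
    cat(sprintf("<transition_matrix> optimal | %d nonzero entries | expected displacement %.1f m\n",
                nrow(x$entries), x$objective_m))
  } else {
    cat(sprintf("<transition_matrix> status: %s\n", x$status))
  }
  invisible(x)
}

# sparse triplet exchange with a SciPy/HiGHS subprocess
solve_backend_highs <- function(spec, python) {
  if (!nzchar(python) || !file.exists(python))
    stop("python interpreter not found; the 'highs' backend needs python ",
         "with scipy (or use backend = \"dense\")")
  script <- system.file("python", "solve_lp.py", package = "deidlp")
  if (!nzchar(script)) stop("bundled solver script not found")
  td <- tempfile("deidlp_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)

  writeLines(format(spec$c, digits = 17, trim = TRUE, scientific = FALSE),
             file.path(td, "c.txt"))
  eq <- Matrix::summary(methods::as(spec$A_eq, "TsparseMatrix"))
  utils::write.table(data.frame(eq$i, eq$j, eq$x), file.path(td, "eq.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  ge <- Matrix::summary(methods::as(spec$A_ge, "TsparseMatrix"))
  utils::write.table(data.frame(ge$i, ge$j, ge$x), file.path(td, "ge.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_var = spec$n_variables,
                            n_eq = nrow(spec$A_eq),
                            n_ge = nrow(spec$A_ge)),
                       file.path(td, "meta.json"), auto_unbox = TRUE)

  out <- suppressWarnings(
    system2(python, c(shQuote(script), shQuote(td)),
            stdout = TRUE, stderr = TRUE))
  code <- attr(out, "status")
  rfile <- file.path(td, "result.json")
  if ((!is.null(code) && code != 0) || !file.exists(rfile))
    stop("highs backend failed: ", paste(out, collapse = "\n"))
  res <- jsonlite::read_json(rfile, simplifyVector = TRUE)
  x <- if (res$status == "optimal")
    scan(file.path(td, "x.txt"), quiet = TRUE) else NULL
  list(status = res$status, x = x,
       objective = if (is.null(res$objective)) NA_real_ else res$objective)
}

solve_backend_dense <- function(spec) {
  if (spec$n_variables > 2000)
    stop("the dense backend is limited to small instances; use \"highs\"")
  simplex_eq_ge(spec$c, as.matrix(spec$A_eq), spec$b_eq,
                as.matrix(spec$A_ge), spec$b_ge)
}

#' Write a transition matrix and its run metadata
#'
#' The matrix goes to `path` as CSV (`origin_id,dest_id,probability`); run
#' metadata (status, objective, variant, epsilon, timing) goes to
#' `paste0(path, ".meta")` as `key=value` lines.
#'
#' @param tm A `transition_matrix` from [solve_lp()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (tm$status == "optimal")
    utils::write.csv(tm$entries, path, row.names = FALSE, quote = FALSE)
  fields <- c(list(status = tm$status,
                   objective_m = format(tm$objective_m, digits = 12)),
              lapply(tm$meta[c("variant", "epsilon", "s", "backend",
                               "tolerance", "solve_seconds")],
                     function(v) if (is.null(v)) NULL else format(v, digits = 12)))
  fields <- fields[!vapply(fields, is.null, TRUE)]
  writeLines(paste0(names(fields), "=", unlist(fields)), paste0(path, ".meta"))
  invisible(path)
}

#' Read a transition matrix written by [write_transition_matrix()]
#'
#' @param path CSV path (`origin_id,dest_id,probability`).
#' @return A `transition_matrix` with status `"optimal"`; the objective is
#'   taken from the metadata sidecar when present.
#' @export
read_transition_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("origin_id", "dest_id", "probability") %in% names(df)))
  df$origin_id <- as.character(df$origin_id)
  df$dest_id <- as.character(df$dest_id)
  obj <- NA_real_
  meta <- list()
  mf <- paste0(path, ".meta")
  if (file.exists(mf)) {
    kv <- strsplit(readLines(mf), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                            vapply(kv, `[`, "", 1))
    if (!is.null(meta$objective_m))
      obj <- suppressWarnings(as.numeric(meta$objective_m))
  }
  structure(list(entries = df, objective_m = obj, status = "optimal",
                 meta = meta),
            class = "transition_matrix")
}
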