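# Values below marked "published" are the analytic entries of the canonical
# Ottawa-scale configuration: N = 264,327 children across 11,740 postal
# codes, s = 224 patients.

test_that("risk coefficients reproduce the published nu table", {
  N <- 264327; s <- 224
  # nu = (s/epsilon)/N for the classic model, tabulated by s/epsilon
  nu <- function(s_over_eps)
    risk_coefficient("wcmb", s = s, N = N, epsilon = s / s_over_eps)
  expect_equal(round(nu(10) * 1e5, 3), 3.783)
  # the s/eps = 20 row: the tabulated formula (s/eps)/N gives 7.566;
  # published tables round this row inconsistently (cf. eps printed as 11.3
  # where 224/20 = 11.2)
  expect_equal(round(nu(20) * 1e5, 3), 7.566)
  expect_equal(round(nu(30) * 1e5, 3), 11.350)
  expect_equal(round(nu(33) * 1e5, 3), 12.485)
})

test_that("revised coefficient caps at the origin population and never exceeds the classic one", {
  expect_equal(risk_coefficient("revised", s = 100, N = 10000, epsilon = 0.5,
                                n_i = 20), 0.004)
  # n_i >= s: the min attains s, identical to the classic value
  expect_equal(risk_coefficient("revised", s = 50, N = 5000, epsilon = 0.3,
                                n_i = c(50, 80, 500)),
               rep(risk_coefficient("wcmb", s = 50, N = 5000, epsilon = 0.3),
                   3))
  set.seed(3)
  for (rep in 1:20) {
    s <- sample(1:300, 1); N <- s + sample(1:5000, 1)
    eps <- runif(1, 0.05, 2); n <- sample(1:400, 10)
    expect_true(all(risk_coefficient("revised", s, N, eps, n) <=
                      risk_coefficient("wcmb", s, N, eps, n) + 1e-15))
  }
})

test_that("the g function has the published minimum, zero crossing and continuity", {
  N <- 264327; s <- 224; eps <- 0.2
  expect_equal(g_function(s, s, N, eps), (s / N) * (1 - 1 / eps))
  expect_equal(g_function(s / eps, s, N, eps), 0)
  expect_equal(g_function(2000, s, N, eps), 880 / 264327)
  # continuity at n_i = s: both branches give the same value
  expect_equal((s / N) * (1 - 1 / eps), (s - s / eps) / N)
  expect_equal(g_function(s - 1e-6, s, N, eps), g_function(s + 1e-6, s, N, eps),
               tolerance = 1e-4)
})

test_that("g sign agrees with constraint redundancy for epsilon < 1", {
  set.seed(8)
  for (rep in 1:30) {
    s <- sample(1:300, 1); N <- s + sample(1:5000, 1)
    eps <- runif(1, 0.05, 0.95)
    n <- sample(1:3000, 25)
    expect_equal(g_function(n, s, N, eps) >= 0,
                 is_redundant_risk_constraint(n, s, eps))
  }
})

test_that("redundancy boundary cases behave as the rearranged constraint implies", {
  expect_true(is_redundant_risk_constraint(1120, s = 224, epsilon = 0.2))
  expect_false(is_redundant_risk_constraint(1000, s = 224, epsilon = 0.2))
  # epsilon >= 1 with n_i >= s: s/epsilon <= s <= n_i
  expect_true(is_redundant_risk_constraint(300, s = 224, epsilon = 1.5))
})

test_that("analytic LP sizes reproduce the published problem dimensions", {
  full <- lp_size(11740)
  expect_equal(full[["variables"]], 137827600)     # 11740^2
  expect_equal(full[["constraints"]], 137839340)   # 11740 * (1 + 11740)
  k10 <- lp_size(11740, 10)
  expect_equal(k10[["variables"]], 117400)
  expect_equal(k10[["constraints"]], 129140)
  k30 <- lp_size(11740, 30)
  expect_equal(k30[["variables"]], 352200)
  expect_equal(k30[["constraints"]], 363940)       # 11740 * (1 + 30)
  expect_equal(unname(lp_size(2)), c(4, 6))
})

test_that("built LPs obey the counting invariants and record pruning", {
  city <- urban_city(20, seed = 2)
  for (k in c(3, 7, 20)) {
    p <- mk_problem(city, k, s = 10, epsilon = 0.5, "revised")
    lp <- build_lp(p, prune = FALSE)
    expect_equal(lp$n_variables, 20 * k)
    expect_equal(lp$n_constraints, 20 + 20 * k)
    expect_equal(lp$n_constraints_unpruned,
                 unname(lp_size(20, k)[["constraints"]]))
    expect_equal(length(lp$pruned_origins), 0)
  }
  # s/eps = 20: all areas with population >= 20 lose their risk rows
  p <- mk_problem(city, 5, s = 10, epsilon = 0.5, "revised")
  lp <- build_lp(p, prune = TRUE)
  expected <- city$area_id[is_redundant_risk_constraint(city$population, 10, 0.5)]
  expect_setequal(lp$pruned_origins, expected)
  expect_equal(lp$n_constraints,
               20 + 5 * (20 - length(expected)))
})

test_that("objective coefficients are expectation-weighted distances in meters", {
  lc <- line_city(pop = c(5, 10, 20, 40))
  p <- mk_problem(lc, 2, s = 8, epsilon = 0.5)
  lp <- build_lp(p)
  nm <- p$neighbors
  N <- total_population(lc)
  pop <- setNames(lc$population, lc$area_id)
  expect_equal(lp$c, unname(pop[nm$origin_id]) / N * nm$distance_m)
})

test_that("risk-constraint columns range only over origins holding the destination", {
  lc <- line_city(pop = c(5, 10, 20, 40))
  p <- mk_problem(lc, 2, s = 8, epsilon = 0.5)
  lp <- build_lp(p, prune = FALSE)
  N <- total_population(lc)
  pop <- setNames(lc$population, lc$area_id)
  A <- as.matrix(lp$A_ge)
  key <- paste(lp$vars$origin_id, lp$vars$dest_id)
  nu <- risk_coefficient("revised", 8, N, 0.5, unname(pop[lp$risk_rows$origin_id]))
  for (r in seq_len(nrow(A))) {
    i <- lp$risk_rows$origin_id[r]; j <- lp$risk_rows$dest_id[r]
    manual <- numeric(lp$n_variables)
    feeds <- which(lp$vars$dest_id == j)   # only existing variables into j
    manual[feeds] <- unname(pop[lp$vars$origin_id[feeds]]) / N
    vi <- match(paste(i, j), key)
    manual[vi] <- manual[vi] - nu[r]
    expect_equal(unname(A[r, ]), manual, tolerance = 1e-12)
  }
})

test_that("with unit populations every classic risk row is the rearranged cap form", {
  # all n_i = 1: row * x == (1/N) * (sum_k x_kj - (s/eps) x_ij), i.e. the
  # constraint is P_ij <= (eps/s) * sum_k P_kj
  ones <- location_table(data.frame(
    area_id = sprintf("U%d", 1:5),
    lat = seq(0, 0.04, by = 0.01), lon = 0, population = 1))
  s <- 3; eps <- 0.5
  p <- mk_problem(ones, 5, s, eps, "wcmb")
  lp <- build_lp(p, prune = FALSE)
  A <- as.matrix(lp$A_ge)
  N <- 5
  set.seed(4)
  for (trial in 1:5) {
    x <- runif(lp$n_variables)
    lhs <- N * as.vector(A %*% x)
    colsum <- tapply(x, lp$vars$dest_id, sum)
    manual <- as.numeric(colsum[lp$risk_rows$dest_id]) -
      (s / eps) * x[match(paste(lp$risk_rows$origin_id, lp$risk_rows$dest_id),
                          paste(lp$vars$origin_id, lp$vars$dest_id))]
    expect_equal(lhs, manual, tolerance = 1e-9)
  }
})

test_that("degenerate model inputs are rejected", {
  lc <- line_city()
  nm <- nearest_neighbors(lc, 2)
  expect_error(deid_problem(lc, nm, s = 0, epsilon = 0.2), "positive integer")
  expect_error(deid_problem(lc, nm, s = 5, epsilon = 0), "epsilon")
  expect_warning(deid_problem(lc, nm, s = 5, epsilon = 2), "impractical")
  expect_warning(deid_problem(lc, nm, s = 1000, epsilon = 0.5), "total population")
  empty <- structure(nm[0, ], k = 2L, class = class(nm))
  p <- suppressWarnings(deid_problem(lc, nm, 5, 0.5))
  p$neighbors <- empty
  expect_error(build_lp(p), "empty neighbor map")
})

test_that("LP export writes triplets, senses and config", {
  lc <- line_city()
  lp <- build_lp(mk_problem(lc, 2, s = 5, epsilon = 0.5), prune = FALSE)
  d <- withr::local_tempdir()
  export_lp(lp, d)
  trip <- utils::read.csv(file.path(d, "triplets.csv"))
  rows <- utils::read.csv(file.path(d, "rows.csv"))
  expect_setequal(rows$sense, c("=", ">="))
  expect_equal(nrow(rows), lp$n_constraints)
  expect_true(all(trip$row %in% rows$row))
  cfg <- readLines(file.path(d, "config.txt"))
  expect_true(any(grepl("^variant=revised$", cfg)))
})
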