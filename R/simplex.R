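# Dense two-phase primal simplex with Bland's rule.
#
# Solves  min c'x  s.t.  A x = b, x >= 0.  Intended for the small instances
# used by the "dense" backend and for cross-checking the sparse HiGHS path;
# Bland's rule makes it slow but cycle-free and fully deterministic.

simplex_standard <- function(cvec, A, b, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == m)
  if (is.null(max_iter)) max_iter <- 200L + 50L * (n + m)

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  # tableau: columns = structural (n) + artificial (m) + rhs
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)

  pivot_run <- function(tab, basis, cost, ncols) {
    it <- 0L
    repeat {
      cb <- cost[basis]
      red <- cost[seq_len(ncols)] -
        as.vector(crossprod(tab[, seq_len(ncols), drop = FALSE], cb))
      enter <- which(red < -tol)
      if (!length(enter))
        return(list(tab = tab, basis = basis, status = "optimal"))
      j <- min(enter)                      # Bland: smallest entering index
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(tab = tab, basis = basis, status = "unbounded"))
      ratio <- tab[pos, ncol(tab)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]    # Bland: smallest leaving variable
      tab[r, ] <- tab[r, ] / tab[r, j]
      upd <- which(abs(tab[, j]) > 0 & seq_len(m) != r)
      if (length(upd))
        tab[upd, ] <- tab[upd, ] - outer(tab[upd, j], tab[r, ])
      basis[r] <- j
      it <- it + 1L
      if (it > max_iter)
        return(list(tab = tab, basis = basis, status = "iteration_limit"))
    }
  }

  # phase 1: drive artificials to zero
  p1 <- pivot_run(tab, basis, c(rep(0, n), rep(1, m)), n + m)
  if (p1$status != "optimal")
    return(list(status = "numeric_failure", x = NULL, objective = NA_real_))
  val1 <- sum(p1$tab[, n + m + 1L] * as.numeric(p1$basis > n))
  if (val1 > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  tab <- p1$tab; basis <- p1$basis

  # pivot remaining zero-level artificials out of the basis where possible
  for (r in which(basis > n)) {
    j <- which(abs(tab[r, seq_len(n)]) > tol)
    if (length(j)) {
      j <- j[1]
      tab[r, ] <- tab[r, ] / tab[r, j]
      upd <- which(abs(tab[, j]) > 0 & seq_len(m) != r)
      if (length(upd))
        tab[upd, ] <- tab[upd, ] - outer(tab[upd, j], tab[r, ])
      basis[r] <- j
    }
  }
  live <- basis <= n
  if (!all(live)) {               # redundant rows: drop them
    keep <- live
    tab <- tab[keep, , drop = FALSE]
    basis <- basis[keep]
    m <- nrow(tab)
  }

  # phase 2 on structural columns only (artificial columns removed)
  tab2 <- cbind(tab[, seq_len(n), drop = FALSE], tab[, ncol(tab)])
  m2 <- nrow(tab2)
  p2 <- local({
    tab <- tab2; basis <- basis
    it <- 0L
    repeat {
      cb <- cvec[basis]
      red <- cvec - as.vector(crossprod(tab[, seq_len(n), drop = FALSE], cb))
      enter <- which(red < -tol)
      if (!length(enter)) return(list(tab = tab, basis = basis, status = "optimal"))
      j <- min(enter)
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(tab = tab, basis = basis, status = "unbounded"))
      ratio <- tab[pos, ncol(tab)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]
      tab[r, ] <- tab[r, ] / tab[r, j]
      upd <- which(abs(tab[, j]) > 0 & seq_len(m2) != r)
      if (length(upd))
        tab[upd, ] <- tab[upd, ] - outer(tab[upd, j], tab[r, ])
      basis[r] <- j
      it <- it + 1L
      if (it > max_iter) return(list(tab = tab, basis = basis, status = "iteration_limit"))
    }
  })
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  if (p2$status != "optimal")
    return(list(status = "numeric_failure", x = NULL, objective = NA_real_))
  x <- numeric(n)
  x[p2$basis] <- p2$tab[, ncol(p2$tab)]
  list(status = "optimal", x = x, objective = sum(cvec * x))
}

# min c'x  s.t.  A_eq x = b_eq, A_ge x >= b_ge, x >= 0,
# via surplus variables; dense.
simplex_eq_ge <- function(cvec, A_eq, b_eq, A_ge, b_ge, tol = 1e-9) {
  A_eq <- as.matrix(A_eq); A_ge <- as.matrix(A_ge)
  n <- length(cvec)
  r <- nrow(A_ge)
  A <- if (r == 0) A_eq else
    rbind(cbind(A_eq, matrix(0, nrow(A_eq), r)),
          cbind(A_ge, -diag(r)))
  b <- c(b_eq, b_ge)
  res <- simplex_standard(c(cvec, rep(0, r)), A, b, tol = tol)
  if (res$status == "optimal") res$x <- res$x[seq_len(n)]
  res
}
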