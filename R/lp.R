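# Dense two-phase primal simplex.
#
# The constraint-based analyses in this package reduce to sequences of small
# linear programs (tens of variables, tens of rows). They are solved with a
# self-contained tableau simplex: Dantzig pricing with a switch to Bland's
# rule after a burn-in (guaranteeing termination under degeneracy, which is
# endemic in flux networks), and fully deterministic tie-breaking so that
# repeated runs yield bit-identical solutions.

# minimize c'x  s.t.  A_eq x = b_eq,  A_le x <= b_le,  0 <= x <= ub
# ub entries may be Inf. Returns list(status, x, objective).
lp_standard <- function(cvec, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                        ub, tol = 1e-9, max_iter = 50000L) {
  n <- length(cvec)
  rows_le <- rbind(A_le, diag(n))
  rhs_le <- c(b_le, ub)
  keep <- is.finite(rhs_le)
  rows_le <- rows_le[keep, , drop = FALSE]
  rhs_le <- rhs_le[keep]
  m_le <- nrow(rows_le)
  m_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  m <- m_le + m_eq
  A <- matrix(0, m, n + m_le)
  b <- numeric(m)
  if (m_le > 0) {
    A[seq_len(m_le), seq_len(n)] <- rows_le
    A[cbind(seq_len(m_le), n + seq_len(m_le))] <- 1
    b[seq_len(m_le)] <- rhs_le
  }
  if (m_eq > 0) {
    A[m_le + seq_len(m_eq), seq_len(n)] <- A_eq
    b[m_le + seq_len(m_eq)] <- b_eq
  }
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  ncol0 <- n + m_le
  basis <- integer(m)
  art_rows <- integer(0)
  for (i in seq_len(m)) {
    if (i <= m_le && !neg[i]) basis[i] <- n + i else art_rows <- c(art_rows, i)
  }
  n_art <- length(art_rows)
  if (n_art > 0) {
    Art <- matrix(0, m, n_art)
    Art[cbind(art_rows, seq_len(n_art))] <- 1
    A <- cbind(A, Art)
    basis[art_rows] <- ncol0 + seq_len(n_art)
  }
  ntot <- ncol(A)
  is_art <- c(rep(FALSE, ncol0), rep(TRUE, n_art))

  pivot <- function(A, b, basis, i, j) {
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    other <- setdiff(seq_len(nrow(A)), i)
    f <- A[other, j]
    A[other, ] <- A[other, , drop = FALSE] - outer(f, A[i, ])
    b[other] <- b[other] - f * b[i]
    b[b < 0 & b > -1e-11] <- 0
    basis[i] <- j
    list(A = A, b = b, basis = basis)
  }

  run_phase <- function(A, b, basis, obj, allow) {
    m <- nrow(A)
    iter <- 0L
    bland_after <- 10L * (m + ncol(A))
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "iteration_limit", A = A, b = b, basis = basis))
      }
      cb <- obj[basis]
      red <- obj - as.vector(crossprod(A, cb))
      red[basis] <- 0
      cand <- which(red < -tol & allow)
      if (length(cand) == 0L) {
        return(list(status = "optimal", A = A, b = b, basis = basis))
      }
      j <- if (iter > bland_after) cand[1L] else cand[which.min(red[cand])]
      col <- A[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(status = "unbounded", A = A, b = b, basis = basis))
      }
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol * (1 + abs(rmin))]
      i <- ties[which.min(basis[ties])]
      st <- pivot(A, b, basis, i, j)
      A <- st$A; b <- st$b; basis <- st$basis
    }
  }

  if (n_art > 0) {
    ph1 <- run_phase(A, b, basis, c(rep(0, ncol0), rep(1, n_art)),
                     allow = rep(TRUE, ntot))
    if (ph1$status != "optimal") return(list(status = "infeasible"))
    A <- ph1$A; b <- ph1$b; basis <- ph1$basis
    if (sum(b[is_art[basis]]) > 1e-7) return(list(status = "infeasible"))
    for (i in which(is_art[basis])) {
      row <- A[i, seq_len(ncol0)]
      j <- which(abs(row) > 1e-7)
      if (length(j) > 0L) {
        st <- pivot(A, b, basis, i, j[1L])
        A <- st$A; b <- st$b; basis <- st$basis
      }
    }
  }
  ph2 <- run_phase(A, b, basis, c(cvec, rep(0, ntot - n)), allow = !is_art)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- numeric(ntot)
  x[ph2$basis] <- ph2$b
  sol <- x[seq_len(n)]
  list(status = "optimal", x = sol, objective = sum(cvec * sol))
}

# General form with finite or infinite lower bounds: variables shifted so the
# kernel sees nonnegative variables only. All model LPs have finite bounds
# (the model's default_bound stands in for "unbounded"), so lb is finite here.
lp_solve <- function(cvec, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = FALSE, tol = 1e-9) {
  stopifnot(all(is.finite(lb)), all(lb <= ub + 1e-12))
  obj <- if (maximize) -cvec else cvec
  b_eq2 <- if (is.null(A_eq)) NULL else b_eq - as.vector(A_eq %*% lb)
  b_le2 <- if (is.null(A_le)) NULL else b_le - as.vector(A_le %*% lb)
  res <- lp_standard(obj, A_eq, b_eq2, A_le, b_le2, ub = ub - lb, tol = tol)
  if (res$status == "optimal") {
    res$x <- res$x + lb
    res$objective <- sum(cvec * res$x)
  }
  res
}
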