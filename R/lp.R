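# Dense two-phase primal simplex with Bland's anti-cycling rule.
# Solves:  max  c'x   s.t.  A x = b,  x >= 0.
# Written for the desk-scale LPs of the knockout screen; exactness and
# robustness on degenerate problems matter more than speed here.

simplex_iterate <- function(TT, basis, obj, nvar, tol = 1e-9) {
  repeat {
    y <- as.vector(obj[basis] %*% TT[, seq_len(nvar), drop = FALSE])
    red <- obj[seq_len(nvar)] - y
    ent <- which(red < -tol)
    if (!length(ent)) break
    j <- min(ent)                               # Bland: smallest index enters
    col <- TT[, j]
    rhs <- TT[, nvar + 1L]
    pos <- which(col > tol)
    if (!length(pos))
      return(list(TT = TT, basis = basis, unbounded = TRUE))
    ratio <- rhs[pos] / col[pos]
    cand <- pos[ratio <= min(ratio) + tol]
    i <- cand[which.min(basis[cand])]           # Bland: smallest basis leaves
    TT[i, ] <- TT[i, ] / TT[i, j]
    other <- setdiff(seq_len(nrow(TT)), i)
    TT[other, ] <- TT[other, , drop = FALSE] -
      outer(TT[other, j], TT[i, ])
    basis[i] <- j
  }
  list(TT = TT, basis = basis, unbounded = FALSE,
       value = sum(obj[basis] * TT[, nvar + 1L]))
}

# max cc'x s.t. A x = b, x >= 0; returns list(status, value, x)
lp_solve_eq <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  # phase 1: drive artificial variables to zero
  TT <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  obj1 <- c(numeric(n), rep(1, m))
  r1 <- simplex_iterate(TT, basis, obj1, n + m, tol)
  if (r1$unbounded || r1$value > 1e-7)
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  TT <- r1$TT; basis <- r1$basis

  # pivot leftover zero-valued artificials out of the basis; drop rows whose
  # original coefficients are all zero (redundant constraints)
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    piv <- which(abs(TT[i, seq_len(n)]) > tol)
    if (length(piv)) {
      j <- min(piv)
      TT[i, ] <- TT[i, ] / TT[i, j]
      other <- setdiff(seq_len(nrow(TT)), i)
      TT[other, ] <- TT[other, , drop = FALSE] - outer(TT[other, j], TT[i, ])
      basis[i] <- j
    } else drop_rows <- c(drop_rows, i)
  }
  if (length(drop_rows)) {
    TT <- TT[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  TT <- TT[, c(seq_len(n), n + m + 1L), drop = FALSE]

  # phase 2: minimize -cc
  r2 <- simplex_iterate(TT, basis, c(-cc), n, tol)
  if (r2$unbounded)
    return(list(status = "unbounded", value = NA_real_, x = NULL))
  x <- numeric(n)
  x[r2$basis] <- r2$TT[, n + 1L]
  list(status = "optimal", value = sum(cc * x), x = x)
}

# max cc'v s.t. S v = 0 (rhs b), lb <= v <= ub, via shift + upper-bound slacks
lp_solve_bounded <- function(cc, S, b, lb, ub, tol = 1e-9) {
  n <- ncol(S)
  bounded <- which(is.finite(ub))
  nb <- length(bounded)
  Aub <- matrix(0, nb, n + nb)
  if (nb) {
    Aub[cbind(seq_len(nb), bounded)] <- 1
    Aub[cbind(seq_len(nb), n + seq_len(nb))] <- 1
  }
  A <- rbind(cbind(S, matrix(0, nrow(S), nb)), Aub)
  rhs <- c(b - as.vector(S %*% lb), (ub - lb)[bounded])
  res <- lp_solve_eq(c(cc, numeric(nb)), A, rhs, tol)
  if (res$status != "optimal") return(res)
  list(status = "optimal",
       value = res$value + sum(cc * lb),
       x = res$x[seq_len(n)] + lb)
}
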