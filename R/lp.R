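# Dense two-phase primal simplex used by every DEA linear program.
# Problems here are small (tens of variables and constraints), so a tableau
# method with Bland's anti-cycling rule is both adequate and robust to the
# heavy degeneracy typical of DEA programs (many reference weights tied at
# zero). Interface mirrors the usual (objective, <=, >=, ==) block form.

lp_solve <- function(objective,
                     A_le = NULL, b_le = NULL,
                     A_ge = NULL, b_ge = NULL,
                     A_eq = NULL, b_eq = NULL,
                     maximize = FALSE,
                     tol = 1e-9, maxit = 20000L) {
  n <- length(objective)
  rows <- function(A, b, type) {
    if (is.null(A)) return(NULL)
    A <- matrix(as.numeric(A), ncol = n)
    stopifnot(nrow(A) == length(b))
    list(A = A, b = as.numeric(b), type = rep(type, nrow(A)))
  }
  blocks <- Filter(Negate(is.null),
                   list(rows(A_le, b_le, "le"),
                        rows(A_ge, b_ge, "ge"),
                        rows(A_eq, b_eq, "eq")))
  A <- do.call(rbind, lapply(blocks, `[[`, "A"))
  b <- unlist(lapply(blocks, `[[`, "b"))
  type <- unlist(lapply(blocks, `[[`, "type"))
  m <- nrow(A)

  # slack / surplus columns
  n_sl <- sum(type != "eq")
  S <- matrix(0, m, n_sl)
  k <- 0L
  for (i in seq_len(m)) {
    if (type[i] == "eq") next
    k <- k + 1L
    S[i, k] <- if (type[i] == "le") 1 else -1
  }
  As <- cbind(A, S)
  # make b non-negative
  neg <- b < 0
  As[neg, ] <- -As[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  cc <- c(if (maximize) -objective else objective, rep(0, n_sl))
  res <- .simplex2p(As, b, cc, tol = tol, maxit = maxit)
  if (res$status != "optimal")
    return(list(ok = FALSE, status = res$status, value = NA_real_, x = NULL))
  x <- res$x[seq_len(n)]
  val <- sum(objective * x)
  list(ok = TRUE, status = "optimal", value = val, x = x)
}

# two-phase simplex: min c'x s.t. Ax = b (b >= 0), x >= 0
.simplex2p <- function(A, b, c, tol = 1e-9, maxit = 20000L) {
  m <- nrow(A); n <- ncol(A)
  # phase 1: artificial basis
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- .simplex_iter(Tab, basis, c1, ncol_real = n + m, tol = tol, maxit = maxit)
  if (ph1$status == "maxit") return(list(status = "maxit"))
  Tab <- ph1$Tab; basis <- ph1$basis
  if (ph1$value > 1e-7) return(list(status = "infeasible"))
  # drive remaining artificials out of the basis (degenerate rows)
  drop_rows <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] <= n) next
    piv <- which(abs(Tab[i, seq_len(n)]) > tol)[1L]
    if (is.na(piv)) { drop_rows <- c(drop_rows, i); next }
    Tab <- .pivot(Tab, i, piv); basis[i] <- piv
  }
  if (length(drop_rows)) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2 on original columns only
  Tab2 <- Tab[, c(seq_len(n), ncol(Tab)), drop = FALSE]
  ph2 <- .simplex_iter(Tab2, basis, c, ncol_real = n, tol = tol, maxit = maxit)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- numeric(n)
  x[ph2$basis] <- ph2$Tab[, ncol(ph2$Tab)]
  list(status = "optimal", x = x, value = sum(c * x))
}

.pivot <- function(Tab, pr, pc) {
  Tab[pr, ] <- Tab[pr, ] / Tab[pr, pc]
  other <- setdiff(seq_len(nrow(Tab)), pr)
  Tab[other, ] <- Tab[other, , drop = FALSE] -
    outer(Tab[other, pc], Tab[pr, ])
  Tab
}

# minimize c'x over the tableau; Bland's rule (lowest eligible index both for
# entering and, on ratio ties, for the leaving basic variable) guarantees
# termination under degeneracy.
.simplex_iter <- function(Tab, basis, c, ncol_real, tol = 1e-9, maxit = 20000L) {
  m <- nrow(Tab)
  for (it in seq_len(maxit)) {
    red <- c[seq_len(ncol_real)] -
      as.numeric(crossprod(c[basis], Tab[, seq_len(ncol_real), drop = FALSE]))
    enter <- which(red < -tol)
    if (!length(enter))
      return(list(status = "optimal", Tab = Tab, basis = basis,
                  value = sum(c[basis] * Tab[, ncol(Tab)])))
    j <- min(enter)                      # Bland
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- Tab[pos, ncol(Tab)] / col[pos]
    best <- ratio <= min(ratio) + 1e-12
    cand <- pos[best]
    i <- cand[which.min(basis[cand])]    # Bland tie-break
    Tab <- .pivot(Tab, i, j)
    basis[i] <- j
  }
  list(status = "maxit")
}
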