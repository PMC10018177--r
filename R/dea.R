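#' Data envelopment analysis: CCR, BCC, SBM and super-SBM
#'
#' Fits one of four DEA models to an m x n input matrix and s x n output
#' matrix whose columns are decision-making units (DMUs):
#'
#' * `"ccr"` — input-oriented radial model under constant returns to scale;
#'   the score is technical efficiency (TE) in (0, 1]. Slacks come from a
#'   second-stage maximization at the optimal radial contraction, and
#'   returns-to-scale labels from the sum of reference weights at the CCR
#'   optimum (IRS < 1 < DRS, with an interval rule robust to alternate
#'   optima).
#' * `"bcc"` — the radial model with the convexity constraint (sum of lambda
#'   equal 1); the score is pure technical efficiency (PTE), always >= TE.
#' * `"sbm"` — Tone's non-oriented slack-based measure under constant
#'   returns; the score rho in (0, 1] equals 1 exactly when all slacks
#'   vanish. Solved through the Charnes-Cooper linearization.
#' * `"super-sbm"` — SBM for all units, then the non-oriented super-efficiency
#'   model (reference set excluding the evaluated unit) for the SBM-efficient
#'   units, whose scores become >= 1; inefficient units keep their SBM score,
#'   so the combined vector ranks every unit.
#'
#' @param inputs m x n numeric matrix (rows variables, columns DMUs), or a
#'   vector for m = 1. All values non-negative; every DMU needs at least one
#'   strictly positive input and output (strictly positive data for SBM).
#' @param outputs s x n numeric matrix, same column convention.
#' @param model one of `"ccr"`, `"bcc"`, `"sbm"`, `"super-sbm"`.
#' @param names optional DMU labels (default column names or DMU1..DMUn).
#' @param rts for `"ccr"`, also classify returns to scale (default `TRUE`).
#' @param tol efficiency tolerance: a score >= 1 - tol with slack norm <= tol
#'   counts as efficient.
#' @return Object of class `dea` with elements `score` (the model's main
#'   per-DMU score), `lambda` (n_ref x n reference-weight matrix),
#'   `slack_input`, `slack_output`, `rts` (CCR only), `efficient`, plus
#'   `sbm_score` and `super_score` for `"super-sbm"`.
#' @examples
#' x <- matrix(c(2, 4, 8), 1)
#' y <- matrix(c(1, 1, 1), 1)
#' dea(x, y, "ccr")$score   # 1, 0.5, 0.25
#' @seealso [scale_efficiency()], [rank_by_score()], [malmquist()]
#' @export
dea <- function(inputs, outputs, model = c("ccr", "bcc", "sbm", "super-sbm"),
                names = NULL, rts = TRUE, tol = 1e-6) {
  model <- match.arg(model)
  X <- .dea_mat(inputs); Y <- .dea_mat(outputs)
  n <- ncol(X)
  if (ncol(Y) != n) stop("inputs and outputs must have the same number of DMUs",
                         call. = FALSE)
  if (is.null(names)) names <- colnames(X)
  if (is.null(names)) names <- paste0("DMU", seq_len(n))
  .dea_validate(X, Y, strict = model %in% c("sbm", "super-sbm"))
  m <- nrow(X); s <- nrow(Y)

  out <- list(model = model, units = names, m = m, s = s, n = n, tol = tol,
              inputs = X, outputs = Y)
  if (model %in% c("ccr", "bcc")) {
    vrs <- model == "bcc"
    theta <- numeric(n)
    lambda <- matrix(0, n, n, dimnames = list(names, names))
    s_in <- matrix(0, m, n); s_out <- matrix(0, s, n)
    for (j in seq_len(n)) {
      sol <- .radial_dea(X, Y, j, vrs = vrs)
      theta[j] <- sol$theta
      lambda[, j] <- sol$lambda
      s_in[, j] <- sol$slack_in
      s_out[, j] <- sol$slack_out
    }
    out$score <- stats::setNames(theta, names)
    out$lambda <- lambda
    out$slack_input <- s_in; out$slack_output <- s_out
    out$efficient <- theta >= 1 - tol &
      colSums(s_in) + colSums(s_out) <= tol * (m + s)
    if (!vrs && rts) out$rts <- .classify_rts_all(X, Y, theta, tol)
  } else {
    rho <- numeric(n)
    lambda <- matrix(0, n, n, dimnames = list(names, names))
    s_in <- matrix(0, m, n); s_out <- matrix(0, s, n)
    for (j in seq_len(n)) {
      sol <- .sbm_dea(X, Y, j)
      rho[j] <- sol$rho
      lambda[, j] <- sol$lambda
      s_in[, j] <- sol$slack_in; s_out[, j] <- sol$slack_out
    }
    out$sbm_score <- stats::setNames(rho, names)
    out$lambda <- lambda
    out$slack_input <- s_in; out$slack_output <- s_out
    out$efficient <- rho >= 1 - tol
    if (model == "sbm") {
      out$score <- out$sbm_score
    } else {
      super <- stats::setNames(rep(NA_real_, n), names)
      combined <- rho
      for (j in which(out$efficient)) {
        if (n == 1L) {
          warning("single DMU: super-efficiency undefined, reported as Inf")
          super[j] <- Inf
        } else {
          sup <- .super_sbm_dea(X, Y, j)
          if (!sup$ok) {
            warning("super-SBM LP not solvable for ", names[j],
                    "; reported as Inf")
            super[j] <- Inf
          } else super[j] <- sup$delta
        }
        combined[j] <- super[j]
      }
      out$super_score <- super
      out$score <- stats::setNames(combined, names)
    }
  }
  class(out) <- "dea"
  out
}

.dea_mat <- function(a) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  storage.mode(a) <- "double"
  a
}

.dea_validate <- function(X, Y, strict = FALSE) {
  if (any(!is.finite(X)) || any(!is.finite(Y)) || any(X < 0) || any(Y < 0))
    stop("DEA data must be finite and non-negative", call. = FALSE)
  if (any(colSums(X > 0) == 0) || any(colSums(Y > 0) == 0))
    stop("every DMU needs at least one positive input and one positive output",
         call. = FALSE)
  if (strict && (any(X <= 0) || any(Y <= 0)))
    stop("SBM requires strictly positive inputs and outputs", call. = FALSE)
  invisible(TRUE)
}

# Two-stage input-oriented radial model for one DMU.
# Stage 1: min theta s.t. X lam <= theta x0, Y lam >= y0 (+ sum lam = 1 if vrs).
# Stage 2: max total slack at theta fixed; lambda reported from stage 2.
.radial_dea <- function(X, Y, j, vrs = FALSE, ref = seq_len(ncol(X)),
                        x0 = X[, j], y0 = Y[, j]) {
  m <- nrow(X); s <- nrow(Y); nr <- length(ref)
  Xr <- X[, ref, drop = FALSE]; Yr <- Y[, ref, drop = FALSE]
  obj <- c(1, rep(0, nr))
  A1 <- cbind(-x0, Xr); b1 <- rep(0, m)
  A2 <- cbind(0, Yr);  b2 <- y0
  A3 <- NULL; b3 <- NULL
  if (vrs) { A3 <- matrix(c(0, rep(1, nr)), 1); b3 <- 1 }
  st1 <- lp_solve(obj, A1, b1, A2, b2, A3, b3, maximize = FALSE)
  if (!st1$ok)
    return(list(ok = FALSE, theta = NA_real_,
                lambda = rep(NA_real_, ncol(X)),
                slack_in = rep(NA_real_, m), slack_out = rep(NA_real_, s)))
  theta <- st1$value
  # stage 2: vars lambda, s_in, s_out
  obj2 <- c(rep(0, nr), rep(1, m), rep(1, s))
  A3b <- rbind(cbind(Xr, diag(m), matrix(0, m, s)),
               cbind(Yr, matrix(0, s, m), -diag(s)))
  b3b <- c(theta * x0, y0)
  if (vrs) { A3b <- rbind(A3b, c(rep(1, nr), rep(0, m + s))); b3b <- c(b3b, 1) }
  st2 <- lp_solve(obj2, A_eq = A3b, b_eq = b3b, maximize = TRUE)
  lam_full <- rep(0, ncol(X))
  if (st2$ok) {
    lam_full[ref] <- st2$x[seq_len(nr)]
    slack_in <- st2$x[nr + seq_len(m)]
    slack_out <- st2$x[nr + m + seq_len(s)]
  } else {
    lam_full[ref] <- st1$x[-1L]
    slack_in <- pmax(theta * x0 - Xr %*% st1$x[-1L], 0)
    slack_out <- pmax(Yr %*% st1$x[-1L] - y0, 0)
  }
  list(ok = TRUE, theta = theta, lambda = lam_full,
       slack_in = as.numeric(slack_in), slack_out = as.numeric(slack_out))
}

# RTS by the sum-of-lambda rule at the CCR optimum, made robust to alternate
# optima: minimize and maximize sum(lambda) over the optimal face; CRS iff
# the interval [min, max] touches 1 (tolerance band), IRS if max < 1,
# DRS if min > 1.
.classify_rts_all <- function(X, Y, theta, tol = 1e-6) {
  n <- ncol(X)
  labels <- character(n)
  for (j in seq_len(n)) {
    obj <- rep(1, n)
    A1 <- X; b1 <- theta[j] * X[, j]
    A2 <- Y; b2 <- Y[, j]
    lo <- lp_solve(obj, A1, b1, A2, b2, maximize = FALSE)
    hi <- lp_solve(obj, A1, b1, A2, b2, maximize = TRUE)
    smin <- if (lo$ok) lo$value else NA_real_
    smax <- if (hi$ok) hi$value else smin
    labels[j] <- if (is.na(smin)) NA_character_
    else if (smin > 1 + 1e-6) "DRS"
    else if (smax < 1 - 1e-6) "IRS"
    else "CRS"
  }
  stats::setNames(labels, colnames(X))
}

# Tone's non-oriented SBM under CRS, Charnes-Cooper linearization:
# min t - (1/m) sum(S_in/x0)  s.t.  t + (1/s) sum(S_out/y0) = 1,
#   X L + S_in = t x0,  Y L - S_out = t y0,  all vars >= 0.
.sbm_dea <- function(X, Y, j) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  x0 <- X[, j]; y0 <- Y[, j]
  # vars: t, L (n), S_in (m), S_out (s)
  obj <- c(1, rep(0, n), -1 / (m * x0), rep(0, s))
  A3 <- rbind(
    c(1, rep(0, n), rep(0, m), 1 / (s * y0)),
    cbind(-x0, X, diag(m), matrix(0, m, s)),
    cbind(-y0, Y, matrix(0, s, m), -diag(s)))
  b3 <- c(1, rep(0, m), rep(0, s))
  sol <- lp_solve(obj, A_eq = A3, b_eq = b3, maximize = FALSE)
  if (!sol$ok) stop("SBM LP failed for DMU ", j, " (status ", sol$status, ")",
                    call. = FALSE)
  t <- sol$x[1L]
  list(rho = sol$value,
       lambda = sol$x[1L + seq_len(n)] / t,
       slack_in = sol$x[1L + n + seq_len(m)] / t,
       slack_out = sol$x[1L + n + m + seq_len(s)] / t)
}

# Tone's non-oriented super-SBM for an SBM-efficient DMU: reference set
# excludes the unit; score delta >= 1 is the minimized ratio of average
# input expansion to average output contraction. Linearized form:
# min (1/m) sum(xb/x0)  s.t. (1/s) sum(yb/y0) = 1,
#   xb >= X_R L, yb <= Y_R L, xb >= t x0, yb <= t y0, vars >= 0.
.super_sbm_dea <- function(X, Y, j) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  ref <- setdiff(seq_len(n), j)
  Xr <- X[, ref, drop = FALSE]; Yr <- Y[, ref, drop = FALSE]
  nr <- length(ref)
  x0 <- X[, j]; y0 <- Y[, j]
  # vars: t, L (nr), xb (m), yb (s)
  obj <- c(0, rep(0, nr), 1 / (m * x0), rep(0, s))
  A3 <- matrix(c(0, rep(0, nr), rep(0, m), 1 / (s * y0)), 1)
  b3 <- 1
  A2 <- rbind(
    cbind(0, -Xr, diag(m), matrix(0, m, s)),          # xb - X_R L >= 0
    cbind(0, Yr, matrix(0, s, m), -diag(s)),          # Y_R L - yb >= 0
    cbind(-x0, matrix(0, m, nr), diag(m), matrix(0, m, s)),  # xb - t x0 >= 0
    cbind(y0, matrix(0, s, nr), matrix(0, s, m), -diag(s)))  # t y0 - yb >= 0
  b2 <- rep(0, 2 * (m + s))
  sol <- lp_solve(obj, A_ge = A2, b_ge = b2, A_eq = A3, b_eq = b3,
                  maximize = FALSE)
  if (!sol$ok) return(list(ok = FALSE, delta = NA_real_))
  list(ok = TRUE, delta = sol$value)
}

#' Scale efficiency from technical and pure technical efficiency
#'
#' SE = TE / PTE, the share of inefficiency attributable to operating away
#' from the most productive scale; clipped to (0, 1 + 1e-9].
#'
#' @param te CCR scores. @param pte BCC scores (same length, PTE > 0).
#' @return Numeric vector of scale efficiencies.
#' @export
scale_efficiency <- function(te, pte) {
  if (length(te) != length(pte))
    stop("te and pte must have the same length", call. = FALSE)
  if (any(pte <= 0)) stop("PTE must be positive", call. = FALSE)
  pmin(te / pte, 1 + 1e-9)
}

#' Rank units by descending score with stable tie-breaking
#'
#' @param scores named numeric vector (e.g. combined super-SBM scores).
#' @return Integer ranks, a permutation of 1..n; exact ties keep input order.
#' @export
rank_by_score <- function(scores) {
  ord <- order(-scores, seq_along(scores))
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  stats::setNames(r, names(scores))
}

#' DEA on one panel year
#'
#' Convenience wrapper slicing a [panel_data()] into matrices (optionally
#' restricting inputs by resource class, which yields the human and non-human
#' efficiency series) and calling [dea()].
#'
#' @inheritParams panel_matrix
#' @inheritParams dea
#' @return A `dea` object.
#' @export
dea_panel <- function(panel, year, model = "ccr", input_class = "all", ...) {
  mats <- panel_matrix(panel, year, input_class)
  dea(mats$X, mats$Y, model, names = mats$units, ...)
}

#' Efficiency scores for every panel year
#'
#' @inheritParams dea_panel
#' @return units x years matrix of scores.
#' @export
dea_scores_by_year <- function(panel, model = "super-sbm",
                               input_class = "all", ...) {
  out <- matrix(NA_real_, length(panel$units), length(panel$years),
                dimnames = list(panel$units, as.character(panel$years)))
  for (y in panel$years)
    out[, as.character(y)] <- dea_panel(panel, y, model, input_class, ...)$score
  out
}

#' Count efficient units per year
#'
#' For each panel year, runs the CCR and BCC models and counts the units at
#' the frontier (score >= 1 - tol) for TE, PTE and SE (SE through the
#' TE = PTE x SE identity). Years with incomplete data are skipped with a
#' warning.
#'
#' @inheritParams dea_panel
#' @param tol efficiency tolerance.
#' @return data.frame with columns `year`, `te`, `pte`, `se`.
#' @export
count_efficient_per_year <- function(panel, input_class = "all", tol = 1e-6) {
  rows <- lapply(panel$years, function(y) {
    mats <- tryCatch(panel_matrix(panel, y, input_class), error = function(e) {
      warning("year ", y, " skipped: ", conditionMessage(e)); NULL
    })
    if (is.null(mats)) return(NULL)
    te <- dea(mats$X, mats$Y, "ccr", names = mats$units, rts = FALSE)$score
    pte <- dea(mats$X, mats$Y, "bcc", names = mats$units)$score
    se <- scale_efficiency(te, pte)
    data.frame(year = y, te = sum(te >= 1 - tol), pte = sum(pte >= 1 - tol),
               se = sum(se >= 1 - tol))
  })
  do.call(rbind, rows)
}

#' @export
print.dea <- function(x, digits = 4, ...) {
  cat("DEA (", toupper(x$model), "): ", x$n, " DMUs, ", x$m, " inputs, ",
      x$s, " outputs\n", sep = "")
  cat("Efficient units:", sum(x$efficient), "of", x$n, "\n")
  print(round(x$score, digits))
  invisible(x)
}

#' @export
summary.dea <- function(object, ...) {
  d <- data.frame(unit = object$units, score = object$score,
                  efficient = object$efficient,
                  row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(object$rts)) d$rts <- object$rts
  if (!is.null(object$super_score)) {
    d$sbm <- object$sbm_score
    d$super <- object$super_score
    d$rank <- rank_by_score(object$score)
  }
  d$slack_input <- colSums(object$slack_input)
  d$slack_output <- colSums(object$slack_output)
  structure(d, class = c("summary.dea", "data.frame"))
}

#' @export
print.summary.dea <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
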