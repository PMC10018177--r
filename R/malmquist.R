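#' Cross-period radial distance
#'
#' Input-oriented radial efficiency of a DMU's data from one period measured
#' against the frontier of (possibly) another period. With identical periods
#' this is the ordinary CCR (or BCC) score; a unit that dominates the old
#' frontier scores above 1.
#'
#' @param X_data,Y_data input/output matrices (columns DMUs) supplying the
#'   evaluated point.
#' @param X_frontier,Y_frontier matrices building the frontier.
#' @param dmu column index of the evaluated unit.
#' @param vrs add the convexity constraint (variable returns to scale).
#' @return list with `theta` (NA when the mixed-period VRS program is
#'   infeasible) and `ok`.
#' @export
cross_period_distance <- function(X_data, Y_data, X_frontier, Y_frontier,
                                  dmu, vrs = FALSE) {
  X_data <- .dea_mat(X_data); Y_data <- .dea_mat(Y_data)
  X_frontier <- .dea_mat(X_frontier); Y_frontier <- .dea_mat(Y_frontier)
  x0 <- X_data[, dmu]; y0 <- Y_data[, dmu]
  nr <- ncol(X_frontier)
  obj <- c(1, rep(0, nr))
  A1 <- cbind(-x0, X_frontier); b1 <- rep(0, nrow(X_frontier))
  A2 <- cbind(0, Y_frontier);  b2 <- y0
  A3 <- NULL; b3 <- NULL
  if (vrs) { A3 <- matrix(c(0, rep(1, nr)), 1); b3 <- 1 }
  sol <- lp_solve(obj, A1, b1, A2, b2, A3, b3, maximize = FALSE)
  if (!sol$ok) return(list(ok = FALSE, theta = NA_real_, status = sol$status))
  list(ok = TRUE, theta = sol$value, status = "optimal")
}

# All four CRS distances plus the two VRS own-period distances for one
# adjacent year pair. Returns a list of per-DMU vectors.
.malmquist_pair <- function(Xt, Yt, Xt1, Yt1) {
  n <- ncol(Xt)
  d <- function(Xd, Yd, Xf, Yf, vrs = FALSE)
    vapply(seq_len(n), function(j)
      cross_period_distance(Xd, Yd, Xf, Yf, j, vrs)$theta, numeric(1))
  list(d_t_t   = d(Xt, Yt, Xt, Yt),
       d_t1_t1 = d(Xt1, Yt1, Xt1, Yt1),
       d_t1_t  = d(Xt1, Yt1, Xt, Yt),    # new data, old frontier
       d_t_t1  = d(Xt, Yt, Xt1, Yt1),    # old data, new frontier
       v_t_t   = d(Xt, Yt, Xt, Yt, vrs = TRUE),
       v_t1_t1 = d(Xt1, Yt1, Xt1, Yt1, vrs = TRUE))
}

#' Malmquist productivity index with four-way decomposition
#'
#' Adjacent-period Fare-style construction: total factor productivity change
#' TFPC = TEC x TC, with catch-up TEC (ratio of own-period CCR scores)
#' further split into pure technical efficiency change PTEC (ratio of BCC
#' scores) and scale efficiency change SEC = TEC / PTEC; the frontier shift
#' TC is the geometric mean of the two cross-period ratios. With more than
#' two years the per-pair records are chained by geometric means per
#' component, which preserves both identities exactly.
#'
#' @param panel a [panel_data()] object.
#' @param years years to span (default all panel years, adjacent pairs).
#' @param input_class input restriction as in [panel_matrix()].
#' @param chain if `TRUE` (default) return one geometric-mean record per
#'   unit over all adjacent pairs; otherwise records per pair.
#' @return Object of class `malmquist`: data.frame with columns `unit`
#'   (and `from`, `to` when unchained), `tec`, `tc`, `ptec`, `sec`, `tfpc`.
#' @export
malmquist <- function(panel, years = NULL, input_class = "all", chain = TRUE) {
  stopifnot(inherits(panel, "panel_data"))
  if (is.null(years)) years <- panel$years
  years <- sort(years)
  if (length(years) < 2) stop("need at least two years", call. = FALSE)
  recs <- list()
  for (k in seq_len(length(years) - 1L)) {
    t0 <- years[k]; t1 <- years[k + 1L]
    a <- panel_matrix(panel, t0, input_class)
    b <- panel_matrix(panel, t1, input_class)
    d <- .malmquist_pair(a$X, a$Y, b$X, b$Y)
    tec <- d$d_t1_t1 / d$d_t_t
    tc <- sqrt((d$d_t1_t / d$d_t1_t1) * (d$d_t_t / d$d_t_t1))
    ptec <- d$v_t1_t1 / d$v_t_t
    sec <- tec / ptec
    tfpc <- tec * tc
    if (any(!is.finite(tfpc) | tfpc <= 0, na.rm = TRUE))
      stop("non-positive Malmquist component between ", t0, " and ", t1,
           call. = FALSE)
    recs[[k]] <- data.frame(unit = a$units, from = t0, to = t1,
                            tec = tec, tc = tc, ptec = ptec, sec = sec,
                            tfpc = tfpc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, recs)
  if (chain && length(recs) >= 1L) {
    gm <- function(v) exp(mean(log(v), na.rm = TRUE))
    agg <- lapply(split(res, res$unit), function(d) {
      tec <- gm(d$tec); tc <- gm(d$tc); ptec <- gm(d$ptec)
      data.frame(unit = d$unit[1L], tec = tec, tc = tc, ptec = ptec,
                 sec = tec / ptec, tfpc = tec * tc,
                 n_pairs = sum(is.finite(d$tfpc)),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, agg[unique(panel$units)])
    rownames(res) <- NULL
  }
  structure(list(records = res, chained = chain,
                 years = years, input_class = input_class),
            class = "malmquist")
}

#' @export
print.malmquist <- function(x, digits = 3, ...) {
  cat("Malmquist productivity decomposition",
      if (x$chained) sprintf("(chained %d-%d)", min(x$years), max(x$years))
      else "(per adjacent pair)", "\n")
  d <- x$records
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits)
  print.data.frame(utils::head(d, 12), row.names = FALSE)
  if (nrow(x$records) > 12) cat("... (", nrow(x$records), "rows )\n")
  invisible(x)
}

#' @export
summary.malmquist <- function(object, ...) {
  d <- object$records
  comp <- c("tec", "tc", "ptec", "sec", "tfpc")
  gmean <- vapply(d[comp], function(v) exp(mean(log(v), na.rm = TRUE)),
                  numeric(1))
  structure(list(geometric_means = gmean,
                 n_decline_tfpc = sum(d$tfpc < 1, na.rm = TRUE),
                 n_units = length(unique(d$unit))),
            class = "summary.malmquist")
}

#' @export
print.summary.malmquist <- function(x, ...) {
  cat("Geometric mean components:\n")
  print(round(x$geometric_means, 3))
  cat("Units with TFPC < 1:", x$n_decline_tfpc, "of", x$n_units, "\n")
  invisible(x)
}
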