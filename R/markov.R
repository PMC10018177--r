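#' Quantile state classification of a score panel
#'
#' Discretizes a units x years score matrix into k ordered states by quantile
#' cut points (default quartiles labelled L, ML, MH, H: lowest quarter is L,
#' top quarter is H). Intervals are right-closed, so a tied score sitting on
#' a cut point falls in the lower state. Cut points are computed either on
#' the whole pooled panel (default, matching two-period transition tables) or
#' per year.
#'
#' @param scores numeric matrix, units in rows, years in columns.
#' @param k number of states (>= 2).
#' @param pooling `"whole_period"` or `"per_year"`.
#' @param labels optional state labels, lowest first.
#' @return Object of class `state_panel`: `states` (character matrix),
#'   `levels`, `cuts`, `scores`, `pooling`.
#' @export
classify_states <- function(scores, k = 4,
                            pooling = c("whole_period", "per_year"),
                            labels = NULL) {
  pooling <- match.arg(pooling)
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (length(scores) < k) stop("need at least k scores", call. = FALSE)
  if (is.null(labels))
    labels <- if (k == 4) c("L", "ML", "MH", "H") else paste0("S", seq_len(k))
  if (k == 1) {   # degenerate single-state classification (no conditioning)
    states <- matrix(labels[1], nrow(scores), ncol(scores),
                     dimnames = dimnames(scores))
    return(structure(list(states = states, levels = labels,
                          cuts = numeric(0), scores = scores, k = 1L,
                          pooling = pooling), class = "state_panel"))
  }
  cut_one <- function(x) {
    cuts <- stats::quantile(x, probs = seq_len(k - 1) / k, names = FALSE)
    breaks <- c(-Inf, cuts, Inf)
    if (anyDuplicated(cuts) || diff(range(x)) == 0)
      stop("degenerate classification: quantile cut points collapse",
           call. = FALSE)
    list(cuts = cuts,
         states = labels[as.integer(cut(x, breaks, right = TRUE))])
  }
  if (pooling == "whole_period") {
    cl <- cut_one(as.numeric(scores))
    states <- matrix(cl$states, nrow(scores), ncol(scores))
    cuts <- cl$cuts
  } else {
    states <- scores
    cuts <- matrix(NA_real_, k - 1, ncol(scores))
    st <- matrix(NA_character_, nrow(scores), ncol(scores))
    for (t in seq_len(ncol(scores))) {
      cl <- cut_one(scores[, t])
      st[, t] <- cl$states
      cuts[, t] <- cl$cuts
    }
    states <- st
  }
  dimnames(states) <- dimnames(scores)
  structure(list(states = states, levels = labels, cuts = cuts,
                 scores = scores, k = k, pooling = pooling),
            class = "state_panel")
}

#' @export
print.state_panel <- function(x, ...) {
  cat("State panel:", nrow(x$states), "units x", ncol(x$states), "years,",
      x$k, "states (", paste(x$levels, collapse = " < "), "),",
      x$pooling, "quantiles\n")
  print(table(factor(x$states, levels = x$levels)))
  invisible(x)
}

# coerce a state_panel or a character/factor matrix to (matrix, levels)
.state_mat <- function(states, levels = NULL) {
  if (inherits(states, "state_panel"))
    return(list(m = states$states, levels = states$levels))
  m <- as.matrix(states)
  if (is.null(levels)) levels <- sort(unique(as.character(m)))
  list(m = m, levels = levels)
}

#' Markov transition matrix from a state panel
#'
#' Pools every (unit, t) to (unit, t+1) movement and estimates M_ij =
#' n_ij / n_i. Rows with no origin observations are undefined (NA), never
#' zero-filled.
#'
#' @param states a [classify_states()] object or character matrix
#'   (units x years).
#' @param levels state order when `states` is a bare matrix.
#' @param years optional subset of origin-year column indices to pool.
#' @return Object of class `transition_model`: `counts`, `probs`, `n_i`,
#'   `levels`, `condition`.
#' @export
transition_matrix <- function(states, levels = NULL, years = NULL) {
  sm <- .state_mat(states, levels)
  m <- sm$m; lv <- sm$levels
  if (ncol(m) < 2) stop("need at least 2 years of states", call. = FALSE)
  org <- if (is.null(years)) seq_len(ncol(m) - 1L) else years
  from <- factor(m[, org, drop = FALSE], levels = lv)
  to <- factor(m[, org + 1L, drop = FALSE], levels = lv)
  keep <- !is.na(from) & !is.na(to)
  counts <- table(from = from[keep], to = to[keep])
  counts <- matrix(as.integer(counts), length(lv), length(lv),
                   dimnames = list(from = lv, to = lv))
  .transition_model(counts, lv)
}

.transition_model <- function(counts, levels, condition = NULL) {
  n_i <- rowSums(counts)
  probs <- counts / ifelse(n_i > 0, n_i, NA_real_)
  probs[n_i == 0, ] <- NA_real_
  structure(list(counts = counts, probs = probs, n_i = n_i,
                 levels = levels, condition = condition),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, digits = 3, ...) {
  cat("Markov transition matrix",
      if (!is.null(x$condition)) paste0("(neighbor state: ", x$condition, ")"),
      "\n")
  print(round(x$probs, digits))
  cat("origin counts:", paste(x$n_i, collapse = " "), "\n")
  invisible(x)
}

#' Spatial lag of a unit vector
#'
#' lag_i = sum_j W_ij y_j; with row-standardized weights this is the weighted
#' neighbor average. Units without neighbors get NA.
#'
#' @param values named numeric vector aligned with the weights.
#' @param w a [spatial_weights()] object.
#' @return Numeric vector of lags.
#' @export
spatial_lag <- function(values, w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(names(values))) check_alignment(w, names(values))
  lag <- as.numeric(w$matrix %*% values)
  lag[rowSums(w$matrix) == 0] <- NA_real_
  stats::setNames(lag, w$unit_ids)
}

#' Spatially conditioned Markov transition matrices
#'
#' Classifies both the scores and their spatial lags into k quantile states
#' (each series on its own pooled quantile scheme), then splits the pooled
#' unit-year transitions by the lag state at the origin year: one k x k
#' transition matrix per neighborhood condition. Cell-wise, the conditional
#' counts sum exactly to the unconditional counts (units with undefined lags
#' are excluded from both sides with a warning).
#'
#' @param scores units x years numeric matrix (rownames = units).
#' @param w a [spatial_weights()] object aligned with the rows.
#' @param k number of score states.
#' @param lag_k number of neighborhood (lag) condition classes; `lag_k = 1`
#'   reduces to the unconditional chain.
#' @param pooling quantile pooling rule, as in [classify_states()].
#' @return Object of class `spatial_markov`: `conditional` (list of
#'   [transition_matrix()] models, one per lag state), `unconditional`,
#'   `states`, `lag_states`.
#' @export
spatial_markov <- function(scores, w, k = 4, lag_k = k,
                           pooling = c("whole_period", "per_year")) {
  pooling <- match.arg(pooling)
  scores <- as.matrix(scores)
  check_alignment(w, rownames(scores))
  lags <- apply(scores, 2, function(col) as.numeric(w$matrix %*% col))
  rownames(lags) <- rownames(scores)
  drop_units <- rowSums(w$matrix) == 0
  if (any(drop_units)) {
    warning("units with no neighbors excluded from spatial Markov: ",
            paste(w$unit_ids[drop_units], collapse = ", "))
    scores <- scores[!drop_units, , drop = FALSE]
    lags <- lags[!drop_units, , drop = FALSE]
  }
  st <- classify_states(scores, k, pooling)
  lag_st <- classify_states(lags, lag_k, pooling,
                            labels = if (lag_k == k) st$levels else NULL)
  lv <- st$levels
  cond <- vector("list", lag_k); names(cond) <- lag_st$levels
  for (cnd in lag_st$levels) {
    counts <- matrix(0L, k, k, dimnames = list(from = lv, to = lv))
    for (t in seq_len(ncol(scores) - 1L)) {
      sel <- lag_st$states[, t] == cnd
      if (!any(sel)) next
      f <- factor(st$states[sel, t], levels = lv)
      g <- factor(st$states[sel, t + 1L], levels = lv)
      counts <- counts + unclass(table(f, g))
    }
    cond[[cnd]] <- .transition_model(counts, lv, condition = cnd)
  }
  uncond <- transition_matrix(st)
  structure(list(conditional = cond, unconditional = uncond,
                 states = st, lag_states = lag_st, k = k),
            class = "spatial_markov")
}

#' @export
print.spatial_markov <- function(x, digits = 3, ...) {
  cat("Spatial Markov chain:", x$k, "conditional matrices\n")
  for (m in x$conditional) print(m, digits)
  invisible(x)
}

#' Anderson-Goodman test of time homogeneity
#'
#' Splits the pooled transitions into sub-periods (a new sub-period starts at
#' each breakpoint year index) and tests whether the per-period transition
#' matrices differ from the pooled matrix, using the Pearson chi-square
#' statistic q = sum_t sum_ij n_i(t) (M_ij(t) - M_ij)^2 / M_ij over cells
#' with pooled M_ij > 0, and the likelihood-ratio statistic
#' LR = 2 sum_t sum_ij n_ij(t) log(M_ij(t) / M_ij) over cells with
#' n_ij(t) > 0. Degrees of freedom: (number of sub-periods - 1) times the
#' sum over defined pooled rows of (positive columns - 1).
#'
#' @param states a [classify_states()] object or character matrix.
#' @param breakpoints indices (1-based, within the year columns) at which a
#'   new sub-period begins; e.g. `breakpoints = 6` splits 8 years into
#'   origin-years 1-5 and 6-7.
#' @param levels state order for bare matrices.
#' @return Object of class `markov_homogeneity` with `chi2`, `lr`, `df`,
#'   p-values, and the per-period transition models.
#' @export
time_homogeneity_test <- function(states, breakpoints, levels = NULL) {
  sm <- .state_mat(states, levels)
  m <- sm$m; lv <- sm$levels
  n_years <- ncol(m)
  breakpoints <- sort(unique(as.integer(breakpoints)))
  if (any(breakpoints <= 1L | breakpoints > n_years - 1L))
    stop("breakpoints must lie strictly inside the origin-year range",
         call. = FALSE)
  starts <- c(1L, breakpoints)
  ends <- c(breakpoints - 1L, n_years - 1L)
  periods <- Map(seq, starts, ends)
  sub <- lapply(periods, function(org) transition_matrix(m, lv, years = org))
  for (i in seq_along(sub))
    if (sum(sub[[i]]$counts) == 0)
      stop("sub-period ", i, " has no transitions", call. = FALSE)
  pooled <- transition_matrix(m, lv)
  M <- pooled$probs
  q <- 0; lr <- 0
  for (s in sub) {
    n_it <- s$n_i
    Mt <- s$probs
    for (i in seq_along(lv)) {
      if (n_it[i] == 0 || pooled$n_i[i] == 0) next
      pos <- which(M[i, ] > 0)
      q <- q + sum(n_it[i] * (Mt[i, pos] - M[i, pos])^2 / M[i, pos])
      nz <- which(s$counts[i, ] > 0)
      lr <- lr + 2 * sum(s$counts[i, nz] * log(Mt[i, nz] / M[i, nz]))
    }
  }
  df <- (length(sub) - 1L) *
    sum(vapply(seq_along(lv), function(i) {
      if (pooled$n_i[i] == 0) return(0L)
      max(sum(M[i, ] > 0) - 1L, 0L)
    }, integer(1)))
  structure(list(chi2 = q, lr = lr, df = df,
                 p_chi2 = stats::pchisq(q, df, lower.tail = FALSE),
                 p_lr = stats::pchisq(lr, df, lower.tail = FALSE),
                 sub_models = sub, pooled = pooled,
                 n_periods = length(sub)),
            class = "markov_homogeneity")
}

#' @export
print.markov_homogeneity <- function(x, ...) {
  cat("Anderson-Goodman time-homogeneity test (", x$n_periods,
      "sub-periods )\n")
  cat(sprintf("  Pearson chi2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_chi2))
  cat(sprintf("  Likelihood ratio = %.3f, df = %d, p = %.4g\n",
              x$lr, x$df, x$p_lr))
  invisible(x)
}
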