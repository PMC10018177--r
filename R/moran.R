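#' Global Moran's I with permutation inference
#'
#' I = (n / S0) * sum_ij W_ij z_i z_j / sum_i z_i^2 with z = x - mean(x) and
#' S0 the total weight; with row-standardized contiguity weights the statistic
#' lies in an interval containing [-1, 1] and its expectation under the
#' randomization null is -1/(n-1). Inference is by random relabeling of the
#' values over the units (two-sided pseudo p-value with the (r+1)/(n+1)
#' correction).
#'
#' Units with missing values are dropped pairwise (the weights submatrix is
#' re-standardized if the weights were standardized).
#'
#' @param x named numeric vector aligned with the weights.
#' @param w a [spatial_weights()] object.
#' @param n_perm number of permutations (0 disables inference).
#' @param seed integer seed for the permutations.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return Object of class `c("moran", "htest")` with `statistic` (I),
#'   `p.value`, `expectation`, `n_perm`, `seed`.
#' @export
moran_test <- function(x, w, n_perm = 999, seed = 20130101,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(names(x))) check_alignment(w, names(x))
  W <- w$matrix
  if (anyNA(x)) {
    keep <- !is.na(x)
    x <- x[keep]; W <- W[keep, keep, drop = FALSE]
    if (w$standardized) {
      rs <- rowSums(W)
      W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
    }
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 units", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in values", call. = FALSE)
  S0 <- sum(W)
  if (S0 <= 0) stop("total weight is zero", call. = FALSE)
  I_of <- function(v) {
    z <- v - mean(v)
    (n / S0) * as.numeric(z %*% W %*% z) / sum(z^2)
  }
  I <- I_of(x)
  E_I <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    sims <- vapply(seq_len(n_perm), function(r) I_of(sample(x)), numeric(1))
    p_ge <- (1 + sum(sims >= I)) / (n_perm + 1)
    p_le <- (1 + sum(sims <= I)) / (n_perm + 1)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  }
  structure(list(statistic = c(I = I), p.value = p,
                 expectation = E_I, n_perm = n_perm, seed = seed,
                 alternative = alternative,
                 method = "Moran's I (permutation inference)",
                 data.name = deparse(substitute(x))),
            class = c("moran", "htest"))
}

#' Local Moran (LISA) statistics with conditional permutation
#'
#' LISA_i = z_i * sum_j W_ij z_j with z standardized by the population
#' standard deviation, so that sum_i LISA_i = n * I under row-standardized
#' weights. Each unit gets a quadrant label from the signs of (z_i, lag_i):
#' HH (high surrounded by high), LL, HL, LH. Per-unit p-values come from
#' conditional permutation (hold unit i fixed, permute the remaining values
#' across its neighbors), the GeoDa convention.
#'
#' @inheritParams moran_test
#' @return Object of class `lisa`: data.frame-like list with `lisa`,
#'   `quadrant`, `p.value`, `z`, `lag`, plus `I` (the global statistic).
#' @export
local_moran <- function(x, w, n_perm = 999, seed = 20130101) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(names(x))) check_alignment(w, names(x))
  n <- length(x)
  if (stats::sd(x) == 0) stop("zero variance in values", call. = FALSE)
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  W <- w$matrix
  lag <- as.numeric(W %*% z)
  isl <- rowSums(W) == 0
  lag[isl] <- NA_real_
  lisa <- z * lag
  quadrant <- ifelse(is.na(lag), NA_character_,
              ifelse(z > 0 & lag > 0, "HH",
              ifelse(z < 0 & lag < 0, "LL",
              ifelse(z > 0, "HL", "LH"))))
  p <- rep(NA_real_, n)
  if (n_perm > 0) {
    set.seed(seed)
    for (i in which(!isl)) {
      wi <- W[i, -i]
      zo <- z[-i]
      sims <- vapply(seq_len(n_perm), function(r)
        z[i] * sum(wi * sample(zo)), numeric(1))
      p_ge <- (1 + sum(sims >= lisa[i])) / (n_perm + 1)
      p_le <- (1 + sum(sims <= lisa[i])) / (n_perm + 1)
      p[i] <- min(1, 2 * min(p_ge, p_le))
    }
  }
  I <- sum(lisa[!isl]) / n
  structure(list(unit = w$unit_ids, lisa = lisa, quadrant = quadrant,
                 p.value = p, z = z, lag = lag, I = I,
                 n_perm = n_perm, seed = seed),
            class = "lisa")
}

#' @export
print.lisa <- function(x, digits = 3, ...) {
  d <- data.frame(unit = x$unit, lisa = round(x$lisa, digits),
                  quadrant = x$quadrant, p = round(x$p.value, digits))
  print.data.frame(d, row.names = FALSE)
  cat("sum(LISA)/n =", round(x$I, digits), "(global Moran's I)\n")
  invisible(x)
}

#' Spatial effect labels from significant LISA quadrants
#'
#' Significant HH units are labelled `diffusion` (rapid growth spilling
#' over), LL `lagging`, HL `polarization` (a high unit draining low
#' neighbors, also called reflux), LH `centrifugal`; insignificant or
#' undefined units get `none`.
#'
#' @param lisa a [local_moran()] result.
#' @param alpha significance level (default 0.05).
#' @return Named character vector of labels.
#' @export
label_effects <- function(lisa, alpha = 0.05) {
  stopifnot(inherits(lisa, "lisa"))
  lab <- rep("none", length(lisa$unit))
  sig <- !is.na(lisa$p.value) & lisa$p.value <= alpha
  map <- c(HH = "diffusion", LL = "lagging",
           HL = "polarization", LH = "centrifugal")
  lab[sig] <- unname(map[lisa$quadrant[sig]])
  stats::setNames(lab, lisa$unit)
}

#' Global Moran's I per year for one or more score series
#'
#' @param series named list of units x years score matrices (or a single
#'   matrix, taken as series `"total"`).
#' @param w a [spatial_weights()] object aligned with the rows.
#' @inheritParams moran_test
#' @return Long data.frame with columns `year`, `series`, `moran_i`, `p`.
#' @export
moran_by_year <- function(series, w, n_perm = 999, seed = 20130101) {
  if (is.matrix(series)) series <- list(total = series)
  rows <- list()
  for (nm in names(series)) {
    sc <- series[[nm]]
    check_alignment(w, rownames(sc))
    for (t in seq_len(ncol(sc))) {
      mt <- moran_test(stats::setNames(sc[, t], rownames(sc)), w,
                       n_perm = n_perm, seed = seed + t)
      rows[[length(rows) + 1L]] <-
        data.frame(year = colnames(sc)[t], series = nm,
                   moran_i = unname(mt$statistic), p = mt$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
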