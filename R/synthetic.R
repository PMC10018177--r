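# Synthetic-data generators with known ground truth. Every analysis stage in
# the package has a recovery test against one of these; none of them attempts
# to imitate the marginals of any real yearbook series — they are structural
# scenarios (known frontier, known spatial strength, known transition matrix,
# known censored-regression coefficients).

#' Panel from a known production frontier
#'
#' Inputs are drawn log-normally; each output is a Cobb-Douglas function of
#' the inputs (equal exponents; summing to one under the default constant
#' returns) scaled by a technology level growing at `tech_drift` per year,
#' and damped by multiplicative inefficiency exp(-u) with half-normal u.
#' The true efficiency exp(-u) per unit-year is returned, so DEA recovery is
#' directly checkable (with one input and one output the CCR score is exactly
#' the normalized output/input ratio, hence rank-identical to the truth).
#'
#' @param n_units,n_years panel dimensions (first year `first_year`).
#' @param m_inputs,s_outputs variable counts. With the default 5 inputs the
#'   variables carry facility-style names and resource classes (staff and
#'   social workers are `human`; institutions, fixed assets and beds are
#'   `non_human`); otherwise generic names alternate classes.
#' @param inefficiency_sd scale of the half-normal inefficiency (0 puts every
#'   unit on the frontier).
#' @param tech_drift proportional frontier shift per year (0.02 = 2%).
#' @param returns `"crs"` (exponents sum to 1) or `"vrs"` (sum 0.8).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param first_year first calendar year label.
#' @param unit_ids optional unit labels (default U01..Un), e.g. province
#'   names so the panel aligns with [china_province_weights()].
#' @return list with `panel` (a [panel_data()]) and `truth` (generator name,
#'   seed, params, and the units x years matrix of true efficiencies).
#' @export
generate_frontier_panel <- function(n_units = 31, n_years = 8,
                                    m_inputs = 5, s_outputs = 5,
                                    inefficiency_sd = 0.25,
                                    tech_drift = 0.02,
                                    returns = c("crs", "vrs"),
                                    seed = 1, first_year = 2013,
                                    unit_ids = NULL) {
  returns <- match.arg(returns)
  if (n_units < 2 || n_years < 1 || m_inputs < 1 || s_outputs < 1)
    stop("invalid dimensions", call. = FALSE)
  set.seed(seed)
  units <- if (is.null(unit_ids)) sprintf("U%02d", seq_len(n_units))
           else as.character(unit_ids)
  if (length(units) != n_units)
    stop("unit_ids length must equal n_units", call. = FALSE)
  years <- first_year + seq_len(n_years) - 1L
  if (m_inputs == 5) {
    in_names <- c("staff", "social_workers", "institutions", "fixed_assets", "beds")
    in_class <- c("human", "human", "non_human", "non_human", "non_human")
  } else {
    in_names <- paste0("input_", seq_len(m_inputs))
    in_class <- rep(c("human", "non_human"), length.out = m_inputs)
  }
  out_names <- if (s_outputs == 5)
    c("revenue", "disabled_residents", "partial_residents",
      "independent_residents", "outpatients")
  else paste0("output_", seq_len(s_outputs))
  schema <- data.frame(
    variable = c(in_names, out_names),
    role = c(rep("input", m_inputs), rep("output", s_outputs)),
    resource_class = c(in_class, rep("other", s_outputs)),
    stringsAsFactors = FALSE)

  expo <- rep(if (returns == "crs") 1 else 0.8, m_inputs) / m_inputs
  out_scale <- exp(stats::runif(s_outputs, -0.5, 0.5))
  eff <- matrix(NA_real_, n_units, n_years,
                dimnames = list(units, as.character(years)))
  rows <- vector("list", n_units * n_years)
  idx <- 0L
  for (t in seq_len(n_years)) {
    tech <- (1 + tech_drift)^(t - 1L)
    for (i in seq_len(n_units)) {
      x <- stats::rlnorm(m_inputs, meanlog = 1, sdlog = 0.4)
      u <- abs(stats::rnorm(1, 0, inefficiency_sd))
      eff[i, t] <- exp(-u)
      frontier <- tech * prod(x^expo)
      y <- out_scale * frontier * exp(-u)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(unit = units[i], year = years[t],
                                variable = c(in_names, out_names),
                                value = c(x, y), stringsAsFactors = FALSE)
    }
  }
  panel <- panel_data(do.call(rbind, rows), schema)
  list(panel = panel,
       truth = list(generator = "frontier_panel", seed = seed,
                    efficiency = eff, inefficiency_sd = inefficiency_sd,
                    tech_drift = tech_drift, returns = returns))
}

#' Spatially autocorrelated field from a SAR process
#'
#' Draws x = (I - rho W)^{-1} eps with standard-normal innovations, the
#' textbook simultaneous autoregressive field used to probe Moran's I.
#'
#' @param w a row-standardized [spatial_weights()] object.
#' @param rho autoregressive strength, |rho| < 1.
#' @param n_reps number of independent fields.
#' @param seed integer seed.
#' @return list with `values` (n x n_reps matrix, rownames = units) and
#'   `truth` (rho, seed).
#' @export
generate_sar_field <- function(w, rho, n_reps = 1, seed = 1) {
  stopifnot(inherits(w, "spatial_weights"))
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  n <- length(w$unit_ids)
  A <- diag(n) - rho * w$matrix
  if (abs(det(A)) < 1e-12) stop("I - rho W is singular", call. = FALSE)
  set.seed(seed)
  eps <- matrix(stats::rnorm(n * n_reps), n, n_reps)
  vals <- solve(A, eps)
  rownames(vals) <- w$unit_ids
  list(values = vals, truth = list(generator = "sar_field", rho = rho,
                                   seed = seed))
}

#' Discrete state sequences from a known transition matrix
#'
#' Units evolve independently by `M_true`; with probability
#' `spatial_coupling` a unit's transition row is replaced by a 50/50 blend of
#' its own row and a point mass on the modal state among its neighbors at the
#' origin year, inducing the kind of neighbor-conditioned mobility a spatial
#' Markov analysis detects. Coupling 0 gives a plain homogeneous chain.
#'
#' @param n_units,n_years dimensions.
#' @param M_true k x k row-stochastic matrix.
#' @param spatial_coupling probability in [0, 1] of the neighbor-tilted row.
#' @param w [spatial_weights()] (required when coupling > 0).
#' @param seed integer seed.
#' @param labels state labels (default L/ML/MH/H for k = 4).
#' @param init optional initial distribution (default stationary).
#' @return list with `states` (units x years character matrix) and `truth`.
#' @export
generate_markov_states <- function(n_units = 31, n_years = 8, M_true,
                                   spatial_coupling = 0, w = NULL, seed = 1,
                                   labels = NULL, init = NULL) {
  M_true <- as.matrix(M_true)
  k <- nrow(M_true)
  if (ncol(M_true) != k || any(M_true < 0) ||
      max(abs(rowSums(M_true) - 1)) > 1e-8)
    stop("M_true must be row-stochastic", call. = FALSE)
  if (spatial_coupling < 0 || spatial_coupling > 1)
    stop("spatial_coupling must be in [0, 1]", call. = FALSE)
  if (spatial_coupling > 0 && is.null(w))
    stop("spatial coupling requires weights", call. = FALSE)
  if (is.null(labels))
    labels <- if (k == 4) c("L", "ML", "MH", "H") else paste0("S", seq_len(k))
  set.seed(seed)
  if (is.null(init)) {
    # stationary distribution of M_true
    ev <- eigen(t(M_true))
    v <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
    init <- v / sum(v)
  }
  S <- matrix(NA_integer_, n_units, n_years)
  S[, 1] <- sample.int(k, n_units, replace = TRUE, prob = init)
  nbr <- if (!is.null(w)) w$matrix > 0 else NULL
  for (t in 2:n_years) {
    for (i in seq_len(n_units)) {
      row <- M_true[S[i, t - 1L], ]
      if (spatial_coupling > 0 && stats::runif(1) < spatial_coupling) {
        nb_states <- S[nbr[i, ], t - 1L]
        if (length(nb_states)) {
          modal <- as.integer(names(which.max(table(nb_states))))
          tilt <- numeric(k); tilt[modal] <- 1
          row <- 0.5 * row + 0.5 * tilt
        }
      }
      S[i, t] <- sample.int(k, 1, prob = row)
    }
  }
  states <- matrix(labels[S], n_units, n_years,
                   dimnames = list(if (!is.null(w)) w$unit_ids
                                   else sprintf("U%02d", seq_len(n_units)),
                                   NULL))
  list(states = states,
       truth = list(generator = "markov_states", M = M_true,
                    spatial_coupling = spatial_coupling, seed = seed,
                    labels = labels))
}

#' Censored linear-model outcomes with known coefficients
#'
#' Latent Y* = alpha + X beta + eps with eps ~ N(0, sigma^2) and standard
#' normal covariates; the observed response is clipped at the censoring
#' bounds.
#'
#' @param n sample size.
#' @param alpha intercept. @param beta coefficient vector. @param sigma
#'   error scale > 0.
#' @param lower,upper censoring bounds (default left at 0, no upper bound).
#' @param seed integer seed.
#' @return list with `data` (data.frame `y`, `x1..xp`) and `truth`.
#' @export
generate_tobit_data <- function(n, alpha = 0, beta, sigma = 1,
                                lower = 0, upper = Inf, seed = 1) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  set.seed(seed)
  p <- length(beta)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  ystar <- alpha + as.numeric(X %*% beta) + stats::rnorm(n, 0, sigma)
  y <- pmin(pmax(ystar, lower), upper)
  list(data = data.frame(y = y, X),
       truth = list(generator = "tobit", alpha = alpha, beta = beta,
                    sigma = sigma, lower = lower, upper = upper, seed = seed,
                    frac_censored = mean(ystar <= lower | ystar >= upper)))
}
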