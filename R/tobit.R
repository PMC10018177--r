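#' Normalize a design matrix, recording the transform
#'
#' Min-max maps every column onto [0, 1]; z-score centers to mean 0, sd 1.
#' The recorded transform can be re-applied to new data so that prediction
#' uses the training scaling. Constant columns are rejected.
#'
#' @param design numeric matrix or data.frame of covariates.
#' @param method `"minmax"`, `"zscore"` or `"none"`.
#' @return list with `design` (transformed matrix) and `transform`
#'   (per-column shift/scale, reusable via [apply_normalization()]).
#' @export
normalize_design <- function(design, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  X <- as.matrix(design)
  if (method == "none")
    return(list(design = X,
                transform = list(method = "none",
                                 shift = rep(0, ncol(X)),
                                 scale = rep(1, ncol(X)))))
  rng <- apply(X, 2, function(col) diff(range(col)))
  if (any(rng == 0))
    stop("constant covariate cannot be normalized: ",
         paste(colnames(X)[rng == 0], collapse = ", "), call. = FALSE)
  if (method == "minmax") {
    shift <- apply(X, 2, min); scale <- rng
  } else {
    shift <- colMeans(X); scale <- apply(X, 2, stats::sd)
  }
  Xn <- sweep(sweep(X, 2, shift), 2, scale, "/")
  list(design = Xn,
       transform = list(method = method, shift = shift, scale = scale))
}

#' Apply a recorded normalization to new data
#' @param design new covariate matrix (same columns).
#' @param transform the `transform` element of [normalize_design()].
#' @return Transformed matrix.
#' @export
apply_normalization <- function(design, transform) {
  X <- as.matrix(design)
  sweep(sweep(X, 2, transform$shift), 2, transform$scale, "/")
}

#' Censored (Tobit) regression by maximum likelihood
#'
#' Fits the censored-normal model: latent Y* = X beta + eps,
#' eps ~ N(0, sigma^2), observed Y clipped at the censoring bounds (default
#' left-censored at 0, no upper bound — the usual setting for DEA efficiency
#' determinants; `right = 1` gives the two-sided variant for scores bounded
#' above). The log-likelihood combines the normal density for interior
#' observations with probit mass at each bound; it is maximized by BFGS from
#' the least-squares start, so with no censored observations the estimates
#' coincide with least squares. Standard errors come from the observed
#' information, or from a cluster-robust sandwich when `cluster` is given
#' (the pooled "panel Tobit" default). The reported LR statistic compares
#' against the intercept-only model and pseudo-R2 is McFadden's
#' 1 - logLik/logLik0.
#'
#' @param formula model formula, e.g. `y ~ x1 + x2`.
#' @param data data.frame holding the variables.
#' @param left,right censoring bounds (defaults 0 and +Inf).
#' @param normalize covariate normalization: `"none"` (default; see
#'   [normalize_design()] to normalize ahead of fitting), `"minmax"` or
#'   `"zscore"`.
#' @param cluster optional vector of cluster ids (e.g. units of a panel) for
#'   robust standard errors.
#' @param control passed to [stats::optim()] (BFGS).
#' @return Object of class `tobit`: coefficients, `sigma`, `se`, `vcov`,
#'   `logLik`, `lr`, `pseudo_r2`, censoring counts, the normalization
#'   transform, and the usual accessor methods (`coef`, `vcov`, `logLik`,
#'   `predict`, `residuals`, `summary`).
#' @examples
#' sim <- generate_tobit_data(500, alpha = 0.5, beta = c(1, -0.5),
#'                            sigma = 0.5, seed = 7)
#' fit <- tobit(y ~ x1 + x2, sim$data)
#' coef(fit)
#' @export
tobit <- function(formula, data, left = 0, right = Inf,
                  normalize = c("none", "minmax", "zscore"),
                  cluster = NULL, control = list()) {
  normalize <- match.arg(normalize)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  transform <- NULL
  if (normalize != "none") {
    keep <- colnames(X) != "(Intercept)"
    nd <- normalize_design(X[, keep, drop = FALSE], normalize)
    X[, keep] <- nd$design
    transform <- nd$transform
  }
  if (any(y < left - 1e-12) || any(y > right + 1e-12))
    stop("responses outside the censoring bounds", call. = FALSE)
  lo <- y <= left
  hi <- is.finite(right) & y >= right
  mid <- !lo & !hi
  if (!any(mid)) stop("need at least one uncensored observation", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)

  fit <- .tobit_mle(y, X, left, right, lo, hi, mid, control)

  # intercept-only null for the LR statistic and pseudo-R2
  X0 <- X[, "(Intercept)", drop = FALSE]
  if (ncol(X) > 1 && "(Intercept)" %in% colnames(X)) {
    null <- .tobit_mle(y, X0, left, right, lo, hi, mid, control)
    lr <- 2 * (fit$logLik - null$logLik)
    pseudo_r2 <- 1 - fit$logLik / null$logLik
  } else {
    lr <- NA_real_; pseudo_r2 <- NA_real_
  }

  vcov_full <- fit$vcov
  if (!is.null(cluster)) {
    sc <- .tobit_scores(y, X, left, right, lo, hi, mid,
                        fit$beta, fit$sigma)
    g <- rowsum(sc, group = as.character(cluster))
    meat <- crossprod(g)
    vcov_full <- fit$vcov %*% meat %*% fit$vcov
  }
  p <- ncol(X)
  se <- sqrt(diag(vcov_full))
  zstat <- c(fit$beta, fit$sigma) / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  ci <- cbind(c(fit$beta, fit$sigma) - 1.96 * se,
              c(fit$beta, fit$sigma) + 1.96 * se)
  nm <- c(colnames(X), "sigma")
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 sigma = fit$sigma,
                 se = stats::setNames(se, nm),
                 z = stats::setNames(zstat, nm),
                 p.values = stats::setNames(pval, nm),
                 ci = structure(ci, dimnames = list(nm, c("2.5%", "97.5%"))),
                 vcov = structure(vcov_full, dimnames = list(nm, nm)),
                 logLik = fit$logLik, lr = lr, pseudo_r2 = pseudo_r2,
                 n = length(y), n_left = sum(lo), n_right = sum(hi),
                 left = left, right = right,
                 transform = transform, cluster = !is.null(cluster),
                 convergence = fit$convergence,
                 formula = formula, X = X, y = y,
                 call = match.call()),
            class = "tobit")
}

# censored-normal log-likelihood, optimized in (beta, log sigma)
.tobit_loglik <- function(y, X, left, right, lo, hi, mid) {
  function(par) {
    p <- ncol(X)
    beta <- par[seq_len(p)]
    s <- exp(par[p + 1L])
    xb <- as.numeric(X %*% beta)
    ll <- 0
    if (any(mid))
      ll <- ll + sum(stats::dnorm((y[mid] - xb[mid]) / s, log = TRUE) - log(s))
    if (any(lo))
      ll <- ll + sum(stats::pnorm((left - xb[lo]) / s, log.p = TRUE))
    if (any(hi))
      ll <- ll + sum(stats::pnorm((xb[hi] - right) / s, log.p = TRUE))
    if (!is.finite(ll)) ll <- -1e10
    ll
  }
}

.tobit_mle <- function(y, X, left, right, lo, hi, mid, control = list()) {
  p <- ncol(X)
  ols <- stats::lm.fit(X, y)
  s0 <- max(stats::sd(ols$residuals), 1e-3)
  start <- c(ols$coefficients, log(s0))
  negll <- .tobit_loglik(y, X, left, right, lo, hi, mid)
  ctl <- utils::modifyList(list(fnscale = -1, maxit = 1000, reltol = 1e-12),
                           control)
  opt <- stats::optim(start, negll, method = "BFGS", control = ctl)
  if (opt$convergence != 0)
    stop("Tobit optimization did not converge (code ", opt$convergence, ")",
         call. = FALSE)
  beta <- unname(opt$par[seq_len(p)])
  sigma <- unname(exp(opt$par[p + 1L]))
  if (sigma < 1e-8) stop("sigma collapsed to the boundary", call. = FALSE)
  # observed information in (beta, sigma) parameterization
  ll_sig <- function(par) {
    q <- c(par[seq_len(p)], log(par[p + 1L]))
    negll(q)
  }
  H <- stats::optimHess(c(beta, sigma), ll_sig)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p + 1, p + 1))
  list(beta = beta, sigma = sigma, logLik = opt$value, vcov = vc,
       convergence = opt$convergence)
}

# per-observation score vectors in (beta, sigma), for the cluster sandwich
.tobit_scores <- function(y, X, left, right, lo, hi, mid, beta, sigma) {
  p <- ncol(X)
  xb <- as.numeric(X %*% beta)
  db <- numeric(length(y)); ds <- numeric(length(y))
  if (any(mid)) {
    r <- (y[mid] - xb[mid]) / sigma
    db[mid] <- r / sigma
    ds[mid] <- (r^2 - 1) / sigma
  }
  if (any(lo)) {
    a <- (left - xb[lo]) / sigma
    mills <- exp(stats::dnorm(a, log = TRUE) -
                   stats::pnorm(a, log.p = TRUE))
    db[lo] <- -mills / sigma
    ds[lo] <- -mills * a / sigma
  }
  if (any(hi)) {
    b <- (xb[hi] - right) / sigma
    mills <- exp(stats::dnorm(b, log = TRUE) -
                   stats::pnorm(b, log.p = TRUE))
    db[hi] <- mills / sigma
    ds[hi] <- -mills * b / sigma
  }
  cbind(X * db, sigma = ds)
}

#' @export
print.tobit <- function(x, digits = 4, ...) {
  cat("Tobit regression (censored at [",
      format(x$left), ", ", format(x$right), "])\n", sep = "")
  cat("n =", x$n, "(", x$n_left, "left-censored,", x$n_right,
      "right-censored )\n")
  print(round(x$coefficients, digits))
  cat("sigma:", round(x$sigma, digits),
      " logLik:", round(x$logLik, 2), "\n")
  invisible(x)
}

#' @export
coef.tobit <- function(object, ...) object$coefficients

#' @export
vcov.tobit <- function(object, ...) object$vcov

#' @export
logLik.tobit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1,
            class = "logLik")
}

#' @export
predict.tobit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(as.numeric(object$X %*% object$coefficients))
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  if (!is.null(object$transform)) {
    keep <- colnames(X) != "(Intercept)"
    X[, keep] <- apply_normalization(X[, keep, drop = FALSE],
                                     object$transform)
  }
  as.numeric(X %*% object$coefficients)
}

#' @export
residuals.tobit <- function(object, ...) object$y - predict(object)

#' Coefficient table with significance stars
#'
#' @param object a [tobit()] fit.
#' @param digits rounding for display.
#' @param ... unused.
#' @return `summary.tobit` object whose `table` mirrors the usual
#'   coefficient/SE/t/p/CI layout, with `*` for p < 0.05 and `**` for
#'   p < 0.01.
#' @export
summary.tobit <- function(object, digits = 4, ...) {
  nm <- names(object$coefficients)
  est <- object$coefficients
  tab <- data.frame(
    term = nm,
    estimate = est,
    std_error = object$se[nm],
    t_value = object$z[nm],
    p_value = object$p.values[nm],
    ci_low = object$ci[nm, 1],
    ci_high = object$ci[nm, 2],
    stars = ifelse(object$p.values[nm] < 0.01, "**",
                   ifelse(object$p.values[nm] < 0.05, "*", "")),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, sigma = object$sigma, lr = object$lr,
                 pseudo_r2 = object$pseudo_r2, logLik = object$logLik,
                 n = object$n, n_left = object$n_left,
                 n_right = object$n_right, digits = digits,
                 cluster = object$cluster),
            class = "summary.tobit")
}

#' @export
print.summary.tobit <- function(x, ...) {
  d <- x$table
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, x$digits)
  print.data.frame(d, row.names = FALSE)
  cat(sprintf("sigma = %.4f; logLik = %.2f; LR = %.2f; pseudo-R2 (McFadden) = %.3f\n",
              x$sigma, x$logLik, x$lr, x$pseudo_r2))
  cat("n =", x$n, "(", x$n_left, "left-,", x$n_right, "right-censored )",
      if (x$cluster) "; cluster-robust SEs", "\n")
  invisible(x)
}
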