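test_that("design normalization is exact and replayable", {
  X <- cbind(a = c(0, 5, 10), b = c(2, 4, 8))
  mm <- normalize_design(X, "minmax")
  expect_equal(unname(mm$design[, "a"]), c(0, 0.5, 1))
  zs <- normalize_design(X, "zscore")
  expect_equal(unname(colMeans(zs$design)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(zs$design, 2, sd)), c(1, 1), tolerance = 1e-12)
  # recorded transform reproduces the training scaling on new data
  Xnew <- cbind(a = c(2.5, 7.5), b = c(3, 6))
  expect_equal(apply_normalization(Xnew, mm$transform)[, "a"],
               c(0.25, 0.75), ignore_attr = TRUE)
  expect_error(normalize_design(cbind(k = c(1, 1, 1))), "constant")
})

test_that("with no censoring the MLE coincides with least squares", {
  sim <- generate_tobit_data(400, alpha = 2, beta = c(1, -0.5), sigma = 0.5,
                             lower = -Inf, seed = 5)
  expect_equal(sim$truth$frac_censored, 0)
  fit <- tobit(y ~ x1 + x2, sim$data, left = -Inf)
  ols <- lm(y ~ x1 + x2, sim$data)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-6)
  expect_equal(fit$n_left, 0)
})

test_that("estimates match the survreg reference on censored data", {
  skip_if_not_installed("survival")
  sim <- generate_tobit_data(800, alpha = 0.5, beta = c(1, -0.5),
                             sigma = 0.6, seed = 12)
  fit <- tobit(y ~ x1 + x2, sim$data)
  sv <- survival::survreg(
    survival::Surv(y, y > 0, type = "left") ~ x1 + x2,
    data = sim$data, dist = "gaussian")
  expect_equal(unname(coef(fit)), unname(coef(sv)), tolerance = 1e-4)
  expect_equal(fit$sigma, unname(sv$scale), tolerance = 1e-4)
  expect_equal(fit$logLik, sv$loglik[2], tolerance = 1e-4)
})

test_that("rescaling a covariate rescales only its coefficient", {
  sim <- generate_tobit_data(600, alpha = 0.5, beta = c(1, -0.5),
                             sigma = 0.5, seed = 9)
  d <- sim$data
  f1 <- tobit(y ~ x1 + x2, d)
  d2 <- transform(d, x1 = 2 * x1)
  f2 <- tobit(y ~ x1 + x2, d2)
  expect_equal(unname(coef(f2)["x1"]), unname(coef(f1)["x1"]) / 2,
               tolerance = 1e-4)
  expect_equal(predict(f2), predict(f1), tolerance = 1e-4)
})

test_that("likelihood-based statistics behave as nested-model theory says", {
  sim <- generate_tobit_data(500, alpha = 0.6, beta = c(0.8, -0.4),
                             sigma = 0.5, seed = 30)
  fit <- tobit(y ~ x1 + x2, sim$data)
  expect_gte(fit$lr, 0)
  expect_true(fit$sigma > 0)
  expect_true(all(fit$ci[, 1] <= c(coef(fit), fit$sigma)))
  expect_true(all(fit$ci[, 2] >= c(coef(fit), fit$sigma)))
  expect_equal(unname(fit$ci[, 2] - fit$ci[, 1]),
               unname(2 * 1.96 * fit$se), tolerance = 1e-10)
})

test_that("coefficient table renders stars by p-value thresholds", {
  sim <- generate_tobit_data(800, alpha = 0.5, beta = c(1, 0.01),
                             sigma = 0.5, seed = 14)
  s <- summary(tobit(y ~ x1 + x2, sim$data))
  tab <- s$table
  expect_equal(tab$stars[tab$p_value < 0.01],
               rep("**", sum(tab$p_value < 0.01)))
  expect_equal(tab$stars[tab$p_value >= 0.05],
               rep("", sum(tab$p_value >= 0.05)))
  expect_true(all(c("estimate", "std_error", "t_value", "p_value",
                    "ci_low", "ci_high") %in% names(tab)))
})

test_that("generator censoring fraction follows the normal tail mass", {
  # alpha set so that P(Y* <= 0) ~ 0.3 with beta = 0
  a <- -qnorm(0.3) * 1
  sim <- generate_tobit_data(5000, alpha = a, beta = 0, sigma = 1, seed = 2)
  expect_equal(mean(sim$data$y == 0), 0.3, tolerance = 0.03)
  sim2 <- generate_tobit_data(200, alpha = 0, beta = 1, sigma = 1,
                              lower = -Inf, upper = Inf, seed = 2)
  expect_equal(sim2$truth$frac_censored, 0)
})

test_that("cluster-robust errors differ from plain errors but keep estimates", {
  sim <- generate_tobit_data(600, alpha = 0.5, beta = c(1, -0.5),
                             sigma = 0.5, seed = 44)
  cl <- rep(1:30, each = 20)
  f0 <- tobit(y ~ x1 + x2, sim$data)
  f1 <- tobit(y ~ x1 + x2, sim$data, cluster = cl)
  expect_equal(coef(f0), coef(f1))
  expect_false(isTRUE(all.equal(f0$se, f1$se)))
  expect_true(all(is.finite(f1$se)))
})
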