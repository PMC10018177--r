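test_that("CCR matches the ratio oracle in one dimension", {
  d <- dea(matrix(c(2, 4, 8), 1), matrix(c(1, 1, 1), 1), "ccr")
  expect_equal(unname(d$score), c(1, 0.5, 0.25), tolerance = 1e-9)
  # single DMU is self-referencing and efficient
  d1 <- dea(matrix(2), matrix(1), "ccr")
  expect_equal(unname(d1$score), 1)
  expect_equal(unname(d1$lambda[1, 1]), 1)
  # doubling inputs at fixed outputs halves the score
  x <- matrix(c(3, 6), 1); y <- matrix(c(2, 2), 1)
  d2 <- dea(x, y, "ccr")
  expect_equal(unname(d2$score[2]), unname(d2$score[1]) / 2)
})

test_that("BCC envelops CCR and dominant units are VRS-efficient", {
  x <- matrix(c(2, 4, 8), 1); y <- matrix(c(1, 2, 3), 1)
  te <- dea(x, y, "ccr")$score
  pte <- dea(x, y, "bcc")$score
  expect_equal(unname(te), c(1, 1, 0.75), tolerance = 1e-9)
  expect_equal(unname(pte), c(1, 1, 1), tolerance = 1e-9)
  set.seed(42)
  for (r in 1:10) {
    n <- sample(3:8, 1); m <- sample(1:3, 1); s <- sample(1:3, 1)
    X <- matrix(runif(m * n, 0.5, 5), m); Y <- matrix(runif(s * n, 0.5, 5), s)
    te <- dea(X, Y, "ccr", rts = FALSE)$score
    pte <- dea(X, Y, "bcc")$score
    expect_true(all(pte >= te - 1e-7))
    # the unit holding the minimum of every input is BCC-efficient
    j <- which.min(colSums(sweep(X, 1, apply(X, 1, min), "/")))
    if (all(X[, j] == apply(X, 1, min))) expect_equal(unname(pte[j]), 1)
  }
})

test_that("units invariance and dominated-unit irrelevance hold", {
  set.seed(7)
  for (r in 1:10) {
    n <- sample(3:7, 1); m <- sample(1:3, 1); s <- sample(1:3, 1)
    X <- matrix(runif(m * n, 0.5, 5), m); Y <- matrix(runif(s * n, 0.5, 5), s)
    te <- dea(X, Y, "ccr", rts = FALSE)$score
    X2 <- X * runif(m, 0.1, 10); Y2 <- Y * runif(s, 0.1, 10)
    expect_equal(unname(dea(X2, Y2, "ccr", rts = FALSE)$score), unname(te),
                 tolerance = 1e-7)
    # adding a dominated copy of unit 1 changes no other score
    Xd <- cbind(X, X[, 1] * 2); Yd <- cbind(Y, Y[, 1] * 0.5)
    ted <- dea(Xd, Yd, "ccr", rts = FALSE)$score
    expect_equal(unname(ted[seq_len(n)]), unname(te), tolerance = 1e-7)
  }
})

test_that("returns-to-scale labels follow the sum-of-lambda rule", {
  f <- dea(matrix(c(2, 4, 8), 1), matrix(c(1, 2, 3), 1), "ccr")
  expect_equal(unname(f$rts), c("CRS", "CRS", "DRS"))
  tiny <- dea(matrix(c(1, 2), 1), matrix(c(0.4, 1), 1), "ccr")
  expect_equal(unname(tiny$rts), c("IRS", "CRS"))
  # an efficient self-referencing unit is CRS
  solo <- dea(matrix(2), matrix(1), "ccr")
  expect_equal(unname(solo$rts), "CRS")
})

test_that("scale efficiency is TE/PTE with the published Hebei value", {
  expect_equal(scale_efficiency(0.923478, 0.941243), 0.981125,
               tolerance = 1e-5)
  expect_equal(scale_efficiency(c(1, 0.5), c(1, 1)), c(1, 0.5))
  expect_equal(scale_efficiency(0.7, 0.7), 1)
  expect_error(scale_efficiency(c(1, 1), 1), "length")
})

test_that("SBM scores penalize slack and never exceed radial efficiency", {
  s <- dea(matrix(c(1, 2), 1), matrix(c(1, 1), 1), "sbm")
  expect_equal(unname(s$score), c(1, 0.5), tolerance = 1e-9)
  expect_true(s$efficient[1]); expect_false(s$efficient[2])
  set.seed(11)
  for (r in 1:10) {
    n <- sample(3:7, 1); m <- sample(1:3, 1); sy <- sample(1:3, 1)
    X <- matrix(runif(m * n, 0.5, 5), m); Y <- matrix(runif(sy * n, 0.5, 5), sy)
    rho <- dea(X, Y, "sbm")$score
    te <- dea(X, Y, "ccr", rts = FALSE)$score
    expect_true(all(rho <= te + 1e-7))
    expect_true(all(rho > 0))
  }
})

test_that("super-SBM matches the brute-force oracle and passes through", {
  x <- c(1, 2); y <- c(1, 1)
  f <- dea(matrix(x, 1), matrix(y, 1), "super-sbm")
  expect_equal(unname(f$score[1]),
               super_sbm_1d_oracle(x, y, 1), tolerance = 1e-3)
  expect_equal(unname(f$score[1]), 2, tolerance = 1e-6)
  expect_equal(unname(f$score[2]), 0.5, tolerance = 1e-9)  # SBM pass-through
  set.seed(3)
  X <- matrix(runif(2 * 6, 1, 5), 2); Y <- matrix(runif(2 * 6, 1, 5), 2)
  f2 <- dea(X, Y, "super-sbm")
  expect_true(all(f2$super_score[f2$efficient] >= 1 - 1e-7))
  expect_equal(unname(f2$score[!f2$efficient]),
               unname(f2$sbm_score[!f2$efficient]))
})

test_that("ranking is descending with stable tie-breaks", {
  expect_equal(unname(rank_by_score(c(1, 1, 0.5))), c(1, 2, 3))
  s <- c(a = 0.3, b = 0.9, c = 0.6)
  expect_equal(rank_by_score(s), c(a = 3L, b = 1L, c = 2L))
  set.seed(5)
  v <- runif(10)
  perm <- sample(10)
  expect_equal(rank_by_score(v[perm]), rank_by_score(v)[perm])
})

test_that("published 2020 table satisfies the DEA identities", {
  t1 <- load_fixture("T1")
  expect_true(all(abs(t1$SE - t1$TE / t1$PTE) < 5e-6))
  expect_true(all(t1$TE <= t1$PTE + 1e-9))
  # provinces on the radial frontier carry super-efficiency scores >= 1
  expect_true(all(t1$SBM[t1$TE == 1] >= 1))
  expect_equal(unname(rank_by_score(setNames(t1$SBM, t1$DMU))["Guangxi"]), 31L)
})

test_that("per-year efficient counts come from both radial models", {
  p <- toy_panel(c(A = 2, B = 4, C = 8), c(A = 1, B = 2, C = 3))
  cnt <- count_efficient_per_year(p)
  expect_equal(cnt$year, c(2013, 2014))
  expect_equal(cnt$te, c(2, 2))   # A and B sit on the CRS ray
  expect_equal(cnt$pte, c(3, 3))  # all three span the VRS hull
  # a panel on one ray is efficient everywhere
  p2 <- toy_panel(c(A = 1, B = 2, C = 4), c(A = 1, B = 2, C = 4))
  cnt2 <- count_efficient_per_year(p2)
  expect_equal(cnt2$te, c(3, 3))
  expect_equal(cnt2$se, c(3, 3))
})
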