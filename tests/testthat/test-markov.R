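test_that("quartile classification is rank-based and right-closed", {
  st <- classify_states(matrix(seq(10, 80, by = 10), ncol = 1), 4)
  expect_equal(as.vector(st$states),
               c("L", "L", "ML", "ML", "MH", "MH", "H", "H"))
  # monotone transformation leaves states unchanged
  st2 <- classify_states(matrix(exp(seq(10, 80, by = 10) / 20), ncol = 1), 4)
  expect_equal(st2$states, st$states)
  # a value tied with a cut point takes the lower state
  st3 <- classify_states(matrix(c(1, 1, 2, 2), ncol = 1), 2)
  expect_equal(as.vector(st3$states), c("S1", "S1", "S2", "S2"))
  expect_error(classify_states(matrix(rep(3, 8), ncol = 1), 4), "degenerate")
})

test_that("transition counts and probabilities follow the pooled pairs", {
  m <- matrix(c("L", "L", "ML", "ML", "L"), 1)
  tm <- transition_matrix(m, levels = c("L", "ML"))
  expect_equal(unname(tm$counts), matrix(1L, 2, 2))
  expect_equal(unname(tm$probs), matrix(0.5, 2, 2))
  expect_equal(unname(tm$n_i), c(2, 2))
  # absorbing sequence: identity row, unvisited rows undefined
  cm <- matrix(rep("L", 5), 1)
  tma <- transition_matrix(cm, levels = c("L", "ML"))
  expect_equal(unname(tma$probs[1, ]), c(1, 0))
  expect_true(all(is.na(tma$probs[2, ])))
  expect_error(transition_matrix(matrix("L", 1, 1), levels = "L"),
               "at least 2 years")
})

test_that("spatial lag reproduces hand calculations on the path graph", {
  w_bin <- read_weights(write_path_gal(), "gal")
  w_std <- read_weights(write_path_gal(), "gal", standardize = TRUE)
  v <- c(a = 1, b = 2, c = 3)
  expect_equal(unname(spatial_lag(v, w_std)), c(2, 2, 2))
  expect_equal(unname(spatial_lag(v, w_bin)), c(2, 4, 2))
  # constant vector is preserved by a standardized lag
  expect_equal(unname(spatial_lag(c(a = 5, b = 5, c = 5), w_std)),
               c(5, 5, 5))
})

test_that("conditional transition counts aggregate to the unconditional", {
  g <- generate_frontier_panel(n_units = 16, n_years = 6, m_inputs = 2,
                               s_outputs = 2, seed = 31)
  sc <- dea_scores_by_year(g$panel, "sbm")
  sm <- spatial_markov(sc, grid_for(4, 4, rownames(sc)), k = 4)
  agg <- Reduce(`+`, lapply(sm$conditional, `[[`, "counts"))
  expect_equal(agg, sm$unconditional$counts)
  expect_equal(sum(agg), 16 * 5)
  # defined rows are stochastic
  for (cm in sm$conditional) {
    ok <- cm$n_i > 0
    if (any(ok))
      expect_equal(unname(rowSums(cm$probs[ok, , drop = FALSE])),
                   rep(1, sum(ok)), tolerance = 1e-12)
  }
})

test_that("a single lag class reduces the spatial chain to the classical one", {
  g <- generate_frontier_panel(n_units = 9, n_years = 5, m_inputs = 1,
                               s_outputs = 1, seed = 17)
  sc <- dea_scores_by_year(g$panel, "ccr", rts = FALSE)
  sm <- spatial_markov(sc, grid_for(3, 3, rownames(sc)), k = 4, lag_k = 1)
  expect_length(sm$conditional, 1)
  expect_equal(sm$conditional[[1]]$counts, sm$unconditional$counts)
})

test_that("homogeneity statistics vanish when sub-periods match", {
  # periodic sequence: both halves produce identical empirical matrices
  m <- matrix(rep(c("L", "ML"), 3)[1:5], 1)
  ht <- time_homogeneity_test(m, breakpoints = 3, levels = c("L", "ML"))
  expect_equal(ht$chi2, 0)
  expect_equal(ht$lr, 0)
  expect_equal(ht$p_chi2, 1)
  expect_error(time_homogeneity_test(m, breakpoints = 1),
               "strictly inside")
})

test_that("transition estimator is consistent at long horizons", {
  M <- matrix(c(0.7, 0.2, 0.1,
                0.15, 0.7, 0.15,
                0.1, 0.2, 0.7), 3, 3, byrow = TRUE)
  g <- generate_markov_states(n_units = 5, n_years = 201, M_true = M,
                              seed = 55)
  tm <- transition_matrix(g$states, levels = g$truth$labels[1:3])
  expect_lt(max(abs(tm$probs - M)), 0.05)   # 1000 pooled transitions
})

test_that("published two-period transition rows are stochastic", {
  t3 <- load_fixture("T3")
  for (pre in c("^super_", "^human_", "^nonhuman_")) {
    rows <- as.matrix(t3[, grep(pre, names(t3))])
    expect_true(all(abs(rowSums(rows) - 1) <= 0.01), label = pre)
  }
  # diagonal dominance of the super-SBM chain, both periods
  sup <- as.matrix(t3[, grep("^super_", names(t3))])
  for (r in seq_len(nrow(sup))) {
    lev <- match(t3$level[r], c("L", "ML", "MH", "H"))
    expect_gte(sup[r, lev], max(sup[r, -lev]))
  }
  t4 <- load_fixture("T4")
  probs <- as.matrix(t4[, -(1:2)])
  for (j in seq(1, ncol(probs), by = 4)) {
    rs <- rowSums(probs[, j:(j + 3)])
    expect_true(all(abs(rs[rs > 0] - 1) <= 0.01))
  }
})
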