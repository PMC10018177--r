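test_that("panel construction validates and counts records", {
  p <- toy_panel(c(A = 2, B = 4, C = 8), c(A = 1, B = 1, C = 1))
  expect_s3_class(p, "panel_data")
  expect_equal(nrow(p$data), 12)  # 3 units x 2 years x 2 variables
  expect_equal(p$units, c("A", "B", "C"))

  bad <- data.frame(unit = "A", year = 2013, variable = "x", value = -1)
  schema <- data.frame(variable = "x", role = "input",
                       resource_class = "human")
  expect_error(panel_data(bad, schema), "unit=A year=2013 variable=x")

  dup <- data.frame(unit = c("A", "A"), year = 2013, variable = "x",
                    value = c(1, 2))
  expect_error(panel_data(dup, schema), "duplicate record")

  unmapped <- data.frame(unit = "A", year = 2013, variable = "z", value = 1)
  expect_error(panel_data(unmapped, schema), "absent from schema")
})

test_that("panel write/read round-trips field by field", {
  p <- toy_panel(c(A = 2, B = 4), c(A = 1, B = 3))
  f <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".csv")
  write_panel(p, f, fs)
  p2 <- read_panel(f, fs)
  expect_equal(p2$data, p$data)
  expect_equal(p2$schema, p$schema)
  expect_equal(p2$units, p$units)
  expect_equal(p2$years, p$years)
})

test_that("GAL path graph reads to the expected contiguity", {
  w <- read_weights(write_path_gal(), "gal")
  expect_equal(w$unit_ids, c("a", "b", "c"))
  expect_equal(w$matrix["a", "b"], 1)
  expect_equal(w$matrix["b", "c"], 1)
  expect_equal(w$matrix["a", "c"], 0)
  expect_true(isSymmetric(w$matrix))

  ws <- read_weights(write_path_gal(), "gal", standardize = TRUE)
  expect_equal(unname(ws$matrix["b", ]), c(0.5, 0, 0.5))
  expect_equal(sum(ws$matrix["a", ]), 1)
})

test_that("asymmetric GAL input is rejected", {
  f <- tempfile(fileext = ".gal")
  writeLines(c("2", "a 1", "b", "b 0"), f)
  expect_error(read_weights(f, "gal"), "asymmetric")
})

test_that("island units give a zero row and a warning", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  expect_warning(w <- spatial_weights(W, c("a", "b", "isle"),
                                      standardize = TRUE),
                 "no neighbors")
  expect_equal(unname(w$matrix[3, ]), c(0, 0, 0))
})

test_that("dense CSV weights round-trip and alignment is enforced", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  w <- spatial_weights(W, c("u1", "u2"))
  f <- tempfile(fileext = ".csv")
  write_weights(w, f)
  w2 <- read_weights(f, "dense_csv")
  expect_equal(w2$matrix, w$matrix)
  expect_silent(check_alignment(w, c("u1", "u2")))
  expect_error(check_alignment(w, c("u2", "u1")), "ordering")
})

test_that("packaged China contiguity is symmetric with Hainan linked to Guangdong", {
  w <- china_province_weights(standardize = FALSE)
  expect_length(w$unit_ids, 31)
  expect_true(isSymmetric(w$matrix))
  expect_equal(sum(diag(w$matrix)), 0)
  expect_equal(w$matrix["Hainan", "Guangdong"], 1)
  expect_equal(sum(w$matrix["Hainan", ]), 1)
  expect_true(all(rowSums(w$matrix) >= 1))
  ws <- china_province_weights(standardize = TRUE)
  expect_equal(unname(rowSums(ws$matrix)), rep(1, 31), tolerance = 1e-12)
})

test_that("fixture tables load with the printed shapes and values", {
  t1 <- load_fixture("T1")
  expect_equal(nrow(t1), 31)
  expect_setequal(t1$Rank, 1:31)
  expect_equal(t1$SBM[t1$DMU == "Tibet"], 4.366281)
  expect_equal(t1$Rank[t1$DMU == "Tibet"], 1)
  t2 <- load_fixture("T2")
  expect_equal(nrow(t2), 31)
  expect_equal(t2$TC[t2$DMU == "Hubei"], 0.874)
  t5 <- load_fixture("T5")
  expect_equal(nrow(t5), 8)
  expect_length(grep("moran_i$", names(t5)), 3)
  expect_error(load_fixture("T9"), "unknown fixture")
  # every numeric cell parses finite
  for (id in c("T1", "T2", "T3", "T4", "T5")) {
    d <- load_fixture(id)
    num <- vapply(d, is.numeric, logical(1))
    expect_true(all(is.finite(as.matrix(d[, num]))), label = id)
  }
})
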