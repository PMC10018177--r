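# Small in-code fixtures shared across test files.

# 3-node path graph 1-2, 2-3 written as a GAL file
write_path_gal <- function(path = tempfile(fileext = ".gal")) {
  writeLines(c("3", "a 1", "b", "b 2", "a c", "c 1", "b"), path)
  path
}

# minimal long panel: units x years x (one input, one output)
toy_panel <- function(x_by_unit, y_by_unit, years = c(2013, 2014)) {
  units <- names(x_by_unit)
  rows <- do.call(rbind, lapply(years, function(yr)
    data.frame(unit = rep(units, 2), year = yr,
               variable = rep(c("x", "y"), each = length(units)),
               value = c(x_by_unit, y_by_unit))))
  schema <- data.frame(variable = c("x", "y"),
                       role = c("input", "output"),
                       resource_class = c("non_human", "other"))
  panel_data(rows, schema)
}

# rook grid weights relabelled to match a set of unit ids (row-wise order)
grid_for <- function(nrow, ncol, ids, standardize = TRUE) {
  w <- grid_weights(nrow, ncol)
  m <- w$matrix
  dimnames(m) <- list(ids, ids)
  spatial_weights(m, ids, standardize = standardize)
}

# brute-force non-oriented super-SBM for 1 input / 1 output over a grid of
# reference weights (independent oracle for the LP)
super_sbm_1d_oracle <- function(x, y, j, grid = seq(1e-3, 10, by = 1e-3)) {
  ref <- setdiff(seq_along(x), j)
  best <- Inf
  for (lam in grid) {
    xbar <- max(sum(x[ref] * lam), x[j])
    ybar <- min(sum(y[ref] * lam), y[j])
    if (ybar <= 0) next
    best <- min(best, (xbar / x[j]) / (ybar / y[j]))
  }
  best
}
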