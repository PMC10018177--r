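#' Spatial contiguity weights
#'
#' Container for an n x n non-negative spatial weights matrix with zero
#' diagonal, aligned to a unit ordering. Built from binary contiguity, the
#' matrix is symmetric; row standardization divides each row by its sum
#' (zero-neighbor "island" rows are left at zero and flagged with a warning).
#'
#' @param matrix square numeric matrix, zero diagonal, non-negative.
#' @param unit_ids character labels in the order of the matrix rows.
#' @param standardize if `TRUE`, row-standardize.
#' @return Object of class `spatial_weights` with elements `matrix`,
#'   `unit_ids`, `standardized`, `islands`.
#' @seealso [read_weights()], [spatial_lag()], [moran_test()]
#' @export
spatial_weights <- function(matrix, unit_ids = rownames(matrix),
                            standardize = FALSE) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (ncol(matrix) != n) stop("weights matrix must be square", call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(n))
  unit_ids <- as.character(unit_ids)
  if (length(unit_ids) != n) stop("unit_ids length must match matrix", call. = FALSE)
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (any(diag(matrix) != 0)) stop("weights diagonal must be zero", call. = FALSE)
  rs <- rowSums(matrix)
  islands <- unit_ids[rs == 0]
  if (length(islands))
    warning("units with no neighbors: ", paste(islands, collapse = ", "))
  if (standardize) {
    nz <- rs > 0
    matrix[nz, ] <- matrix[nz, , drop = FALSE] / rs[nz]
  }
  dimnames(matrix) <- list(unit_ids, unit_ids)
  structure(list(matrix = matrix, unit_ids = unit_ids,
                 standardized = standardize, islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", length(x$unit_ids), "units,",
      sum(x$matrix > 0), "nonzero links,",
      if (x$standardized) "row-standardized" else "binary/raw", "\n")
  if (length(x$islands)) cat("  islands:", paste(x$islands, collapse = ", "), "\n")
  invisible(x)
}

#' Read spatial weights from GAL or dense CSV
#'
#' GAL follows the standard dialect: a header line whose last field is the
#' number of units, then for each unit a line `label n_neighbors` followed by
#' a line listing its neighbors. Contiguity read from GAL must be symmetric.
#' Dense CSV is a square table with unit labels as header and first column.
#'
#' @param path file path.
#' @param format `"gal"` or `"dense_csv"` (guessed from the extension by
#'   default).
#' @param standardize row-standardize after reading.
#' @return A [spatial_weights()] object.
#' @export
read_weights <- function(path, format = c("auto", "gal", "dense_csv"),
                         standardize = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gal$", path, ignore.case = TRUE)) "gal" else "dense_csv"
  if (format == "gal") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    n <- as.integer(hdr[length(hdr)])
    labels <- character(n)
    nbrs <- vector("list", n)
    pos <- 2L
    for (i in seq_len(n)) {
      head_i <- strsplit(trimws(lines[pos]), "\\s+")[[1L]]
      labels[i] <- head_i[1L]
      k <- as.integer(head_i[2L])
      nbrs[[i]] <- if (k > 0L) strsplit(trimws(lines[pos + 1L]), "\\s+")[[1L]] else character(0)
      pos <- pos + (if (k > 0L) 2L else {
        # zero-neighbor units may or may not carry an empty neighbor line
        if (pos + 1L <= length(lines) &&
            length(strsplit(trimws(lines[pos + 1L]), "\\s+")[[1L]]) == 0L) 2L else 1L
      })
    }
    W <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n)) {
      unknown <- setdiff(nbrs[[i]], labels)
      if (length(unknown))
        stop("GAL neighbor label not among units: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      W[labels[i], nbrs[[i]]] <- 1
    }
    if (!isTRUE(all.equal(W, t(W), tolerance = 0)))
      stop("GAL contiguity is asymmetric", call. = FALSE)
    spatial_weights(W, labels, standardize = standardize)
  } else {
    d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    labels <- as.character(d[[1L]])
    W <- as.matrix(d[, -1L, drop = FALSE])
    rownames(W) <- labels
    if (!identical(colnames(W), labels))
      stop("dense weights header labels do not match row labels", call. = FALSE)
    spatial_weights(W, labels, standardize = standardize)
  }
}

#' Write spatial weights to GAL or dense CSV
#'
#' GAL output requires binary (0/1) non-standardized weights.
#'
#' @param w a [spatial_weights()] object.
#' @param path output path.
#' @param format `"gal"` or `"dense_csv"`.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path, format = c("auto", "gal", "dense_csv")) {
  stopifnot(inherits(w, "spatial_weights"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gal$", path, ignore.case = TRUE)) "gal" else "dense_csv"
  if (format == "gal") {
    if (w$standardized || !all(w$matrix %in% c(0, 1)))
      stop("GAL output requires binary non-standardized weights", call. = FALSE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(length(w$unit_ids)), con)
    for (i in seq_along(w$unit_ids)) {
      nb <- w$unit_ids[w$matrix[i, ] > 0]
      writeLines(paste(w$unit_ids[i], length(nb)), con)
      if (length(nb)) writeLines(paste(nb, collapse = " "), con)
    }
  } else {
    d <- data.frame(unit = w$unit_ids, w$matrix, check.names = FALSE)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Check that weights and a unit vector are aligned
#'
#' Every operation combining a panel/score vector with weights goes through
#' this assertion; no positional joins.
#' @param w a [spatial_weights()] object.
#' @param unit_ids labels to compare with.
#' @return `TRUE`, invisibly; error on mismatch.
#' @export
check_alignment <- function(w, unit_ids) {
  if (!identical(w$unit_ids, as.character(unit_ids)))
    stop("unit ordering of weights does not match the data", call. = FALSE)
  invisible(TRUE)
}

#' Rook-contiguity weights for a rectangular grid
#'
#' Cells are labelled row-wise (`r<i>c<j>`); horizontally or vertically
#' adjacent cells are neighbors. Handy for simulation studies and worked
#' examples.
#'
#' @param nrow,ncol grid dimensions.
#' @param standardize row-standardize.
#' @return A [spatial_weights()] object with `nrow * ncol` units.
#' @export
grid_weights <- function(nrow, ncol, standardize = FALSE) {
  idx <- function(i, j) (i - 1L) * ncol + j
  n <- nrow * ncol
  W <- matrix(0, n, n)
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    if (i > 1L) W[idx(i, j), idx(i - 1L, j)] <- 1
    if (i < nrow) W[idx(i, j), idx(i + 1L, j)] <- 1
    if (j > 1L) W[idx(i, j), idx(i, j - 1L)] <- 1
    if (j < ncol) W[idx(i, j), idx(i, j + 1L)] <- 1
  }
  labels <- as.vector(t(outer(seq_len(nrow), seq_len(ncol),
                              function(i, j) sprintf("r%dc%d", i, j))))
  spatial_weights(W, labels, standardize = standardize)
}

#' Ring (cycle) contiguity weights
#'
#' Unit i is adjacent to i - 1 and i + 1 modulo n.
#'
#' @param n number of units (>= 3).
#' @param standardize row-standardize.
#' @return A [spatial_weights()] object.
#' @export
ring_weights <- function(n, standardize = FALSE) {
  stopifnot(n >= 3)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, if (i == 1L) n else i - 1L] <- 1
    W[i, if (i == n) 1L else i + 1L] <- 1
  }
  spatial_weights(W, as.character(seq_len(n)), standardize = standardize)
}

#' Reorder a weights matrix to a given unit ordering
#'
#' Operations combining weights with a panel require identical unit order;
#' this permutes the matrix (same unit set, new order).
#'
#' @param w a [spatial_weights()] object.
#' @param unit_ids target ordering (a permutation of `w$unit_ids`).
#' @return The reordered [spatial_weights()] object.
#' @export
align_weights <- function(w, unit_ids) {
  unit_ids <- as.character(unit_ids)
  if (!setequal(w$unit_ids, unit_ids))
    stop("weights and panel unit sets differ", call. = FALSE)
  perm <- match(unit_ids, w$unit_ids)
  w$matrix <- w$matrix[perm, perm, drop = FALSE]
  w$unit_ids <- unit_ids
  w
}

#' First-order contiguity for China's 31 provincial units
#'
#' Packaged convenience weights built from first-order land borders between
#' the 31 mainland provincial units, with the island province Hainan linked
#' to Guangdong (the usual convention in China spatial econometrics). This is
#' a documented convention fixture, not survey data.
#'
#' @param standardize row-standardize (default `TRUE`).
#' @return A [spatial_weights()] object with province names as labels.
#' @export
china_province_weights <- function(standardize = TRUE) {
  path <- system.file("extdata", "china_provinces.gal", package = "ltcfdea")
  w <- read_weights(path, "gal", standardize = standardize)
  # GAL labels cannot hold spaces; restore the printed province names
  ids <- gsub("_", " ", w$unit_ids)
  dimnames(w$matrix) <- list(ids, ids)
  w$unit_ids <- ids
  w
}
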