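#' Panel dataset of tagged input/output variables
#'
#' Constructs the long-format panel container used by every analysis stage:
#' decision-making units (e.g. provinces) by years by named variables, where
#' each variable is tagged with a role (`input`/`output`) and a resource class
#' (`human`/`non_human`/`other`). All values must be non-negative and finite;
#' duplicate (unit, year, variable) records are an error.
#'
#' @param data data.frame with columns `unit`, `year`, `variable`, `value`.
#' @param schema data.frame with columns `variable`, `role`, `resource_class`
#'   mapping every variable name occurring in `data`.
#' @return An object of class `panel_data`: the validated long table plus the
#'   schema, with `units` and `years` attributes sorted and unique.
#' @seealso [read_panel()], [panel_matrix()], [dea()]
#' @export
panel_data <- function(data, schema) {
  need <- c("unit", "year", "variable", "value")
  if (!all(need %in% names(data)))
    stop("panel data must have columns unit, year, variable, value", call. = FALSE)
  if (!all(c("variable", "role", "resource_class") %in% names(schema)))
    stop("schema must have columns variable, role, resource_class", call. = FALSE)

  data <- data.frame(unit = as.character(data$unit),
                     year = as.integer(data$year),
                     variable = as.character(data$variable),
                     value = as.numeric(data$value),
                     stringsAsFactors = FALSE)
  schema <- data.frame(variable = as.character(schema$variable),
                       role = as.character(schema$role),
                       resource_class = as.character(schema$resource_class),
                       stringsAsFactors = FALSE)

  bad_role <- setdiff(schema$role, c("input", "output"))
  if (length(bad_role))
    stop("schema role must be 'input' or 'output', got: ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  bad_cls <- setdiff(schema$resource_class, c("human", "non_human", "other"))
  if (length(bad_cls))
    stop("schema resource_class must be human/non_human/other, got: ",
         paste(bad_cls, collapse = ", "), call. = FALSE)

  unmapped <- setdiff(unique(data$variable), schema$variable)
  if (length(unmapped))
    stop("variables absent from schema: ", paste(unmapped, collapse = ", "),
         call. = FALSE)

  bad <- !is.finite(data$value) | data$value < 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("invalid value %s at unit=%s year=%d variable=%s (must be finite and >= 0)",
                 format(data$value[i]), data$unit[i], data$year[i], data$variable[i]),
         call. = FALSE)
  }

  key <- paste(data$unit, data$year, data$variable, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate record for unit=%s year=%d variable=%s",
                 data$unit[i], data$year[i], data$variable[i]), call. = FALSE)
  }

  units <- sort(unique(data$unit))
  years <- sort(unique(data$year))
  # missing cells reported (not filled): DEA stages re-check completeness
  n_missing <- length(units) * length(years) * length(unique(data$variable)) - nrow(data)

  data <- data[order(data$unit, data$year, data$variable), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data,
                 schema = schema,
                 units = units, years = years,
                 n_missing = n_missing),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("Panel dataset:", length(x$units), "units x", length(x$years), "years,",
      nrow(x$schema), "variables (",
      sum(x$schema$role == "input"), "inputs /",
      sum(x$schema$role == "output"), "outputs )\n")
  if (x$n_missing > 0)
    cat("  incomplete:", x$n_missing, "missing (unit, year, variable) cells\n")
  invisible(x)
}

#' Read a long-format panel CSV with its schema
#'
#' @param path CSV with columns `unit,year,variable,value`.
#' @param schema either a data.frame (see [panel_data()]) or the path of a
#'   schema CSV with columns `variable,role,resource_class`.
#' @return A validated [panel_data()] object.
#' @export
read_panel <- function(path, schema) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(schema) && length(schema) == 1L)
    schema <- utils::read.csv(schema, stringsAsFactors = FALSE)
  panel_data(data, schema)
}

#' Write a panel (and optionally its schema) back to CSV
#'
#' @param panel a [panel_data()] object.
#' @param path output CSV path for the long table.
#' @param schema_path optional output path for the schema CSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, schema_path = NULL) {
  stopifnot(inherits(panel, "panel_data"))
  utils::write.csv(panel$data, path, row.names = FALSE, quote = FALSE)
  if (!is.null(schema_path))
    utils::write.csv(panel$schema, schema_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract aligned input/output matrices for one year
#'
#' Builds the m x n input and s x n output matrices (columns are units, in the
#' panel's unit order) that the DEA solvers consume. Variables can be
#' restricted by resource class, which is how the human / non-human efficiency
#' series are produced: inputs of the requested class against all outputs.
#'
#' @param panel a [panel_data()] object.
#' @param year the year to slice.
#' @param input_class `"all"`, `"human"` or `"non_human"`; which input
#'   variables to keep (outputs are always all output-role variables).
#' @return list with `X` (inputs), `Y` (outputs), `units`.
#' @export
panel_matrix <- function(panel, year, input_class = "all") {
  stopifnot(inherits(panel, "panel_data"))
  if (!year %in% panel$years) stop("year ", year, " not in panel", call. = FALSE)
  sch <- panel$schema
  in_vars <- sch$variable[sch$role == "input" &
                          (input_class == "all" | sch$resource_class == input_class)]
  out_vars <- sch$variable[sch$role == "output"]
  if (!length(in_vars)) stop("no input variables for class ", input_class, call. = FALSE)
  if (!length(out_vars)) stop("no output variables in schema", call. = FALSE)
  d <- panel$data[panel$data$year == year, , drop = FALSE]
  grab <- function(vars) {
    m <- matrix(NA_real_, length(vars), length(panel$units),
                dimnames = list(vars, panel$units))
    for (v in vars) {
      dv <- d[d$variable == v, , drop = FALSE]
      m[v, dv$unit] <- dv$value
    }
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value for unit=%s variable=%s in year %d",
                   colnames(m)[idx[2L]], rownames(m)[idx[1L]], year), call. = FALSE)
    }
    m
  }
  list(X = grab(in_vars), Y = grab(out_vars), units = panel$units)
}
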