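.fixture_files <- c(
  T1 = "t1_overall_efficiency.csv",
  T2 = "t2_malmquist.csv",
  T3 = "t3_markov.csv",
  T4 = "t4_spatial_markov.csv",
  T5 = "t5_moran.csv",
  T6 = "t6_tobit.csv")

#' Packaged result tables (T1-T6)
#'
#' Machine-readable copies of the published provincial result tables that the
#' reporting layer reproduces arithmetically: T1 overall 2020 efficiency
#' (TE/PTE/SE, returns-to-scale, super-SBM score and rank for 31 provinces),
#' T2 chained Malmquist decomposition 2013-2020, T3 two-period Markov
#' transition matrices for three efficiency series, T4 spatially conditioned
#' transition matrices, T5 yearly global Moran's I per series, T6 the Tobit
#' determinants table (with the LR statistic and pseudo-R2 as trailing
#' rows). Values are kept digit-identical to print.
#'
#' @param table_id one of `"T1"` ... `"T6"`.
#' @return data.frame with attribute `table_id`.
#' @examples
#' t1 <- load_fixture("T1")
#' sum(t1$TE == 1)   # provinces on the CCR frontier in 2020
#' @export
load_fixture <- function(table_id) {
  if (!table_id %in% names(.fixture_files))
    stop("unknown fixture table: ", table_id, call. = FALSE)
  path <- system.file("extdata", .fixture_files[[table_id]],
                      package = "ltcfdea")
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  attr(d, "table_id") <- table_id
  d
}

#' Headline arithmetic recomputed from the packaged tables
#'
#' Reproduces, from the fixtures alone, the headline counts the result
#' tables support: frontier and decreasing-returns counts and the extreme
#' ranks from T1, the technology-driven productivity-decline count and the
#' decomposition identities from T2, and transition-row diagnostics from
#' T3/T4.
#'
#' @return list of named scalars (see names).
#' @export
fixture_report <- function() {
  t1 <- load_fixture("T1")
  t2 <- load_fixture("T2")
  t3 <- load_fixture("T3")
  t4 <- load_fixture("T4")
  rank <- rank_by_score(stats::setNames(t1$SBM, t1$DMU))
  sup_rows <- as.matrix(t3[, grep("^super_", names(t3))])
  t4_rows <- as.matrix(t4[, -(1:2)])
  list(
    n_te_efficient = sum(t1$TE == 1),
    n_drs = sum(t1$RTS == "DRS"),
    rank_tibet = unname(rank["Tibet"]),
    rank_guangxi = unname(rank["Guangxi"]),
    hebei_se = unname(t1$TE[t1$DMU == "Hebei"] / t1$PTE[t1$DMU == "Hebei"]),
    se_identity_max_err = max(abs(t1$SE - t1$TE / t1$PTE)),
    tibet_tfpc = round(t2$TEC[t2$DMU == "Tibet"] * t2$TC[t2$DMU == "Tibet"], 3),
    n_tech_decline = sum(t2$TFPC < 1 & t2$TC < 1),
    tfpc_identity_max_err = max(abs(t2$TEC * t2$TC - t2$TFPC)),
    tec_identity_max_err = max(abs(t2$PTEC * t2$SEC - t2$TEC)),
    t3_rowsum_max_err = max(abs(rowSums(matrix(sup_rows, ncol = 4)) - 1),
                            abs(rowSums(matrix(as.matrix(
                              t3[, grep("^human_", names(t3))]), ncol = 4)) - 1),
                            abs(rowSums(matrix(as.matrix(
                              t3[, grep("^nonhuman_", names(t3))]), ncol = 4)) - 1)),
    t4_rowsum_max_err = max(vapply(seq(1, ncol(t4_rows), by = 4), function(j) {
      rs <- rowSums(t4_rows[, j:(j + 3)])
      max(abs(rs[rs > 0] - 1))
    }, numeric(1)))
  )
}
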