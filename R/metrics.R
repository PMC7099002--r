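## The four accuracy measures and their Tables-style aggregation.

#' Percent departure of estimated from true times
#'
#' Signed percent departure `100 * (ET - TT) / TT`; positive values are
#' overestimates.
#'
#' @param TT True node ages (my, > 0).
#' @param ET Estimated node ages (my).
#' @return Numeric vector of signed percentages.
#' @export
etDeparture <- function(TT, ET) {
  stopifnot2(all(TT > 0), "TT must be positive")
  100 * (ET - TT) / TT
}

#' Through-origin slope of estimated on true times
#'
#' Least-squares slope of ET on TT with the intercept fixed at 0:
#' `sum(TT * ET) / sum(TT^2)`.  A slope below 1 indicates systematic
#' underestimation.
#'
#' @inheritParams etDeparture
#' @return Single numeric slope.
#' @export
ttEtSlope <- function(TT, ET) {
  stopifnot2(length(TT) >= 2, "need at least 2 nodes")
  stopifnot2(sum(TT^2) > 0, "all true times are zero")
  sum(TT * ET) / sum(TT^2)
}

#' CI accuracy: fraction of intervals containing the true time
#'
#' Boundaries are inclusive.
#'
#' @param TT True node ages.
#' @param lo,hi CI boundaries.
#' @return Proportion in \[0, 1\].
#' @export
ciAccuracy <- function(TT, lo, hi) {
  stopifnot2(length(TT) > 0, "empty comparison set")
  mean(lo <= TT & TT <= hi)
}

#' CI precision: interval range normalized to node depth
#'
#' `(hi - lo) / TT`; smaller is more precise.
#'
#' @inheritParams ciAccuracy
#' @return Numeric vector of ratios.
#' @export
ciPrecision <- function(TT, lo, hi) {
  stopifnot2(all(TT > 0), "TT must be positive")
  (hi - lo) / TT
}

#' CI skewness: normalized distance of each boundary from the true time
#'
#' Returns `|(lo - TT) / TT|` and `|(hi - TT) / TT|` plus a flag for
#' intervals skewed toward older times, defined as the upper-boundary
#' excess over TT exceeding the lower-boundary excess
#' (`hi - TT > TT - lo`).
#'
#' @inheritParams ciAccuracy
#' @return data.frame with columns `lower`, `upper`, `skewed_older`.
#' @export
ciSkewness <- function(TT, lo, hi) {
  stopifnot2(all(TT > 0), "TT must be positive")
  data.frame(lower = abs((lo - TT) / TT),
             upper = abs((hi - TT) / TT),
             skewed_older = (hi - TT) > (TT - lo))
}

#' Aggregate a study into Tables-style accuracy summaries
#'
#' For every (setting, scenario, concatenation) cell the per-node measures
#' are computed over the metric-eligible nodes (internal ingroup nodes,
#' calibrated nodes excluded): mean absolute and mean signed percent
#' departure, through-origin slope, CI accuracy and mean CI precision,
#' plus the skewed-older flag of the overlap node where that node is
#' estimated rather than calibrated.  Cells are then summarized per
#' (setting, scenario) as mean and sample standard deviation (n - 1)
#' across concatenations, and an `Average` row per setting averages the
#' scenario means (SD across scenario means).
#'
#' @param study A `StudyResults` object from [runStudy()], or its
#'   `comparisons` data.frame.
#' @return data.frame of class `MetricsTable` with columns `setting`,
#'   `scenario`, `measure`, `mean`, `sd`, `n`.
#' @export
aggregateMetrics <- function(study) {
  cmp <- if (inherits(study, "StudyResults")) study$comparisons else study
  cells <- perRunMetrics(cmp)
  measures <- setdiff(names(cells), c("setting", "scenario", "concat"))
  out <- list()
  for (st in unique(cells$setting)) {
    sub <- cells[cells$setting == st, ]
    scMeans <- list()
    for (sc in unique(sub$scenario)) {
      cell <- sub[sub$scenario == sc, ]
      for (ms in measures) {
        v <- cell[[ms]]
        v <- v[!is.na(v)]
        out[[length(out) + 1L]] <- data.frame(
          setting = st, scenario = sc, measure = ms,
          mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) >= 2) sd(v) else NA_real_,
          n = length(v))
        scMeans[[ms]] <- c(scMeans[[ms]],
                           if (length(v)) mean(v) else NA_real_)
      }
    }
    for (ms in measures) {
      v <- scMeans[[ms]]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        setting = st, scenario = "Average", measure = ms,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2) sd(v) else NA_real_,
        n = length(v))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("MetricsTable", "data.frame")
  res
}

#' Per-(setting, scenario, concatenation) measures
#'
#' The long per-run table underlying [aggregateMetrics()].
#'
#' @param cmp The `comparisons` data.frame of a study.
#' @return data.frame with one row per run and one column per measure.
#' @export
perRunMetrics <- function(cmp) {
  keys <- unique(cmp[, c("setting", "scenario", "concat")])
  rownames(keys) <- NULL
  res <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    run <- cmp[cmp$setting == k$setting & cmp$scenario == k$scenario &
                 cmp$concat == k$concat, ]
    m <- run[run$in_metrics, ]
    ovr <- run[run$overlap & !run$calibrated, ]
    dep <- if (nrow(m)) etDeparture(m$TT, m$ET) else numeric(0)
    data.frame(
      k,
      abs_departure = if (length(dep)) mean(abs(dep)) else NA_real_,
      signed_departure = if (length(dep)) mean(dep) else NA_real_,
      slope = if (nrow(m) >= 2) ttEtSlope(m$TT, m$ET) else NA_real_,
      ci_accuracy = if (nrow(m)) ciAccuracy(m$TT, m$ci_lo, m$ci_hi)
                    else NA_real_,
      ci_precision = if (nrow(m)) mean(ciPrecision(m$TT, m$ci_lo, m$ci_hi))
                     else NA_real_,
      overlap_skewed_older = if (nrow(ovr) == 1L)
        as.numeric(ciSkewness(ovr$TT, ovr$ci_lo, ovr$ci_hi)$skewed_older)
      else NA_real_)
  })
  do.call(rbind, res)
}

#' Write the aggregated tables as CSV files
#'
#' Emits `table2_ci_accuracy.csv` and `table3_ci_precision.csv`
#' (scenario rows by setting columns, `mean (sd)` cells), `departures.csv`
#' and `slopes.csv` in the same layout, plus `per_run_metrics.csv` and the
#' long `metrics.csv`.
#'
#' @param mt A `MetricsTable` from [aggregateMetrics()].
#' @param perRun Optional [perRunMetrics()] table.
#' @param dir Output directory (created if missing).
#' @export
writeMetricsTables <- function(mt, dir, perRun = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pivot <- function(measure) {
    sub <- mt[mt$measure == measure, ]
    scen <- c(intersect(scenarioCodes(), sub$scenario), "Average")
    sets <- unique(sub$setting)
    out <- data.frame(scenario = scen)
    for (st in sets)
      out[[st]] <- vapply(scen, function(sc) {
        r <- sub[sub$scenario == sc & sub$setting == st, ]
        if (!nrow(r) || is.na(r$mean)) return(NA_character_)
        sprintf("%.4f (%.4f)", r$mean, if (is.na(r$sd)) 0 else r$sd)
      }, character(1L))
    out
  }
  write.csv(pivot("ci_accuracy"),
            file.path(dir, "table2_ci_accuracy.csv"), row.names = FALSE)
  write.csv(pivot("ci_precision"),
            file.path(dir, "table3_ci_precision.csv"), row.names = FALSE)
  write.csv(pivot("abs_departure"),
            file.path(dir, "departures.csv"), row.names = FALSE)
  write.csv(pivot("slope"), file.path(dir, "slopes.csv"), row.names = FALSE)
  write.csv(mt, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(perRun))
    write.csv(perRun, file.path(dir, "per_run_metrics.csv"),
              row.names = FALSE)
  invisible(dir)
}
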