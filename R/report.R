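#' Turn a fitted model into a plain report
#'
#' Flattens a `cindex_fit` into plain lists/data frames mirroring the
#' published table shapes: cohort provenance and sizes, reference means,
#' per-group summary rows, rank-test results, the four-row performance
#' table, per-episode index values, a long table of marker values by group
#' for density/violin plotting, and the analysis conventions in force.
#'
#' @param fit a [cindex_fit()] object.
#' @return a named list (JSON-serializable).
#' @export
as_report <- function(fit) {
  stopifnot(inherits(fit, "cindex_fit"))
  co <- fit$cohort
  tests <- do.call(rbind, lapply(names(fit$tests), function(m) {
    t <- fit$tests[[m]]
    data.frame(marker = m, statistic = t$statistic, p_value = t$p_value,
               method = t$method, n1 = t$n1, n2 = t$n2,
               stringsAsFactors = FALSE)
  }))
  roc_points <- do.call(rbind, lapply(fit$curves, function(cv) {
    data.frame(marker = cv$marker, threshold = cv$thresholds, fpr = cv$fpr,
               tpr = cv$tpr, stringsAsFactors = FALSE)
  }))
  rownames(roc_points) <- NULL
  long <- do.call(rbind, lapply(c(BIOMARKERS, "cindex"), function(m) {
    v <- if (m == "cindex") fit$scores$cindex else co[[m]]
    data.frame(marker = m, group = ifelse(co$infection == 1, "infection",
                                          "no_infection"),
               value = v, stringsAsFactors = FALSE)
  }))
  list(
    cohort = list(provenance = attr(co, "provenance"), n = nrow(co),
                  n_infection = sum(co$infection == 1),
                  n_no_infection = sum(co$infection == 0)),
    reference_means = list(pct = fit$ref[["pct"]], crp = fit$ref[["crp"]],
                           il6 = fit$ref[["il6"]],
                           source = attr(fit$ref, "source")),
    summaries = fit$summaries,
    rank_tests = tests,
    performance = fit$performance,
    cindex = fit$scores,
    roc_points = roc_points,
    density_long = long,
    decisions = fit$decisions
  )
}

#' Write the analysis report to disk
#'
#' Emits `report.json` (the full [as_report()] document) plus flat CSVs per
#' table: `summary.csv`, `rank_tests.csv`, `performance.csv`, `cindex.csv`,
#' `roc_points.csv`, `density_long.csv`.
#'
#' @param fit a [cindex_fit()] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  rep <- as_report(fit)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tables <- c(summaries = "summary.csv", rank_tests = "rank_tests.csv",
              performance = "performance.csv", cindex = "cindex.csv",
              roc_points = "roc_points.csv", density_long = "density_long.csv")
  for (nm in names(tables)) {
    utils::write.csv(rep[[nm]], file.path(dir, tables[[nm]]),
                     row.names = FALSE)
  }
  invisible(dir)
}
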