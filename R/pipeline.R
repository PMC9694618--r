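#' Command-line pipeline entry point
#'
#' Implements the two shell subcommands behind `inst/cli/cindex.R`:
#' \describe{
#'   \item{simulate}{`--seed <int> [--config cfg.json] --out cohort.csv` --
#'     draw a synthetic cohort (default configuration unless a config JSON
#'     is given; `--seed` overrides the config seed) and write the cohort
#'     CSV plus a `<out>_fit.json` fit report (target vs achieved summaries
#'     per distribution spec).}
#'   \item{analyze}{`--in cohort.csv [--reference-means means.json]
#'     [--no-strict] --out report_dir` -- read a cohort, fit the model and
#'     write the report files of [write_report()]. The means JSON is an
#'     object with keys `pct`, `crp`, `il6`.}
#' }
#' Errors are printed to stderr and turn into a non-zero exit code; the
#' function never calls [quit()] itself so it can be driven in-process.
#'
#' @param args character vector of command-line arguments
#'   (default: `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code: 0 on success, 1 on any error, 2 on usage
#'   errors.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage:",
    "  simulate --seed <int> [--config cfg.json] --out cohort.csv",
    "  analyze --in cohort.csv [--reference-means means.json] [--no-strict] --out report_dir",
    sep = "\n")
  if (length(args) < 1L || !args[1] %in% c("simulate", "analyze")) {
    message(usage)
    return(2L)
  }
  cmd <- args[1]
  opts <- tryCatch(parse_flags(args[-1]), error = function(e) {
    message("error: ", conditionMessage(e), "\n", usage)
    NULL
  })
  if (is.null(opts)) return(2L)

  res <- tryCatch({
    if (cmd == "simulate") run_simulate(opts) else run_analyze(opts)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}

parse_flags <- function(args) {
  flags_with_value <- c("--seed", "--out", "--config", "--in",
                        "--reference-means", "--log-level")
  opts <- list(strict = TRUE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--strict") {
      opts$strict <- TRUE
    } else if (a == "--no-strict") {
      opts$strict <- FALSE
    } else if (a %in% flags_with_value) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      key <- gsub("-", "_", sub("^--", "", a))
      opts[[key]] <- args[i + 1L]
      i <- i + 1L
    } else {
      stop("unknown flag: ", a)
    }
    i <- i + 1L
  }
  opts
}

run_simulate <- function(opts) {
  if (is.null(opts$out)) stop("simulate needs --out <cohort.csv>")
  config <- if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) stop("config not found: ", opts$config)
    read_sim_config(opts$config)
  } else {
    default_cohort_config(seed = 1L)
  }
  if (!is.null(opts$seed)) {
    config <- sim_config(config$n_infection, config$n_no_infection,
                         config$specs, as.integer(opts$seed))
  }
  cohort <- sample_cohort(config)
  write_cohort(cohort, opts$out)
  fit_path <- paste0(sub("\\.csv$", "", opts$out), "_fit.json")
  jsonlite::write_json(fit_report(config), fit_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  message("wrote ", nrow(cohort), " episodes to ", opts$out,
          " (fit report: ", fit_path, ")")
  invisible(NULL)
}

run_analyze <- function(opts) {
  if (is.null(opts$`in`)) stop("analyze needs --in <cohort.csv>")
  if (is.null(opts$out)) stop("analyze needs --out <report_dir>")
  cohort <- read_cohort(opts$`in`, strict = opts$strict)
  ref <- NULL
  if (!is.null(opts$reference_means)) {
    if (!file.exists(opts$reference_means)) {
      stop("reference means file not found: ", opts$reference_means)
    }
    m <- jsonlite::read_json(opts$reference_means, simplifyVector = TRUE)
    ref <- external_reference_means(m$pct, m$crp, m$il6)
  }
  fit <- cindex_fit(cohort, reference = ref)
  write_report(fit, opts$out)
  message("report written to ", opts$out)
  invisible(NULL)
}
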