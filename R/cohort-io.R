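#' @title Fever-episode cohorts
#' @description A cohort is a data frame with one row per fever onset and the
#'   fixed columns `episode_id`, `patient_id`, `infection`, `pct`, `crp`,
#'   `il6`. `infection` is 1 for a microbiologically documented infection and
#'   0 for fever without documented infection; the three biomarker columns
#'   hold the serum values measured at fever onset (procalcitonin,
#'   C-reactive protein, interleukin-6), in whatever assay units the source
#'   laboratory reports. Units are carried as annotations only and never
#'   converted.
#' @name cohort
NULL

COHORT_COLUMNS <- c("episode_id", "patient_id", "infection", "pct", "crp", "il6")
BIOMARKERS <- c("pct", "crp", "il6")

#' Construct a cohort from a data frame
#'
#' Validates and normalizes a data frame of fever episodes into a `cohort`
#' object. Biomarker values must be present, finite and non-negative; the
#' infection label must be exactly 0 or 1; `episode_id` values must be unique.
#' A value of 0 is legal input for a biomarker (assays may report
#' below-detection results as small or zero values).
#'
#' @param x data frame with at least columns `episode_id`, `infection`,
#'   `pct`, `crp`, `il6`; `patient_id` is optional.
#' @param provenance free-text origin of the data (file path, simulation
#'   seed, ...).
#' @return an object of class `cohort` (a data frame).
#' @export
as_cohort <- function(x, provenance = "in-memory") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- setdiff(COHORT_COLUMNS, "patient_id")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("cohort is empty", call. = FALSE)
  if (!"patient_id" %in% names(x)) x$patient_id <- NA_character_
  x <- x[COHORT_COLUMNS]
  x$episode_id <- as.character(x$episode_id)
  x$patient_id <- as.character(x$patient_id)
  x$infection <- suppressWarnings(as.numeric(x$infection))
  for (b in BIOMARKERS) x[[b]] <- suppressWarnings(as.numeric(x[[b]]))

  if (anyDuplicated(x$episode_id)) {
    stop("duplicate episode_id value(s): ",
         paste(unique(x$episode_id[duplicated(x$episode_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !episode_rows_valid(x)
  if (any(bad)) {
    stop(sum(bad), " row(s) violate episode invariants ",
         "(biomarkers must be finite and >= 0, infection must be 0 or 1)",
         call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, provenance = provenance, class = c("cohort", "data.frame"))
}

# row-wise validity under the episode invariants
episode_rows_valid <- function(x) {
  ok <- x$infection %in% c(0, 1)
  for (b in BIOMARKERS) {
    v <- x[[b]]
    ok <- ok & !is.na(v) & is.finite(v) & v >= 0
  }
  ok & !is.na(x$episode_id) & nzchar(x$episode_id)
}

#' Read a fever-episode cohort from CSV
#'
#' Reads a CSV with header `episode_id,patient_id,infection,pct,crp,il6`
#' (extra columns are ignored with a warning; `patient_id` may be absent).
#' In strict mode any row with a missing or non-numeric biomarker value, a
#' negative value, or a label other than 0/1 is an error; otherwise such rows
#' are dropped and their count recorded in the `dropped` attribute and
#' reported via a message.
#'
#' @param path path to a CSV file (UTF-8, "." decimal separator, header
#'   required).
#' @param strict if `TRUE` (default) invalid rows abort; if `FALSE` they are
#'   dropped with a logged count.
#' @return a [cohort] with attributes `provenance` (the path) and `dropped`
#'   (number of rows removed; 0 in strict mode).
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  required <- setdiff(COHORT_COLUMNS, "patient_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra) > 0L) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (!"patient_id" %in% names(raw)) raw$patient_id <- NA_character_
  raw <- raw[COHORT_COLUMNS]
  raw$patient_id[!nzchar(raw$patient_id)] <- NA_character_

  parsed <- raw
  parsed$infection <- suppressWarnings(as.numeric(raw$infection))
  for (b in BIOMARKERS) parsed[[b]] <- suppressWarnings(as.numeric(raw[[b]]))
  ok <- episode_rows_valid(parsed)
  dropped <- sum(!ok)
  if (dropped > 0L) {
    if (strict) {
      stop(dropped, " invalid row(s) in ", path,
           " (missing/non-numeric/negative biomarker or bad label); ",
           "use strict = FALSE to drop them", call. = FALSE)
    }
    message("read_cohort: dropped ", dropped, " invalid row(s) from ", path)
    parsed <- parsed[ok, , drop = FALSE]
  }
  cohort <- as_cohort(parsed, provenance = path)
  attr(cohort, "dropped") <- dropped
  cohort
}

#' Write a cohort to CSV
#'
#' Writes the fixed header `episode_id,patient_id,infection,pct,crp,il6`.
#' Numeric values are serialized with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces every double bit-exactly.
#' Absent `patient_id` values are written as empty fields, not `"NA"`.
#'
#' @param cohort a [cohort].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) == 0L) stop("cannot write an empty cohort", call. = FALSE)
  out <- data.frame(
    episode_id = cohort$episode_id,
    patient_id = ifelse(is.na(cohort$patient_id), "", cohort$patient_id),
    infection = format_full(cohort$infection),
    pct = format_full(cohort$pct),
    crp = format_full(cohort$crp),
    il6 = format_full(cohort$il6),
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = c(1L, 2L), eol = "\n")
  invisible(path)
}

# shortest decimal string that round-trips the double exactly
format_full <- function(x) {
  vapply(x, function(v) {
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x)
  n_inf <- sum(x$infection == 1)
  cat(sprintf("Fever-episode cohort: %d episodes (%d documented infection, %d fever only)\n",
              n, n_inf, n - n_inf))
  cat("provenance:", attr(x, "provenance"), "\n\n")
  print.data.frame(utils::head(x, 10))
  if (n > 10) cat("... and", n - 10, "more rows\n")
  invisible(x)
}
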