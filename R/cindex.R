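#' Reference means for CIndex normalization
#'
#' The composite index divides each biomarker by a reference mean before
#' summing, which removes the very different natural scales of the three
#' assays. By default the reference is the arithmetic mean of each biomarker
#' over the entire analyzed cohort (both groups pooled); for deployment, an
#' external reference derived from a large homogeneous sample can be supplied
#' instead.
#'
#' @param cohort a [cohort].
#' @return a `reference_means` object: named numeric vector
#'   `c(pct, crp, il6)` with attribute `source = "cohort"`.
#' @seealso [external_reference_means()]
#' @export
reference_means <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  m <- vapply(BIOMARKERS, function(b) mean(cohort[[b]]), numeric(1))
  if (any(m <= 0)) {
    stop("biomarker(s) with non-positive mean: ",
         paste(BIOMARKERS[m <= 0], collapse = ", "),
         " -- normalization undefined", call. = FALSE)
  }
  structure(m, source = "cohort", class = "reference_means")
}

#' Externally supplied reference means
#'
#' @param pct,crp,il6 strictly positive reference means on the assays'
#'   native scales.
#' @return a `reference_means` object with attribute `source = "external"`.
#' @export
external_reference_means <- function(pct, crp, il6) {
  m <- c(pct = pct, crp = crp, il6 = il6)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("reference means must be finite and > 0", call. = FALSE)
  }
  structure(m, source = "external", class = "reference_means")
}

#' @export
print.reference_means <- function(x, ...) {
  cat(sprintf("Reference means (%s): pct = %g, crp = %g, il6 = %g\n",
              attr(x, "source"), x[["pct"]], x[["crp"]], x[["il6"]]))
  invisible(x)
}

#' Compute the composite index per episode
#'
#' For episode i the index is the unweighted sum of the three mean-normalized
#' biomarkers:
#' \deqn{CIndex_i = PCT_i/\hat{PCT} + CRP_i/\hat{CRP} + IL6_i/\hat{IL6}.}
#' It is dimensionless, and when the reference means are the cohort's own
#' means the cohort average of the index is exactly 3 (each normalized column
#' has mean 1); an episode sitting at the mean of all three markers scores
#' exactly 3.
#'
#' @param cohort a [cohort].
#' @param ref a `reference_means` object; defaults to the cohort's own means.
#' @return data frame `episode_id, cindex, pct_term, crp_term, il6_term`,
#'   one row per episode in cohort order.
#' @export
compute_cindex <- function(cohort, ref = reference_means(cohort)) {
  stopifnot(inherits(cohort, "cohort"), inherits(ref, "reference_means"))
  terms <- vapply(BIOMARKERS, function(b) cohort[[b]] / ref[[b]],
                  numeric(nrow(cohort)))
  terms <- matrix(terms, nrow = nrow(cohort),
                  dimnames = list(NULL, BIOMARKERS))
  data.frame(
    episode_id = cohort$episode_id,
    cindex = terms[, "pct"] + terms[, "crp"] + terms[, "il6"],
    pct_term = terms[, "pct"],
    crp_term = terms[, "crp"],
    il6_term = terms[, "il6"],
    stringsAsFactors = FALSE
  )
}
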