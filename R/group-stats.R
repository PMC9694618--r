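#' Summary statistics for one marker in one group
#'
#' N, mean, median, sample SD (n-1 denominator) and quartiles by linear
#' interpolation of order statistics (quantile position 1 + (n-1)p, the
#' `type = 7` convention).
#'
#' @param values non-empty numeric vector.
#' @param name marker name for the row.
#' @param group group label for the row (`"total"`, `"infection"`,
#'   `"no_infection"`).
#' @return one-row data frame `marker, group, n, mean, median, sd, q1, q3`.
#' @export
summarize_marker <- function(values, name = "value", group = "total") {
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("values must be non-empty and finite", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  data.frame(
    marker = name, group = group, n = length(values),
    mean = mean(values), median = stats::median(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    q1 = q[1], q3 = q[2],
    stringsAsFactors = FALSE
  )
}

#' Per-group summary table for a cohort
#'
#' One row per marker (the three biomarkers plus the composite index when
#' supplied) and group (total / infection / no_infection).
#'
#' @param cohort a [cohort].
#' @param cindex optional per-episode index values aligned with the cohort
#'   (e.g. the `cindex` column of [compute_cindex()]).
#' @return data frame of [summarize_marker()] rows.
#' @export
summarize_cohort <- function(cohort, cindex = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  markers <- lapply(BIOMARKERS, function(b) cohort[[b]])
  names(markers) <- BIOMARKERS
  if (!is.null(cindex)) {
    stopifnot(length(cindex) == nrow(cohort))
    markers$cindex <- cindex
  }
  groups <- list(total = rep(TRUE, nrow(cohort)),
                 infection = cohort$infection == 1,
                 no_infection = cohort$infection == 0)
  rows <- list()
  for (m in names(markers)) {
    for (g in names(groups)) {
      if (!any(groups[[g]])) next
      rows[[length(rows) + 1L]] <-
        summarize_marker(markers[[m]][groups[[g]]], m, g)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group Wilcoxon-Mann-Whitney rank test
#'
#' Midranks are used for ties. The two-sided p-value is exact (full
#' enumeration of all label reassignments of the observed pooled values,
#' valid with ties) when `n1 + n2 <= exact_limit`, otherwise a normal
#' approximation with tie correction and continuity correction is used. The
#' statistic reported is the Mann-Whitney U of the first sample.
#'
#' @param x,y non-empty numeric vectors (the two groups).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) switches on `exact_limit`.
#' @param exact_limit combined size up to which enumeration is used
#'   (default 12; C(12, 6) = 924 reassignments).
#' @return object of class `rank_sum_test`: `statistic` (U), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, exact = NULL, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                    # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- if (is.null(exact)) n <= exact_limit else isTRUE(exact)

  if (use_exact) {
    combos <- utils::combn(n, n1)
    offset <- n1 * (n1 + 1) / 2
    u_all <- colSums(matrix(r[combos], nrow = n1)) - offset
    center <- n1 * n2 / 2
    p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
    method <- "exact"
  } else {
    center <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1                            # all values tied
    } else {
      z <- (abs(u_obs - center) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = u_obs, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon-Mann-Whitney test (%s): U = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}
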