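---
title: "Methods: a mean-normalized composite biomarker index for infection at fever onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mean-normalized composite biomarker index for infection at fever onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cindexr)
```

## The clinical question and the model

In haematological patients under chemotherapy-induced neutropenia, most
fever episodes are not microbiologically documented infections, but the ones
that are need antibiotics early. At fever onset only serum inflammation
markers are available: procalcitonin (PCT), C-reactive protein (CRP) and
interleukin-6 (IL-6). The three live on incommensurable scales (their
clinical cut-offs differ by orders of magnitude), which makes naive sums
meaningless. The composite implemented here divides each marker by a
reference mean before summing:

$$\mathrm{CIndex}_i \;=\; \frac{\mathrm{PCT}_i}{\widehat{\mathrm{PCT}}} +
\frac{\mathrm{CRP}_i}{\widehat{\mathrm{CRP}}} +
\frac{\mathrm{IL6}_i}{\widehat{\mathrm{IL6}}},$$

where $i$ indexes fever episodes and the hatted terms are the arithmetic
means of each marker over the entire analyzed sample, both outcome groups
pooled. The index is dimensionless and unweighted: no coefficients are
learned, so each marker contributes through its own variability and
discrimination. Two identities pin the construction down and are enforced
by the tests:

* an episode whose three markers sit exactly at the reference means scores
  exactly 3;
* when the reference is the cohort's own means, the cohort average of the
  index is exactly 3 (each normalized column has mean 1).

The index is also invariant to rescaling any one marker column by a positive
constant (with the reference recomputed), which is what "removing the scale
problem" means operationally, and it is strictly increasing in each marker.

Reference means default to the analyzed cohort's own pooled means. For
deployment on new patients, means estimated from a large homogeneous sample
can be supplied instead (`external_reference_means()`); the fitted object
records which source was used.

## Evaluation machinery

**Group summaries.** For every marker and group (total, infection,
no infection) the package reports N, mean, median, sample SD (the $n-1$
denominator, appropriate for a sample description) and quartiles. Quartiles
use linear interpolation of order statistics — quantile $p$ at position
$1 + (n-1)p$, R's `type = 7` — the most common default in scientific
software; the convention is recorded in every report because published
summary tables rarely state theirs.

**Two-group comparison.** Differences between the infection and fever-only
groups are tested with the Wilcoxon–Mann–Whitney rank test, two-sided, using
midranks for ties. When the combined sample size is at most 12 the p-value
is exact: all $\binom{n_1+n_2}{n_1}$ reassignments of the group labels over
the observed pooled values are enumerated, which remains valid under ties
and is cheap at that scale (at most 924 reassignments; the threshold matches
the size of the smaller group in the reference cohort, $n = 11$). Larger
samples use the normal approximation with tie correction and a 0.5
continuity correction. Both routes are labelled in the output, since
published p-values usually do not say which was used. The significance
threshold $\alpha = 0.05$ is reported, never hard-coded into filtering, and
no multiplicity correction is applied (none is part of the procedure being
implemented).

**ROC analysis.** For each single marker and for the composite, the
empirical ROC curve is built over the distinct observed scores plus a
sentinel above the maximum (the "predict nobody" operating point), under the
decision rule *score ≥ threshold predicts infection*. The ≥ convention at
observed values matches how clinical cut-offs are quoted; whether a given
published table used ≥ or >, observed values or midpoints, is generally not
recoverable, so the choice is logged in the report rather than claimed to be
canonical. The AUC is computed by trapezoidal integration, which for this
curve construction is algebraically identical to the tie-corrected rank
statistic $U/(n_{pos} n_{neg})$ — the probability that a random positive
outscores a random negative, ties counting one half. The test suite checks
this identity to $10^{-12}$ against an independent pairwise-counting
implementation (and against pROC), rather than trusting either route alone.

The reported cut-off maximizes Youden's $J = \text{sensitivity} +
\text{specificity} - 1$. Ties in $J$ are broken toward higher sensitivity —
a missed infection being the costly error in this setting — then toward the
lower cut-off; under the ≥ rule a lower observed cut-off is weakly more
sensitive, so the degenerate sentinel never wins a tie and a
no-discrimination marker is reported at the all-positive operating point
($J = 0$, sensitivity 1). Cut-offs are reported as observed score values,
not interpolated midpoints. No confidence intervals are attached to the
AUCs; interval estimation (e.g. bootstrap or DeLong) is outside this
package's scope.

## The synthetic cohort generator

The raw episode-level data behind the reference cohort (51 fever episodes in
adult haematological patients: 40 without documented infection, 11 with)
were never deposited; only per-group summary cells are published. The
generator therefore exists to reproduce the *statistical structure* the
analysis assumes, not the real joint distribution.

Each (marker, group) cell is modelled as a two-parameter lognormal. The
family was chosen once, on the grounds that every published cell shows mean
well above median — strong right skew on a positive support — and no family
is stated by the source; gamma or Weibull alternatives are deliberately not
offered. Two fitting routes exist:

* **moment matching** (the default): $\sigma^2 = \log(1 + s^2/m^2)$,
  $\mu = \log m - \sigma^2/2$, so the analytic mean and SD equal the targets
  exactly (round-trip enforced to $10^{-9}$ relative over a wide grid);
* **quantile matching** (the fallback): $\mu = \log(\text{median})$,
  $\sigma = |\log(q/\text{median})| / z_{0.75}$ from the median and one
  quartile.

The fallback exists because one published cell (IL-6, infection group)
prints an SD of 0.04 against a mean of 325.81 — impossible alongside the
rest of its row. That cell is fitted from its median (189.00) and Q1
(93.45); the fitted distribution's analytic mean comes out at ≈ 326, in
agreement with the printed mean, which is strong evidence the SD cell is
the corrupted entry. This is surfaced as a consistency check in the fit
report, not applied as a silent correction. A second cell (PCT, infection)
has summaries that are mutually inconsistent with *any* two-parameter
family (mean 19.05, SD 36.45, but median 0.79); there the moment fit is
retained, because the mean is the quantity the index normalizes by, and the
implied-versus-printed median discrepancy is left visible in the fit report.

Sampling is seeded through deterministic substreams derived from
(seed, marker, group), so a cohort is bit-identical for a given seed
regardless of evaluation order. The default configuration uses the
published group sizes (40/11). Episodes are independent: the roughly 1.5
episodes per patient of the real cohort are not modelled (the analysis
treats episodes as the unit), and the three markers are drawn independently
within an episode because no correlation information is published.

That last limitation matters for interpretation: simulated AUCs and
cut-offs are **not** expected to reproduce the real-cohort values, and the
package makes no such claim. Independence between markers typically changes
the composite's advantage over the best single marker, and lognormal tails
fitted to means/SDs can make an individual marker (notably PCT, whose two
group means differ 16-fold) look stronger than it is in correlated real
data. What the simulation *does* support is property-level validation: the
closed-form AUC between two lognormal groups,
$\Phi\!\big((\mu_1-\mu_0)/\sqrt{\sigma_0^2+\sigma_1^2}\big)$, is recovered
empirically to within ±0.01 at $10^5$ draws per group for every default
spec, which exercises the generator and the ROC machinery against each
other through an independent closed form.

## Numerical and design choices

* **Exact identities over tolerances.** The mean-of-3 identities hold to
  $10^{-12}$ relative; AUC-vs-rank-statistic to $10^{-12}$; fit round-trips
  to $10^{-9}$ relative. These are floating-point-tight bounds, not
  statistical slack.
* **CSV round-trip.** Cohort values are serialized with up to 17 significant
  digits (shortest representation that restores the double bit-exactly), so
  write-then-read is the identity.
* **Zero is legal input** for a biomarker (assays report below-detection as
  small values); only negative, missing or non-numeric values are invalid.
  An all-zero marker column makes the normalization undefined and is an
  error.
* **Labels** are stored only as 0/1; group display names are applied at
  report time.
* **Units are annotations, not data.** The source's printed units are
  unusual for two of the assays; no conversion could be justified, so values
  pass through untouched and the index is dimensionless regardless.
* **Config files** for the simulator are JSON mirroring the config object
  (targets and fit method; parameters are refitted on read). One format was
  chosen deliberately to keep the interface small.
* **Problem sizes in tests.** Enumeration oracles run at combined sizes
  ≤ 10–20, Monte-Carlo checks at $10^5$ draws per group; these sizes make
  the whole suite run in well under a minute while leaving Monte-Carlo
  standard errors a factor of several below the asserted tolerances.

## Known limitations

* Generalization of a cohort-mean-normalized index to new patients requires
  externally estimated reference means; the package supports them but
  cannot tell you which population they should come from.
* The rank tests and ROC analysis treat episodes as independent; repeated
  episodes from one patient violate that silently.
* The generator emulates marginal per-group distributions only. Any
  quantity sensitive to inter-marker correlation (including the composite's
  real-world AUC) cannot be validated against it.
* Two published summary cells are internally inconsistent (see above); the
  package documents its reading of them rather than resolving the source's
  typography.
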