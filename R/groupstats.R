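#' @title Comparing perception distributions across rater strata
#' @description Nonparametric two-sample comparisons of the per-level
#'   interval-extreme distributions (IEDs) elicited from two strata
#'   (e.g. doctors vs laypeople), and a binned summary of the qualitative
#'   inverse mapping from numeric values to severity labels.
#' @name groupstats
NULL

#' Build an IED sample for one level and stratum
#'
#' Three sources are supported: `extremes` pools both interval endpoints
#' (so n respondents contribute 2n values, matching the reported IED sample
#' sizes), `centroids` uses interval midpoints, `rps` uses representative
#' points (rows without one are dropped).
#'
#' @param responses validated interval-response data.frame.
#' @param level,stratum the group to extract.
#' @param source `"extremes"`, `"centroids"` or `"rps"`.
#' @return An `ied_sample`: list with `level`, `stratum`, `source`, `values`.
#' @export
ied_sample <- function(responses, level, stratum,
                       source = c("extremes", "centroids", "rps")) {
  source <- match.arg(source)
  sub <- responses[responses$level == level & responses$stratum == stratum, , drop = FALSE]
  values <- switch(source,
    extremes = c(sub$lower, sub$upper),
    centroids = if (nrow(sub)) interval_central_tendency(sub$lower, sub$upper) else numeric(0),
    rps = sub$representative_point[!is.na(sub$representative_point)]
  )
  structure(list(level = level, stratum = stratum, source = source,
                 values = as.numeric(values)), class = "ied_sample")
}

check_nonempty <- function(a, b) {
  if (length(a$values) == 0 || length(b$values) == 0)
    stop("degenerate input: empty IED sample")
}

#' Two-sample Kolmogorov-Smirnov comparison of IEDs
#'
#' Two-sided test of equality of distribution shapes:
#' \eqn{D = \sup_x |F_a(x) - F_b(x)|} over the pooled support. With
#' integer-valued data ties are unavoidable and the p-value is the
#' asymptotic approximation (conservative under heavy ties).
#'
#' @param a,b `ied_sample`s for the same level from different strata.
#' @return List with `statistic` (D in \[0,1\]) and `p_value`.
#' @export
ks_compare <- function(a, b) {
  check_nonempty(a, b)
  res <- suppressWarnings(stats::ks.test(a$values, b$values,
                                         alternative = "two.sided", exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Two-sample Mann-Whitney U comparison of IEDs
#'
#' Two-sided rank-sum test of mean-rank equality. The reported U counts
#' pairs where an `a` value exceeds a `b` value (ties count one half); the
#' complement identity U + U' = n_a n_b links the two orientations. The
#' p-value is exact when both samples have at most 8 values and no ties,
#' and uses the tie-corrected normal approximation otherwise.
#'
#' @param a,b `ied_sample`s.
#' @return List with `U` and `p_value`.
#' @export
mw_compare <- function(a, b) {
  check_nonempty(a, b)
  exact <- length(a$values) <= 8 && length(b$values) <= 8 &&
    !anyDuplicated(c(a$values, b$values))
  res <- suppressWarnings(stats::wilcox.test(a$values, b$values,
                                             alternative = "two.sided", exact = exact))
  list(U = unname(res$statistic), p_value = res$p.value)
}

#' Per-level two-stratum comparison table
#'
#' Runs [ks_compare()] and [mw_compare()] for every level of the scale on
#' the chosen IED source and returns one row per level. Raw p-values are
#' reported with no multiplicity correction.
#'
#' @param responses validated interval-response data.frame holding both
#'   strata.
#' @param scale an `ordinal_scale`.
#' @param strata character vector of exactly two stratum labels.
#' @param source IED source passed to [ied_sample()].
#' @return data.frame with columns `level, ks_D, ks_p, mw_U, mw_p`.
#' @export
compare_all_levels <- function(responses, scale = severity_scale(),
                               strata = c("doctor", "patient"),
                               source = c("extremes", "centroids", "rps")) {
  source <- match.arg(source)
  stopifnot(length(strata) == 2)
  rows <- lapply(unclass(scale), function(lv) {
    a <- ied_sample(responses, lv, strata[1], source)
    b <- ied_sample(responses, lv, strata[2], source)
    if (length(a$values) == 0 || length(b$values) == 0)
      stop("level '", lv, "' is missing in one stratum")
    ks <- ks_compare(a, b)
    mw <- mw_compare(a, b)
    data.frame(level = lv, ks_D = ks$statistic, ks_p = ks$p_value,
               mw_U = mw$U, mw_p = mw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binned summary of the qualitative inverse mapping
#'
#' Partitions the value range 1--99 into consecutive bins of width
#' `granularity` (anchored at 1; the default width 3 yields 33 bins) and
#' summarizes, per non-empty bin, which label respondents chose for values
#' in that bin. The prevalence classification escalates:
#' \itemize{
#'   \item `superiority` -- the modal label (ties broken towards the lower
#'     scale rank);
#'   \item `majority` -- the modal label covers more than half the bin;
#'   \item `statistical_majority` -- additionally, a 1-df chi-squared
#'     goodness-of-fit test of the top two label counts against equal
#'     expectation has p < 0.05 (the second count is 0 when only one label
#'     occurs; no continuity correction).
#' }
#'
#' @param responses validated qualitative-response data.frame.
#' @param granularity positive integer bin width (default 3).
#' @param scale an `ordinal_scale`.
#' @return data.frame with one row per non-empty bin: `bin_lo, bin_hi,
#'   bin_center, n, mode_level, mode_share, prevalence_class, p_value`,
#'   plus one count column per scale level (prefixed `n_`).
#' @export
qualitative_bin_summary <- function(responses, granularity = 3L,
                                    scale = severity_scale()) {
  granularity <- as.integer(granularity)
  if (is.na(granularity) || granularity < 1L) stop("granularity must be a positive integer")
  lv <- unclass(scale)
  bin_of <- function(v) (as.integer(v) - 1L) %/% granularity
  bins <- sort(unique(bin_of(responses$value)))
  rows <- lapply(bins, function(b) {
    lo <- b * granularity + 1L
    hi <- min(99L, lo + granularity - 1L)
    sub <- responses[bin_of(responses$value) == b, , drop = FALSE]
    counts <- vapply(lv, function(v) sum(sub$chosen_level == v), integer(1))
    total <- sum(counts)
    mode_i <- which.max(counts)  # first max = lowest scale rank
    top2 <- c(sort(counts, decreasing = TRUE), 0L)[1:2]
    chi <- suppressWarnings(stats::chisq.test(top2, correct = FALSE))
    p <- chi$p.value
    cls <- "superiority"
    if (counts[mode_i] / total > 0.5) {
      cls <- "majority"
      if (!is.na(p) && p < 0.05) cls <- "statistical_majority"
    }
    out <- data.frame(bin_lo = lo, bin_hi = hi, bin_center = mean(lo:hi),
                      n = total, mode_level = lv[mode_i],
                      mode_share = counts[mode_i] / total,
                      prevalence_class = cls, p_value = p,
                      stringsAsFactors = FALSE)
    for (j in seq_along(lv)) out[[paste0("n_", lv[j])]] <- counts[j]
    out
  })
  do.call(rbind, rows)
}
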