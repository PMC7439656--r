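#' @title Fuzzification of elicited ordinal-level perceptions
#' @description Each severity label is given a quantitative semantics as a
#'   discrete fuzzy set over the integer grid 0..100: a non-negative weight
#'   function built either from representative points, from interval central
#'   tendencies, or from whole intervals with inverse-width weights. The
#'   resulting sets are not required to be fuzzy numbers (no convexity or
#'   unimodality is imposed).
#' @name fuzzify
NULL

#' Construct a discrete fuzzy set
#'
#' Normalizations are derived from the raw weights: `membership` divides by
#' the maximum (so the modal grid value has membership 1) and `prob` divides
#' by the sum (a probability distribution over the grid).
#'
#' @param grid numeric vector of grid positions (strictly increasing).
#' @param raw_weight non-negative weights, same length as `grid`.
#' @param level label the set gives semantics to.
#' @return An object of class `fuzzy_set`: list with `level`, `grid`,
#'   `raw_weight`, `membership`, `prob`.
#' @export
fuzzy_set <- function(grid, raw_weight, level) {
  stopifnot(length(grid) == length(raw_weight))
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (any(raw_weight < 0)) stop("raw weights must be non-negative")
  total <- sum(raw_weight)
  if (total <= 0) stop("degenerate fuzzy set: total mass is zero for level '", level, "'")
  structure(list(
    level = as.character(level),
    grid = as.numeric(grid),
    raw_weight = as.numeric(raw_weight),
    membership = raw_weight / max(raw_weight),
    prob = raw_weight / total
  ), class = "fuzzy_set")
}

#' @exportS3Method base::print
print.fuzzy_set <- function(x, ...) {
  sup <- range(x$grid[x$raw_weight > 0])
  cat("Fuzzy set for level '", x$level, "': ", sum(x$raw_weight > 0),
      " support points in [", sup[1], ", ", sup[2], "], total mass ",
      format(sum(x$raw_weight)), "\n", sep = "")
  invisible(x)
}

base_grid <- function() 0:100

#' Fuzzy set from representative points
#'
#' Counts how many times each grid value was named as the representative
#' point of the level: `raw_weight(x)` is the number of occurrences of `x`.
#'
#' @param points integer values in \[0, 100\] (non-integers rounded half-up).
#' @param level label.
#' @return A `fuzzy_set` on the full 0..100 grid.
#' @export
fuzzify_from_points <- function(points, level) {
  if (length(points) == 0) stop("degenerate input: no points for level '", level, "'")
  points <- round_half_up(as.numeric(points))
  if (any(is.na(points)) || any(points < 0 | points > 100)) {
    stop("points must lie in [0, 100]")
  }
  w <- tabulate(points + 1L, nbins = 101L)
  fuzzy_set(base_grid(), w, level)
}

#' Central tendency of an elicited interval
#'
#' For a single interval the centroid and the median coincide at the
#' midpoint, hence the one available method. Midpoints are rounded half-up
#' to the integer grid.
#'
#' @param lower,upper interval extremes in \[0, 100\], vectorized.
#' @param method currently only `"midpoint"`.
#' @return Integer midpoint(s).
#' @export
interval_central_tendency <- function(lower, upper, method = c("midpoint")) {
  method <- match.arg(method)
  stopifnot(all(lower <= upper))
  round_half_up((lower + upper) / 2)
}

#' Fuzzy set from interval central tendencies
#'
#' Reduces each respondent's interval to its midpoint and counts midpoints
#' as representative points.
#'
#' @param responses data.frame with `lower` and `upper` columns, all rows
#'   for the same level.
#' @param level label.
#' @return A `fuzzy_set`.
#' @export
fuzzify_from_interval_centers <- function(responses, level) {
  if (nrow(responses) == 0) stop("degenerate input: no intervals for level '", level, "'")
  fuzzify_from_points(interval_central_tendency(responses$lower, responses$upper), level)
}

#' Fuzzy set from whole intervals with inverse-width weights
#'
#' Every grid point covered by a respondent's interval \eqn{[l_i, u_i]}
#' receives weight \eqn{w_i = 1/(u_i - l_i + 1)}, so each interval
#' contributes total mass exactly 1 and wide (vague) intervals spread their
#' unit of evidence thinly. A degenerate interval \eqn{[x, x]} is a unit
#' point mass.
#'
#' @inheritParams fuzzify_from_interval_centers
#' @return A `fuzzy_set` on the full 0..100 grid; its total raw mass equals
#'   the number of input intervals.
#' @export
fuzzify_from_whole_intervals <- function(responses, level) {
  n <- nrow(responses)
  if (n == 0) stop("degenerate input: no intervals for level '", level, "'")
  lo <- as.integer(responses$lower)
  hi <- as.integer(responses$upper)
  stopifnot(all(lo >= 0), all(hi <= 100), all(lo <= hi))
  w <- numeric(101L)
  for (i in seq_len(n)) {
    span <- (lo[i]:hi[i]) + 1L
    w[span] <- w[span] + 1 / (hi[i] - lo[i] + 1)
  }
  fuzzy_set(base_grid(), w, level)
}

#' Coarsen a fuzzy set by binning
#'
#' Grid points are partitioned into consecutive bins of width `granularity`,
#' anchored at the smallest grid value (the last bin may be short). A bin's
#' weight is the sum of its members' weights and its representative position
#' is the arithmetic mean of its members' grid values; membership and
#' probability normalizations are re-derived. Total raw mass is preserved.
#'
#' @param f a `fuzzy_set`.
#' @param granularity positive integer bin width; 1 returns `f` unchanged.
#' @return A `fuzzy_set` on the binned grid.
#' @export
bin_fuzzy_set <- function(f, granularity) {
  stopifnot(inherits(f, "fuzzy_set"))
  granularity <- as.integer(granularity)
  if (is.na(granularity) || granularity < 1L) stop("granularity must be a positive integer")
  if (granularity == 1L) return(f)
  bin <- (seq_along(f$grid) - 1L) %/% granularity
  grid2 <- as.numeric(tapply(f$grid, bin, mean))
  w2 <- as.numeric(tapply(f$raw_weight, bin, sum))
  fuzzy_set(grid2, w2, f$level)
}

#' Build fuzzy sets for every level of a scale
#'
#' Convenience dispatcher over the three fuzzification routes, applied
#' per level to a validated interval-response table (or, for the `points`
#' route, its representative points).
#'
#' @param responses validated interval-response data.frame (single stratum
#'   or pooled, as the caller intends).
#' @param scale an `ordinal_scale`.
#' @param route `"interval_centers"`, `"whole_intervals"`, or `"points"`
#'   (representative points; rows without an RP are ignored on that route).
#' @param granularity optional binning width applied to each set (default 1,
#'   no binning).
#' @return Named list of `fuzzy_set`s, one per scale level.
#' @export
build_fuzzy_sets <- function(responses, scale = severity_scale(),
                             route = c("interval_centers", "whole_intervals", "points"),
                             granularity = 1L) {
  route <- match.arg(route)
  out <- lapply(unclass(scale), function(lv) {
    sub <- responses[responses$level == lv, , drop = FALSE]
    f <- switch(route,
      interval_centers = fuzzify_from_interval_centers(sub, lv),
      whole_intervals = fuzzify_from_whole_intervals(sub, lv),
      points = fuzzify_from_points(
        sub$representative_point[!is.na(sub$representative_point)], lv)
    )
    bin_fuzzy_set(f, granularity)
  })
  names(out) <- unclass(scale)
  out
}

#' Serialize fuzzy sets to JSON
#'
#' Only `level`, `grid` and `raw_weight` are stored; membership and
#' probability normalizations are recomputed on load.
#'
#' @param fuzzy_sets a single `fuzzy_set` or a named list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fuzzy_sets <- function(fuzzy_sets, path) {
  if (inherits(fuzzy_sets, "fuzzy_set")) fuzzy_sets <- list(fuzzy_sets)
  payload <- lapply(unname(fuzzy_sets), function(f) {
    list(level = f$level, grid = f$grid, raw_weight = f$raw_weight)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fuzzy sets from JSON
#'
#' @param path file written by [write_fuzzy_sets()].
#' @return Named list of `fuzzy_set`s (names are the levels).
#' @export
read_fuzzy_sets <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- lapply(payload, function(p) fuzzy_set(p$grid, p$raw_weight, p$level))
  names(out) <- vapply(out, function(f) f$level, character(1))
  out
}
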