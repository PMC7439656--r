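#' Ordered label set for an ordinal variable
#'
#' An `ordinal_scale` is an ordered, duplicate-free set of label strings
#' \eqn{V = \{v_1 < \dots < v_k\}}. The order is fixed at construction and
#' drives every rank-based encoding and tie-break in the package.
#'
#' @param levels character vector of unique labels, in increasing order of
#'   the underlying quantity (at least 2).
#' @return An object of class `ordinal_scale` (a character vector of labels).
#' @examples
#' sc <- ordinal_scale(c("Low", "High"))
#' level_rank(sc, "High")
#' @export
ordinal_scale <- function(levels) {
  levels <- as.character(levels)
  if (length(levels) < 1L) stop("an ordinal scale needs at least one level")
  if (anyDuplicated(levels)) stop("scale levels must be unique")
  if (anyNA(levels) || any(!nzchar(levels))) stop("scale levels must be non-empty strings")
  structure(levels, class = "ordinal_scale")
}

#' Five-level HL7 severity scale
#'
#' The default scale used throughout: Absent < Mild < Moderate < Severe <
#' Extreme, the five-category severity terminology of HL7 FHIR.
#'
#' @return An `ordinal_scale` of length 5.
#' @export
severity_scale <- function() {
  ordinal_scale(c("Absent", "Mild", "Moderate", "Severe", "Extreme"))
}

#' Rank of a level within its scale
#'
#' @param scale an `ordinal_scale`.
#' @param level character vector of labels.
#' @return Integer rank(s), 1-based; errors on unknown labels.
#' @export
level_rank <- function(scale, level) {
  r <- match(as.character(level), unclass(scale))
  if (anyNA(r)) {
    bad <- unique(as.character(level)[is.na(r)])
    stop("unknown level(s): ", paste(bad, collapse = ", "))
  }
  r
}

#' @exportS3Method base::print
print.ordinal_scale <- function(x, ...) {
  cat("Ordinal scale (", length(x), " levels): ",
      paste(unclass(x), collapse = " < "), "\n", sep = "")
  invisible(x)
}

# round-half-up to integers; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

clip01_100 <- function(x) pmin(100, pmax(0, x))
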