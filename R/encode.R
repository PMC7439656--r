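#' @title From fuzzy sets to feature encodings
#' @description Defuzzification-style transforms that turn per-level fuzzy
#'   sets into machine-learning features: the centroid scalar (CoIED),
#'   Monte-Carlo style weighted sampling, and the membership vector, plus
#'   the classical rank / one-hot / rank-hot baselines.
#' @name encode
NULL

#' Centroid of a fuzzy set (CoIED)
#'
#' Center-of-gravity defuzzification:
#' \deqn{CoIED(v) = \sum_x x\,\mu_v(x) / \sum_x \mu_v(x).}
#' The result is invariant to rescaling the weights, so raw weights,
#' membership and probability normalizations all give the same centroid.
#'
#' @param f a `fuzzy_set`.
#' @return Scalar centroid in \[min support, max support\].
#' @export
coied <- function(f) {
  stopifnot(inherits(f, "fuzzy_set"))
  sum(f$grid * f$raw_weight) / sum(f$raw_weight)
}

#' Per-level CoIED encoding map
#'
#' Computes the centroid of each level's fuzzy set and flags whether the
#' map preserves the scale order (non-strictly): whenever
#' \eqn{v_i \le v_j} the centroids satisfy
#' \eqn{CoIED(v_i) \le CoIED(v_j)}. An order-preserving map guarantees that
#' the encoding never reverses the ordinality of the labels.
#'
#' @param fuzzy_sets named list of `fuzzy_set`s covering every scale level.
#' @param scale an `ordinal_scale`.
#' @return An `encoding_map` of kind `"coied"` with fields `per_level`
#'   (named numeric) and `order_preserving` (logical).
#' @export
build_coied_map <- function(fuzzy_sets, scale = severity_scale()) {
  lv <- unclass(scale)
  missing <- setdiff(lv, names(fuzzy_sets))
  if (length(missing)) stop("no fuzzy set for level(s): ", paste(missing, collapse = ", "))
  vals <- vapply(lv, function(v) coied(fuzzy_sets[[v]]), numeric(1))
  structure(list(
    scale = scale,
    kind = "coied",
    per_level = vals,
    order_preserving = !is.unsorted(vals)
  ), class = "encoding_map")
}

#' @exportS3Method base::print
print.encoding_map <- function(x, ...) {
  cat("Encoding map (", x$kind, ") over ", length(x$scale), " levels\n", sep = "")
  if (x$kind %in% c("coied", "ordinal_rank")) {
    print(round(x$per_level, 3))
    if (!is.null(x$order_preserving))
      cat("order preserving:", x$order_preserving, "\n")
  }
  invisible(x)
}

#' Weighted-sampling encoding of an ordinal column
#'
#' Converts each level's fuzzy set into the probability distribution
#' \eqn{p_v(x) = \mu_v(x) / \sum_y \mu_v(y)} and replaces the labels with
#' draws from it. Two sampling granularities are supported:
#' `per_cell` draws independently for every occurrence (so one row can
#' receive a value pair that reverses the label order when supports
#' overlap), while `per_label` draws one value per level and reuses it for
#' all its occurrences. Output is a pure function of
#' (column, fuzzy sets, seed, mode); the caller's RNG state is untouched.
#'
#' @param column character vector of levels.
#' @param fuzzy_sets named list of `fuzzy_set`s covering every level that
#'   occurs in `column`.
#' @param seed integer seed.
#' @param mode `"per_cell"` (default) or `"per_label"`.
#' @return Numeric vector, same length as `column`; every value lies in the
#'   support of its level's fuzzy set.
#' @export
weighted_sampling_encode <- function(column, fuzzy_sets, seed,
                                     mode = c("per_cell", "per_label")) {
  mode <- match.arg(mode)
  column <- as.character(column)
  used <- unique(column)
  missing <- setdiff(used, names(fuzzy_sets))
  if (length(missing)) stop("no fuzzy set for level(s): ", paste(missing, collapse = ", "))
  draw <- function(f, n) {
    sup <- f$prob > 0
    if (sum(sup) == 1L) return(rep(f$grid[sup], n))
    sample(f$grid[sup], n, replace = TRUE, prob = f$prob[sup])
  }
  with_preserved_seed(seed, {
    if (mode == "per_label") {
      one <- vapply(used, function(v) draw(fuzzy_sets[[v]], 1L), numeric(1))
      unname(one[column])
    } else {
      out <- numeric(length(column))
      for (v in used) {
        idx <- which(column == v)
        out[idx] <- draw(fuzzy_sets[[v]], length(idx))
      }
      out
    }
  })
}

# Run expr under set.seed(seed) and restore the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Membership-vector encoding of a level
#'
#' Selects the grid value most representative of the level,
#' \eqn{x_v = \arg\max_x \mu_v(x)} (ties broken towards the smallest grid
#' value), and returns the vector of all levels' memberships at that point,
#' \eqn{\langle \mu_{v_1}(x_v), \dots, \mu_{v_k}(x_v) \rangle}. The
#' component for `v` itself is 1 by construction; when the supports of the
#' level sets are pairwise disjoint the vector degenerates to the one-hot
#' encoding of `v`.
#'
#' @param v level label.
#' @param fuzzy_sets named list of `fuzzy_set`s, one per scale level.
#' @param scale an `ordinal_scale`.
#' @return Numeric vector of length `k` named by the scale levels.
#' @export
membership_encode <- function(v, fuzzy_sets, scale = severity_scale()) {
  lv <- unclass(scale)
  missing <- setdiff(lv, names(fuzzy_sets))
  if (length(missing)) stop("no fuzzy set for level(s): ", paste(missing, collapse = ", "))
  fv <- fuzzy_sets[[as.character(v)]]
  if (is.null(fv)) stop("unknown level: ", v)
  x_v <- fv$grid[which.max(fv$membership)]  # which.max returns the first max
  out <- vapply(lv, function(u) {
    fu <- fuzzy_sets[[u]]
    i <- match(x_v, fu$grid)
    if (is.na(i)) 0 else fu$membership[i]
  }, numeric(1))
  names(out) <- lv
  out
}

#' Full membership encoding map
#'
#' @inheritParams build_coied_map
#' @return An `encoding_map` of kind `"membership"`; `per_level` is a
#'   k-by-k matrix, one row per encoded level.
#' @export
build_membership_map <- function(fuzzy_sets, scale = severity_scale()) {
  lv <- unclass(scale)
  m <- t(vapply(lv, function(v) membership_encode(v, fuzzy_sets, scale),
                numeric(length(lv))))
  rownames(m) <- lv
  structure(list(scale = scale, kind = "membership", per_level = m),
            class = "encoding_map")
}

#' Classical ordinal encodings
#'
#' `ordinal_rank` maps the i-th level to the integer i-1; `one_hot` to the
#' unit vector with a 1 at position i; `rank_hot` to the staircase vector
#' with 1s at positions 1..i.
#'
#' @param column character vector of levels.
#' @param scale an `ordinal_scale`.
#' @param kind one of `"ordinal_rank"`, `"one_hot"`, `"rank_hot"`.
#' @return For `ordinal_rank`, a numeric vector; otherwise a 0/1 matrix
#'   with one column per level.
#' @export
baseline_encode <- function(column, scale = severity_scale(),
                            kind = c("ordinal_rank", "one_hot", "rank_hot")) {
  kind <- match.arg(kind)
  r <- level_rank(scale, column)
  k <- length(scale)
  if (kind == "ordinal_rank") return(r - 1)
  m <- matrix(0L, nrow = length(r), ncol = k, dimnames = list(NULL, unclass(scale)))
  if (kind == "one_hot") {
    m[cbind(seq_along(r), r)] <- 1L
  } else {
    for (j in seq_len(k)) m[, j] <- as.integer(r >= j)
  }
  m
}

#' Serialize an encoding map to JSON
#'
#' @param map an `encoding_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_encoding_map <- function(map, path) {
  stopifnot(inherits(map, "encoding_map"))
  payload <- list(
    kind = map$kind,
    levels = as.character(unclass(map$scale)),
    per_level = if (is.matrix(map$per_level)) {
      stats::setNames(lapply(seq_len(nrow(map$per_level)),
                             function(i) unname(map$per_level[i, ])),
                      rownames(map$per_level))
    } else as.list(map$per_level),
    order_preserving = map$order_preserving
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an encoding map from JSON
#'
#' @param path file written by [write_encoding_map()].
#' @return An `encoding_map`.
#' @export
read_encoding_map <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  scale <- ordinal_scale(p$levels)
  per_level <- if (p$kind == "membership") {
    m <- do.call(rbind, p$per_level)
    colnames(m) <- p$levels
    m
  } else unlist(p$per_level)
  structure(list(scale = scale, kind = p$kind, per_level = per_level,
                 order_preserving = p$order_preserving),
            class = "encoding_map")
}
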