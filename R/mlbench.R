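#' @title Nested cross-validated encoding benchmark
#' @description Harness comparing ordinal feature encodings (rank baseline,
#'   CoIED, membership vectors, weighted sampling) across four regression
#'   model families -- random forest, k-nearest neighbours, LASSO and
#'   RBF-kernel support vector regression -- under 5-fold nested
#'   cross-validation, scoring MAE and R2 with t-based confidence
#'   intervals over the outer folds.
#' @name mlbench
NULL

#' Construct a mixed-role feature table
#'
#' @param data data.frame of feature columns (no target).
#' @param roles named character vector mapping every column of `data` to
#'   `"continuous"`, `"categorical"` or `"ordinal"`.
#' @param target numeric target vector, one value per row, no missing.
#' @param scale an `ordinal_scale`; every ordinal cell must be one of its
#'   levels.
#' @return A `feature_table` object.
#' @export
feature_table <- function(data, roles, target, scale = severity_scale()) {
  stopifnot(is.data.frame(data))
  if (!setequal(names(roles), names(data)))
    stop("roles must name exactly the columns of data")
  if (!all(roles %in% c("continuous", "categorical", "ordinal")))
    stop("unknown role(s): ", paste(setdiff(roles, c("continuous", "categorical", "ordinal")), collapse = ", "))
  target <- as.numeric(target)
  if (length(target) != nrow(data)) stop("target length must match row count")
  if (anyNA(target)) stop("missing target values are not allowed")
  for (nm in names(roles)[roles == "ordinal"]) {
    bad <- setdiff(unique(as.character(data[[nm]])), unclass(scale))
    if (length(bad)) stop("ordinal feature '", nm, "' holds non-scale value(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(data = data, roles = roles[names(data)], target = target,
                 scale = scale), class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$data), "rows,", ncol(x$data), "features (",
      sum(x$roles == "continuous"), "continuous,",
      sum(x$roles == "categorical"), "categorical,",
      sum(x$roles == "ordinal"), "ordinal )\n")
  invisible(x)
}

#' Weighted-sampling encoding map
#'
#' Packages per-level sampling distributions (the probability-normalized
#' fuzzy sets) for use by [apply_encoding()].
#'
#' @inheritParams build_coied_map
#' @return An `encoding_map` of kind `"weighted_sampling"` whose
#'   `per_level` holds one `fuzzy_set` per level.
#' @export
build_ws_map <- function(fuzzy_sets, scale = severity_scale()) {
  lv <- unclass(scale)
  missing <- setdiff(lv, names(fuzzy_sets))
  if (length(missing)) stop("no fuzzy set for level(s): ", paste(missing, collapse = ", "))
  structure(list(scale = scale, kind = "weighted_sampling",
                 per_level = fuzzy_sets[lv]), class = "encoding_map")
}

encoding_kinds <- c("ordinal", "coied", "membership", "weighted_sampling",
                    "one_hot", "rank_hot")

#' Encode a feature table to a numeric matrix
#'
#' Continuous features pass through; categorical features are one-hot
#' expanded (`<feature>__<category>`, categories in sorted order); ordinal
#' features are transformed by the requested encoding. Vector encodings
#' expand to `<feature>__<level>` columns. Deterministic for everything
#' but `weighted_sampling`, which derives a distinct stream per ordinal
#' feature from `seed`.
#'
#' @param ft a `feature_table`.
#' @param encoding one of `"ordinal"`, `"coied"`, `"membership"`,
#'   `"weighted_sampling"`, `"one_hot"`, `"rank_hot"`.
#' @param maps an `encoding_map` of the matching kind, shared by all
#'   ordinal features, or a named list with one map per ordinal feature.
#'   Not needed for the rank/one-hot/rank-hot baselines.
#' @param seed integer seed (required for `weighted_sampling`).
#' @return List with `X` (numeric matrix, stable column names) and `y`.
#' @export
apply_encoding <- function(ft, encoding = encoding_kinds, maps = NULL, seed = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(ft, "feature_table"))
  needs_map <- encoding %in% c("coied", "membership", "weighted_sampling")
  map_for <- function(feature) {
    m <- if (inherits(maps, "encoding_map")) maps else maps[[feature]]
    if (is.null(m)) stop("no encoding map supplied for ordinal feature '", feature, "'")
    want <- if (encoding == "weighted_sampling") "weighted_sampling" else encoding
    if (m$kind != want)
      stop("encoding map kind '", m$kind, "' does not match requested encoding '",
           encoding, "'")
    m
  }
  if (encoding == "weighted_sampling" && is.null(seed))
    stop("weighted_sampling requires a seed")
  cols <- list()
  ord_idx <- 0L
  for (nm in names(ft$data)) {
    role <- ft$roles[[nm]]
    v <- ft$data[[nm]]
    if (role == "continuous") {
      cols[[nm]] <- as.numeric(v)
    } else if (role == "categorical") {
      for (cat in sort(unique(as.character(v))))
        cols[[paste0(nm, "__", cat)]] <- as.numeric(v == cat)
    } else {
      ord_idx <- ord_idx + 1L
      v <- as.character(v)
      if (encoding == "ordinal") {
        cols[[nm]] <- baseline_encode(v, ft$scale, "ordinal_rank")
      } else if (encoding %in% c("one_hot", "rank_hot")) {
        m <- baseline_encode(v, ft$scale, encoding)
        for (j in colnames(m)) cols[[paste0(nm, "__", j)]] <- as.numeric(m[, j])
      } else if (encoding == "coied") {
        pm <- map_for(nm)
        cols[[nm]] <- unname(pm$per_level[v])
      } else if (encoding == "membership") {
        pm <- map_for(nm)
        for (j in colnames(pm$per_level))
          cols[[paste0(nm, "__", j)]] <- unname(pm$per_level[v, j])
      } else {
        pm <- map_for(nm)
        cols[[nm]] <- weighted_sampling_encode(v, pm$per_level,
                                               seed = as.integer(seed) + ord_idx,
                                               mode = "per_cell")
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = ft$target)
}

#' Default hyperparameter grids for the four model families
#'
#' Small published-style grids tuned by the inner CV loop: neighbour counts
#' for kNN, log-spaced lambda for LASSO, log-spaced C and gamma for the RBF
#' SVR; the random forest uses a fixed moderate tree count and default
#' mtry (no inner tuning).
#'
#' @return Named list of parameter-combination lists per model.
#' @export
model_grids <- function() {
  list(
    RF = list(list(ntree = 300L)),
    kNN = lapply(c(3L, 5L, 7L, 11L), function(k) list(k = k)),
    LASSO = lapply(10^seq(-3, 1, length.out = 9), function(l) list(lambda = l)),
    SVR_RBF = {
      g <- expand.grid(cost = 2^c(0, 2, 4), gamma = 2^c(-7, -5, -3))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    }
  )
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")

# Fit one model with one parameter set and predict on X_test.
# kNN/LASSO/SVR see fold-standardized features; RF sees raw values.
fit_predict <- function(model, params, X_train, y_train, X_test) {
  # constant training target: every model degenerates to the mean predictor
  if (stats::sd(y_train) == 0) return(rep(y_train[1], nrow(X_test)))
  if (model != "RF") {
    s <- standardize_fit(X_train)
    X_train <- standardize_apply(X_train, s)
    X_test <- standardize_apply(X_test, s)
  }
  switch(model,
    RF = {
      fit <- randomForest::randomForest(X_train, y_train, ntree = params$ntree)
      as.numeric(stats::predict(fit, X_test))
    },
    kNN = {
      fit <- caret::knnreg(X_train, y_train, k = params$k)
      as.numeric(stats::predict(fit, X_test))
    },
    LASSO = {
      fit <- glmnet::glmnet(X_train, y_train, alpha = 1, lambda = params$lambda)
      as.numeric(stats::predict(fit, X_test, s = params$lambda))
    },
    SVR_RBF = {
      fit <- e1071::svm(X_train, y_train, type = "eps-regression",
                        kernel = "radial", cost = params$cost, gamma = params$gamma,
                        scale = FALSE)
      as.numeric(stats::predict(fit, X_test))
    },
    stop("unknown model: ", model)
  )
}

mae <- function(obs, pred) mean(abs(obs - pred))
r2_score <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

ci_t <- function(x, level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(lo = m, hi = m))
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(lo = m - half, hi = m + half)
}

# One nested-CV pass over an encoded matrix: outer folds score, inner
# folds pick the parameter set with lowest mean MAE (first minimum).
# Returns per-outer-fold MAE/R2 and the out-of-fold prediction vector.
nested_cv_run <- function(X, y, model, grid, outer_k, inner_k, seed) {
  n <- length(y)
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(outer_k), length.out = n))
  fold_mae <- fold_r2 <- numeric(outer_k)
  oof <- numeric(n)
  for (f in seq_len(outer_k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    best <- grid[[1]]
    if (length(grid) > 1) {
      set.seed(as.integer(seed) + 1000L + f)
      inner <- sample(rep(seq_len(inner_k), length.out = length(tr)))
      score <- vapply(grid, function(par) {
        errs <- vapply(seq_len(inner_k), function(g) {
          itr <- tr[inner != g]; ite <- tr[inner == g]
          pred <- fit_predict(model, par, X[itr, , drop = FALSE], y[itr],
                              X[ite, , drop = FALSE])
          mae(y[ite], pred)
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- grid[[which.min(score)]]
    }
    set.seed(as.integer(seed) + 2000L + f)
    pred <- fit_predict(model, best, X[tr, , drop = FALSE], y[tr],
                        X[te, , drop = FALSE])
    oof[te] <- pred
    fold_mae[f] <- mae(y[te], pred)
    fold_r2[f] <- r2_score(y[te], pred)
    if (is.na(fold_r2[f]))
      warning("constant target in outer fold ", f, "; R2 undefined and excluded")
  }
  list(fold_mae = fold_mae, fold_r2 = fold_r2, oof = oof, folds = folds)
}

#' Evaluate one (model, encoding) pair with nested cross-validation
#'
#' The outer loop (default 5 folds) gives unbiased scores; the inner loop
#' tunes hyperparameters by MAE. For the stochastic weighted-sampling
#' encoding the whole evaluation is repeated `n_repeats` times (default
#' 10) with distinct derived seeds -- the table is re-encoded before each
#' repeat -- and fold scores are pooled. Confidence intervals are 95%
#' t-intervals over the (pooled) outer-fold scores.
#'
#' @param ft a `feature_table`.
#' @param model `"RF"`, `"kNN"`, `"LASSO"` or `"SVR_RBF"`.
#' @param encoding `"ordinal"`, `"coied"`, `"membership"` or
#'   `"weighted_sampling"`.
#' @param maps encoding map(s) as in [apply_encoding()].
#' @param outer_k,inner_k outer and inner fold counts.
#' @param seed integer seed controlling folds, model fits and sampling.
#' @param n_repeats evaluation repeats (defaults to 10 for
#'   `weighted_sampling`, 1 otherwise).
#' @param grids hyperparameter grids, as [model_grids()].
#' @return One-row data.frame: model, encoding, `mae_mean`, `mae_lo`,
#'   `mae_hi`, `r2_mean`, `r2_lo`, `r2_hi`, `n_folds`, `n_repeats`, `seed`.
#' @export
nested_cv_evaluate <- function(ft, model, encoding, maps = NULL,
                               outer_k = 5L, inner_k = 3L, seed = 1L,
                               n_repeats = NULL, grids = model_grids()) {
  if (!model %in% names(grids)) stop("unknown model: ", model)
  encoding <- match.arg(encoding, encoding_kinds)
  if (is.null(n_repeats)) n_repeats <- if (encoding == "weighted_sampling") 10L else 1L
  all_mae <- all_r2 <- numeric(0)
  for (r in seq_len(n_repeats)) {
    run_seed <- as.integer(seed) + (r - 1L) * 101L
    enc <- apply_encoding(ft, encoding, maps, seed = run_seed)
    res <- nested_cv_run(enc$X, enc$y, model, grids[[model]], outer_k, inner_k,
                         seed = run_seed)
    all_mae <- c(all_mae, res$fold_mae)
    all_r2 <- c(all_r2, res$fold_r2)
  }
  mci <- ci_t(all_mae)
  rci <- ci_t(all_r2)
  data.frame(model = model, encoding = encoding,
             mae_mean = mean(all_mae), mae_lo = mci[["lo"]], mae_hi = mci[["hi"]],
             r2_mean = mean(all_r2, na.rm = TRUE), r2_lo = rci[["lo"]], r2_hi = rci[["hi"]],
             n_folds = outer_k, n_repeats = n_repeats, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Random-forest order-invariance diagnostic
#'
#' Regression trees split on thresholds, so they see only the ordering of
#' a feature's values, not their spacing: any strictly increasing
#' per-level encoding must grow the same trees as the rank encoding.
#' This check encodes the table both ways, runs the same seeded
#' cross-validated forest on each, and reports whether the out-of-fold
#' predictions coincide.
#'
#' A non-monotone map violates the premise: the check is skipped with a
#' message and `NA` is returned. A monotone map with tied (collapsed)
#' centroids is run as-is and may legitimately return `FALSE`.
#'
#' @param ft a `feature_table`.
#' @param maps a CoIED `encoding_map` (shared or per-feature list).
#' @param seed integer seed.
#' @param outer_k folds for the out-of-fold predictions.
#' @param ntree forest size.
#' @return `TRUE` if predictions are identical (within floating-point
#'   equality), `FALSE` if not, `NA` if the map is not monotone.
#' @export
rf_order_invariance_check <- function(ft, maps, seed = 1L, outer_k = 5L,
                                      ntree = 300L) {
  one_map <- if (inherits(maps, "encoding_map")) list(maps) else maps
  mono <- vapply(one_map, function(m) !is.unsorted(m$per_level), logical(1))
  if (!all(mono)) {
    message("CoIED map is not order-preserving; invariance check skipped")
    return(NA)
  }
  grid <- list(list(ntree = as.integer(ntree)))
  enc_o <- apply_encoding(ft, "ordinal")
  enc_c <- apply_encoding(ft, "coied", maps)
  run_o <- nested_cv_run(enc_o$X, enc_o$y, "RF", grid, outer_k, 2L, seed)
  run_c <- nested_cv_run(enc_c$X, enc_c$y, "RF", grid, outer_k, 2L, seed)
  isTRUE(all.equal(run_o$oof, run_c$oof, tolerance = 1e-12))
}

#' Benchmark a grid of models times encodings
#'
#' Builds the CoIED, membership and weighted-sampling maps from the given
#' fuzzy sets, evaluates every (model, encoding) pair with
#' [nested_cv_evaluate()], and renders a text summary that marks, per
#' model, encodings whose MAE confidence interval does not overlap the
#' ordinal baseline's.
#'
#' @param ft a `feature_table`.
#' @param fuzzy_sets named list of `fuzzy_set`s, one per scale level.
#' @param models subset of `c("RF","kNN","LASSO","SVR_RBF")`.
#' @param encodings subset of
#'   `c("ordinal","coied","membership","weighted_sampling")`.
#' @param seed integer seed.
#' @param outer_k,inner_k,n_repeats,grids passed through.
#' @return A `benchmark_result`: list with `results` (data.frame, one row
#'   per pair) and `summary` (character lines).
#' @export
benchmark_grid <- function(ft, fuzzy_sets,
                           models = c("RF", "kNN", "LASSO", "SVR_RBF"),
                           encodings = c("ordinal", "coied", "membership",
                                         "weighted_sampling"),
                           seed = 1L, outer_k = 5L, inner_k = 3L,
                           n_repeats = 10L, grids = model_grids()) {
  stopifnot(length(models) >= 1, length(encodings) >= 1)
  maps <- list(
    ordinal = NULL,
    coied = build_coied_map(fuzzy_sets, ft$scale),
    membership = build_membership_map(fuzzy_sets, ft$scale),
    weighted_sampling = build_ws_map(fuzzy_sets, ft$scale)
  )
  rows <- list()
  for (m in models) for (e in encodings) {
    reps <- if (e == "weighted_sampling") n_repeats else 1L
    rows[[paste(m, e)]] <- nested_cv_evaluate(
      ft, m, e, maps[[e]], outer_k = outer_k, inner_k = inner_k,
      seed = seed, n_repeats = reps, grids = grids)
  }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  lines <- character(0)
  for (m in intersect(models, unique(results$model))) {
    sub <- results[results$model == m, ]
    base <- sub[sub$encoding == "ordinal", ]
    lines <- c(lines, sprintf("%s:", m))
    for (i in seq_len(nrow(sub))) {
      mark <- ""
      if (nrow(base) == 1 && sub$encoding[i] != "ordinal") {
        overlap <- sub$mae_lo[i] <= base$mae_hi && base$mae_lo <= sub$mae_hi[i]
        if (!overlap) mark <- "  ** CI disjoint from ordinal baseline"
      }
      lines <- c(lines, sprintf("  %-18s MAE [%.3f, %.3f]  R2 [%.3f, %.3f]%s",
                                sub$encoding[i], sub$mae_lo[i], sub$mae_hi[i],
                                sub$r2_lo[i], sub$r2_hi[i], mark))
    }
  }
  structure(list(results = results, summary = lines), class = "benchmark_result")
}

#' @exportS3Method base::print
print.benchmark_result <- function(x, ...) {
  cat(x$summary, sep = "\n")
  invisible(x)
}
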