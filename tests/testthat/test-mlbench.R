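# Small feature table with one ordinal feature for fast harness checks.
tiny_table <- function(n = 60, seed = 1, noise_sd = 0.5) {
  set.seed(seed)
  z <- stats::runif(n, 0, 100)
  lev <- unclass(scale5)[findInterval(z, c(20, 40, 60, 80)) + 1L]
  x <- stats::rnorm(n)
  target <- 0.05 * z + x + stats::rnorm(n, 0, noise_sd)
  feature_table(data.frame(sev = lev, x = x, stringsAsFactors = FALSE),
                c(sev = "ordinal", x = "continuous"), target, scale5)
}

test_that("encodings expand the feature matrix as documented", {
  ft <- gen_outcome_dataset(latent_outcome_spec(n_rows = 50L), seed = 2)
  maps_c <- build_coied_map(point_mass_sets(c(0, 25, 50, 75, 100)), scale5)
  maps_m <- build_membership_map(point_mass_sets(c(0, 25, 50, 75, 100)), scale5)

  eo <- apply_encoding(ft, "ordinal")
  em <- apply_encoding(ft, "membership", maps_m)
  # each of the 9 ordinal features gains 5 columns instead of 1
  expect_equal(ncol(em$X), ncol(eo$X) + 9 * 4)
  expect_true(all(paste0("ord01__", unclass(scale5)) %in% colnames(em$X)))

  # rank of Mild is 1; point masses at 0,25,...,100 scale ranks by 25
  i <- which(ft$data$ord01 == "Mild")[1]
  expect_equal(eo$X[i, "ord01"], 1, ignore_attr = TRUE)
  ec <- apply_encoding(ft, "coied", maps_c)
  expect_equal(ec$X[, "ord01"], eo$X[, "ord01"] * 25)

  expect_error(apply_encoding(ft, "coied", maps_m), "does not match")
  expect_error(apply_encoding(ft, "weighted_sampling", maps_c, seed = 1), "does not match")
  expect_error(apply_encoding(ft, "weighted_sampling",
                              build_ws_map(point_mass_sets(1:5 * 10), scale5)),
               "seed")
})

test_that("outer folds partition the rows and seeds reproduce results", {
  ft <- tiny_table()
  enc <- apply_encoding(ft, "ordinal")
  run <- ordifuzz:::nested_cv_run(enc$X, enc$y, "kNN",
                                  model_grids()$kNN, 5L, 3L, seed = 7)
  expect_equal(sort(unique(run$folds)), 1:5)
  expect_equal(length(run$folds), nrow(enc$X))
  expect_equal(sum(table(run$folds)), 60)

  r1 <- nested_cv_evaluate(ft, "kNN", "ordinal", seed = 7, outer_k = 5L)
  r2 <- nested_cv_evaluate(ft, "kNN", "ordinal", seed = 7, outer_k = 5L)
  expect_identical(r1, r2)
  expect_lte(r1$mae_lo, r1$mae_mean)
  expect_gte(r1$mae_hi, r1$mae_mean)
  expect_gte(r1$mae_mean, 0)
  expect_lte(r1$r2_mean, 1)
})

test_that("a leaked target hits the ceiling and a constant target degrades gracefully", {
  n <- 50
  set.seed(3)
  y <- stats::rnorm(n, 10, 3)
  ft <- feature_table(data.frame(leak = y, x = stats::rnorm(n)),
                      c(leak = "continuous", x = "continuous"), y, scale5)
  res <- nested_cv_evaluate(ft, "LASSO", "ordinal", seed = 1, outer_k = 5L)
  expect_lt(res$mae_mean, 0.05)
  expect_gt(res$r2_mean, 0.99)

  ftc <- feature_table(data.frame(x = stats::rnorm(n), w = stats::rnorm(n)),
                       c(x = "continuous", w = "continuous"), rep(2, n), scale5)
  expect_warning(resc <- nested_cv_evaluate(ftc, "LASSO", "ordinal",
                                            seed = 1, outer_k = 5L),
                 "R2 undefined")
  expect_lt(resc$mae_mean, 1e-8)
})

test_that("weighted-sampling repeats pool fold scores with consistent bookkeeping", {
  ft <- tiny_table()
  ws <- build_ws_map(stats::setNames(lapply(seq(10, 90, 20), function(c) {
    fuzzy_set(0:100, as.numeric(abs(0:100 - c) <= 8), as.character(c))
  }), unclass(scale5)), scale5)
  pooled <- nested_cv_evaluate(ft, "kNN", "weighted_sampling", ws,
                               seed = 5, n_repeats = 3L)
  singles <- vapply(0:2, function(r) {
    nested_cv_evaluate(ft, "kNN", "weighted_sampling", ws,
                       seed = 5 + r * 101L, n_repeats = 1L)$mae_mean
  }, numeric(1))
  expect_equal(pooled$mae_mean, mean(singles))
  expect_equal(pooled$n_repeats, 3L)
})

test_that("random forests are invariant to rank-affine CoIED maps", {
  ft <- gen_outcome_dataset(latent_outcome_spec(n_rows = 120L,
                                                cutpoints = c(20, 40, 60, 80)),
                            seed = 21)
  set.seed(77)
  for (i in 1:3) {
    # integer-valued affine maps keep midpoint thresholds exact in floats
    slope <- sample(2:24, 1)
    offset <- sample(0:4, 1)
    centers <- offset + slope * 0:4
    map <- structure(list(scale = scale5, kind = "coied",
                          per_level = stats::setNames(centers, unclass(scale5)),
                          order_preserving = TRUE), class = "encoding_map")
    expect_true(rf_order_invariance_check(ft, map, seed = i, outer_k = 3L,
                                          ntree = 60L))
  }
})

test_that("non-monotone maps gate the invariance check; non-affine maps stay near-equivalent", {
  ft <- gen_outcome_dataset(latent_outcome_spec(n_rows = 120L), seed = 22)
  bad <- structure(list(scale = scale5, kind = "coied",
                        per_level = stats::setNames(c(0, 60, 30, 75, 100), unclass(scale5)),
                        order_preserving = FALSE), class = "encoding_map")
  expect_message(res <- rf_order_invariance_check(ft, bad, seed = 1, outer_k = 3L,
                                                  ntree = 40L), "skipped")
  expect_true(is.na(res))

  # a strictly increasing but non-affine map: trees agree up to threshold
  # navigation of locally-unseen levels, so out-of-fold MAEs nearly coincide
  map <- structure(list(scale = scale5, kind = "coied",
                        per_level = stats::setNames(c(2, 10, 22, 52, 90), unclass(scale5)),
                        order_preserving = TRUE), class = "encoding_map")
  eo <- apply_encoding(ft, "ordinal")
  ec <- apply_encoding(ft, "coied", map)
  ro <- ordifuzz:::nested_cv_run(eo$X, eo$y, "RF", list(list(ntree = 100L)), 3L, 2L, 9)
  rc <- ordifuzz:::nested_cv_run(ec$X, ec$y, "RF", list(list(ntree = 100L)), 3L, 2L, 9)
  expect_lt(abs(mean(ro$fold_mae) - mean(rc$fold_mae)), 0.05 * mean(ro$fold_mae))
})

test_that("the benchmark grid returns one result per model-encoding pair", {
  ft <- tiny_table(n = 70)
  sets <- stats::setNames(lapply(c(10, 30, 50, 70, 90), function(c) {
    fuzzy_set(0:100, as.numeric(abs(0:100 - c) <= 6), as.character(c))
  }), unclass(scale5))
  bench <- benchmark_grid(ft, sets, models = c("kNN", "LASSO"),
                          encodings = c("ordinal", "coied", "weighted_sampling"),
                          seed = 4, outer_k = 3L, inner_k = 2L, n_repeats = 2L)
  expect_equal(nrow(bench$results), 6)
  expect_setequal(unique(bench$results$model), c("kNN", "LASSO"))
  expect_true(all(bench$results$mae_mean >= 0))
  expect_true(any(grepl("kNN", bench$summary)))
  expect_output(print(bench), "MAE")
})
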