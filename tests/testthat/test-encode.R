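test_that("centroid defuzzification matches hand evaluations and is scale invariant", {
  expect_equal(coied(fuzzy_set(0:100, rep(1, 101), "Mild")), 50)
  expect_equal(coied(fuzzify_from_points(42, "Mild")), 42)
  f <- fuzzy_set(0:100, as.numeric(0:100 == 10) + 3 * (0:100 == 20), "Mild")
  expect_equal(coied(f), 17.5)

  set.seed(5)
  for (i in 1:8) {
    w <- stats::runif(101)
    g1 <- fuzzy_set(0:100, w, "x")
    g2 <- fuzzy_set(0:100, w * stats::runif(1, 0.1, 50), "x")
    expect_equal(coied(g1), coied(g2))
    sup <- range(g1$grid[g1$raw_weight > 0])
    expect_gte(coied(g1), sup[1])
    expect_lte(coied(g1), sup[2])
  }
})

test_that("CoIED maps flag order preservation correctly", {
  m1 <- build_coied_map(point_mass_sets(c(0, 25, 50, 75, 100)), scale5)
  expect_equal(unname(m1$per_level), c(0, 25, 50, 75, 100))
  expect_true(m1$order_preserving)

  m2 <- build_coied_map(point_mass_sets(c(0, 60, 30, 75, 100)), scale5)
  expect_false(m2$order_preserving)

  same <- fuzzify_from_points(c(30, 40), "x")
  m3 <- build_coied_map(stats::setNames(rep(list(same), 5), unclass(scale5)), scale5)
  expect_true(m3$order_preserving)
  expect_true(all(m3$per_level == m3$per_level[1]))

  expect_error(build_coied_map(point_mass_sets(c(0, 25, 50, 75, 100))[1:4], scale5),
               "Extreme")
})

test_that("weighted sampling is reproducible, support-respecting, and frequency-calibrated", {
  pm <- list(Mild = fuzzify_from_points(30, "Mild"))
  col <- rep("Mild", 20)
  expect_equal(weighted_sampling_encode(col, pm, seed = 1), rep(30, 20))
  expect_equal(weighted_sampling_encode(col, pm, seed = 1, mode = "per_label"),
               rep(30, 20))

  two <- list(Mild = fuzzy_set(0:100, as.numeric(0:100 %in% c(5, 7)), "Mild"))
  draws <- weighted_sampling_encode(rep("Mild", 10000), two, seed = 99)
  expect_true(all(draws %in% c(5, 7)))
  # binomial oracle: p = 0.5, 3 sigma over 10,000 draws
  expect_lt(abs(mean(draws == 5) - 0.5), 0.015)

  expect_identical(weighted_sampling_encode(rep("Mild", 50), two, seed = 7),
                   weighted_sampling_encode(rep("Mild", 50), two, seed = 7))
  per_label <- weighted_sampling_encode(rep("Mild", 50), two, seed = 7,
                                        mode = "per_label")
  expect_equal(length(unique(per_label)), 1)
  expect_error(weighted_sampling_encode("Severe", two, seed = 1), "Severe")
})

test_that("weighted sampling can reverse ordered labels within a row when supports overlap", {
  sets <- list(
    Mild = fuzzy_set(0:100, as.numeric(0:100 %in% 40:60), "Mild"),
    Moderate = fuzzy_set(0:100, as.numeric(0:100 %in% 45:55), "Moderate"))
  # CoIEDs are ordered, yet this seed draws a reversed pair for one row
  expect_lt(coied(sets$Mild) - 1e-9, coied(sets$Moderate))
  x <- weighted_sampling_encode(c("Mild", "Moderate"), sets, seed = 4)
  expect_gt(x[1], x[2])
})

test_that("membership encoding degenerates to one-hot on disjoint supports", {
  set.seed(13)
  for (i in 1:6) {
    cuts <- sort(sample(5:95, 4))
    bounds <- cbind(c(0, cuts), c(cuts - 1, 100))
    sets <- stats::setNames(lapply(1:5, function(j) {
      pts <- sample(bounds[j, 1]:bounds[j, 2], 3, replace = TRUE)
      fuzzify_from_points(pts, unclass(scale5)[j])
    }), unclass(scale5))
    for (j in 1:5) {
      v <- unclass(scale5)[j]
      enc <- membership_encode(v, sets, scale5)
      onehot <- as.numeric(seq_len(5) == j)
      expect_equal(unname(enc), onehot)
    }
  }
})

test_that("membership encoding reads cross-memberships at the modal point", {
  two <- ordinal_scale(c("lo", "hi"))
  sets <- list(
    lo = fuzzy_set(0:100, as.numeric(0:100 == 20), "lo"),
    hi = fuzzy_set(0:100, 0.4 * (0:100 == 20) + 1.0 * (0:100 == 60), "hi"))
  expect_equal(unname(membership_encode("lo", sets, two)), c(1, 0.4))
  expect_equal(unname(membership_encode("hi", sets, two)), c(0, 1))

  one <- ordinal_scale("only")
  s1 <- list(only = fuzzify_from_points(c(10, 20), "only"))
  expect_equal(unname(membership_encode("only", s1, one)), 1)

  # argmax tie-break: smallest grid value wins
  tie <- list(only = fuzzy_set(0:100, as.numeric(0:100 %in% c(30, 70)), "only"))
  m <- build_membership_map(tie, one)
  expect_equal(unname(m$per_level["only", "only"]), 1)
})

test_that("classical baselines follow their definitions", {
  expect_equal(baseline_encode("Mild", scale5, "ordinal_rank"), 1)
  expect_equal(baseline_encode(unclass(scale5), scale5, "ordinal_rank"), 0:4)
  expect_equal(unname(baseline_encode("Mild", scale5, "one_hot")[1, ]),
               c(0, 1, 0, 0, 0))
  expect_equal(unname(baseline_encode("Moderate", scale5, "rank_hot")[1, ]),
               c(1, 1, 1, 0, 0))
  expect_error(baseline_encode("Bogus", scale5), "Bogus")

  # monotone staircase: consecutive rank-hot vectors differ in exactly one slot
  rh <- baseline_encode(unclass(scale5), scale5, "rank_hot")
  for (i in 1:4) expect_equal(sum(rh[i + 1, ] != rh[i, ]), 1)
})

test_that("encoding maps survive a JSON round-trip", {
  sets <- point_mass_sets(c(5, 20, 50, 75, 95))
  cm <- build_coied_map(sets, scale5)
  p1 <- tempfile(fileext = ".json")
  write_encoding_map(cm, p1)
  back <- read_encoding_map(p1)
  expect_equal(back$kind, "coied")
  expect_equal(back$per_level, cm$per_level)
  expect_equal(back$order_preserving, TRUE)

  mm <- build_membership_map(sets, scale5)
  p2 <- tempfile(fileext = ".json")
  write_encoding_map(mm, p2)
  back2 <- read_encoding_map(p2)
  expect_equal(back2$per_level, mm$per_level)
})
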