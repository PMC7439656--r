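# Shared fixtures: tiny CSV writers and reference interval data built in code.

scale5 <- severity_scale()

# One clinician row of the published dataset extract: five intervals in
# scale order (Absent .. Extreme).
tab1_row1 <- data.frame(
  respondent_id = "r1", stratum = "doctor",
  level = unclass(scale5),
  lower = c(3, 23, 39, 56, 83),
  upper = c(20, 40, 55, 76, 100),
  representative_point = NA_real_,
  stringsAsFactors = FALSE
)

write_interval_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "respondent_id,stratum,level,lower,upper,representative_point"
  writeLines(c(header, rows), path)
  path
}

write_qualitative_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("respondent_id,value,chosen_level", rows), path)
  path
}

# Random valid interval-response table for property tests.
random_intervals <- function(n, level = "Mild", stratum = "doctor") {
  lo <- sample(0:100, n, replace = TRUE)
  hi <- pmin(100, lo + sample(0:30, n, replace = TRUE))
  data.frame(respondent_id = paste0("r", seq_len(n)), stratum = stratum,
             level = level, lower = lo, upper = hi,
             representative_point = NA_real_, stringsAsFactors = FALSE)
}

# Brute-force per-cell oracle for the whole-interval fuzzification route.
oracle_whole_intervals <- function(responses) {
  w <- numeric(101)
  for (x in 0:100) {
    for (i in seq_len(nrow(responses))) {
      if (responses$lower[i] <= x && x <= responses$upper[i]) {
        w[x + 1] <- w[x + 1] + 1 / (responses$upper[i] - responses$lower[i] + 1)
      }
    }
  }
  w
}

# Brute-force two-sample oracles.
oracle_ks_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}
oracle_mw_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Point-mass fuzzy sets at given positions, one per scale level.
point_mass_sets <- function(positions, scale = scale5) {
  stats::setNames(
    lapply(seq_along(positions),
           function(i) fuzzify_from_points(positions[i], unclass(scale)[i])),
    unclass(scale))
}

# Matched zero-noise survey -> CoIED map at the given level centers.
matched_coied_map <- function(centers, scale = scale5, half_width = 6,
                              n = 11, seed = 3) {
  prof <- stratum_profile("doctor", stats::setNames(centers, unclass(scale)),
                          center_sd = 0, half_width_mean = half_width,
                          half_width_sd = 0, rp_jitter_sd = 0, scale = scale)
  sets <- build_fuzzy_sets(gen_interval_survey(prof, n, seed = seed),
                           scale, route = "interval_centers")
  build_coied_map(sets, scale)
}
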