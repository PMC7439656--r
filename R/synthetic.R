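#' @title Seeded synthetic generators for surveys and outcome data
#' @description Emulators for the three data sources the pipeline consumes:
#'   two-strata interval/representative-point elicitation surveys, the
#'   qualitative inverse-mapping survey, and a PROM-style regression dataset
#'   whose ordinal features discretize a latent severity continuum through
#'   (possibly non-uniform) cutpoints. All generators are pure functions of
#'   their seed. They emulate the structure of real elicitation data, not
#'   any particular deposited dataset.
#' @name synthetic
NULL

#' Stratum response profile for survey generation
#'
#' Describes how one stratum of respondents perceives the scale levels:
#' per-level location centers on the 0--100 continuum (monotone in scale
#' order), between-respondent center spread, interval half-width
#' distribution, and representative-point jitter.
#'
#' @param stratum stratum label (e.g. `"doctor"`).
#' @param level_centers named numeric vector, one center in \[0,100\] per
#'   scale level, non-decreasing in scale order.
#' @param center_sd between-respondent SD of the interval center (>= 0).
#' @param half_width_mean,half_width_sd half-width is `|Normal(mean, sd)|`.
#' @param rp_jitter_sd SD of the representative point around the center.
#' @param scale an `ordinal_scale` the centers refer to.
#' @return A `stratum_profile` object.
#' @export
stratum_profile <- function(stratum, level_centers, center_sd = 5,
                            half_width_mean = 8, half_width_sd = 3,
                            rp_jitter_sd = 4, scale = severity_scale()) {
  lv <- unclass(scale)
  if (!all(lv %in% names(level_centers)))
    stop("level_centers must name every scale level")
  centers <- level_centers[lv]
  if (any(centers < 0 | centers > 100)) stop("level centers must lie in [0, 100]")
  if (is.unsorted(centers)) stop("level centers must be non-decreasing in scale order")
  if (center_sd < 0 || half_width_mean <= 0 || half_width_sd < 0 || rp_jitter_sd < 0)
    stop("invalid profile dispersion parameters")
  structure(list(stratum = stratum, level_centers = centers,
                 center_sd = center_sd, half_width_mean = half_width_mean,
                 half_width_sd = half_width_sd, rp_jitter_sd = rp_jitter_sd,
                 scale = scale), class = "stratum_profile")
}

#' Default doctor/patient profiles
#'
#' Ships the package's reference survey-generator configuration, read from
#' `inst/extdata/default_profiles.yaml`. Level centers are inspired by the
#' stratum-specific centroid locations reported for clinicians and
#' laypeople on the HL7 severity scale (doctors place Absent lower and
#' Extreme higher than laypeople); they are an emulation, not estimates.
#'
#' @return Named list with `doctor` and `patient` `stratum_profile`s.
#' @export
default_profiles <- function() {
  path <- system.file("extdata", "default_profiles.yaml", package = "ordifuzz")
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg$profiles), function(s) {
    p <- cfg$profiles[[s]]
    stratum_profile(s, unlist(p$level_centers), p$center_sd,
                    p$half_width_mean, p$half_width_sd, p$rp_jitter_sd)
  })
  names(out) <- names(cfg$profiles)
  out
}

#' Generate a two-page interval-elicitation survey for one stratum
#'
#' Per respondent and level: the interval center is
#' `Normal(level_center, center_sd)`, the half-width `|Normal(hw_mean,
#' hw_sd)|`; the interval is the center +/- half-width clipped to \[0,100\]
#' and rounded to the integer grid (clipping preserves lower <= upper; ties
#' give degenerate point intervals, which do occur in real elicitations).
#' The representative point is the center plus `Normal(0, rp_jitter_sd)`,
#' clipped and rounded.
#'
#' @param profile a `stratum_profile`.
#' @param n_respondents number of respondents (>= 1).
#' @param seed integer seed; output is a pure function of it.
#' @return data.frame in the interval-response dialect (one row per
#'   respondent x level).
#' @export
gen_interval_survey <- function(profile, n_respondents, seed) {
  stopifnot(inherits(profile, "stratum_profile"), n_respondents >= 1)
  lv <- unclass(profile$scale)
  with_preserved_seed(seed, {
    rows <- vector("list", n_respondents)
    for (i in seq_len(n_respondents)) {
      centers <- stats::rnorm(length(lv), profile$level_centers, profile$center_sd)
      hw <- abs(stats::rnorm(length(lv), profile$half_width_mean, profile$half_width_sd))
      lower <- round_half_up(clip01_100(centers - hw))
      upper <- round_half_up(clip01_100(centers + hw))
      rp <- round_half_up(clip01_100(centers + stats::rnorm(length(lv), 0, profile$rp_jitter_sd)))
      rows[[i]] <- data.frame(
        respondent_id = sprintf("%s%04d", substr(profile$stratum, 1, 1), i),
        stratum = profile$stratum, level = lv,
        lower = lower, upper = upper, representative_point = rp,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a qualitative inverse-mapping survey
#'
#' Each simulated respondent receives a value drawn uniformly from 1--99
#' and names the severity label whose perceived center is closest, with
#' Gaussian perception noise: label probabilities are proportional to
#' `exp(-(value - center)^2 / (2 center_sd^2))`. As `center_sd` shrinks the
#' choice becomes the nearest-center label. Respondents are assigned
#' uniformly to the supplied stratum profiles.
#'
#' @param profiles named list of `stratum_profile`s.
#' @param n number of responses.
#' @param seed integer seed.
#' @return data.frame in the qualitative-response dialect.
#' @export
gen_qualitative_survey <- function(profiles, n, seed) {
  stopifnot(length(profiles) >= 1, n >= 1)
  with_preserved_seed(seed, {
    strata <- sample(names(profiles), n, replace = TRUE)
    value <- sample.int(99L, n, replace = TRUE)
    chosen <- character(n)
    for (i in seq_len(n)) {
      p <- profiles[[strata[i]]]
      lv <- unclass(p$scale)
      d2 <- (value[i] - p$level_centers)^2
      if (p$center_sd <= 0) {
        chosen[i] <- lv[which.min(d2)]
      } else {
        logw <- -d2 / (2 * p$center_sd^2)
        w <- exp(logw - max(logw))
        chosen[i] <- sample(lv, 1L, prob = w)
      }
    }
    data.frame(respondent_id = sprintf("q%05d", seq_len(n)), value = value,
               chosen_level = chosen, sex = NA_character_,
               age_range = NA_character_, stringsAsFactors = FALSE)
  })
}

#' Specification of the latent-severity outcome dataset
#'
#' The generated table mimics a 15-feature prognostic PROM dataset:
#' 3 demographic features (gender, age, intervention type), `n_continuous`
#' continuous scores, and `n_ordinal` ordinal items. Each ordinal item has
#' a latent severity `z ~ Normal(latent_mean, latent_sd)` clipped to
#' \[0,100\]; the recorded label is the cutpoint interval containing `z`.
#' The continuous target is a linear function of the latent severities (not
#' their ranks) plus the continuous and demographic features and Gaussian
#' noise, so an equally-spaced rank encoding is misspecified exactly when
#' the cutpoints are non-uniform.
#'
#' @param n_rows number of patients (default 336).
#' @param cutpoints strictly increasing interior cutpoints on (0, 100)
#'   shared by all ordinal features, or a named list with one vector per
#'   ordinal feature. The default 5/15/30/80 is strongly non-uniform (a
#'   wide Severe band, as in PROM items administered to surgical
#'   candidates), so the per-level conditional means of the latent
#'   severity are far from affine in the level rank.
#' @param latent_means per-ordinal-feature latent mean; default 50 for
#'   all items (the items share the severity-scale semantics the
#'   elicitation survey measures).
#' @param latent_sd SD of the latent severities (default 20).
#' @param n_continuous,n_ordinal feature counts (defaults 3 and 9, giving
#'   15 features with the demographics).
#' @param beta_ordinal,beta_continuous linear coefficients of the latent
#'   severities and the continuous scores.
#' @param noise_sd SD of the target noise.
#' @param scale an `ordinal_scale` with one more level than there are
#'   cutpoints.
#' @return A `latent_outcome_spec` object.
#' @export
latent_outcome_spec <- function(n_rows = 336L,
                                cutpoints = c(5, 15, 30, 80),
                                latent_means = NULL,
                                latent_sd = 20,
                                n_continuous = 3L, n_ordinal = 9L,
                                beta_ordinal = 0.05, beta_continuous = 0.05,
                                noise_sd = 1.0,
                                scale = severity_scale()) {
  if (is.null(latent_means)) latent_means <- rep(50, n_ordinal)
  ord_names <- sprintf("ord%02d", seq_len(n_ordinal))
  if (!is.list(cutpoints)) {
    cutpoints <- stats::setNames(rep(list(cutpoints), n_ordinal), ord_names)
  }
  if (!all(ord_names %in% names(cutpoints)))
    stop("cutpoints must cover every ordinal feature")
  for (nm in ord_names) {
    cp <- cutpoints[[nm]]
    if (is.unsorted(cp, strictly = TRUE) || length(cp) != length(scale) - 1L)
      stop("cutpoints for ", nm, " must be strictly increasing with one fewer ",
           "entry than the scale has levels")
  }
  structure(list(n_rows = as.integer(n_rows), cutpoints = cutpoints,
                 latent_means = stats::setNames(latent_means, ord_names),
                 latent_sd = latent_sd, n_continuous = as.integer(n_continuous),
                 n_ordinal = as.integer(n_ordinal),
                 beta_ordinal = rep_len(beta_ordinal, n_ordinal),
                 beta_continuous = rep_len(beta_continuous, n_continuous),
                 noise_sd = noise_sd, scale = scale),
            class = "latent_outcome_spec")
}

#' Generate the latent-severity outcome dataset
#'
#' @param spec a `latent_outcome_spec`.
#' @param seed integer seed.
#' @param keep_latent if `TRUE`, the latent severities are attached as an
#'   attribute `"latent"` (useful for noiseless-recovery checks); they are
#'   never part of the feature table itself.
#' @return A `feature_table` (see [feature_table()]) with 15 declared
#'   features and a continuous target.
#' @export
gen_outcome_dataset <- function(spec, seed, keep_latent = FALSE) {
  stopifnot(inherits(spec, "latent_outcome_spec"))
  n <- spec$n_rows
  lv <- unclass(spec$scale)
  ord_names <- names(spec$latent_means)
  with_preserved_seed(seed, {
    gender <- sample(c("F", "M"), n, replace = TRUE)
    age <- round(stats::runif(n, 40, 85), 1)
    intervention <- sample(c("hip", "knee", "spine"), n, replace = TRUE)
    cont <- matrix(stats::rnorm(n * spec$n_continuous, 50, 10), nrow = n)
    colnames(cont) <- sprintf("score%d", seq_len(spec$n_continuous))
    z <- matrix(0, nrow = n, ncol = spec$n_ordinal, dimnames = list(NULL, ord_names))
    labels <- matrix("", nrow = n, ncol = spec$n_ordinal, dimnames = list(NULL, ord_names))
    for (j in seq_len(spec$n_ordinal)) {
      zj <- clip01_100(stats::rnorm(n, spec$latent_means[j], spec$latent_sd))
      z[, j] <- zj
      labels[, j] <- lv[findInterval(zj, spec$cutpoints[[ord_names[j]]]) + 1L]
    }
    target <- as.numeric(z %*% spec$beta_ordinal) +
      as.numeric(cont %*% spec$beta_continuous) +
      0.5 * (gender == "M") - 0.02 * age +
      c(hip = 0, knee = 0.4, spine = -0.3)[intervention] +
      stats::rnorm(n, 0, spec$noise_sd)
    dat <- data.frame(gender = gender, age = age, intervention = intervention,
                      cont, labels, stringsAsFactors = FALSE, check.names = FALSE)
    roles <- c(gender = "categorical", age = "continuous",
               intervention = "categorical",
               stats::setNames(rep("continuous", spec$n_continuous), colnames(cont)),
               stats::setNames(rep("ordinal", spec$n_ordinal), ord_names))
    ft <- feature_table(dat, roles, unname(target), spec$scale)
    if (keep_latent) attr(ft, "latent") <- z
    ft
  })
}

#' Write a feature table to CSV (target as final column)
#'
#' @param ft a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- ft$data
  df$target <- ft$target
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
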