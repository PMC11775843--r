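#' Specification of one planted endotype
#'
#' Describes the multivariate Gaussian from which a synthetic endotype's
#' clustering variables (SVI, HR, SVRI, SVV) are drawn, together with its
#' mixing weight and a marginal Normal for dP/dt (carried through summaries
#' but never clustered on).
#'
#' @param name Endotype name.
#' @param weight Mixing proportion in \[0, 1\].
#' @param mean Length-4 vector of means, original units, order
#'   (svi, hr, svri, svv).
#' @param sd Length-4 vector of standard deviations (positive).
#' @param correlation 4x4 correlation matrix (default identity: published
#'   endotype tables report only marginal mean/sd, so no cross-correlations
#'   are assumed).
#' @param dpdt_mean,dpdt_sd Marginal Normal parameters for dP/dt, mmHg/s.
#' @return An object of class `endotype_spec`.
#' @export
endotype_spec <- function(name, weight, mean, sd, correlation = diag(4),
                          dpdt_mean = 600, dpdt_sd = 250) {
  stopifnot(is.character(name), length(name) == 1)
  check_scalar(weight, "weight")
  if (weight < 0 || weight > 1) stop("`weight` must lie in [0, 1]",
                                     call. = FALSE)
  if (length(mean) != 4 || length(sd) != 4)
    stop("`mean` and `sd` must have length 4 (svi, hr, svri, svv)",
         call. = FALSE)
  if (any(sd <= 0)) stop("all standard deviations must be positive",
                         call. = FALSE)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)))
    stop("`correlation` must be symmetric", call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("`correlation` must be positive-definite",
                         call. = FALSE)
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  names(mean) <- names(sd) <- CLUSTER_VARS
  structure(list(name = name, weight = weight, mean = mean, sd = sd,
                 correlation = correlation,
                 dpdt_mean = dpdt_mean, dpdt_sd = dpdt_sd),
            class = "endotype_spec")
}

#' Published endotype parameters for the three cohorts
#'
#' Mixing weights, per-variable means and standard deviations of the four
#' hypotension endotypes (vasodilation, hypovolaemia, myocardial depression,
#' bradycardia) as reported for the development cohort of surgical patients
#' and the two validation cohorts (surgical and critically ill). These are
#' the default parameters of the synthetic cohort generator.
#'
#' @param dataset Which cohort's parameters to use.
#' @return A named list of four [endotype_spec()] objects whose weights sum
#'   to 1.
#' @export
#' @examples
#' sapply(published_endotype_specs(), function(s) s$weight)
published_endotype_specs <- function(dataset = c("development", "validation_surgical",
                                     "validation_critical")) {
  dataset <- match.arg(dataset)
  p <- switch(dataset,
    development = list(
      vasodilation          = list(0.349, c(47, 82, 1253,  7), c(13, 15, 296, 3), 682, 258),
      hypovolaemia          = list(0.321, c(34, 87, 1610, 16), c( 8, 16, 342, 6), 629, 275),
      myocardial_depression = list(0.224, c(35, 64, 2268, 16), c( 9,  7, 957, 6), 534, 227),
      bradycardia           = list(0.106, c(42, 52, 2255,  9), c( 9,  5, 579, 3), 590, 203)),
    validation_surgical = list(
      vasodilation          = list(0.292, c(47, 92, 1130,  8), c(12, 14, 351, 3), 731, 263),
      hypovolaemia          = list(0.307, c(35, 86, 1591, 16), c(10, 15, 442, 7), 627, 270),
      myocardial_depression = list(0.211, c(34, 65, 2289, 16), c(10,  8, 908, 7), 591, 236),
      bradycardia           = list(0.190, c(53, 57, 1705,  8), c(16, 10, 628, 3), 666, 258)),
    validation_critical = list(
      vasodilation          = list(0.396, c(40, 94, 1312,  8), c(14, 18, 360, 3), 768, 347),
      hypovolaemia          = list(0.478, c(31, 93, 1648, 17), c( 8, 14, 394, 6), 582, 277),
      myocardial_depression = list(0.105, c(32, 68, 2518, 18), c(12, 11, 1402, 8), 658, 339),
      bradycardia           = list(0.021, c(41, 53, 2223,  9), c( 9,  6, 589, 4), 985, 546))
  )
  specs <- lapply(names(p), function(nm) {
    s <- p[[nm]]
    endotype_spec(nm, s[[1]], s[[2]], s[[3]], dpdt_mean = s[[4]],
                  dpdt_sd = s[[5]])
  })
  names(specs) <- names(p)
  specs
}

#' Draw clustering-variable points from an endotype specification
#'
#' Samples from the endotype's multivariate Gaussian. No truncation is
#' applied, so sample moments are unbiased estimates of the specification
#' (negative values are possible in far tails, e.g. for SVV).
#'
#' @param spec An [endotype_spec()].
#' @param n Number of points (>= 1).
#' @param seed Optional seed; when given, draws are reproducible and the
#'   caller's RNG state is untouched.
#' @return An n x 4 matrix with columns `svi`, `hr`, `svri`, `svv`.
#' @export
sample_endotype_points <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "endotype_spec"))
  check_scalar(n, "n", positive = TRUE)
  sigma <- diag(spec$sd) %*% spec$correlation %*% diag(spec$sd)
  draw <- function() {
    x <- MASS::mvrnorm(n, mu = spec$mean, Sigma = sigma)
    x <- matrix(x, ncol = 4)
    colnames(x) <- CLUSTER_VARS
    x
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the structure the endotyping analysis assumes:
#' per-patient MAP trajectories on a 20-second grid consisting of
#' normotensive baseline segments (MAP at or above 72 mmHg), pre-episode
#' descents (MAP uniform on \[65, 71\]) and hypotensive plateaus of at least
#' three consecutive points (MAP uniform on \[55, 64\]). Each episode is
#' assigned one latent endotype drawn from the mixing weights, and the
#' haemodynamic variables of its episode and pre-episode points are drawn
#' from that endotype's Gaussian.
#'
#' Two modes: in `"direct"` mode all four clustering variables, SVRI
#' included, are drawn from the endotype Gaussian without truncation, so
#' sample moments match the specification exactly in expectation (used for
#' parameter-recovery studies). In `"consistent"` mode SVI, HR and SVV are
#' drawn (negative draws rejected and redrawn) and SVRI is derived from MAP
#' and CI via the physiological identity, giving an internally consistent
#' cohort.
#'
#' @param n_patients Number of patients (>= 1).
#' @param points_per_patient Points per patient series.
#' @param mode `"direct"` or `"consistent"`.
#' @param specs Named list of [endotype_spec()]; weights must sum to 1.
#' @param baseline_spec Spec for normotensive baseline points (weight unused).
#' @param baseline_map_range MAP range for baseline segments, mmHg.
#' @param episode_map_range MAP range inside episodes; must lie entirely
#'   below the hypotension threshold.
#' @param preceding_map_range MAP range of pre-episode points.
#' @param baseline_len_range Baseline segment length range, points.
#' @param preceding_len_range Pre-episode window length range, points.
#' @param episode_len_min Minimum episode length, points (>= 3).
#' @param episode_len_mean Mean episode length, points (geometric tail above
#'   the minimum).
#' @param derivation A [derivation_config()] used in consistent mode.
#' @param seed Integer seed; a fixed seed makes the generated cohort
#'   byte-identical across runs.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          points_per_patient = 400,
                          mode = c("consistent", "direct"),
                          specs = published_endotype_specs("development"),
                          baseline_spec = endotype_spec(
                            "baseline", 1, c(45, 75, 2100, 8),
                            c(8, 10, 300, 2), dpdt_mean = 700, dpdt_sd = 250),
                          baseline_map_range = c(75, 90),
                          episode_map_range = c(55, 64),
                          preceding_map_range = c(65, 71),
                          baseline_len_range = c(4, 10),
                          preceding_len_range = c(0, 6),
                          episode_len_min = 3,
                          episode_len_mean = 5.5,
                          derivation = derivation_config(),
                          seed = 1) {
  mode <- match.arg(mode)
  check_scalar(n_patients, "n_patients", positive = TRUE)
  check_scalar(points_per_patient, "points_per_patient", positive = TRUE)
  w <- vapply(specs, function(s) s$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9)
    stop("endotype weights must sum to 1", call. = FALSE)
  if (max(episode_map_range) >= 65)
    stop("`episode_map_range` must lie entirely below 65 mmHg; ",
         "such a configuration cannot produce a hypotensive episode",
         call. = FALSE)
  if (episode_len_min < 3)
    stop("`episode_len_min` must be >= 3 points (one minute on a 20-s grid)",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 points_per_patient = as.integer(points_per_patient),
                 mode = mode, specs = specs, baseline_spec = baseline_spec,
                 baseline_map_range = baseline_map_range,
                 episode_map_range = episode_map_range,
                 preceding_map_range = preceding_map_range,
                 baseline_len_range = baseline_len_range,
                 preceding_len_range = preceding_len_range,
                 episode_len_min = episode_len_min,
                 episode_len_mean = episode_len_mean,
                 derivation = derivation, seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw n rows of clustering variables from `spec` under the given mode.
# In consistent mode negative draws are rejected and redrawn so the derived
# physiology stays positive; in direct mode draws are kept untruncated.
draw_haemo <- function(spec, n, mode) {
  x <- sample_endotype_points(spec, n)
  if (mode == "consistent") {
    bad <- which(x[, "svi"] <= 0 | x[, "hr"] <= 0 | x[, "svv"] <= 0)
    guard <- 0
    while (length(bad) && guard < 1000) {
      x[bad, ] <- sample_endotype_points(spec, length(bad))
      bad <- which(x[, "svi"] <= 0 | x[, "hr"] <= 0 | x[, "svv"] <= 0)
      guard <- guard + 1
    }
  }
  x
}

#' Generate a synthetic cohort with planted hypotension endotypes
#'
#' See [cohort_config()] for the generative model. Ground-truth per-point
#' endotype labels and the constructed episode intervals are returned
#' alongside the haemodynamic data, enabling parameter-recovery and
#' detector-validation studies.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with
#'   * `data`: cohort data frame (`patient_id`, `time_s`, `map`, `svi`,
#'     `hr`, `svv`, `dpdt`, `quality_ok`, `ci`, `svri`);
#'   * `truth`: `patient_id`, `time_s`, `true_endotype` (NA outside
#'     episodes), `in_episode`, `is_preceding`;
#'   * `episodes`: constructed intervals (`patient_id`, `start`, `end`,
#'     `pre_start`, 1-based within-patient indices, `end` inclusive).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  specs <- config$specs
  weights <- vapply(specs, function(s) s$weight, numeric(1))
  spec_names <- names(specs)
  geo_p <- 1 / (config$episode_len_mean - config$episode_len_min + 1)
  data_rows <- vector("list", config$n_patients)
  truth_rows <- vector("list", config$n_patients)
  episode_rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", p)
    total <- config$points_per_patient
    seg_type <- character(); seg_len <- integer(); seg_endo <- character()
    used <- 0L
    add <- function(type, len, endo = NA_character_) {
      seg_type <<- c(seg_type, type)
      seg_len <<- c(seg_len, as.integer(len))
      seg_endo <<- c(seg_endo, endo)
      used <<- used + as.integer(len)
    }
    # opening baseline so every series starts normotensive
    add("baseline", min(sample(config$baseline_len_range[1]:
                                 config$baseline_len_range[2], 1), total))
    while (used < total) {
      remaining <- total - used
      if (remaining < config$episode_len_min) {
        add("baseline", remaining)
        break
      }
      pre_len <- sample(config$preceding_len_range[1]:
                          config$preceding_len_range[2], 1)
      epi_len <- min(config$episode_len_min + stats::rgeom(1, geo_p), 30L)
      if (pre_len + epi_len > remaining) {
        pre_len <- min(pre_len, max(0L, remaining - config$episode_len_min))
        epi_len <- remaining - pre_len
      }
      endo <- sample(spec_names, 1, prob = weights)
      if (pre_len > 0) add("preceding", pre_len, endo)
      add("hypotensive", epi_len, endo)
      remaining <- total - used
      if (remaining > 0)
        add("baseline", min(sample(config$baseline_len_range[1]:
                                     config$baseline_len_range[2], 1),
                            remaining))
    }
    n <- sum(seg_len)
    map <- numeric(n); svi <- numeric(n); hr <- numeric(n)
    svv <- numeric(n); svri <- numeric(n); dpdt <- numeric(n)
    true_endo <- rep(NA_character_, n)
    in_episode <- integer(n); is_preceding <- integer(n)
    pos <- 0L
    i <- 1
    while (i <= length(seg_len)) {
      len <- seg_len[i]
      if (len == 0L) { i <- i + 1; next }
      idx <- pos + seq_len(len)
      type <- seg_type[i]
      spec <- if (type == "baseline") config$baseline_spec
              else specs[[seg_endo[i]]]
      h <- draw_haemo(spec, len, config$mode)
      map[idx] <- switch(type,
        baseline = stats::runif(len, config$baseline_map_range[1],
                                config$baseline_map_range[2]),
        preceding = stats::runif(len, config$preceding_map_range[1],
                                 config$preceding_map_range[2]),
        hypotensive = stats::runif(len, config$episode_map_range[1],
                                   config$episode_map_range[2]))
      svi[idx] <- h[, "svi"]; hr[idx] <- h[, "hr"]; svv[idx] <- h[, "svv"]
      svri[idx] <- h[, "svri"]
      dpdt[idx] <- stats::rnorm(len, spec$dpdt_mean, spec$dpdt_sd)
      if (type != "baseline") true_endo[idx] <- seg_endo[i]
      if (type == "hypotensive") {
        in_episode[idx] <- 1L
        pre_n <- if (i > 1 && seg_type[i - 1] == "preceding")
          seg_len[i - 1] else 0L
        episode_rows[[length(episode_rows) + 1]] <-
          data.frame(patient_id = pid, start = idx[1], end = idx[len],
                     pre_start = idx[1] - pre_n, stringsAsFactors = FALSE)
      }
      if (type == "preceding") is_preceding[idx] <- 1L
      pos <- pos + len
      i <- i + 1
    }
    ci <- compute_ci(pmax(svi, 1e-6), pmax(hr, 1e-6))
    if (config$mode == "consistent")
      svri <- compute_svri(map, ci, config$derivation)
    data_rows[[p]] <- data.frame(
      patient_id = pid, time_s = (seq_len(n) - 1) * 20,
      map = map, svi = svi, hr = hr, svv = svv, dpdt = dpdt,
      quality_ok = 1L, ci = ci, svri = svri, stringsAsFactors = FALSE)
    truth_rows[[p]] <- data.frame(
      patient_id = pid, time_s = (seq_len(n) - 1) * 20,
      true_endotype = true_endo, in_episode = in_episode,
      is_preceding = is_preceding, stringsAsFactors = FALSE)
  }
  out <- list(data = do.call(rbind, data_rows),
              truth = do.call(rbind, truth_rows),
              episodes = do.call(rbind, episode_rows))
  rownames(out$data) <- rownames(out$truth) <- NULL
  if (!is.null(out$episodes)) rownames(out$episodes) <- NULL
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic haemodynamic cohort\n")
  cat("  patients:       ", length(unique(x$data$patient_id)), "\n")
  cat("  data points:    ", nrow(x$data), "\n")
  cat("  episodes:       ", if (is.null(x$episodes)) 0 else nrow(x$episodes),
      "\n")
  cat("  episode points: ", sum(x$truth$in_episode), "\n")
  cat("  preceding points:", sum(x$truth$is_preceding), "\n")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes the cohort data in the standard cohort CSV schema plus a
#' ground-truth CSV (`patient_id`, `time_s`, `true_endotype`, `in_episode`,
#' `is_preceding`). Direct-mode cohorts also carry their drawn SVRI column so
#' the round trip preserves it.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Cohort CSV path.
#' @param truth_path Optional ground-truth CSV path.
#' @param mode The generation mode the cohort was produced with; direct-mode
#'   cohorts write their SVRI column.
#' @return `path`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, path, truth_path = NULL,
                                   mode = c("consistent", "direct")) {
  mode <- match.arg(mode)
  write_cohort_csv(cohort$data, path, keep_svri = (mode == "direct"))
  if (!is.null(truth_path))
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
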