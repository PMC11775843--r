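#' Derivation settings for computed haemodynamic variables
#'
#' Systemic vascular resistance index is derived from mean arterial pressure
#' and cardiac index under an assumed central venous pressure, because a
#' measured central venous pressure is usually unavailable from an arterial
#' line alone. The conventional assumption is 5 mmHg.
#'
#' @param cvp_mmhg Assumed central venous pressure, mmHg (non-negative).
#' @return An object of class `derivation_config`.
#' @export
#' @examples
#' derivation_config()
derivation_config <- function(cvp_mmhg = 5) {
  check_scalar(cvp_mmhg, "cvp_mmhg")
  if (cvp_mmhg < 0) stop("`cvp_mmhg` must be >= 0", call. = FALSE)
  structure(list(cvp_mmhg = cvp_mmhg), class = "derivation_config")
}

#' Cardiac index from stroke volume index and heart rate
#'
#' CI (L min^-1 m^-2) = SVI (ml m^-2) * HR (beats min^-1) / 1000.
#'
#' @param svi Stroke volume index, ml m^-2 (positive).
#' @param hr Heart rate, beats min^-1 (positive).
#' @return Cardiac index, L min^-1 m^-2. Vectorized.
#' @export
#' @examples
#' compute_ci(47, 82)
compute_ci <- function(svi, hr) {
  if (!is.numeric(svi) || !is.numeric(hr))
    stop("`svi` and `hr` must be numeric", call. = FALSE)
  if (any(!is.finite(svi)) || any(!is.finite(hr)) ||
      any(svi <= 0) || any(hr <= 0))
    stop("`svi` and `hr` must be finite and positive", call. = FALSE)
  svi * hr / 1000
}

#' Systemic vascular resistance index from MAP and cardiac index
#'
#' SVRI (dyn s cm^-5 m^2) = 80 * (MAP - CVP) / CI, with the assumed central
#' venous pressure taken from `cfg`.
#'
#' @param map Mean arterial pressure, mmHg; must exceed the assumed CVP.
#' @param ci Cardiac index, L min^-1 m^-2 (positive).
#' @param cfg A [derivation_config()].
#' @return SVRI, dyn s cm^-5 m^2. Vectorized.
#' @export
#' @examples
#' compute_svri(65, 2.4)  # 2000
compute_svri <- function(map, ci, cfg = derivation_config()) {
  stopifnot(inherits(cfg, "derivation_config"))
  if (!is.numeric(map) || !is.numeric(ci))
    stop("`map` and `ci` must be numeric", call. = FALSE)
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop("`ci` must be finite and positive", call. = FALSE)
  if (any(!is.finite(map)) || any(map <= cfg$cvp_mmhg))
    stop("`map` must exceed the assumed central venous pressure", call. = FALSE)
  80 * (map - cfg$cvp_mmhg) / ci
}

# Coerce a points input (data frame or matrix) to an n x 4 numeric matrix
# with the canonical clustering columns svi, hr, svri, svv.
as_cluster_matrix <- function(x) {
  if (is.data.frame(x)) {
    missing <- setdiff(CLUSTER_VARS, names(x))
    if (length(missing))
      stop("missing clustering variable(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    x <- as.matrix(x[CLUSTER_VARS])
  } else {
    x <- as.matrix(x)
    if (ncol(x) != length(CLUSTER_VARS))
      stop("expected a 4-column matrix (svi, hr, svri, svv)", call. = FALSE)
    colnames(x) <- CLUSTER_VARS
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite values in clustering variables",
                               call. = FALSE)
  x
}

#' Fit a per-variable z-score normalizer
#'
#' Each clustering variable (SVI, HR, SVRI, SVV) is standardized to mean 0 and
#' standard deviation 1 so that no variable dominates the embedding through
#' its units. The sample standard deviation uses the n-1 denominator.
#' Normalization parameters are part of the persisted model: applying a
#' trained model to a new dataset reuses the development-set parameters.
#'
#' @param x Data frame or matrix holding columns `svi`, `hr`, `svri`, `svv`
#'   (at least two rows).
#' @return An object of class `normalization_params` with `mean` and `sd`
#'   vectors named by variable.
#' @export
fit_normalizer <- function(x) {
  m <- as_cluster_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 points to fit a normalizer",
                        call. = FALSE)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  if (any(sd <= 0 | !is.finite(sd))) {
    bad <- colnames(m)[sd <= 0 | !is.finite(sd)]
    stop("zero-variance variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sd), class = "normalization_params")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param x Points in original units (see [fit_normalizer()]).
#' @param params A `normalization_params` object.
#' @return An n x 4 matrix of z-scores.
#' @export
apply_normalizer <- function(x, params) {
  stopifnot(inherits(params, "normalization_params"))
  m <- as_cluster_matrix(x)
  sweep(sweep(m, 2, params$mean, "-"), 2, params$sd, "/")
}

#' @rdname apply_normalizer
#' @param z An n x 4 matrix of z-scores to map back to original units.
#' @export
invert_normalizer <- function(z, params) {
  stopifnot(inherits(params, "normalization_params"))
  z <- as.matrix(z)
  if (ncol(z) != length(CLUSTER_VARS))
    stop("expected a 4-column z-score matrix", call. = FALSE)
  out <- sweep(sweep(z, 2, params$sd, "*"), 2, params$mean, "+")
  colnames(out) <- CLUSTER_VARS
  out
}

#' @export
print.normalization_params <- function(x, ...) {
  cat("Per-variable normalization (z-score):\n")
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Read a cohort CSV of 20-second haemodynamic data points
#'
#' Expected columns: `patient_id`, `time_s`, `map_mmhg`, `svi_ml_m2`,
#' `hr_bpm`, `svv_pct`; optional `dpdt_mmhg_s` (may be empty) and
#' `quality_ok` (0/1, default 1). Cardiac index is always derived as
#' SVI*HR/1000. SVRI is derived from MAP and CI with the configured central
#' venous pressure unless the file carries an explicit `svri_dyn_s_cm5_m2`
#' column (written by the synthetic generator in direct mode, where SVRI is
#' drawn rather than derived).
#'
#' Points flagged `quality_ok = 0` (poor-quality arterial waveform signal)
#' are dropped before any analysis.
#'
#' @param path CSV file path.
#' @param cfg A [derivation_config()].
#' @param drop_poor_quality Drop rows with `quality_ok = 0` (default TRUE).
#' @return A data frame with columns `patient_id`, `time_s`, `map`, `svi`,
#'   `hr`, `svv`, `dpdt`, `quality_ok`, `ci`, `svri`, ordered by patient and
#'   time.
#' @export
read_cohort_csv <- function(path, cfg = derivation_config(),
                            drop_poor_quality = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_s", "map_mmhg", "svi_ml_m2", "hr_bpm",
            "svv_pct")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- data.frame(
    patient_id = as.character(raw$patient_id),
    time_s = as.numeric(raw$time_s),
    map = as.numeric(raw$map_mmhg),
    svi = as.numeric(raw$svi_ml_m2),
    hr = as.numeric(raw$hr_bpm),
    svv = as.numeric(raw$svv_pct),
    dpdt = if ("dpdt_mmhg_s" %in% names(raw)) as.numeric(raw$dpdt_mmhg_s)
           else NA_real_,
    quality_ok = if ("quality_ok" %in% names(raw)) as.integer(raw$quality_ok)
                 else 1L,
    stringsAsFactors = FALSE
  )
  has_svri <- "svri_dyn_s_cm5_m2" %in% names(raw)
  if (has_svri) df$svri_file <- as.numeric(raw$svri_dyn_s_cm5_m2)
  if (drop_poor_quality) df <- df[df$quality_ok == 1L, , drop = FALSE]
  df <- df[order(df$patient_id, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  df$ci <- compute_ci(df$svi, df$hr)
  df$svri <- if (has_svri) df$svri_file else compute_svri(df$map, df$ci, cfg)
  df$svri_file <- NULL
  df
}

#' Write a cohort data frame to the cohort CSV schema
#'
#' @param cohort A cohort data frame (columns as returned by
#'   [read_cohort_csv()] or [generate_cohort()]).
#' @param path Output CSV path.
#' @param keep_svri Also write the stored `svri` column (needed to round-trip
#'   direct-mode synthetic cohorts, where SVRI is drawn, not derived).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, keep_svri = FALSE) {
  out <- data.frame(
    patient_id = cohort$patient_id,
    time_s = cohort$time_s,
    map_mmhg = cohort$map,
    svi_ml_m2 = cohort$svi,
    hr_bpm = cohort$hr,
    svv_pct = cohort$svv,
    dpdt_mmhg_s = cohort$dpdt,
    quality_ok = cohort$quality_ok,
    stringsAsFactors = FALSE
  )
  if (keep_svri) out$svri_dyn_s_cm5_m2 <- cohort$svri
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
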