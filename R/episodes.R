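#' Hypotensive-episode detection settings
#'
#' Hypotension is defined as a mean arterial pressure below 65 mmHg sustained
#' for at least one minute; on a 20-second grid that is three or more
#' consecutive sub-65 points. Points with MAP in \[65, 72) that immediately
#' precede an episode form the pre-episode window, capturing the phase in
#' which pressure is decaying toward overt hypotension.
#'
#' Both thresholds are strict: a point with MAP exactly 65 is not
#' hypotensive, and a point with MAP exactly 72 does not belong to a
#' pre-episode window.
#'
#' @param hypo_threshold_mmhg Hypotension threshold (default 65 mmHg).
#' @param preceding_threshold_mmhg Pre-episode threshold (default 72 mmHg);
#'   must exceed the hypotension threshold.
#' @param min_duration_s Minimum sustained duration (default 60 s); must be a
#'   positive multiple of `grid_s`.
#' @param grid_s Sampling grid (default 20 s).
#' @return An object of class `episode_config`.
#' @export
episode_config <- function(hypo_threshold_mmhg = 65,
                           preceding_threshold_mmhg = 72,
                           min_duration_s = 60,
                           grid_s = 20) {
  check_scalar(hypo_threshold_mmhg, "hypo_threshold_mmhg", positive = TRUE)
  check_scalar(preceding_threshold_mmhg, "preceding_threshold_mmhg",
               positive = TRUE)
  check_scalar(min_duration_s, "min_duration_s", positive = TRUE)
  check_scalar(grid_s, "grid_s", positive = TRUE)
  if (preceding_threshold_mmhg <= hypo_threshold_mmhg)
    stop("`preceding_threshold_mmhg` must exceed `hypo_threshold_mmhg`",
         call. = FALSE)
  if (min_duration_s %% grid_s != 0)
    stop("`min_duration_s` must be a positive multiple of `grid_s`",
         call. = FALSE)
  structure(list(hypo_threshold_mmhg = hypo_threshold_mmhg,
                 preceding_threshold_mmhg = preceding_threshold_mmhg,
                 min_duration_s = min_duration_s,
                 grid_s = grid_s),
            class = "episode_config")
}

# Detect episodes within one patient's sorted series. Returns a data frame of
# 1-based row indices into that patient's rows: start, end (inclusive),
# pre_start (start of the contiguous preceding run; equals start when empty).
detect_episodes_one <- function(time_s, map, cfg) {
  n <- length(map)
  if (n == 0) return(NULL)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("timestamps must be strictly increasing within a patient",
         call. = FALSE)
  min_pts <- as.integer(round(cfg$min_duration_s / cfg$grid_s))
  hypo <- map < cfg$hypo_threshold_mmhg
  # runs of consecutive hypotensive points; a grid gap (missing time) breaks
  # a run just like a point at or above the threshold does
  if (n == 1) {
    run_id <- 1L
  } else {
    grid_break <- diff(time_s) != cfg$grid_s
    run_id <- cumsum(c(TRUE, hypo[-1] != hypo[-n] | grid_break))
  }
  out <- list()
  for (id in unique(run_id[hypo])) {
    idx <- which(run_id == id)
    if (length(idx) < min_pts) next
    start <- idx[1]; end <- idx[length(idx)]
    # walk the preceding window backward: contiguous, 65 <= MAP < 72
    pre_start <- start
    j <- start - 1
    while (j >= 1 &&
           time_s[j + 1] - time_s[j] == cfg$grid_s &&
           map[j] >= cfg$hypo_threshold_mmhg &&
           map[j] < cfg$preceding_threshold_mmhg) {
      pre_start <- j
      j <- j - 1
    }
    out[[length(out) + 1]] <- c(start = start, end = end,
                                pre_start = pre_start)
  }
  if (!length(out)) return(NULL)
  as.data.frame(do.call(rbind, out))
}

#' Detect hypotensive episodes in a cohort
#'
#' Scans each patient's series for maximal runs of consecutive points with
#' MAP below the hypotension threshold lasting at least the minimum duration,
#' and attaches to each the maximal contiguous run of immediately preceding
#' points with MAP in \[hypotension threshold, preceding threshold). Runs are
#' broken by any point at or above the hypotension threshold and by gaps in
#' the 20-second grid (missing time is never interpolated).
#'
#' @param cohort A cohort data frame (see [read_cohort_csv()]); must contain
#'   `patient_id`, `time_s`, `map`.
#' @param cfg An [episode_config()].
#' @return A data frame with one row per episode: `episode_id`, `patient_id`,
#'   `start`, `end`, `pre_start` (1-based row indices into that patient's
#'   time-sorted rows, `end` inclusive; `pre_start == start` when the
#'   preceding window is empty), plus `start_time_s`, `end_time_s`,
#'   `n_points`, `n_preceding`.
#' @export
detect_episodes <- function(cohort, cfg = episode_config()) {
  stopifnot(inherits(cfg, "episode_config"))
  need <- c("patient_id", "time_s", "map")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cohort[c("patient_id", "time_s")]))
    stop("duplicate timestamps within a patient", call. = FALSE)
  res <- list()
  for (pid in unique(cohort$patient_id)) {
    rows <- which(cohort$patient_id == pid)
    sub <- cohort[rows, , drop = FALSE]
    ord <- order(sub$time_s)
    sub <- sub[ord, , drop = FALSE]
    ep <- detect_episodes_one(sub$time_s, sub$map, cfg)
    if (is.null(ep)) next
    ep$patient_id <- pid
    ep$start_time_s <- sub$time_s[ep$start]
    ep$end_time_s <- sub$time_s[ep$end]
    ep$n_points <- ep$end - ep$start + 1L
    ep$n_preceding <- ep$start - ep$pre_start
    res[[length(res) + 1]] <- ep
  }
  if (!length(res)) {
    return(data.frame(episode_id = integer(), patient_id = character(),
                      start = integer(), end = integer(),
                      pre_start = integer(), start_time_s = numeric(),
                      end_time_s = numeric(), n_points = integer(),
                      n_preceding = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$episode_id <- seq_len(nrow(out))
  out[c("episode_id", "patient_id", "start", "end", "pre_start",
        "start_time_s", "end_time_s", "n_points", "n_preceding")]
}

#' Extract the analysis point set for endotyping
#'
#' Returns the hypotensive data points of every detected episode, optionally
#' together with the immediately preceding sub-72 mmHg points, each tagged
#' with its class and source episode. Dropping the preceding points gives the
#' sensitivity variant that endotypes overt hypotension only.
#'
#' @param cohort The cohort data frame the episodes were detected on.
#' @param episodes Output of [detect_episodes()] on `cohort`.
#' @param include_preceding Include pre-episode points (default TRUE).
#' @return A data frame of the selected points (all cohort columns) plus
#'   `class` (`"hypotensive"` or `"preceding"`) and `episode_id`.
#' @export
extract_analysis_points <- function(cohort, episodes,
                                    include_preceding = TRUE) {
  # assemble global row indices first; a single subset at the end keeps
  # this linear in the number of points
  take <- vector("list", nrow(episodes))
  cls <- vector("list", nrow(episodes))
  epi <- vector("list", nrow(episodes))
  j <- 0
  for (pid in unique(episodes$patient_id)) {
    rows <- which(cohort$patient_id == pid)
    rows <- rows[order(cohort$time_s[rows])]
    eps <- episodes[episodes$patient_id == pid, , drop = FALSE]
    for (i in seq_len(nrow(eps))) {
      if (eps$end[i] > length(rows) || eps$pre_start[i] < 1)
        stop("episode indices out of range for patient ", pid, call. = FALSE)
      idx <- eps$start[i]:eps$end[i]
      cl <- rep("hypotensive", length(idx))
      if (include_preceding && eps$pre_start[i] < eps$start[i]) {
        pre <- eps$pre_start[i]:(eps$start[i] - 1L)
        idx <- c(pre, idx)
        cl <- c(rep("preceding", length(pre)), cl)
      }
      j <- j + 1
      take[[j]] <- rows[idx]
      cls[[j]] <- cl
      epi[[j]] <- rep(eps$episode_id[i], length(idx))
    }
  }
  if (j == 0) {
    empty <- cohort[0, , drop = FALSE]
    empty$class <- character()
    empty$episode_id <- integer()
    return(empty)
  }
  res <- cohort[unlist(take), , drop = FALSE]
  res$class <- unlist(cls)
  res$episode_id <- unlist(epi)
  rownames(res) <- NULL
  res
}
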