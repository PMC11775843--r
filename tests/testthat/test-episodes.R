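series_df <- function(map, time_s = (seq_along(map) - 1) * 20,
                      pid = "P1") {
  data.frame(patient_id = pid, time_s = time_s, map = map,
             svi = 40, hr = 80, svv = 10, dpdt = 600, quality_ok = 1L,
             ci = 3.2, svri = 1800, stringsAsFactors = FALSE)
}

test_that("episode detection follows the sustained-hypotension rule", {
  expect_equal(nrow(detect_episodes(series_df(c(80, 80, 80)))), 0)
  ep <- detect_episodes(series_df(c(70, 64, 64, 64, 70)))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, 2)
  expect_equal(ep$end, 4)
  expect_equal(ep$pre_start, 1)  # the single sub-72 point before
  expect_equal(ep$n_preceding, 1)
  # 40 s is below the one-minute minimum
  expect_equal(nrow(detect_episodes(series_df(c(70, 64, 64, 70)))), 0)
})

test_that("thresholds are strict at both boundaries", {
  expect_equal(nrow(detect_episodes(series_df(c(65, 65, 65)))), 0)
  ep <- detect_episodes(series_df(c(64.999, 64.999, 64.999)))
  expect_equal(nrow(ep), 1)
  # MAP = 72 terminates the preceding window, 71.999 does not
  ep <- detect_episodes(series_df(c(72, 71.999, 64, 64, 64)))
  expect_equal(ep$pre_start, 2)
  ep <- detect_episodes(series_df(c(72, 72, 64, 64, 64)))
  expect_equal(ep$pre_start, 3)
})

test_that("a grid gap breaks a hypotensive run", {
  # 3 sub-65 points but the middle one is 40 s after the first
  df <- series_df(c(64, 64, 64), time_s = c(0, 40, 60))
  expect_equal(nrow(detect_episodes(df)), 0)
  # gap between preceding window and episode breaks contiguity
  df <- series_df(c(70, 64, 64, 64), time_s = c(0, 40, 60, 80))
  ep <- detect_episodes(df)
  expect_equal(ep$n_preceding, 0)
})

test_that("unsorted or duplicated timestamps are rejected", {
  df <- series_df(c(64, 64, 64, 64), time_s = c(0, 20, 20, 40))
  expect_error(detect_episodes(df), "duplicate")
})

test_that("detector agrees with the exhaustive window-scan oracle", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_map_series(sample(5:40, 1))
    if (!length(s$map)) next
    df <- series_df(s$map, time_s = s$time_s)
    got <- detect_episodes(df)
    want <- oracle_detect(s$time_s, s$map)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$pre_start, want$pre_start)
    }
  }
})

test_that("detection is idempotent and point classes partition correctly", {
  set.seed(7)
  cfg <- cohort_config(n_patients = 10, points_per_patient = 150, seed = 77)
  coh <- generate_cohort(cfg)
  e1 <- detect_episodes(coh$data)
  e2 <- detect_episodes(coh$data)
  expect_identical(e1, e2)
  both <- extract_analysis_points(coh$data, e1, include_preceding = TRUE)
  only <- extract_analysis_points(coh$data, e1, include_preceding = FALSE)
  expect_true(all(only$class == "hypotensive"))
  # the hypotensive subset is identical under both flags
  key <- function(d) paste(d$patient_id, d$time_s)
  expect_setequal(key(both[both$class == "hypotensive", ]), key(only))
  expect_setequal(key(both[both$class == "preceding", ]),
                  setdiff(key(both), key(only)))
})

test_that("extracted point counts match the generator's ground truth", {
  cfg <- cohort_config(n_patients = 15, points_per_patient = 200, seed = 303)
  coh <- generate_cohort(cfg)
  eps <- detect_episodes(coh$data)
  pts <- extract_analysis_points(coh$data, eps)
  expect_equal(sum(pts$class == "hypotensive"), sum(coh$truth$in_episode))
  expect_equal(sum(pts$class == "preceding"), sum(coh$truth$is_preceding))
  # constructed intervals are recovered exactly
  got <- eps[order(eps$patient_id, eps$start), c("patient_id", "start",
                                                 "end", "pre_start")]
  want <- coh$episodes[order(coh$episodes$patient_id, coh$episodes$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("episode config validates its invariants", {
  expect_error(episode_config(preceding_threshold_mmhg = 60), "exceed")
  expect_error(episode_config(min_duration_s = 50), "multiple")
})
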