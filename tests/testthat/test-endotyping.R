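# Table-style cluster means for the three cohorts (svi, hr, svri, svv),
# used to exercise the physiological labelling rule.
cohort_centroids <- function(dataset) {
  specs <- published_endotype_specs(dataset)
  t(vapply(specs, function(s) s$mean, numeric(4)))
}

summary_from_centroids <- function(centroids) {
  data.frame(cluster = seq_len(nrow(centroids)),
             n = 100, share = 0.25,
             svi_mean = centroids[, "svi"], hr_mean = centroids[, "hr"],
             svri_mean = centroids[, "svri"], svv_mean = centroids[, "svv"])
}

test_that("cluster summaries report original-unit statistics per cluster", {
  pts <- data.frame(svi = c(rep(40, 5), rep(30, 5)),
                    hr = c(rep(80, 5), rep(60, 5)),
                    svri = 2000, svv = 10, ci = 3, dpdt = 600)
  s <- summarize_clusters(pts, rep(1:2, each = 5))
  expect_equal(nrow(s), 2)
  expect_equal(sum(s$share), 1)
  expect_equal(s$svi_mean, c(40, 30))
  # degenerate cluster: sd 0, median = mean
  expect_equal(s$svi_sd, c(0, 0))
  expect_equal(s$svi_median, s$svi_mean)
  expect_equal(s$hr_q25, s$hr_q75)
})

test_that("labelling rule reproduces the published signatures in all cohorts", {
  for (ds in c("development", "validation_surgical", "validation_critical")) {
    cent <- cohort_centroids(ds)
    s <- summary_from_centroids(cent)
    lab <- label_endotypes(s)
    expect_equal(unname(lab), rownames(cent))  # specs are in canonical order
  }
})

test_that("labelling is invariant to cluster order and refuses k != 4", {
  cent <- cohort_centroids("development")
  s <- summary_from_centroids(cent)
  perm <- c(3, 1, 4, 2)
  s2 <- summary_from_centroids(cent[perm, ])
  lab <- label_endotypes(s)
  lab2 <- label_endotypes(s2)
  expect_equal(unname(lab2), unname(lab)[perm])
  expect_error(label_endotypes(s[1:3, ]), "exactly 4")
})

test_that("labelling is stable across replicate cohort fits", {
  # ten replicate mixture draws, each clustered with a fresh 4-component
  # mixture fit; the physiological rule must name the clusters identically
  specs <- published_endotype_specs("development")
  weights <- vapply(specs, function(s) s$weight, numeric(1))
  stable <- 0
  for (rep in 1:10) {
    set.seed(1000 + rep)
    n <- stats::rmultinom(1, 6000, weights)[, 1]
    pts <- do.call(rbind, lapply(seq_along(specs), function(i)
      sample_endotype_points(specs[[i]], n[i])))
    np <- fit_normalizer(pts)
    fit <- fit_gmm(apply_normalizer(pts, np), 4, seed = rep, n_restarts = 4)
    labels <- endotyper:::hard_assign(fit, apply_normalizer(pts, np))
    s <- summarize_clusters(as.data.frame(pts), labels)
    lab <- suppressWarnings(label_endotypes(s))
    # every named cluster must sit nearest (in normalized space) to the
    # generating spec of the same name
    cl_means <- apply_normalizer(
      as.matrix(s[, c("svi_mean", "hr_mean", "svri_mean", "svv_mean")]), np)
    spec_means <- apply_normalizer(
      t(vapply(specs, function(sp) sp$mean, numeric(4))), np)
    nearest <- names(specs)[apply(cl_means, 1, function(m)
      which.min(colSums((t(spec_means) - m)^2)))]
    if (identical(nearest, unname(lab[as.character(s$cluster)])))
      stable <- stable + 1
  }
  expect_gte(stable, 9)
})

test_that("implausible signatures trigger the consistency warning", {
  cent <- cohort_centroids("development")
  cent["vasodilation", "svv"] <- 30  # vasodilation should have low SVV
  expect_warning(label_endotypes(summary_from_centroids(cent)), "SVV")
})

# a small fitted model shared by the assignment tests
fit_small_model <- function() {
  cfg <- cohort_config(n_patients = 30, points_per_patient = 250,
                       mode = "direct", seed = 55)
  coh <- generate_cohort(cfg)
  pcfg <- pipeline_config(
    autoencoder = autoencoder_config(epochs = 40, seed = 1),
    k_range = 4, n_restarts = 3, seed = 99)
  run <- suppressWarnings(run_pipeline(coh, pcfg))
  run
}
small_run <- fit_small_model()

test_that("assignment is a frozen, idempotent map with proper probabilities", {
  run <- small_run
  a1 <- assign_endotypes(run$model, run$points)
  a2 <- assign_endotypes(run$model, run$points)
  expect_identical(a1, a2)
  pcols <- grep("^p_", names(a1), value = TRUE)
  expect_setequal(pcols, paste0("p_", c("vasodilation", "hypovolaemia",
                                        "myocardial_depression",
                                        "bradycardia")))
  probs <- as.matrix(a1[pcols])
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
  expect_true(all(probs >= 0 & probs <= 1))
  # hard label consistent with argmax
  expect_equal(a1$label,
               sub("^p_", "", pcols[max.col(probs, ties.method = "first")]))
  # assignment of the training points reproduces the training posteriors
  expect_equal(unname(run$report$shares[unique(a1$label)]) > 0,
               rep(TRUE, length(unique(a1$label))))
})

test_that("points at an endotype's own mean are assigned to it", {
  run <- small_run
  # cluster means in original units, from the run's own summary
  s <- run$summary
  for (i in seq_len(nrow(s))) {
    pt <- data.frame(svi = s$svi_mean[i], hr = s$hr_mean[i],
                     svri = s$svri_mean[i], svv = s$svv_mean[i])
    a <- assign_endotypes(run$model, pt)
    expect_equal(a$label, s$endotype[i])
  }
})

test_that("model JSON round trip preserves assignments exactly", {
  run <- small_run
  path <- withr::local_tempfile(fileext = ".json")
  save_endotype_model(run$model, path)
  back <- load_endotype_model(path)
  a1 <- assign_endotypes(run$model, run$points[1:50, ])
  a2 <- assign_endotypes(back, run$points[1:50, ])
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("episode-level roll-up averages point posteriors", {
  run <- small_run
  a <- assign_endotypes(run$model, run$points)
  roll <- episode_endotypes(a)
  expect_equal(nrow(roll), length(unique(run$points$episode_id)))
  one <- a[a$episode_id == roll$episode_id[1], ]
  expect_equal(roll$p_vasodilation[1], mean(one$p_vasodilation))
  pcols <- grep("^p_", names(roll), value = TRUE)
  expect_lt(max(abs(rowSums(roll[pcols]) - 1)), 1e-9)
})
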