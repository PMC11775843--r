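# small configs keep these tests fast
fast_cfg <- function(...) autoencoder_config(epochs = 60, batch_size = 64,
                                             seed = 5, ...)

test_that("a 2-D linear manifold in 4-D is reconstructed almost exactly", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  scores <- matrix(rnorm(2 * 1500), ncol = 2)
  x <- scores %*% t(basis)  # exactly rank 2
  ae <- train_autoencoder(x, autoencoder_config(epochs = 400,
                                                batch_size = 128,
                                                val_fraction = 0,
                                                seed = 2))
  mse <- mean((decode(ae, encode(ae, x)) - x)^2)
  expect_lt(mse, 0.01)
})

test_that("training reduces reconstruction loss and records history", {
  set.seed(2)
  x <- matrix(rnorm(4 * 500), ncol = 4)
  ae <- train_autoencoder(x, fast_cfg())
  h <- ae$history
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(h)))
  expect_lte(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)))
})

test_that("training longer does not worsen the converged training loss", {
  set.seed(3)
  basis <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  x <- matrix(rnorm(2 * 800), ncol = 2) %*% t(basis) +
    0.05 * matrix(rnorm(4 * 800), ncol = 4)
  short <- train_autoencoder(x, autoencoder_config(epochs = 150,
                                                   val_fraction = 0,
                                                   seed = 4))
  long <- train_autoencoder(x, autoencoder_config(epochs = 300,
                                                  val_fraction = 0,
                                                  seed = 4))
  expect_lte(tail(long$history$train_loss, 1),
             tail(short$history$train_loss, 1) + 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(6)
  x <- matrix(rnorm(4 * 400), ncol = 4)
  a <- train_autoencoder(x, fast_cfg())
  b <- train_autoencoder(x, fast_cfg())
  expect_identical(a$W, b$W)
  expect_identical(a$b, b$b)
  c <- train_autoencoder(x, autoencoder_config(epochs = 60, batch_size = 64,
                                               seed = 6))
  expect_false(identical(a$W, c$W))
})

test_that("encode is a pure function with non-degenerate output", {
  set.seed(7)
  x <- matrix(rnorm(4 * 400), ncol = 4)
  ae <- train_autoencoder(x, fast_cfg())
  z1 <- encode(ae, x)
  expect_identical(z1, encode(ae, x))
  expect_equal(dim(z1), c(400, 2))
  expect_true(all(is.finite(z1)))
  expect_true(all(apply(z1, 2, sd) > 0))
  expect_equal(dim(decode(ae, z1)), c(400, 4))
  expect_error(encode(ae, x[, 1:3]), "4-dimensional")
  expect_error(decode(ae, x), "2-dimensional")
})

test_that("invalid training input is rejected", {
  x <- matrix(rnorm(4 * 200), ncol = 4)
  x[5, 2] <- NA
  expect_error(train_autoencoder(x, fast_cfg()), "non-finite")
  expect_error(train_autoencoder(matrix(rnorm(40), ncol = 4), fast_cfg()),
               "at least 100")
  expect_error(autoencoder_config(latent_dim = 3), "fixed at 2")
})

test_that("latent clusters of a planted 4-cluster cohort are separable", {
  # four well-separated endotypes (tighter spreads than the published
  # cohorts) so the latent structure has an unambiguous expected geometry
  specs <- list(
    vasodilation = endotype_spec("vasodilation", 0.25,
                                 c(47, 82, 1253, 7), c(5, 5, 100, 1)),
    hypovolaemia = endotype_spec("hypovolaemia", 0.25,
                                 c(34, 87, 1610, 16), c(3, 5, 110, 2)),
    myocardial_depression = endotype_spec("myocardial_depression", 0.25,
                                          c(35, 64, 2268, 16),
                                          c(3, 3, 150, 2)),
    bradycardia = endotype_spec("bradycardia", 0.25,
                                c(42, 52, 2255, 9), c(3, 2, 120, 1)))
  cfg <- cohort_config(n_patients = 40, points_per_patient = 200,
                       mode = "direct", specs = specs, seed = 21)
  coh <- generate_cohort(cfg)
  eps <- detect_episodes(coh$data)
  pts <- extract_analysis_points(coh$data, eps)
  truth <- coh$truth[coh$truth$in_episode == 1 | coh$truth$is_preceding == 1, ]
  key <- paste(pts$patient_id, pts$time_s)
  truth <- truth[match(key, paste(truth$patient_id, truth$time_s)), ]
  z <- apply_normalizer(pts, fit_normalizer(pts))
  ae <- train_autoencoder(z, autoencoder_config(seed = 22))
  lat <- encode(ae, z)
  # average silhouette of the true labels in the latent space, on a
  # subsample for speed
  set.seed(23)
  idx <- sample(nrow(lat), 1500)
  d <- as.matrix(dist(lat[idx, ]))
  lab <- truth$true_endotype[idx]
  sil <- vapply(seq_along(idx), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(d[i, lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0.3)
})
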