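# Shared large-scale fixture: one direct-mode cohort generated from the
# development-cohort endotype table (about 50 000 analysis points) pushed
# through the full pipeline once, then reused by every block that needs it.
# Built lazily so cheap test files never pay for it.
.fixture_env <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.fixture_env$fix)) return(.fixture_env$fix)
  seed <- 20260922
  cfg <- cohort_config(n_patients = 250, points_per_patient = 400,
                       mode = "direct", specs = published_endotype_specs("development"),
                       seed = seed)
  coh <- generate_cohort(cfg)
  run <- suppressWarnings(run_pipeline(coh, pipeline_config(seed = seed)))
  run4 <- if (run$k_selection$selected == 4) run else refit_at_k(run, 4)
  # ground-truth endotype per analysis point, aligned to run$points order
  key <- paste(run$points$patient_id, run$points$time_s)
  tkey <- paste(coh$truth$patient_id, coh$truth$time_s)
  truth <- coh$truth$true_endotype[match(key, tkey)]
  z <- apply_normalizer(run$points, run$model$normalizer)
  latent <- encode(run$model$encoder, z)
  .fixture_env$fix <- list(cohort = coh, run = run, run4 = run4,
                           truth = truth, latent = latent, seed = seed)
  .fixture_env$fix
}
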