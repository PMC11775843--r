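#' End-to-end pipeline configuration
#'
#' Collects the stage configurations of the full endotyping workflow:
#' episode detection, derived-variable computation, autoencoder embedding,
#' and mixture clustering with cluster-count selection. A single global
#' `seed` fans out to per-stage seeds through [derive_seed()], so the whole
#' run is reproducible from one integer.
#'
#' @param episode An [episode_config()].
#' @param derivation A [derivation_config()].
#' @param autoencoder An [autoencoder_config()] (its own seed is ignored;
#'   the stage seed derives from `seed`).
#' @param k_range Candidate cluster counts for [select_k()].
#' @param n_restarts EM restarts per candidate k.
#' @param include_preceding Include pre-episode points in the analysis set
#'   (FALSE gives the hypotension-only sensitivity variant).
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(episode = episode_config(),
                            derivation = derivation_config(),
                            autoencoder = autoencoder_config(),
                            k_range = 2:8,
                            n_restarts = 10,
                            include_preceding = TRUE,
                            seed = 1) {
  stopifnot(inherits(episode, "episode_config"),
            inherits(derivation, "derivation_config"),
            inherits(autoencoder, "autoencoder_config"))
  structure(list(episode = episode, derivation = derivation,
                 autoencoder = autoencoder, k_range = k_range,
                 n_restarts = n_restarts,
                 include_preceding = isTRUE(include_preceding),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_config_hash <- function(config) {
  string_hash(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Run the full endotyping pipeline
#'
#' Executes, in order: quality filtering, hypotensive-episode detection,
#' analysis-point extraction, per-variable normalization, autoencoder
#' training, latent encoding, cluster-count selection by
#' Calinski-Harabasz/Davies-Bouldin, physiological labelling (when the
#' selected k is 4), and cluster summarization in original units.
#'
#' @param cohort A cohort data frame (see [read_cohort_csv()]) or a
#'   `synthetic_cohort`, whose `$data` is used.
#' @param config A [pipeline_config()].
#' @return An object of class `endotype_run`: the fitted `model`
#'   ([endotype_model()]), the `k_selection`, per-cluster `summary` in
#'   original units, the `assignment` of the analysis points, the analysis
#'   `points` themselves with `cluster` and (if labelled) `endotype`
#'   columns, `episodes`, and dataset descriptives in `report`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$data
  if (!is.null(cohort$quality_ok))
    cohort <- cohort[cohort$quality_ok == 1L, , drop = FALSE]
  episodes <- detect_episodes(cohort, config$episode)
  if (!nrow(episodes))
    stop("pipeline aborted at episode detection: no hypotensive episodes",
         call. = FALSE)
  points <- extract_analysis_points(cohort, episodes,
                                    include_preceding =
                                      config$include_preceding)
  if (nrow(points) < 100)
    stop("pipeline aborted: too few analysis points (",
         nrow(points), ")", call. = FALSE)
  normalizer <- fit_normalizer(points)
  z <- apply_normalizer(points, normalizer)
  ae_cfg <- config$autoencoder
  ae_cfg$seed <- derive_seed(config$seed, "autoencoder")
  encoder <- train_autoencoder(z, ae_cfg)
  latent <- encode(encoder, z)
  ks <- select_k(latent, k_range = config$k_range,
                 seed = derive_seed(config$seed, "clustering"),
                 n_restarts = config$n_restarts)
  mixture <- ks$fits[[as.character(ks$selected)]]
  labels <- hard_assign(mixture, latent)
  summary <- summarize_clusters(points, labels)
  label_map <- if (ks$selected == 4) {
    label_endotypes(summary)
  } else {
    warning("selected k = ", ks$selected,
            " != 4; clusters keep numeric ids", call. = FALSE)
    setNames(as.character(summary$cluster), as.character(summary$cluster))
  }
  model <- endotype_model(
    normalizer, encoder, mixture, label_map,
    provenance = list(seed = config$seed,
                      config_hash = pipeline_config_hash(config),
                      n_points = nrow(points),
                      include_preceding = config$include_preceding))
  assignment <- assign_endotypes(model, points)
  points$cluster <- labels
  if (ks$selected == 4)
    points$endotype <- unname(label_map[as.character(labels)])
  summary$endotype <- unname(label_map[as.character(summary$cluster)])
  shares <- setNames(summary$share, summary$endotype)
  report <- list(
    n_patients = length(unique(cohort$patient_id)),
    n_episodes = nrow(episodes),
    n_hypotensive = sum(points$class == "hypotensive"),
    n_preceding = sum(points$class == "preceding"),
    shares = shares)
  structure(list(model = model, k_selection = ks, summary = summary,
                 assignment = assignment, points = points,
                 episodes = episodes, report = report, config = config),
            class = "endotype_run")
}

#' Rebuild a run's model at a fixed cluster count
#'
#' The cluster-count selection keeps every candidate mixture fit, so a run
#' can be re-expressed at any k in its `k_range` without re-fitting — for
#' example to examine the four-component solution when prior knowledge fixes
#' the number of endotypes, whatever the indices preferred on a given
#' dataset.
#'
#' @param run An `endotype_run`.
#' @param k A cluster count present in the run's `k_range`.
#' @return A new `endotype_run` whose model, labels, summary and assignment
#'   use the k-component mixture (the `k_selection` record is kept as is).
#' @export
refit_at_k <- function(run, k) {
  stopifnot(inherits(run, "endotype_run"))
  mixture <- run$k_selection$fits[[as.character(k)]]
  if (is.null(mixture))
    stop("no stored fit for k = ", k, "; it was not in the run's k_range",
         call. = FALSE)
  points <- run$points
  points$cluster <- NULL; points$endotype <- NULL
  z <- apply_normalizer(points, run$model$normalizer)
  latent <- encode(run$model$encoder, z)
  labels <- hard_assign(mixture, latent)
  summary <- summarize_clusters(points, labels)
  label_map <- if (k == 4) label_endotypes(summary)
               else setNames(as.character(summary$cluster),
                             as.character(summary$cluster))
  model <- endotype_model(run$model$normalizer, run$model$encoder, mixture,
                          label_map,
                          provenance = c(run$model$provenance,
                                         list(k_fixed = k)))
  assignment <- assign_endotypes(model, points)
  points$cluster <- labels
  if (k == 4) points$endotype <- unname(label_map[as.character(labels)])
  summary$endotype <- unname(label_map[as.character(summary$cluster)])
  out <- run
  out$model <- model
  out$summary <- summary
  out$assignment <- assignment
  out$points <- points
  out$report$shares <- setNames(summary$share, summary$endotype)
  out
}

#' @export
print.endotype_run <- function(x, ...) {
  r <- x$report
  cat("Endotyping run\n")
  cat(sprintf("  %d patients, %d episodes, %d hypotensive + %d preceding points\n",
              r$n_patients, r$n_episodes, r$n_hypotensive, r$n_preceding))
  cat(sprintf("  selected k = %d (%s)\n", x$k_selection$selected,
              if (x$k_selection$agreement) "CH and DB agree"
              else "CH/DB disagree"))
  if (length(r$shares)) {
    cat("  endotype shares:\n")
    for (nm in names(r$shares))
      cat(sprintf("    %-22s %5.1f%%\n", nm, 100 * r$shares[[nm]]))
  }
  invisible(x)
}

#' Write the run report to disk
#'
#' Writes the per-cluster summary table (original units), the
#' cluster-count-selection table, the endotype shares, and optionally a
#' latent-space scatter plot with posterior-probability contour rings.
#'
#' @param run An `endotype_run`.
#' @param out_dir Output directory (created if needed).
#' @param plot Also write `latent.png` (default FALSE; image encoding is
#'   excluded from determinism guarantees).
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(run, out_dir, plot = FALSE) {
  stopifnot(inherits(run, "endotype_run"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character()
  p <- file.path(out_dir, "cluster_summary.csv")
  utils::write.csv(run$summary, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "k_selection.csv")
  tab <- run$k_selection$table
  tab$selected <- tab$k == run$k_selection$selected
  utils::write.csv(tab, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "endotype_shares.csv")
  utils::write.csv(data.frame(endotype = names(run$report$shares),
                              share = as.numeric(run$report$shares)),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  if (plot) {
    p <- file.path(out_dir, "latent.png")
    grDevices::png(p, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_latent(run)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Latent-space scatter with posterior-probability rings
#'
#' Plots the encoded analysis points colored by hard endotype assignment and
#' overlays, for each mixture component, density contours of its Gaussian
#' (rings of decreasing posterior probability away from the component mean).
#'
#' @param run An `endotype_run`.
#' @param max_points Subsample cap for the scatter.
#' @return Invisibly, NULL. Called for its side effect.
#' @export
plot_latent <- function(run, max_points = 20000) {
  stopifnot(inherits(run, "endotype_run"))
  z <- apply_normalizer(run$points, run$model$normalizer)
  latent <- encode(run$model$encoder, z)
  lab <- factor(run$points$cluster)
  if (nrow(latent) > max_points) {
    idx <- seq(1, nrow(latent), length.out = max_points)
    latent <- latent[idx, , drop = FALSE]; lab <- lab[idx]
  }
  cols <- grDevices::hcl.colors(nlevels(lab), "Dark 3")
  graphics::plot(latent, col = cols[as.integer(lab)], pch = 16,
                 cex = 0.3, xlab = "latent 1", ylab = "latent 2",
                 main = "Latent space endotypes")
  mix <- run$model$mixture
  th <- seq(0, 2 * pi, length.out = 120)
  circ <- cbind(cos(th), sin(th))
  for (j in seq_len(mix$k)) {
    ch <- chol(mix$covs[[j]])
    for (r in c(1, 2)) {  # 1 and 2 sd rings
      ring <- sweep(r * circ %*% ch, 2, mix$means[j, ], "+")
      graphics::lines(ring, col = "grey25", lwd = 1.2, lty = r)
    }
  }
  invisible(NULL)
}
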