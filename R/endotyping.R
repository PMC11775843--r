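SUMMARY_VARS <- c("svi", "hr", "svri", "svv", "ci", "dpdt")

#' Summarize clusters in original units
#'
#' Produces the standard endotype characterization table: per cluster, the
#' point count and share of all points, and mean, standard deviation, median
#' and quartiles of SVI, HR, SVRI, SVV, CI and dP/dt in original
#' (de-normalized) units.
#'
#' @param points Data frame of points in original units (columns `svi`,
#'   `hr`, `svri`, `svv`; optionally `ci`, `dpdt`).
#' @param labels Cluster labels, one per point.
#' @return A data frame with one row per non-empty cluster: `cluster`, `n`,
#'   `share`, then `<var>_mean`, `<var>_sd`, `<var>_median`, `<var>_q25`,
#'   `<var>_q75` for each variable present.
#' @export
summarize_clusters <- function(points, labels) {
  if (length(labels) != nrow(points))
    stop("`labels` must have one entry per point", call. = FALSE)
  lev <- sort(unique(labels))
  vars <- intersect(SUMMARY_VARS, names(points))
  rows <- lapply(lev, function(cl) {
    idx <- labels == cl
    if (!any(idx)) {
      warning("cluster ", cl, " is empty; excluded", call. = FALSE)
      return(NULL)
    }
    row <- data.frame(cluster = cl, n = sum(idx),
                      share = sum(idx) / length(labels))
    for (v in vars) {
      vals <- points[[v]][idx]
      vals <- vals[is.finite(vals)]
      q <- if (length(vals)) stats::quantile(vals, c(0.25, 0.5, 0.75),
                                             names = FALSE)
           else rep(NA_real_, 3)
      row[[paste0(v, "_mean")]] <- if (length(vals)) mean(vals) else NA_real_
      row[[paste0(v, "_sd")]] <- if (length(vals) > 1) stats::sd(vals)
                                 else 0
      row[[paste0(v, "_median")]] <- q[2]
      row[[paste0(v, "_q25")]] <- q[1]
      row[[paste0(v, "_q75")]] <- q[3]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label four clusters with physiological endotype names
#'
#' Deterministic reconstruction of the physiological labelling: the cluster
#' with the lowest mean heart rate is `bradycardia`; among the remaining
#' three, the lowest mean SVRI is `vasodilation`; of the final two, the one
#' with the lower mean heart rate is `myocardial_depression` and the other
#' `hypovolaemia`. This rule separates the four endotypes consistently
#' across the published cohort tables. A consistency warning is emitted when
#' the resulting signature looks wrong (vasodilation should have low SVV,
#' hypovolaemia high SVV).
#'
#' @param summaries Output of [summarize_clusters()] with exactly 4 rows.
#' @return A named character vector mapping cluster id (names) to endotype
#'   name (values); a bijection onto the four endotype names.
#' @export
label_endotypes <- function(summaries) {
  if (nrow(summaries) != 4)
    stop("labelling requires exactly 4 clusters; got ", nrow(summaries),
         " (clusters keep numeric ids)", call. = FALSE)
  s <- summaries
  lab <- setNames(rep(NA_character_, 4), as.character(s$cluster))
  brady <- which.min(s$hr_mean)
  lab[brady] <- "bradycardia"
  rest <- setdiff(seq_len(4), brady)
  vaso <- rest[which.min(s$svri_mean[rest])]
  lab[vaso] <- "vasodilation"
  rest <- setdiff(rest, vaso)
  myo <- rest[which.min(s$hr_mean[rest])]
  hypo <- setdiff(rest, myo)
  lab[myo] <- "myocardial_depression"
  lab[hypo] <- "hypovolaemia"
  if (!is.null(s$svv_mean) && s$svv_mean[vaso] >= s$svv_mean[hypo])
    warning("endotype signature check: vasodilation mean SVV is not below ",
            "hypovolaemia mean SVV; labels may be unreliable",
            call. = FALSE)
  lab
}

#' Assemble a complete endotype model
#'
#' Bundles the fitted pipeline state needed to endotype new data without
#' re-fitting: the normalizer, the encoder, the mixture parameters, and the
#' cluster-to-endotype label map, with provenance metadata.
#'
#' @param normalizer A `normalization_params`.
#' @param encoder An `encoder_model`.
#' @param mixture A `mixture_params`.
#' @param label_map Named character vector from [label_endotypes()] (or
#'   numeric ids as names and values when k != 4).
#' @param provenance Optional list (seed, configuration hash, ...).
#' @return An object of class `endotype_model`.
#' @export
endotype_model <- function(normalizer, encoder, mixture, label_map,
                           provenance = list()) {
  stopifnot(inherits(normalizer, "normalization_params"),
            inherits(encoder, "encoder_model"),
            inherits(mixture, "mixture_params"))
  if (mixture$k == 4 &&
      !setequal(unname(label_map), ENDOTYPE_NAMES))
    stop("`label_map` must be a bijection onto the four endotype names",
         call. = FALSE)
  structure(list(normalizer = normalizer, encoder = encoder,
                 mixture = mixture, label_map = label_map,
                 provenance = provenance),
            class = "endotype_model")
}

#' @export
print.endotype_model <- function(x, ...) {
  cat("Hypotension endotype model\n")
  cat("  encoder:", paste(x$encoder$sizes, collapse = " -> "), "\n")
  cat("  mixture: k =", x$mixture$k, "\n")
  cat("  endotypes:", paste(sprintf("%s=%s", names(x$label_map),
                                    x$label_map), collapse = ", "), "\n")
  invisible(x)
}

#' Assign endotype probabilities to data points with a frozen model
#'
#' Normalizes the points with the model's stored normalization parameters,
#' encodes them with the stored autoencoder weights, evaluates mixture
#' responsibilities with the stored Gaussian parameters, and maps component
#' probabilities to named endotypes. No re-fitting occurs, so a development
#' model can be applied unchanged to an independent dataset.
#'
#' @param model An [endotype_model()].
#' @param points Data frame with the clustering variables in original units
#'   (columns `svi`, `hr`, `svri`, `svv`; optional `class`, `patient_id`,
#'   `time_s` are carried through).
#' @return A data frame with one row per point: any carried identifier
#'   columns, one `p_<endotype>` column per endotype, and `label` (the
#'   argmax endotype; ties break in the canonical endotype order
#'   vasodilation, hypovolaemia, myocardial_depression, bradycardia).
#' @export
assign_endotypes <- function(model, points) {
  stopifnot(inherits(model, "endotype_model"))
  z <- apply_normalizer(points, model$normalizer)
  latent <- encode(model$encoder, z)
  resp <- posterior_probs(model$mixture, latent)
  endo_names <- unname(model$label_map[as.character(seq_len(model$mixture$k))])
  if (anyNA(endo_names)) endo_names <- unname(model$label_map)
  colnames(resp) <- endo_names
  # canonical column order where the four standard names are present
  ord <- if (setequal(endo_names, ENDOTYPE_NAMES)) ENDOTYPE_NAMES
         else endo_names
  resp <- resp[, ord, drop = FALSE]
  label <- ord[max.col(resp, ties.method = "first")]
  carry <- intersect(c("patient_id", "time_s", "class", "episode_id"),
                     names(points))
  out <- if (length(carry)) points[carry]
         else data.frame(point = seq_len(nrow(resp)))
  rownames(out) <- NULL
  probs <- as.data.frame(resp)
  names(probs) <- paste0("p_", ord)
  out <- cbind(out, probs)
  out$label <- label
  out
}

#' Roll endotype probabilities up to episode level
#'
#' Convenience summary: mean posterior probability per episode over its
#' points, plus the episode-level argmax label.
#'
#' @param assignment Output of [assign_endotypes()] containing an
#'   `episode_id` column.
#' @return One row per episode with mean probabilities and `label`.
#' @export
episode_endotypes <- function(assignment) {
  if (is.null(assignment$episode_id))
    stop("`assignment` must carry an `episode_id` column", call. = FALSE)
  pcols <- grep("^p_", names(assignment), value = TRUE)
  agg <- stats::aggregate(assignment[pcols],
                          by = list(episode_id = assignment$episode_id),
                          FUN = mean)
  m <- as.matrix(agg[pcols])
  agg$label <- sub("^p_", "", pcols)[max.col(m, ties.method = "first")]
  agg
}

#' Save / load an endotype model as JSON
#'
#' The model file is a single JSON document holding the normalization
#' parameters, all encoder weights, the Gaussian mixture parameters, the
#' cluster-to-endotype label map, and provenance metadata. Serialization is
#' at full double precision, so identical fits produce byte-identical files.
#'
#' @param model An [endotype_model()].
#' @param path File path.
#' @return `path` (save) or the restored `endotype_model` (load).
#' @export
save_endotype_model <- function(model, path) {
  stopifnot(inherits(model, "endotype_model"))
  obj <- list(
    format = "endotyper-model",
    version = 1L,
    normalizer = list(mean = as.list(model$normalizer$mean),
                      sd = as.list(model$normalizer$sd)),
    encoder = list(sizes = model$encoder$sizes,
                   linear_layers = model$encoder$linear_layers,
                   W = lapply(model$encoder$W, function(w)
                     apply(w, 1, as.numeric, simplify = FALSE)),
                   b = model$encoder$b),
    mixture = list(k = model$mixture$k,
                   weights = model$mixture$weights,
                   means = apply(model$mixture$means, 1, as.numeric,
                                 simplify = FALSE),
                   covs = lapply(model$mixture$covs, function(s)
                     apply(s, 1, as.numeric, simplify = FALSE))),
    label_map = as.list(model$label_map),
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_endotype_model
#' @export
load_endotype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "endotyper-model"))
    stop("not an endotyper model file: ", path, call. = FALSE)
  normalizer <- structure(
    list(mean = unlist(obj$normalizer$mean)[CLUSTER_VARS],
         sd = unlist(obj$normalizer$sd)[CLUSTER_VARS]),
    class = "normalization_params")
  sizes <- as.integer(unlist(obj$encoder$sizes))
  W <- lapply(obj$encoder$W, function(w)
    do.call(rbind, lapply(w, function(row) as.numeric(unlist(row)))))
  b <- lapply(obj$encoder$b, function(v) as.numeric(unlist(v)))
  L <- length(sizes) - 1
  lin <- if (!is.null(obj$encoder$linear_layers))
    as.integer(unlist(obj$encoder$linear_layers)) else c(L %/% 2 + L %% 2, L)
  encoder <- structure(
    list(W = W, b = b, sizes = sizes,
         n_encoder_layers = L %/% 2,
         linear_layers = lin,
         history = data.frame(), config = NULL),
    class = "encoder_model")
  mix <- new_mixture_params(
    k = as.integer(unlist(obj$mixture$k)),
    weights = as.numeric(unlist(obj$mixture$weights)),
    means = do.call(rbind, lapply(obj$mixture$means,
                                  function(m) as.numeric(unlist(m)))),
    covs = lapply(obj$mixture$covs, function(s)
      do.call(rbind, lapply(s, function(row) as.numeric(unlist(row))))))
  label_map <- unlist(obj$label_map)
  endotype_model(normalizer, encoder, mix, label_map,
                 provenance = obj$provenance)
}
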