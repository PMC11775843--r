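# Per-component log densities (n x k), including log mixing weights.
gmm_weighted_logdens <- function(x, params) {
  n <- nrow(x); d <- ncol(x); k <- params$k
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    S <- params$covs[[j]]
    if (d == 2) {
      # explicit 2x2 inverse: the dominant cost in large-n EM
      det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
      if (!is.finite(det) || det <= 0)
        stop("singular covariance in component ", j, call. = FALSE)
      logdet <- log(det)
      a <- x[, 1] - params$means[j, 1]
      bb <- x[, 2] - params$means[j, 2]
      quad <- (S[2, 2] * a * a - 2 * S[1, 2] * a * bb + S[1, 1] * bb * bb) /
        det
    } else {
      ch <- tryCatch(chol(S), error = function(e)
        stop("singular covariance in component ", j, call. = FALSE))
      logdet <- 2 * sum(log(diag(ch)))
      xc <- sweep(x, 2, params$means[j, ], "-")
      y <- backsolve(ch, t(xc), transpose = TRUE)
      quad <- colSums(y^2)
    }
    out[, j] <- log(params$weights[j]) -
      0.5 * (d * log(2 * pi) + logdet + quad)
  }
  out
}

logsumexp_rows <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

new_mixture_params <- function(k, weights, means, covs, loglik = NA_real_,
                               loglik_trace = numeric(), n_iter = NA_integer_,
                               converged = NA) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  structure(list(k = k, weights = weights, means = means, covs = covs,
                 loglik = loglik, loglik_trace = loglik_trace,
                 n_iter = n_iter, converged = converged),
            class = "mixture_params")
}

# One EM run from a given initialization. Returns mixture_params.
gmm_em_run <- function(x, k, init_means, init_covs, init_weights,
                       max_iter, tol, ridge) {
  n <- nrow(x); d <- ncol(x)
  params <- new_mixture_params(k, init_weights, init_means, init_covs)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0
  ridge_mat <- diag(ridge, d)
  while (it < max_iter) {
    it <- it + 1
    wl <- gmm_weighted_logdens(x, params)
    ll_rows <- logsumexp_rows(wl)
    ll <- mean(ll_rows)
    trace[it] <- ll
    resp <- exp(wl - ll_rows)
    # M-step
    Nj <- colSums(resp)
    Nj <- pmax(Nj, 1e-300)
    weights <- Nj / n
    means <- t(resp) %*% x / Nj
    covs <- vector("list", k)
    for (j in seq_len(k)) {
      xc <- sweep(x, 2, means[j, ], "-")
      covs[[j]] <- crossprod(xc * sqrt(resp[, j])) / Nj[j] + ridge_mat
    }
    params <- new_mixture_params(k, weights / sum(weights), means, covs)
    if (is.finite(prev) && abs(ll - prev) < tol) { converged <- TRUE; break }
    prev <- ll
  }
  # log-likelihood of the final parameters
  final_ll <- mean(logsumexp_rows(gmm_weighted_logdens(x, params)))
  params$loglik <- final_ll
  params$loglik_trace <- c(trace, final_ll)
  params$n_iter <- it
  params$converged <- converged
  params
}

#' Fit a full-covariance Gaussian mixture model by EM
#'
#' Runs expectation-maximization with full covariance matrices from
#' `n_restarts` initializations (the first from a k-means partition, the
#' rest from randomly chosen points) and keeps the solution with the highest
#' log-likelihood. A small ridge is added to each covariance at every
#' M-step to keep the components non-singular.
#'
#' @param latent An n x d matrix (the 2-D latent points in this analysis).
#' @param k Number of components; must satisfy `1 <= k <= n/10`.
#' @param seed Seed controlling all initializations.
#' @param n_restarts Number of EM runs.
#' @param max_iter Maximum EM iterations per run.
#' @param tol Convergence tolerance on the change in mean log-likelihood.
#' @param ridge Diagonal ridge added to each covariance.
#' @return An object of class `mixture_params`: `k`, `weights`, `means`
#'   (k x d), `covs` (list of d x d), `loglik` (mean log-likelihood of the
#'   kept run), `loglik_trace`, `n_iter`, `converged`.
#' @export
fit_gmm <- function(latent, k, seed = 1, n_restarts = 10, max_iter = 500,
                    tol = 1e-6, ridge = 1e-6) {
  x <- as.matrix(latent)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (k < 1 || k > n / 10)
    stop("`k` must satisfy 1 <= k <= n/10", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite latent values", call. = FALSE)
  overall_cov <- stats::cov(x) + diag(ridge, d)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(derive_seed(seed, paste0("gmm-init-", r)), {
      # first restart starts from a k-means partition, the rest from
      # random points: the structured start converges fast, the random
      # ones keep the search diverse
      if (r == 1 && n > 10 * k && k > 1) {
        km <- tryCatch(stats::kmeans(x, centers = k, nstart = 1,
                                     iter.max = 50),
                       error = function(e) NULL)
      } else km <- NULL
      if (!is.null(km)) {
        means <- km$centers
        weights <- pmax(km$size, 1) / sum(pmax(km$size, 1))
        covs <- lapply(seq_len(k), function(j) {
          pts <- x[km$cluster == j, , drop = FALSE]
          if (nrow(pts) > d + 1) stats::cov(pts) + diag(ridge, d)
          else overall_cov
        })
      } else {
        means <- x[sample.int(n, k), , drop = FALSE]
        weights <- rep(1 / k, k)
        covs <- replicate(k, overall_cov, simplify = FALSE)
      }
      list(means = means, covs = covs, weights = weights)
    })
    fit <- gmm_em_run(x, k, init$means, init$covs, init$weights,
                      max_iter, tol, ridge)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Gaussian mixture, k = %d (mean log-likelihood %.4f, %s)\n",
              x$k, x$loglik,
              if (isTRUE(x$converged)) "converged" else "max iterations"))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Posterior component responsibilities
#'
#' Evaluates, for each point, the posterior probability of each mixture
#' component from the weighted component densities. Rows sum to 1.
#'
#' @param params A `mixture_params` object.
#' @param latent An n x d matrix of points.
#' @return An n x k matrix of responsibilities.
#' @export
posterior_probs <- function(params, latent) {
  stopifnot(inherits(params, "mixture_params"))
  x <- as.matrix(latent)
  wl <- gmm_weighted_logdens(x, params)
  exp(wl - logsumexp_rows(wl))
}

# Hard assignment by maximum responsibility (ties break to lowest index).
hard_assign <- function(params, latent) {
  max.col(posterior_probs(params, latent), ties.method = "first")
}

check_partition <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(x))
    stop("`labels` must have one entry per point", call. = FALSE)
  k <- length(unique(labels))
  if (k < 2) stop("need at least 2 non-empty clusters", call. = FALSE)
  if (nrow(x) <= k) stop("need more points than clusters", call. = FALSE)
  list(x = x, labels = labels, k = k)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `[B/(k-1)] / [W/(n-k)]` with `B = sum_i n_i ||c_i - c||^2` and
#' `W = sum_i sum_{x in C_i} ||x - c_i||^2` (Euclidean). Higher indicates
#' better-separated, more compact clusters.
#'
#' @param x An n x d matrix of points.
#' @param labels Cluster labels (at least two non-empty clusters).
#' @return The index value (non-negative).
#' @export
calinski_harabasz <- function(x, labels) {
  p <- check_partition(x, labels)
  x <- p$x; labels <- p$labels; k <- p$k; n <- nrow(x)
  overall <- colMeans(x)
  B <- 0; W <- 0
  for (j in seq_len(k)) {
    pts <- x[labels == j, , drop = FALSE]
    cj <- colMeans(pts)
    B <- B + nrow(pts) * sum((cj - overall)^2)
    W <- W + sum(sweep(pts, 2, cj, "-")^2)
  }
  if (W == 0) stop("within-cluster dispersion is zero; index undefined",
                   call. = FALSE)
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case similarity
#' `max_{j != i} (s_i + s_j) / d_ij`, where `s_i` is the mean Euclidean
#' distance of cluster i's points to their centroid and `d_ij` the distance
#' between centroids. Lower indicates better clustering.
#'
#' @inheritParams calinski_harabasz
#' @return The index value (non-negative).
#' @export
davies_bouldin <- function(x, labels) {
  p <- check_partition(x, labels)
  x <- p$x; labels <- p$labels; k <- p$k
  centroids <- matrix(0, k, ncol(x))
  s <- numeric(k)
  for (j in seq_len(k)) {
    pts <- x[labels == j, , drop = FALSE]
    centroids[j, ] <- colMeans(pts)
    s[j] <- mean(sqrt(rowSums(sweep(pts, 2, centroids[j, ], "-")^2)))
  }
  total <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      if (dij == 0) stop("coincident centroids; index undefined",
                         call. = FALSE)
      best <- max(best, (s[i] + s[j]) / dij)
    }
    total <- total + best
  }
  total / k
}

#' Select the number of mixture components
#'
#' For each candidate k, fits a Gaussian mixture in the latent space,
#' hard-assigns points by maximum responsibility, and evaluates the
#' Calinski-Harabasz and Davies-Bouldin indices on the partition. The
#' selected k maximizes Calinski-Harabasz; the `agreement` flag records
#' whether the same k also minimizes Davies-Bouldin (when the two indices
#' disagree, Calinski-Harabasz wins and a warning is emitted).
#'
#' @param latent An n x d matrix of latent points.
#' @param k_range Candidate cluster counts, within 2..10.
#' @param seed Seed (fanned out per k).
#' @param n_restarts EM restarts per k.
#' @param ... Passed to [fit_gmm()].
#' @return An object of class `k_selection`: `table` (k, ch, db), `selected`,
#'   `agreement`, and `fits` (the fitted `mixture_params` per k, so the
#'   chosen model need not be refit).
#' @export
select_k <- function(latent, k_range = 2:8, seed = 1, n_restarts = 10, ...) {
  if (any(k_range < 2) || any(k_range > 10))
    stop("`k_range` must lie within 2..10", call. = FALSE)
  x <- as.matrix(latent)
  rows <- list(); fits <- list()
  for (k in k_range) {
    fit <- tryCatch(
      fit_gmm(x, k, seed = derive_seed(seed, paste0("select-k-", k)),
              n_restarts = n_restarts, ...),
      error = function(e) {
        warning("GMM fit failed for k = ", k, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    labels <- hard_assign(fit, x)
    if (length(unique(labels)) < 2) {
      warning("degenerate hard assignment for k = ", k, "; excluded",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      k = k,
      ch = calinski_harabasz(x, labels),
      db = davies_bouldin(x, labels))
    fits[[as.character(k)]] <- fit
  }
  if (!length(rows)) stop("all mixture fits failed", call. = FALSE)
  tab <- do.call(rbind, rows)
  selected <- tab$k[which.max(tab$ch)]
  db_choice <- tab$k[which.min(tab$db)]
  agreement <- selected == db_choice
  if (!agreement)
    warning(sprintf(paste0("cluster-count indices disagree: ",
                           "Calinski-Harabasz prefers k = %d, ",
                           "Davies-Bouldin prefers k = %d; using %d"),
                    selected, db_choice, selected), call. = FALSE)
  structure(list(table = tab, selected = selected, agreement = agreement,
                 fits = fits),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-count selection (GMM in latent space):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Selected k = %d (indices %s)\n", x$selected,
              if (x$agreement) "agree" else "disagree"))
  invisible(x)
}

#' k-means clustering in the latent space (sensitivity analysis)
#'
#' Standard iterative centroid refinement via [stats::kmeans()], best of
#' `n_restarts` random starts by within-cluster sum of squares. Used to
#' check that the endotypes found by the Gaussian mixture are not an
#' artifact of the mixture's distributional assumptions.
#'
#' @param latent An n x d matrix of latent points.
#' @param k Number of clusters.
#' @param seed Seed for the restarts.
#' @param n_restarts Number of random starts.
#' @return A list with `labels`, `centers`, `tot_withinss`.
#' @export
fit_kmeans <- function(latent, k, seed = 1, n_restarts = 10) {
  x <- as.matrix(latent)
  if (k < 1 || k > nrow(x) / 10)
    stop("`k` must satisfy 1 <= k <= n/10", call. = FALSE)
  km <- with_seed(derive_seed(seed, "kmeans"),
                  stats::kmeans(x, centers = k, nstart = n_restarts,
                                iter.max = 100))
  list(labels = km$cluster, centers = km$centers,
       tot_withinss = km$tot.withinss)
}
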