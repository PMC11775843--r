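suppressMessages(library(mclust))  # independent GMM/ARI oracle

# Independent oracles used to validate the package's implementations.
# These are deliberately written as naive enumerations / Monte-Carlo
# estimators, not as calls into the code paths they check.

# Exhaustive window-scan episode detector: checks every contiguous window
# for the maximal-run + duration conditions directly.
oracle_detect <- function(time_s, map, hypo = 65, pre = 72, min_pts = 3,
                          grid = 20) {
  n <- length(map)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_pts) next
      win <- i:j
      if (length(win) > 1 && any(diff(time_s[win]) != grid)) next
      if (!all(map[win] < hypo)) next
      left_max <- i == 1 || map[i - 1] >= hypo ||
        time_s[i] - time_s[i - 1] != grid
      right_max <- j == n || map[j + 1] >= hypo ||
        time_s[j + 1] - time_s[j] != grid
      if (!left_max || !right_max) next
      ps <- i
      while (ps > 1 && time_s[ps] - time_s[ps - 1] == grid &&
             map[ps - 1] >= hypo && map[ps - 1] < pre) {
        ps <- ps - 1
      }
      out[[length(out) + 1]] <- c(start = i, end = j, pre_start = ps)
    }
  }
  if (!length(out)) return(NULL)
  as.data.frame(do.call(rbind, out))
}

# Naive per-point evaluation of the Calinski-Harabasz formula.
oracle_ch <- function(x, labels) {
  x <- as.matrix(x)
  labs <- unique(labels)
  k <- length(labs)
  n <- nrow(x)
  c_all <- colMeans(x)
  B <- 0
  W <- 0
  for (l in labs) {
    idx <- which(labels == l)
    cl <- colMeans(x[idx, , drop = FALSE])
    B <- B + length(idx) * sum((cl - c_all)^2)
    for (i in idx) W <- W + sum((x[i, ] - cl)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Naive per-point evaluation of the Davies-Bouldin formula.
oracle_db <- function(x, labels) {
  x <- as.matrix(x)
  labs <- unique(labels)
  k <- length(labs)
  cent <- do.call(rbind, lapply(labs, function(l)
    colMeans(x[labels == l, , drop = FALSE])))
  s <- sapply(seq_along(labs), function(ii) {
    idx <- which(labels == labs[ii])
    mean(sapply(idx, function(i) sqrt(sum((x[i, ] - cent[ii, ])^2))))
  })
  total <- 0
  for (i in seq_len(k)) {
    ratios <- c()
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      ratios <- c(ratios, (s[i] + s[j]) / dij)
    }
    total <- total + max(ratios)
  }
  total / k
}

# Monte-Carlo KL(P || Q) between Gaussians: sample from P, average the
# log-density ratio. Densities via mclust's dmvnorm (independent of the
# package's closed form).
oracle_kl_mc <- function(p, q, n = 200000) {
  x <- MASS::mvrnorm(n, p$mean, p$cov)
  lp <- mclust::dmvnorm(x, p$mean, p$cov, log = TRUE)
  lq <- mclust::dmvnorm(x, q$mean, q$cov, log = TRUE)
  mean(lp - lq)
}

# Random positive-definite covariance of dimension d.
random_cov <- function(d, scale = 1) {
  a <- matrix(rnorm(d * d), d, d)
  scale * (crossprod(a) / d + diag(0.2, d))
}

# Random MAP series with occasional plateaus near the clinical thresholds,
# including exact-boundary values, on a possibly gappy 20-s grid.
random_map_series <- function(n) {
  map <- sample(c(55, 60, 63, 64.999, 65, 66, 70, 71.999, 72, 80),
                n, replace = TRUE,
                prob = c(2, 2, 2, 1, 1, 2, 2, 1, 1, 3))
  keep <- runif(n) > 0.08  # drop some grid points to create gaps
  time_s <- ((seq_len(n) - 1) * 20)[keep]
  list(time_s = time_s, map = map[keep])
}
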