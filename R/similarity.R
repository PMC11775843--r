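#' Fit a Gaussian to one endotype's points
#'
#' Approximates an endotype's distribution in the shared comparison space
#' (the normalized four-variable space) by a single Gaussian with the sample
#' mean and sample covariance (n-1 denominator) of the endotype's points. A
#' tiny ridge (1e-9) stabilizes the covariance; truly degenerate point sets
#' are rejected.
#'
#' @param points An n x d matrix of points in the comparison space.
#' @param labels Endotype labels, one per point.
#' @param endotype Which endotype to fit.
#' @param source Optional source dataset id carried in the result.
#' @return An object of class `endotype_gaussian`: `endotype`, `mean`,
#'   `cov`, `n`, `source`.
#' @export
fit_endotype_gaussian <- function(points, labels, endotype, source = NA) {
  x <- as.matrix(points)
  idx <- labels == endotype
  if (sum(idx) < 10)
    stop("fewer than 10 points for endotype '", endotype, "'", call. = FALSE)
  x <- x[idx, , drop = FALSE]
  mu <- colMeans(x)
  S <- stats::cov(x)
  if (max(abs(S)) < 1e-12)
    stop("degenerate (constant) point set for endotype '", endotype, "'",
         call. = FALSE)
  S <- S + diag(1e-9, ncol(x))
  structure(list(endotype = endotype, mean = mu, cov = S, n = sum(idx),
                 source = source),
            class = "endotype_gaussian")
}

#' Kullback-Leibler divergence between two multivariate Gaussians
#'
#' Closed form for `KL(P || Q)`:
#' `0.5 * (tr(Sq^-1 Sp) + (mq - mp)' Sq^-1 (mq - mp) - d + ln(det Sq / det Sp))`.
#' Asymmetric in its arguments; zero iff the distributions are identical,
#' and unbounded above.
#'
#' @param p,q `endotype_gaussian` objects (or lists with `mean` and `cov`)
#'   of the same dimension, with positive-definite covariances.
#' @return The divergence in nats (non-negative).
#' @export
#' @examples
#' g <- list(mean = c(0, 0), cov = diag(2))
#' kl_gaussian(g, g)  # 0
kl_gaussian <- function(p, q) {
  mp <- as.numeric(p$mean); mq <- as.numeric(q$mean)
  Sp <- as.matrix(p$cov); Sq <- as.matrix(q$cov)
  d <- length(mp)
  if (length(mq) != d || any(dim(Sp) != d) || any(dim(Sq) != d))
    stop("dimension mismatch between P and Q", call. = FALSE)
  chq <- tryCatch(chol(Sq), error = function(e)
    stop("covariance of Q is not positive-definite", call. = FALSE))
  chp <- tryCatch(chol(Sp), error = function(e)
    stop("covariance of P is not positive-definite", call. = FALSE))
  logdet_q <- 2 * sum(log(diag(chq)))
  logdet_p <- 2 * sum(log(diag(chp)))
  Sq_inv <- chol2inv(chq)
  tr_term <- sum(Sq_inv * Sp)
  dm <- mq - mp
  quad <- as.numeric(t(dm) %*% Sq_inv %*% dm)
  val <- 0.5 * (tr_term + quad - d + logdet_q - logdet_p)
  # clamp sub-round-off negatives (identical distributions) to exact zero
  if (val < 0 && val > -1e-9) val <- 0
  val
}

#' Fit the four endotype Gaussians of a labelled point set
#'
#' Helper producing the inputs of [similarity_matrix()]: one Gaussian per
#' endotype, fitted in the shared normalized four-variable space. Use the
#' development model's normalizer for both datasets being compared, so both
#' sets of Gaussians live in the same space.
#'
#' @param points Data frame of points in original units (clustering
#'   variables present).
#' @param labels Endotype name per point.
#' @param normalizer The `normalization_params` defining the shared space.
#' @param source Optional dataset id.
#' @return Named list of `endotype_gaussian`, in canonical endotype order.
#' @export
endotype_gaussians <- function(points, labels, normalizer, source = NA) {
  z <- apply_normalizer(points, normalizer)
  present <- intersect(ENDOTYPE_NAMES, unique(labels))
  if (!length(present)) present <- sort(unique(labels))  # numeric ids
  out <- lapply(present, function(e)
    fit_endotype_gaussian(z, labels, e, source = source))
  names(out) <- present
  out
}

#' Pairwise KL divergences between the endotypes of two models
#'
#' Builds the endotype-correspondence matrix: entry (i, j) is
#' `KL(A_i || B_j)` for endotype i of dataset A against endotype j of
#' dataset B, both approximated as Gaussians in the shared comparison space.
#' The minimum-total-divergence bijection between rows and columns is found
#' by exhaustive search over the 4! pairings; a flag records whether it
#' coincides with the name-based pairing (it should, when the same four
#' endotypes were found in both datasets).
#'
#' @param gaussians_a,gaussians_b Named lists of `endotype_gaussian` (see
#'   [endotype_gaussians()]), same endotype names.
#' @return An object of class `similarity_matrix`: `kl` (the matrix, rows =
#'   A, columns = B), `matching` (named character vector row -> column),
#'   `matching_cost`, and `name_match` (TRUE when the optimal matching is
#'   the identity on names).
#' @export
similarity_matrix <- function(gaussians_a, gaussians_b) {
  na <- names(gaussians_a); nb <- names(gaussians_b)
  if (!length(na))
    stop("no endotype Gaussians to compare", call. = FALSE)
  if (!setequal(na, nb))
    stop("both models must provide the same endotype names", call. = FALSE)
  nb_ord <- na  # align columns to row order
  k <- length(na)
  kl <- matrix(NA_real_, k, k, dimnames = list(na, nb_ord))
  for (i in seq_len(k))
    for (j in seq_len(k))
      kl[i, j] <- kl_gaussian(gaussians_a[[na[i]]],
                              gaussians_b[[nb_ord[j]]])
  # exhaustive minimum-cost bijection (k! is tiny for k = 4)
  perms <- permutations_all(k)
  costs <- apply(perms, 1, function(p) sum(kl[cbind(seq_len(k), p)]))
  best <- perms[which.min(costs), ]
  matching <- setNames(nb_ord[best], na)
  structure(list(kl = kl, matching = matching,
                 matching_cost = min(costs),
                 name_match = all(matching == names(matching))),
            class = "similarity_matrix")
}

# All permutations of 1..n as an (n!) x n matrix.
permutations_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_all(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 1
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      row <- sub[s, ]
      row[row >= i] <- row[row >= i] + 1L
      out[r, ] <- c(i, row)
      r <- r + 1
    }
  }
  out
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Endotype similarity (KL divergence, rows || columns):\n")
  print(round(x$kl, 2))
  cat("Minimum-cost matching",
      if (x$name_match) "coincides with" else "DIFFERS from",
      "the name-based pairing\n")
  invisible(x)
}
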