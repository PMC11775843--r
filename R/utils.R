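#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed
#' arithmetic derivation so that stages are reproducible in isolation
#' (re-running only the clustering stage uses the same stream it saw inside
#' the full pipeline) while remaining decoupled from one another.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"autoencoder"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "autoencoder")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u)) %% 2147483629
  # exact in double arithmetic: all intermediates < 2^53
  as.integer((abs(seed) %% 2147483629 * 7919 + h * 104729) %% 2147483629)
}

# Deterministic polynomial hash of a character scalar, as 8 hex digits.
# Used only for provenance stamps in serialized models.
string_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Internal: check a numeric scalar.
check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# The four clustering variables, in canonical order.
CLUSTER_VARS <- c("svi", "hr", "svri", "svv")

# Canonical endotype order; ties in argmax assignment break in this order.
ENDOTYPE_NAMES <- c("vasodilation", "hypovolaemia", "myocardial_depression",
                    "bradycardia")
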