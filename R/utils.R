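#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer indices (replicate number,
#' condition number, bootstrap stream, ...) into a new seed, so that every
#' stochastic step of a study is a deterministic function of the master seed.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in idx) {
    # 48271 is a classic Lehmer multiplier; arithmetic stays exact in doubles
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Set the RNG for the remainder of the calling function if a seed is given;
# with seed = NULL the caller's global RNG stream is used untouched.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

# Clip probabilities away from {0, 1} so odds e/(1-e) never overflow.
clip_probability <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
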