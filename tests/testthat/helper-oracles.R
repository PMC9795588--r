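# Independent oracles and small fixture builders used across test files.

# Literal transcription of best-first greedy matching: repeatedly scan all
# remaining (treated, control) pairs for the global minimum distance within
# the caliper, ties broken by lowest treated then lowest control index.
# Deliberately quadratic and separate from the package implementation.
oracle_greedy_match <- function(pt, pc, caliper) {
  rem_t <- seq_along(pt)
  rem_c <- seq_along(pc)
  pairs <- matrix(integer(0), 0, 2)
  repeat {
    if (length(rem_t) == 0L || length(rem_c) == 0L) break
    best <- NULL
    for (i in rem_t) for (j in rem_c) {
      dij <- abs(pt[i] - pc[j])
      if (dij > caliper) next
      if (is.null(best) || dij < best$d ||
          (dij == best$d && (i < best$i || (i == best$i && j < best$j))))
        best <- list(d = dij, i = i, j = j)
    }
    if (is.null(best)) break
    pairs <- rbind(pairs, c(best$i, best$j))
    rem_t <- setdiff(rem_t, best$i)
    rem_c <- setdiff(rem_c, best$j)
  }
  pairs
}

# Tiny deterministic dataset with explicit values for hand-checked examples.
toy_dataset <- function(y, t, d = 2L) {
  n <- length(y)
  X <- matrix(seq_len(n * d) / (n * d), n, d)
  eca_dataset(X, t, y)
}

# Randomized (unconfounded) scenario-1 style dataset: treatment independent
# of covariates, outcome a sparse linear score plus noise.
randomized_dataset <- function(n, theta = 0, d = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
  t <- rbinom(n, 1L, 0.5)
  if (sum(t) < 2L || sum(1 - t) < 2L) t[1:4] <- c(1L, 1L, 0L, 0L)
  y <- rowSums(X[, 1:10]) / sqrt(10) + theta * t + rnorm(n)
  eca_dataset(X, t, y)
}
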