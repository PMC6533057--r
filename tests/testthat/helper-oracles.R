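# Independent brute-force oracles used across tests. These deliberately use
# the most naive formulation available so they share no code path with the
# package implementation.

# All-pairs time-averaged MSD of one track by an explicit double loop.
oracle_msd_track <- function(pos, max_lag) {
  n <- nrow(pos)
  out <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    acc <- 0
    cnt <- 0
    for (t in seq_len(n - k)) {
      d <- pos[t + k, ] - pos[t, ]
      if (!anyNA(d)) {
        acc <- acc + sum(d^2)
        cnt <- cnt + 1
      }
    }
    out[k] <- if (cnt > 0) acc / cnt else NA_real_
  }
  out
}

# Exact two-tailed Mann-Whitney p by enumeration of all C(n, na) group
# assignments of the pooled sample (no ties assumed).
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(ii) {
    sum(rank(pooled)[ii]) - na * (na + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small still-image configuration used where many stacks must be rendered;
# a 1 um nucleus in a compact stack, imaging-regime pitches.
quick_still_config <- function(seed, ...) {
  sim_config(mode = "still", stack_shape = c(22L, 34L, 34L),
             nucleus_semiaxes = c(0.95, 0.95, 0.95), seed = seed, ...)
}
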