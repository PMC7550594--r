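# Low-level random-draw primitives shared (by protocol) with the compiled run
# core. Both implementations consume R's global RNG stream in exactly the same
# order, so a pure-R round sequence and the compiled run are bit-identical
# under the same seed. Do not reorder draws here without mirroring the change
# in src/run_core.cpp.

# uniform index in 1..n from a single runif draw
draw_index <- function(n) {
  as.integer(min(floor(runif(1L) * n) + 1, n))
}

# one draw from a categorical distribution given by the probability vector p
# (assumed to sum to 1); walks the cumulative sum, skipping zero-mass cells
draw_categorical <- function(p) {
  u <- runif(1L)
  acc <- 0
  last_pos <- 0L
  for (j in seq_along(p)) {
    if (p[j] > 0) {
      acc <- acc + p[j]
      last_pos <- j
      if (u <= acc) {
        return(j)
      }
    }
  }
  if (last_pos == 0L) {
    abort("cannot draw from an all-zero probability vector")
  }
  last_pos
}

# Fisher-Yates shuffle of 1..n (descending form)
fy_shuffle <- function(n) {
  perm <- seq_len(n)
  if (n < 2L) {
    return(perm)
  }
  for (t in seq.int(n, 2L)) {
    j <- draw_index(t)
    tmp <- perm[t]
    perm[t] <- perm[j]
    perm[j] <- tmp
  }
  perm
}

# m distinct indices from 1..k via partial Fisher-Yates, returned sorted
sample_mask_indices <- function(k, m) {
  if (m <= 0L) {
    return(integer(0))
  }
  pool <- seq_len(k)
  for (t in seq_len(m)) {
    j <- (t - 1L) + draw_index(k - t + 1L)
    tmp <- pool[t]
    pool[t] <- pool[j]
    pool[j] <- tmp
  }
  sort(pool[seq_len(m)])
}

# seed helper: derive n child seeds (< 2^31) from the global RNG stream
derive_seeds <- function(n) {
  as.integer(floor(runif(n) * .Machine$integer.max))
}
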