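# Independent brute-force oracles and small fixture builders. These
# deliberately use explicit index loops so they share no code path with
# the implementation they check.

rand_tensor <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

# Mode-l unfolding by explicit enumeration: row = index along `mode`,
# column = position of the remaining indices, lower-numbered remaining
# mode varying fastest.
naive_unfold <- function(x, mode) {
  d <- dim(x)
  rest <- setdiff(1:3, mode)
  out <- matrix(NA_real_, d[mode], prod(d[rest]))
  for (i1 in seq_len(d[1])) {
    for (i2 in seq_len(d[2])) {
      for (i3 in seq_len(d[3])) {
        idx <- c(i1, i2, i3)
        col <- (idx[rest[1]] - 1) + (idx[rest[2]] - 1) * d[rest[1]] + 1
        out[idx[mode], col] <- x[i1, i2, i3]
      }
    }
  }
  out
}

# Mode product by explicit triple-loop contraction.
naive_mode_product <- function(x, u, mode) {
  d <- dim(x)
  k <- ncol(u)
  out_dims <- d
  out_dims[mode] <- k
  out <- array(0, out_dims)
  for (i1 in seq_len(out_dims[1])) {
    for (i2 in seq_len(out_dims[2])) {
      for (i3 in seq_len(out_dims[3])) {
        acc <- 0
        for (j in seq_len(d[mode])) {
          src <- c(i1, i2, i3)
          src[mode] <- j
          acc <- acc + u[j, c(i1, i2, i3)[mode]] * x[src[1], src[2], src[3]]
        }
        out[i1, i2, i3] <- acc
      }
    }
  }
  out
}

# Strictly positive random fixation stack (already-smoothed surrogate).
rand_fixation_stack <- function(d4, shape, seed) {
  set.seed(seed)
  maps <- lapply(seq_len(d4), function(f) {
    matrix(stats::runif(prod(shape), 0.01, 2), shape[1], shape[2])
  })
  structure(list(maps = maps, sigma = 1, epsilon = 1e-6),
            class = "fixation_map_stack")
}

# Small in-memory synthetic dataset + fast config for pipeline tests.
small_dataset <- function(n = 40, seed = 11) {
  gen_dataset(n_images = n, seed = seed)
}

fast_config <- function(...) {
  defaults <- list(d4 = 5L, extractors = "toy:g=2,toy:g=3", lambda = 0.1)
  do.call(pipeline_config, utils::modifyList(defaults, list(...)))
}
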