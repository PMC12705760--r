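## Independent brute-force oracles used across test files.  These
## deliberately avoid the package's own code paths (no upper_tri_vec,
## no cor shortcuts) so they can serve as cross-checks.

manual_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

## average ranks computed from first principles
manual_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

manual_spearman <- function(x, y) manual_pearson(manual_rank(x), manual_rank(y))

## pairwise correlation-distance matrix by explicit double loop
manual_corr_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- 1 - manual_pearson(m[i, ], m[j, ])
    }
  }
  d
}

## off-diagonal cells row-major (matches the package's documented order)
manual_utv <- function(m) {
  out <- numeric(0)
  n <- nrow(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) out <- c(out, m[i, j])
  out
}

## wrap a raw concepts x mask-voxel matrix as a trial_beta_set
make_beta_set <- function(B, mask, concepts = rownames(B), voxel_size = c(2, 2, 2)) {
  if (is.null(concepts)) concepts <- sprintf("cond_%02d", seq_len(nrow(B)))
  structure(list(concepts = concepts, betas = B, mask = mask, dim = dim(mask),
                 voxel_size = voxel_size, ar1_phi = 0),
            class = "trial_beta_set")
}

## rank-2 target RDM with distinct off-diagonal values (for harmonic planting)
rank2_target <- function(k, seed = 7) {
  sm <- make_semantic_space(k, 400, n_latent = 2, noise_sd = 0, seed = seed)
  correlation_distance_rdm(sm$vectors)
}
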