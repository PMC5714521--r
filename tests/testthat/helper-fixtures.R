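# shared fixtures, generated in code

# smooth deterministic test volume: Gaussian blob plus low-frequency ripple
smooth_volume <- function(n = 20, spacing = c(2, 2, 2), ripple = 0.1,
                          scale = 1, offset = 0) {
  x <- seq(-1, 1, length.out = n)
  a <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    zz <- x[k]^2
    a[, , k] <- outer(x, x, function(xi, yj)
      exp(-4 * (xi^2 + yj^2 + zz)) + ripple * sin(3 * xi) * cos(2 * yj))
  }
  volume(a * scale + offset, spacing = spacing)
}

# random blob-union mask on a small grid
random_mask <- function(dims, p_blob = 3) {
  m <- array(FALSE, dims)
  for (b in seq_len(p_blob)) {
    c0 <- runif(3, 1, dims)
    r <- runif(1, 1.2, max(dims) / 2.5)
    idx <- which(array(TRUE, dims), arr.ind = TRUE)
    d2 <- (idx[, 1] - c0[1])^2 + (idx[, 2] - c0[2])^2 + (idx[, 3] - c0[3])^2
    m[d2 <= r^2] <- TRUE
  }
  m
}

# brute-force surface distances: O(N*M) pairwise over boundary points
brute_surface <- function(S, T, spacing) {
  sb <- boundary_points(S, spacing)
  tb <- boundary_points(T, spacing)
  d <- apply(sb, 1, function(p) min(sqrt(colSums((t(tb) - p)^2))))
  list(DE = mean(d), HD = max(d))
}

# one cached 64^3 phantom case shared across test files
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(seed = 7) {
  key <- paste0("case", seed)
  if (is.null(.phantom_cache[[key]])) {
    an <- generate_anatomy(seed)
    .phantom_cache[[key]] <- warp_case(an, seed = seed)
  }
  .phantom_cache[[key]]
}

# small configuration for fast registration smoke tests
tiny_config <- function(seed = 1L) {
  reg_config(
    rigid_schedule = list(schedule_entry(4, 60, a = 4000),
                          schedule_entry(2, 40, a = 4000)),
    elastic_schedule = list(schedule_entry(2, 40, a = 1500, alpha = 0.602)),
    samples_rigid = 2000L, samples_elastic = 2000L, seed = seed)
}
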