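# Independent brute-force oracles and fixture builders shared across tests.
# The oracles deliberately use direct enumeration / dense matrix arithmetic
# rather than the package's transforms, so the two routes only share the
# mathematical definition.

# Brute-force sphere-fitting local thickness in voxel units on a logical
# array. r(q)^2 = min squared distance from q to any background voxel centre,
# capped by the squared distance to the first out-of-grid layer (faces are
# background); th(p) = 2 * max{ r(q) : ||p-q||^2 < r(q)^2 }.
oracle_local_thickness_vox <- function(mask) {
  dims <- dim(mask)
  coords <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                  seq_len(dims[3])))
  fg <- which(mask)
  bg <- which(!mask)
  A <- coords[fg, , drop = FALSE]
  face2 <- (pmin(A[, 1], dims[1] + 1 - A[, 1], A[, 2], dims[2] + 1 - A[, 2],
                 A[, 3], dims[3] + 1 - A[, 3]))^2
  r2 <- face2
  if (length(bg) > 0) {
    B <- coords[bg, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) - 2 * A %*% t(B) +
      outer(rep(1, nrow(A)), rowSums(B^2))
    r2 <- pmin(apply(d2, 1, min), face2)
  }
  D2 <- outer(rowSums(A^2), rep(1, nrow(A))) - 2 * A %*% t(A) +
    outer(rep(1, nrow(A)), rowSums(A^2))
  R2 <- matrix(r2, nrow(A), nrow(A), byrow = TRUE)
  covered <- D2 < R2 - 1e-9
  th <- 2 * sqrt(apply(ifelse(covered, R2, NA), 1, max, na.rm = TRUE))
  out <- array(NA_real_, dims)
  out[fg] <- th
  out
}

# Exhaustive Otsu: same fixed-width histogram, every split tried naively.
oracle_otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  vals <- centers[idx]
  best <- -Inf
  best_k <- 1L
  for (k in seq_len(n_bins - 1L)) {
    lo <- vals[idx <= k]
    hi <- vals[idx > k]
    if (length(lo) == 0L || length(hi) == 0L) next
    between <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (between > best + 1e-9) {
      best <- between
      best_k <- k
    }
  }
  breaks[best_k + 1L]
}

# smooth random blob mask: thresholded blurred white noise
random_blob_mask <- function(dims = c(16, 16, 16), fill = 0.4, sigma = 1.5,
                             seed = 1, spacing = 50) {
  field <- withr::with_seed(seed, stats::rnorm(prod(dims)))
  field <- trabmorph:::.gauss_blur_cpp(field, as.integer(dims),
                                       rep(sigma, 3))
  thr <- stats::quantile(field, 1 - fill, names = FALSE)
  binary_mask(array(field >= thr, dim = dims), spacing)
}

# plain Bernoulli mask
random_salt_mask <- function(dims = c(16, 16, 16), p = 0.5, seed = 1,
                             spacing = 50) {
  m <- withr::with_seed(seed, stats::runif(prod(dims)) < p)
  binary_mask(array(m, dim = dims), spacing)
}

# classical tie-free Spearman formula
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# axis-aligned thin fixtures on a 9^3 grid
line_mask <- function(spacing = 50) {
  a <- array(FALSE, c(9, 9, 9))
  a[, 5, 5] <- TRUE
  binary_mask(a, spacing)
}
plus_mask <- function(spacing = 50) {
  a <- array(FALSE, c(9, 9, 9))
  a[, 5, 5] <- TRUE
  a[5, , 5] <- TRUE
  binary_mask(a, spacing)
}
planar_y_mask <- function(spacing = 50) {
  a <- array(FALSE, c(9, 9, 9))
  a[1:9, 5, 5] <- TRUE   # two collinear arms
  a[5, 5:9, 5] <- TRUE   # third arm in the same plane
  binary_mask(a, spacing)
}
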