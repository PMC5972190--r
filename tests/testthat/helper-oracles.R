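# Independent brute-force oracles and fixture builders.  These deliberately
# avoid the package's computational paths: padding, window enumeration and
# weighting are re-derived from the operator definitions.

# symmetric (edge-included) reflection of 1-based index i into 1..n
refl1 <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * n
  j <- (i - 1L) %% p
  j[j < 0] <- j[j < 0] + p
  ifelse(j < n, j + 1L, p - j)
}

# reflect-pad a 3D array by r on every side
pad_reflect_arr <- function(x, r) {
  d <- dim(x)
  x[refl1(seq(1 - r, d[1] + r), d[1]),
    refl1(seq(1 - r, d[2] + r), d[2]),
    refl1(seq(1 - r, d[3] + r), d[3]), drop = FALSE]
}

rand_vol <- function(n, seed) {
  set.seed(seed)
  array(runif(prod(rep(n, 3))), dim = rep(n, 3))
}

# Guided filter by direct per-window enumeration: windows centered at every
# voxel of the reflect-padded input; A, B are box means (reflect padding) of
# the per-window coefficients.
oracle_guided <- function(x, r, eps) {
  d <- dim(x)
  P <- pad_reflect_arr(x, r)
  a <- array(0, d); b <- array(0, d)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    w <- P[k:(k + 2 * r), j:(j + 2 * r), i:(i + 2 * r)]
    m <- mean(w)
    v <- max(mean(w^2) - m^2, 0)
    ak <- v / (v + eps)
    a[k, j, i] <- ak
    b[k, j, i] <- (1 - ak) * m
  }
  Pa <- pad_reflect_arr(a, r); Pb <- pad_reflect_arr(b, r)
  A <- array(0, d); B <- array(0, d)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    A[k, j, i] <- mean(Pa[k:(k + 2 * r), j:(j + 2 * r), i:(i + 2 * r)])
    B[k, j, i] <- mean(Pb[k:(k + 2 * r), j:(j + 2 * r), i:(i + 2 * r)])
  }
  q <- A * x + B
  q[q < 0] <- 0; q[q > 1] <- 1
  q
}

# Bilateral filter by direct triple loop over the cubic support.
oracle_bilateral <- function(x, sigma, mu, S) {
  d <- dim(x)
  out <- array(0, d)
  offs <- as.matrix(expand.grid(dz = -S:S, dy = -S:S, dx = -S:S))
  spat <- exp(-0.5 * rowSums(offs^2) / sigma^2)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    zz <- refl1(k + offs[, 1], d[1])
    yy <- refl1(j + offs[, 2], d[2])
    xx <- refl1(i + offs[, 3], d[3])
    vals <- x[cbind(zz, yy, xx)]
    w <- spat * exp(-(vals - x[k, j, i])^2 / (2 * mu))
    out[k, j, i] <- sum(w * vals) / sum(w)
  }
  out
}

# Truncated Gaussian blur over the same cubic support (radial weights).
oracle_gauss_cube <- function(x, sigma, S) {
  d <- dim(x)
  out <- array(0, d)
  offs <- as.matrix(expand.grid(dz = -S:S, dy = -S:S, dx = -S:S))
  w <- exp(-0.5 * rowSums(offs^2) / sigma^2)
  w <- w / sum(w)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    zz <- refl1(k + offs[, 1], d[1])
    yy <- refl1(j + offs[, 2], d[2])
    xx <- refl1(i + offs[, 3], d[3])
    out[k, j, i] <- sum(w * x[cbind(zz, yy, xx)])
  }
  out
}

# Offsets of a structuring element, derived from its set definition.
oracle_se_offsets <- function(shape, r) {
  g <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  switch(shape,
         cross = g[rowSums(g != 0) <= 1, , drop = FALSE],
         box = g,
         ball = g[rowSums(g^2) <= r^2, , drop = FALSE])
}

# Erosion/dilation by direct offset enumeration.  pad = "replicate" clamps
# indices (grayscale); pad = "zero" treats outside as background (binary).
oracle_morph <- function(x, offsets, do_min, pad = "replicate") {
  d <- dim(x)
  out <- NULL
  for (q in seq_len(nrow(offsets))) {
    off <- offsets[q, ]
    iz <- seq_len(d[1]) + off[1]
    iy <- seq_len(d[2]) + off[2]
    ix <- seq_len(d[3]) + off[3]
    if (pad == "replicate") {
      sh <- x[pmin(pmax(iz, 1), d[1]), pmin(pmax(iy, 1), d[2]),
              pmin(pmax(ix, 1), d[3]), drop = FALSE]
    } else {
      sh <- array(0, d)
      okz <- iz >= 1 & iz <= d[1]; oky <- iy >= 1 & iy <= d[2]
      okx <- ix >= 1 & ix <= d[3]
      sh[okz, oky, okx] <- x[iz[okz], iy[oky], ix[okx], drop = FALSE]
    }
    out <- if (is.null(out)) sh else if (do_min) pmin(out, sh)
    else pmax(out, sh)
  }
  array(out, d)
}

# Two-sample Kolmogorov-Smirnov sup distance between empirical CDFs.
ks_sup_distance <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}

# Mask of random balls ("blobs") for idempotence/property sweeps.
random_blob_mask <- function(n, n_blobs, r_range, seed) {
  set.seed(seed)
  m <- array(FALSE, dim = rep(n, 3))
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  for (b in seq_len(n_blobs)) {
    ctr <- runif(3, 1, n)
    rad <- runif(1, r_range[1], r_range[2])
    hit <- (g$z - ctr[1])^2 + (g$y - ctr[2])^2 + (g$x - ctr[3])^2 <= rad^2
    m[as.matrix(g[hit, ])] <- TRUE
  }
  m
}

# Small, fast phantom for pipeline smoke tests.
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(64, 64, 64), speckle_count = 0, ...)
}
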