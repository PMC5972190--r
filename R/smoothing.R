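## Edge-preserving smoothing and intensity transforms.
## All filters are fully 3D (cubic windows/kernels) and use symmetric
## (reflect) border padding; histogram matching alone works per z-slice.

# 3D box mean with half-width r (separable line passes, reflect padding)
box_mean3 <- function(x, r, pad = "reflect") {
  d <- dim(x)
  pad_mode <- match(pad, c("reflect", "replicate", "constant")) - 1L
  for (ax in 0:2)
    x <- line_filter_cpp(x, d, ax, as.integer(r), 2L, pad_mode, 0)
  x
}

# Separable 3D Gaussian blur; kernel truncated at `radius` voxels
# (default ceiling(3*sigma)), reflect padding.
gaussian_blur3 <- function(x, sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  d <- dim(x)
  k <- exp(-0.5 * ((-radius):radius)^2 / sigma^2)
  k <- k / sum(k)
  for (ax in 0:2) x <- line_conv_cpp(x, d, ax, k)
  x
}

#' Guided filter (self-guided, 3D)
#'
#' Edge-preserving smoother expressing the output as a locally linear
#' function of the input, used here with the input as its own guide.  Over
#' every cubic window `w_k` of half-width `r` the local mean `m_k` and
#' variance `v_k` give coefficients `a_k = v_k / (v_k + eps)` and
#' `b_k = (1 - a_k) m_k`; the output at a voxel is `A x + B` where `A`, `B`
#' are the box means of `a`, `b` over the windows containing the voxel.
#' Borders are reflect-padded and the result is clipped to `[0, 1]`.
#'
#' With normalized intensities (variance at most 0.25) and the default
#' `eps = 1`, every `a_k <= 0.2`, so the filter acts close to a box mean on
#' flat noisy regions while retaining a fraction of strong edges.
#'
#' @param vol an [intensity_volume()] (or bare 3D array).
#' @param r window half-width in voxels (integer `>= 1`).
#' @param eps regularization on the normalized-intensity variance (`> 0`).
#' @return Filtered volume of the same class as `vol`.
#' @export
guided_filter <- function(vol, r = 1, eps = 1) {
  if (length(r) != 1 || is.na(r) || r < 1 || r != round(r))
    stop("guided filter radius r must be an integer >= 1", call. = FALSE)
  if (length(eps) != 1 || is.na(eps) || eps <= 0)
    stop("guided filter eps must be > 0", call. = FALSE)
  x <- as_volume_data(vol)
  m <- box_mean3(x, r)
  m2 <- box_mean3(x * x, r)
  v <- pmax(m2 - m * m, 0)
  a <- v / (v + eps)
  b <- (1 - a) * m
  q <- box_mean3(a, r) * x + box_mean3(b, r)
  rewrap(vol, clip01(q))
}

#' Bilateral filter (3D)
#'
#' Smoother weighting each neighbor by spatial distance (Gaussian with
#' standard deviation `sigma` voxels) and by intensity difference (Gaussian
#' range kernel `exp(-dI^2 / (2 mu))`, i.e. `mu` is the *variance* of the
#' range kernel in normalized-intensity units; the chain default
#' `mu = 0.00017` corresponds to a range standard deviation of about 0.013).
#' The neighborhood is the cube of half-width `support_radius`
#' (default `ceiling(2 sigma)`), reflect-padded at borders.  All weights are
#' strictly positive, so the output is a convex combination of neighborhood
#' values and never leaves their range.
#'
#' @param vol an [intensity_volume()] (or bare 3D array).
#' @param sigma spatial standard deviation in voxels (`> 0`).
#' @param mu variance of the intensity (range) kernel (`> 0`).
#' @param support_radius kernel truncation half-width in voxels; must be at
#'   least `ceiling(2 * sigma)`.
#' @return Filtered volume of the same class as `vol`.
#' @export
bilateral_filter <- function(vol, sigma = 1, mu = 0.00017,
                             support_radius = ceiling(2 * sigma)) {
  if (length(sigma) != 1 || is.na(sigma) || sigma <= 0)
    stop("bilateral sigma must be > 0", call. = FALSE)
  if (length(mu) != 1 || is.na(mu) || mu <= 0)
    stop("bilateral mu must be > 0", call. = FALSE)
  if (support_radius < ceiling(2 * sigma))
    stop("support_radius must be >= ceiling(2*sigma)", call. = FALSE)
  x <- as_volume_data(vol)
  q <- bilateral3d_cpp(x, dim(x), sigma, mu, as.integer(support_radius))
  rewrap(vol, q)
}

#' Unsharp-mask sharpening (3D)
#'
#' `q = clip(I + amount * (I - G(I)), 0, 1)` with a 3D Gaussian blur `G`
#' of standard deviation `blur_sigma` voxels (reflect borders).  Visually
#' counteracts the blurring introduced by the smoothing chain.
#'
#' @param vol an [intensity_volume()] (or bare 3D array).
#' @param amount gain `alpha >= 0`; 0 is the identity.
#' @param blur_sigma Gaussian standard deviation in voxels (`> 0`).
#' @return Sharpened volume of the same class as `vol`.
#' @export
sharpen <- function(vol, amount = 1, blur_sigma = 1) {
  if (length(amount) != 1 || is.na(amount) || amount < 0)
    stop("sharpen amount must be >= 0", call. = FALSE)
  if (length(blur_sigma) != 1 || is.na(blur_sigma) || blur_sigma <= 0)
    stop("sharpen blur_sigma must be > 0", call. = FALSE)
  x <- as_volume_data(vol)
  if (amount == 0) return(rewrap(vol, x))
  q <- x + amount * (x - gaussian_blur3(x, blur_sigma))
  rewrap(vol, clip01(q))
}

#' Per-slice histogram matching along the stack axis
#'
#' Remaps every z-slice through the monotone map `F_ref^-1 o F_k` (empirical
#' quantile mapping with linear interpolation between `n_quantiles` knots) so
#' all slices share the reference slice's intensity distribution.  This
#' equalizes contrast along the scan axis, removing slice-to-slice intensity
#' drift before the iterated filtering.
#'
#' @param vol an [intensity_volume()] (or bare 3D array).
#' @param reference_slice 1-based z index of the reference slice; defaults to
#'   the middle slice.
#' @param n_quantiles number of interpolation knots (`>= 2`).
#' @return Matched volume of the same class as `vol`; the reference slice is
#'   returned unchanged (up to interpolation error below `1/n_quantiles`).
#' @export
histogram_match_slices <- function(vol, reference_slice = NULL,
                                   n_quantiles = 1024) {
  x <- as_volume_data(vol)
  nz <- dim(x)[1]
  if (is.null(reference_slice)) reference_slice <- max(1L, nz %/% 2L)
  reference_slice <- as.integer(reference_slice)
  if (is.na(reference_slice) || reference_slice < 1 || reference_slice > nz)
    stop("reference_slice must be in [1, ", nz, "]", call. = FALSE)
  if (n_quantiles < 2) stop("n_quantiles must be >= 2", call. = FALSE)
  ref <- x[reference_slice, , ]
  if (max(ref) - min(ref) == 0) {
    # a fully constant volume already matches its reference everywhere
    if (max(x) - min(x) == 0) return(rewrap(vol, x))
    stop("reference slice is constant: histogram mapping is undefined ",
         "(degenerate reference)", call. = FALSE)
  }
  probs <- seq(0, 1, length.out = n_quantiles)
  qref <- quantile(ref, probs, names = FALSE, type = 7)
  out <- x
  for (k in seq_len(nz)) {
    if (k == reference_slice) next
    out[k, , ] <- quantile_map(x[k, , ], qref, probs)
  }
  rewrap(vol, clip01(out))
}

# Map values through F_k^-1 given the reference quantiles qref at probs.
quantile_map <- function(slice, qref, probs) {
  qk <- quantile(slice, probs, names = FALSE, type = 7)
  # collapse duplicate source knots (flat parts of F_k^-1), keeping the mean
  # target so the map stays monotone and well defined
  if (anyDuplicated(qk)) {
    agg <- vapply(split(qref, qk), mean, numeric(1))
    qk <- as.numeric(names(agg))
    qref_u <- unname(agg)
  } else qref_u <- qref
  if (length(qk) == 1L) return(array(qref_u, dim = dim(slice)))
  mapped <- approx(qk, qref_u, xout = as.vector(slice), rule = 2,
                   ties = "ordered")$y
  array(mapped, dim = dim(slice))
}

# Return filtered data in the same wrapper class as the input.
rewrap <- function(template, data) {
  if (inherits(template, "intensity_volume"))
    return(intensity_volume(data, spacing = template$spacing,
                            source_dtype = template$source_dtype,
                            name = template$name))
  if (inherits(template, "binary_mask"))
    return(binary_mask(data, spacing = template$spacing))
  data
}
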