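#' Structuring element for 3D morphology
#'
#' * `cross`: the union of three axis-aligned segments through the origin —
#'   all offsets with at most one nonzero coordinate, each of magnitude at
#'   most `radius` (the 3D analogue of a 2D cross matrix).
#' * `box`: the full `(2r+1)^3` cube.
#' * `ball`: offsets with Euclidean norm at most `radius`.
#'
#' `cross(0)` and `box(0)` degenerate to the origin.  `radius` may be a
#' single integer (isotropic) or one integer per `(z, y, x)` axis for cross
#' and box shapes.
#'
#' @param shape `"cross"`, `"box"` or `"ball"`.
#' @param radius non-negative integer radius in voxels (length 1 or 3).
#' @return An object of class `structuring_element`.
#' @examples
#' se_cross1 <- structuring_element("cross", 1)   # center + 6 face neighbors
#' @export
structuring_element <- function(shape = c("cross", "box", "ball"), radius) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (anyNA(radius) || any(radius < 0))
    stop("structuring element radius must be a non-negative integer",
         call. = FALSE)
  if (!length(radius) %in% c(1L, 3L))
    stop("radius must have length 1 or 3", call. = FALSE)
  if (shape == "ball" && length(radius) != 1L)
    stop("ball radius must be isotropic (length 1)", call. = FALSE)
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  structure(list(shape = shape, radius = radius),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> %s, radius (z,y,x) = %s\n", x$shape,
              paste(x$radius, collapse = " ")))
  invisible(x)
}

# Offsets (n x 3 integer matrix, columns z,y,x) of a structuring element;
# used for ball morphology and exposed for enumeration-based checks.
se_offsets <- function(se) {
  r <- se$radius
  if (se$shape == "cross") {
    offs <- rbind(c(0L, 0L, 0L))
    for (ax in 1:3) {
      if (r[ax] == 0) next
      d <- setdiff(seq.int(-r[ax], r[ax]), 0L)
      m <- matrix(0L, length(d), 3)
      m[, ax] <- d
      offs <- rbind(offs, m)
    }
    return(offs)
  }
  g <- expand.grid(z = seq.int(-r[1], r[1]), y = seq.int(-r[2], r[2]),
                   x = seq.int(-r[3], r[3]))
  m <- as.matrix(g)
  storage.mode(m) <- "integer"
  if (se$shape == "ball")
    m <- m[rowSums(m^2) <= r[1]^2, , drop = FALSE]
  unname(m)
}

check_se_fit <- function(se, d) {
  if (any(2L * se$radius + 1L > min(d)))
    warning("structuring element (radius ", paste(se$radius, collapse = "x"),
            ") exceeds the smallest axis (", min(d),
            " voxels); result degenerates toward a constant", call. = FALSE)
}

# Core min/max morphology.  Grayscale pads by edge replication; binary pads
# with background (0), so binary components touching a volume face erode
# from the face side.
morph_minmax <- function(x, se, do_min, binary) {
  d <- dim(x)
  type <- if (do_min) 0L else 1L
  pad_mode <- if (binary) 2L else 1L   # constant-0 vs replicate
  r <- se$radius
  if (se$shape == "box") {
    for (ax in 0:2)
      if (r[ax + 1] > 0)
        x <- line_filter_cpp(x, d, ax, r[ax + 1], type, pad_mode, 0)
    return(x)
  }
  if (se$shape == "cross") {
    out <- x  # the SE always contains the origin
    for (ax in 0:2) {
      if (r[ax + 1] == 0) next
      lx <- line_filter_cpp(x, d, ax, r[ax + 1], type, pad_mode, 0)
      out <- if (do_min) pmin(out, lx) else pmax(out, lx)
    }
    dim(out) <- d
    return(out)
  }
  # ball: direct offset enumeration via shifted copies
  offs <- se_offsets(se)
  out <- NULL
  for (i in seq_len(nrow(offs))) {
    sh <- shift_array(x, offs[i, ], pad_mode, 0)
    out <- if (is.null(out)) sh
    else if (do_min) pmin(out, sh) else pmax(out, sh)
  }
  dim(out) <- d
  out
}

# x shifted so output(p) = x(p + off); out-of-range handled by replicate
# (pad_mode 1) or constant value (pad_mode 2).
shift_array <- function(x, off, pad_mode, pad_value) {
  d <- dim(x)
  idx <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + off[ax]
    if (pad_mode == 1L) pmin(pmax(i, 1L), d[ax]) else i
  })
  if (pad_mode == 1L) return(x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  out <- array(pad_value, dim = d)
  src <- lapply(1:3, function(ax) idx[[ax]] >= 1L & idx[[ax]] <= d[ax])
  out[src[[1]], src[[2]], src[[3]]] <-
    x[idx[[1]][src[[1]]], idx[[2]][src[[2]]], idx[[3]][src[[3]]],
      drop = FALSE]
  out
}

morph_apply <- function(vol, se, do_min) {
  if (!inherits(se, "structuring_element"))
    stop("se must be a structuring_element", call. = FALSE)
  binary <- inherits(vol, "binary_mask")
  x <- as_volume_data(vol)
  if (is.logical(x)) { binary <- TRUE; x <- x * 1 }
  check_se_fit(se, dim(x))
  out <- morph_minmax(x, se, do_min, binary)
  if (binary && inherits(vol, "binary_mask")) return(rewrap(vol, out != 0))
  rewrap(vol, out)
}

#' Grayscale / binary erosion and dilation
#'
#' Erosion takes the minimum (dilation the maximum) of the input over the
#' structuring element translated to every voxel.  Grayscale volumes are
#' padded by edge replication; binary masks are padded with background, so
#' mask components touching a volume face are eroded from that side.
#' Erosion and dilation by a cross are computed as the pointwise min/max of
#' three 1D van Herk line filters and are exactly equal to direct offset
#' enumeration; box elements use separable line passes.
#'
#' @param vol an [intensity_volume()], [binary_mask()] or 3D array.
#' @param se a [structuring_element()].
#' @return Same type as `vol`.
#' @export
erode <- function(vol, se) morph_apply(vol, se, do_min = TRUE)

#' @rdname erode
#' @export
dilate <- function(vol, se) morph_apply(vol, se, do_min = FALSE)

#' Morphological opening and closing
#'
#' `opening = dilate(erode(v))` removes bright structures the element cannot
#' fit into; `closing = erode(dilate(v))` fills dark gaps.  Voxelwise,
#' `opening(v) <= v <= closing(v)`, and both are idempotent.
#'
#' @inheritParams erode
#' @return Same type as `vol`.
#' @export
opening <- function(vol, se) dilate(erode(vol, se), se)

#' @rdname opening
#' @export
closing <- function(vol, se) erode(dilate(vol, se), se)

#' White top-hat transform
#'
#' `vol - opening(vol, se)`: extracts bright structures that are narrower
#' than the structuring element in at least one of its directions (for the
#' large cross element of the 3D chain, anything that cannot contain all
#' three 129-voxel arms — thin hyperdense neural structures), while broad
#' structures such as bone are suppressed to near zero.  Output is
#' non-negative.
#'
#' @inheritParams erode
#' @return An [intensity_volume()] (or array) of non-negative residuals.
#' @export
white_tophat <- function(vol, se) {
  x <- as_volume_data(vol)
  if (is.logical(x)) stop("white_tophat expects a grayscale volume",
                          call. = FALSE)
  op <- as_volume_data(opening(vol, se))
  rewrap(vol, pmax(x - op, 0))
}

#' Threshold a volume into a binary mask
#'
#' Foreground iff intensity `>= threshold` (ties at the threshold are
#' foreground).  The threshold is an absolute normalized intensity, meaningful
#' across volumes because normalization divides by the sample-type maximum.
#'
#' @param vol an [intensity_volume()] or 3D array.
#' @param threshold normalized intensity strictly inside `(0, 1)`.
#' @return A [binary_mask()].
#' @export
binarize <- function(vol, threshold) {
  if (length(threshold) != 1 || is.na(threshold) || threshold <= 0 ||
      threshold >= 1)
    stop("binarize threshold must lie strictly inside (0, 1)", call. = FALSE)
  x <- as_volume_data(vol)
  spacing <- if (inherits(vol, "intensity_volume")) vol$spacing else c(1, 1, 1)
  binary_mask(x >= threshold, spacing = spacing)
}

#' Connected components of a binary mask
#'
#' Labels foreground voxels under 6- (faces only) or 26- (faces, edges,
#' corners) connectivity.
#'
#' @param mask a [binary_mask()] or logical/0-1 3D array.
#' @param connectivity 6 or 26.
#' @return A list with `labels` (integer 3D array, 0 = background, components
#'   numbered from 1) and `sizes` (integer vector of voxel counts, one per
#'   component).
#' @export
connected_components <- function(mask, connectivity = 26) {
  x <- as_volume_data(mask)
  if (!is.logical(x)) x <- array(x != 0, dim = dim(x))
  labels <- label_components_cpp(x, dim(x), as.integer(connectivity))
  n <- max(labels)
  sizes <- if (n > 0) tabulate(labels[labels > 0L], nbins = n) else integer(0)
  list(labels = labels, sizes = sizes)
}

#' Geodesic opening of a binary mask
#'
#' Erodes the mask by a cubic box of half-width `size` and reconstructs, by
#' geodesic dilation under the original mask, every component that survives
#' the erosion.  Equivalently: a connected component is kept voxel-identically
#' iff it contains at least one voxel of the eroded marker; all other
#' components — the small unconnected objects that resemble noise — are
#' removed entirely.  The output is always a subset of the input and the
#' operation is idempotent.
#'
#' @param mask a [binary_mask()] or logical/0-1 3D array.
#' @param size erosion half-width in voxels (`>= 1`); the default 15 removes
#'   components that cannot contain a 31^3 box.
#' @param connectivity reconstruction connectivity, 26 (default; preserves
#'   thin diagonal fiber paths) or 6.
#' @return Same type as `mask`.
#' @export
geodesic_opening <- function(mask, size = 15, connectivity = 26) {
  if (length(size) != 1 || is.na(size) || size < 1 || size != round(size))
    stop("geodesic opening size must be an integer >= 1", call. = FALSE)
  x <- as_volume_data(mask)
  if (!is.logical(x)) x <- array(x != 0, dim = dim(x))
  marker <- as_volume_data(erode(binary_mask(x), structuring_element("box",
                                                                     size)))
  if (!any(marker)) return(rewrap(mask, array(
    if (inherits(mask, "binary_mask") || is.logical(as_volume_data(mask)))
      FALSE else 0, dim = dim(x))))
  cc <- connected_components(x, connectivity)
  keep <- unique(cc$labels[marker])
  keep <- keep[keep > 0L]
  out <- array(cc$labels %in% keep, dim = dim(x))
  if (inherits(mask, "binary_mask") || is.logical(as_volume_data(mask)))
    rewrap(mask, out)
  else rewrap(mask, out * 1)
}

#' Apply a binary mask to a volume
#'
#' Voxelwise product: voxels outside the mask become exactly 0, voxels inside
#' are unchanged.
#'
#' @param vol an [intensity_volume()] or 3D array.
#' @param mask a [binary_mask()] or logical/0-1 array of the same shape.
#' @return Same type as `vol`.
#' @export
apply_mask <- function(vol, mask) {
  x <- as_volume_data(vol)
  m <- as_volume_data(mask)
  if (!identical(dim(x), dim(m)))
    stop("volume shape (", paste(dim(x), collapse = "x"),
         ") and mask shape (", paste(dim(m), collapse = "x"),
         ") differ (dimension error)", call. = FALSE)
  rewrap(vol, x * (m != 0))
}
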