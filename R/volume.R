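#' Intensity volume container
#'
#' A 3D scalar field holding normalized micro-CT intensities in `[0, 1]`,
#' with axis order `(z, y, x)` where `z` is the slice/stack (acquisition)
#' axis, so slice `k` is `vol$data[k, , ]`.  Voxel spacing is carried as
#' descriptive metadata in micrometres; all filters operate in voxel units.
#'
#' @param data numeric 3D array with all values finite and in `[0, 1]`.
#' @param spacing numeric length-3 vector `(sz, sy, sx)` of voxel sizes in
#'   micrometres; strictly positive.
#' @param source_dtype character, the on-disk sample type the data came from
#'   (e.g. `"uint16"` for 16-bit micro-CT reconstructions, `"float32"`).
#' @param name free-text provenance label.
#' @return An object of class `intensity_volume` with fields `data`,
#'   `spacing`, `source_dtype`, `name`.
#' @examples
#' v <- intensity_volume(array(runif(64), c(4, 4, 4)))
#' dim(v)
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1),
                             source_dtype = "float32", name = "") {
  data <- validate_volume_data(data)
  spacing <- validate_spacing(spacing)
  structure(list(data = data, spacing = spacing,
                 source_dtype = as.character(source_dtype)[1],
                 name = as.character(name)[1]),
            class = "intensity_volume")
}

#' Binary mask container
#'
#' A 3D boolean field congruent with an [intensity_volume()]; produced by
#' [binarize()] and the morphological mask-cleaning operators, or read from a
#' manual segmentation made in an external tool.
#'
#' @param data logical (or coercible 0/1 numeric) 3D array.
#' @param spacing numeric length-3 `(sz, sy, sx)` voxel sizes in micrometres.
#' @return An object of class `binary_mask` with fields `data` (logical
#'   array) and `spacing`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array", call. = FALSE)
  if (is.numeric(data)) {
    if (anyNA(data) || any(!is.finite(data)))
      stop("mask data contains non-finite values", call. = FALSE)
    data <- array(data != 0, dim = dim(data))
  } else if (is.logical(data)) {
    if (anyNA(data)) stop("mask data contains NA", call. = FALSE)
  } else {
    stop("mask data must be logical or numeric", call. = FALSE)
  }
  structure(list(data = data, spacing = validate_spacing(spacing)),
            class = "binary_mask")
}

validate_volume_data <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array (z, y, x), got ",
         if (is.null(dim(data))) "a vector" else
           paste0(length(dim(data)), "D"), call. = FALSE)
  if (any(dim(data) < 1L)) stop("every axis must have length >= 1",
                                call. = FALSE)
  if (!is.numeric(data)) stop("volume data must be numeric", call. = FALSE)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  if (min(data) < 0 || max(data) > 1)
    stop("normalized intensities must lie in [0, 1]; range is [",
         signif(min(data), 4), ", ", signif(max(data), 4), "]",
         call. = FALSE)
  data
}

validate_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (sz, sy, sx) in um",
         call. = FALSE)
  spacing
}

#' @export
dim.intensity_volume <- function(x) dim(x$data)

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' @export
as.array.intensity_volume <- function(x, ...) x$data

#' @export
as.array.binary_mask <- function(x, ...) x$data

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_volume> %d x %d x %d voxels (z,y,x)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (um): %g x %g x %g | source dtype: %s\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$source_dtype))
  cat(sprintf("  intensity range [%.5f, %.5f], mean %.5f\n",
              min(x$data), max(x$data), mean(x$data)))
  if (nzchar(x$name)) cat("  name:", x$name, "\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels (z,y,x)\n", d[1], d[2], d[3]))
  cat(sprintf("  foreground: %d of %d voxels (%.2f%%)\n", sum(x$data),
              length(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' @export
summary.intensity_volume <- function(object, ...) {
  v <- object$data
  out <- c(min = min(v), q25 = unname(quantile(v, 0.25)), median = median(v),
           mean = mean(v), q75 = unname(quantile(v, 0.75)), max = max(v),
           sd = sd(v))
  class(out) <- "summaryDefault"
  out
}

as_volume_data <- function(x) {
  if (inherits(x, "intensity_volume") || inherits(x, "binary_mask"))
    return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected an intensity_volume, binary_mask or 3D array", call. = FALSE)
}

same_shape <- function(a, b) identical(dim(as_volume_data(a)),
                                       dim(as_volume_data(b)))

#' @importFrom stats median
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
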