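## Quantitative surrogates for the qualitative assessment of noise,
## contrast and segmentation completeness.

truth_label_mask <- function(truth, target_label) {
  labels <- if (inherits(truth, "phantom_truth")) truth$labels
  else if (is.array(truth) && length(dim(truth)) == 3L) truth
  else stop("truth must be a phantom_truth or a 3D label array",
            call. = FALSE)
  lmap <- phantom_labels()
  if (is.character(target_label)) {
    if (!target_label %in% names(lmap))
      stop("unknown label '", target_label, "'; known labels: ",
           paste(names(lmap), collapse = ", "), call. = FALSE)
    target_label <- lmap[[target_label]]
  }
  if (!target_label %in% lmap)
    stop("unknown label id ", target_label, "; known ids: ",
         paste(lmap, collapse = ", "), call. = FALSE)
  array(labels == target_label, dim = dim(labels))
}

#' Score a predicted segmentation against phantom ground truth
#'
#' Computes the Dice coefficient, precision and recall on voxel counts,
#' excluding from the false-positive/false-negative counts every voxel
#' within `boundary_tolerance` (Euclidean) of the truth boundary — a band
#' that absorbs the 1-2 voxel partial-volume uncertainty the phantom's blur
#' introduces.  Also reports component bookkeeping: how many truth
#' components are detected (overlap the prediction) and how many predicted
#' components are spurious (no voxel within the tolerance band of the
#' truth).
#'
#' @param pred a [binary_mask()] (or logical array), the predicted mask.
#' @param truth a `phantom_truth` (or integer label array).
#' @param target_label label name (`"nerve"`, `"speckle"`, ...) or id (0-4).
#' @param boundary_tolerance band half-width in voxels (`>= 0`).
#' @param connectivity 26 or 6, for component counting.
#' @return An object of class `segmentation_score`: `dice`, `precision`,
#'   `recall`, `tp`, `fp`, `fn`, `true_components_detected`,
#'   `true_components_total`, `false_components`, `boundary_tolerance`.
#' @export
score_segmentation <- function(pred, truth, target_label = "nerve",
                               boundary_tolerance = 1, connectivity = 26) {
  if (boundary_tolerance < 0 || boundary_tolerance != round(boundary_tolerance))
    stop("boundary_tolerance must be a non-negative integer", call. = FALSE)
  p <- as_volume_data(pred)
  if (!is.logical(p)) p <- array(p != 0, dim = dim(p))
  tmask <- truth_label_mask(truth, target_label)
  if (!identical(dim(p), dim(tmask)))
    stop("prediction shape (", paste(dim(p), collapse = "x"),
         ") and truth shape (", paste(dim(tmask), collapse = "x"),
         ") differ", call. = FALSE)
  if (boundary_tolerance > 0) {
    ball <- structuring_element("ball", boundary_tolerance)
    tdil <- as_volume_data(dilate(binary_mask(tmask), ball))
    tero <- as_volume_data(erode(binary_mask(tmask), ball))
    band <- tdil & !tero
  } else {
    tdil <- tmask
    band <- array(FALSE, dim = dim(tmask))
  }
  tp <- sum(p & tmask)
  fp <- sum(p & !tmask & !band)
  fn <- sum(!p & tmask & !band)
  dice <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  cc_t <- connected_components(tmask, connectivity)
  cc_p <- connected_components(p, connectivity)
  detected <- 0L
  if (length(cc_t$sizes) > 0) {
    hit <- unique(cc_t$labels[p & tmask])
    detected <- length(hit[hit > 0L])
  }
  false_comp <- 0L
  if (length(cc_p$sizes) > 0) {
    touching <- unique(cc_p$labels[tdil])
    false_comp <- length(cc_p$sizes) - length(touching[touching > 0L])
  }
  structure(list(
    dice = dice,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn,
    true_components_detected = detected,
    true_components_total = length(cc_t$sizes),
    false_components = false_comp,
    boundary_tolerance = boundary_tolerance),
    class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf(
    "<segmentation_score> dice %.4f | precision %.4f | recall %.4f\n",
    x$dice, x$precision, x$recall))
  cat(sprintf("  TP %d, FP %d, FN %d (boundary tolerance %d voxel%s)\n",
              x$tp, x$fp, x$fn, x$boundary_tolerance,
              if (x$boundary_tolerance == 1) "" else "s"))
  cat(sprintf("  truth components detected: %d / %d; false components: %d\n",
              x$true_components_detected, x$true_components_total,
              x$false_components))
  invisible(x)
}

#' Count truth components surviving in a predicted mask
#'
#' How many connected components of the given truth label contain at least
#' one predicted-foreground voxel.  With `target_label = "speckle"` this
#' counts injected noise blobs the segmentation failed to delete.
#'
#' @inheritParams score_segmentation
#' @return Integer count.
#' @export
surviving_components <- function(pred, truth, target_label = "speckle",
                                 connectivity = 26) {
  p <- as_volume_data(pred)
  if (!is.logical(p)) p <- array(p != 0, dim = dim(p))
  tmask <- truth_label_mask(truth, target_label)
  cc <- connected_components(tmask, connectivity)
  if (length(cc$sizes) == 0) return(0L)
  hit <- unique(cc$labels[p & tmask])
  length(hit[hit > 0L])
}

#' Noise and contrast statistics over two regions
#'
#' Sample mean and standard deviation of the volume inside two disjoint,
#' non-empty regions, plus the contrast `|mean_a - mean_b| / pooled_sd`.
#' When both regions are constant the pooled standard deviation is zero and
#' the contrast is degenerate: `NA` is returned with `degenerate = TRUE` and
#' a warning.
#'
#' @param vol an [intensity_volume()] or 3D array.
#' @param region_a,region_b [binary_mask()]s or logical arrays, non-empty
#'   and disjoint, congruent with `vol`.
#' @return A list: `mean_a`, `mean_b`, `std_a`, `std_b`, `contrast`,
#'   `degenerate`.
#' @export
noise_contrast_stats <- function(vol, region_a, region_b) {
  x <- as_volume_data(vol)
  a <- as_volume_data(region_a); a <- if (is.logical(a)) a else a != 0
  b <- as_volume_data(region_b); b <- if (is.logical(b)) b else b != 0
  if (!identical(dim(x), dim(a)) || !identical(dim(x), dim(b)))
    stop("regions must be congruent with the volume", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na == 0 || nb == 0) stop("regions must be non-empty", call. = FALSE)
  if (any(a & b)) stop("regions must be disjoint", call. = FALSE)
  va <- x[a]; vb <- x[b]
  sa <- if (na > 1) sd(va) else 0
  sb <- if (nb > 1) sd(vb) else 0
  pooled <- sqrt((max(na - 1, 0) * sa^2 + max(nb - 1, 0) * sb^2) /
                   max(na + nb - 2, 1))
  degenerate <- pooled == 0
  if (degenerate)
    warning("pooled standard deviation is zero: contrast is undefined",
            call. = FALSE)
  list(mean_a = mean(va), mean_b = mean(vb), std_a = sa, std_b = sb,
       contrast = if (degenerate) NA_real_ else
         abs(mean(va) - mean(vb)) / pooled,
       degenerate = degenerate)
}
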