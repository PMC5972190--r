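#' Pipeline configuration
#'
#' Collects every parameter of the two processing chains.  The defaults are
#' the reference protocol settings: guided filter radius 1, `eps = 1`;
#' bilateral filter `sigma = 1, mu = 0.00017`; top-hat cross element of
#' radius 64; binarization threshold 0.035; geodesic opening size 15;
#' closing size 2 (box); dilation cross radius 1; and
#' `block_iterations = 4` repeats of the (guided, bilateral, guided) filter
#' triplet, i.e. 12 nonlinear-filter applications in the 2D chain.  Sizes
#' printed without a shape (closing, geodesic opening) use box elements;
#' cross elements are used exactly where a cross matrix is named.
#'
#' @param guided list with `r`, `eps`.
#' @param bilateral list with `sigma`, `mu`, optional `support_radius`.
#' @param sharpen list with `amount`, `blur_sigma` (declared defaults; the
#'   sharpening step has no prescribed parameters).
#' @param histogram list with `reference_slice` (`NULL` = middle slice) and
#'   `n_quantiles`.
#' @param block_iterations repeats of the (guided, bilateral, guided)
#'   triplet in the 2D chain.
#' @param tophat_se,closing_se,dilation_se [structuring_element()]s of the
#'   3D chain.
#' @param binarize_threshold absolute normalized-intensity threshold.
#' @param geodesic_size erosion half-width of the geodesic opening.
#' @param connectivity 26 or 6, used by reconstruction and component
#'   bookkeeping.
#' @param manual_mask_path optional path of a manual mask to intersect with
#'   the automatic mask (an exclusion of circumjacent structures).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(guided = list(r = 1, eps = 1),
                            bilateral = list(sigma = 1, mu = 0.00017),
                            sharpen = list(amount = 1, blur_sigma = 1),
                            histogram = list(reference_slice = NULL,
                                             n_quantiles = 1024),
                            block_iterations = 4,
                            tophat_se = structuring_element("cross", 64),
                            binarize_threshold = 0.035,
                            geodesic_size = 15,
                            closing_se = structuring_element("box", 2),
                            dilation_se = structuring_element("cross", 1),
                            connectivity = 26,
                            manual_mask_path = NULL) {
  cfg <- structure(list(
    guided = guided, bilateral = bilateral, sharpen = sharpen,
    histogram = histogram, block_iterations = block_iterations,
    tophat_se = as_se(tophat_se), binarize_threshold = binarize_threshold,
    geodesic_size = geodesic_size, closing_se = as_se(closing_se),
    dilation_se = as_se(dilation_se), connectivity = connectivity,
    manual_mask_path = manual_mask_path), class = "pipeline_config")
  validate_config(cfg)
}

as_se <- function(x) {
  if (inherits(x, "structuring_element")) return(x)
  if (is.list(x) && !is.null(x$shape) && !is.null(x$radius))
    return(structuring_element(x$shape, x$radius))
  stop("expected a structuring_element or list(shape=, radius=)",
       call. = FALSE)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg$guided), is.list(cfg$bilateral))
  if (cfg$guided$r < 1 || cfg$guided$eps <= 0)
    stop("config: guided filter needs r >= 1 and eps > 0", call. = FALSE)
  if (cfg$bilateral$sigma <= 0 || cfg$bilateral$mu <= 0)
    stop("config: bilateral filter needs sigma > 0 and mu > 0",
         call. = FALSE)
  if (cfg$sharpen$amount < 0 || cfg$sharpen$blur_sigma <= 0)
    stop("config: sharpen needs amount >= 0 and blur_sigma > 0",
         call. = FALSE)
  if (cfg$block_iterations < 0 ||
      cfg$block_iterations != round(cfg$block_iterations))
    stop("config: block_iterations must be a non-negative integer",
         call. = FALSE)
  if (cfg$binarize_threshold <= 0 || cfg$binarize_threshold >= 1)
    stop("config: binarize_threshold must lie in (0, 1)", call. = FALSE)
  if (cfg$geodesic_size < 1)
    stop("config: geodesic_size must be >= 1", call. = FALSE)
  if (!cfg$connectivity %in% c(6, 26))
    stop("config: connectivity must be 6 or 26", call. = FALSE)
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  2D chain: histogram match (ref %s, %d knots) -> %d x\n",
              if (is.null(x$histogram$reference_slice)) "middle slice"
              else x$histogram$reference_slice, x$histogram$n_quantiles,
              x$block_iterations))
  cat(sprintf("    (guided r=%g eps=%g; bilateral sigma=%g mu=%g; guided)",
              x$guided$r, x$guided$eps, x$bilateral$sigma, x$bilateral$mu))
  cat(sprintf(" -> sharpen (amount %g, sigma %g)\n", x$sharpen$amount,
              x$sharpen$blur_sigma))
  cat(sprintf("  3D chain: guided -> tophat (%s r=%d) -> binarize %g -> ",
              x$tophat_se$shape, x$tophat_se$radius[1], x$binarize_threshold))
  cat(sprintf("geodesic %d -> closing (%s r=%d) -> dilate (%s r=%d) -> mask\n",
              x$geodesic_size, x$closing_se$shape, x$closing_se$radius[1],
              x$dilation_se$shape, x$dilation_se$radius[1]))
  cat(sprintf("  connectivity: %d\n", x$connectivity))
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' The serialized file round-trips losslessly through [read_config()]
#' (missing keys fall back to the defaults of [pipeline_config()]).
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- unclass(cfg)
  for (f in c("tophat_se", "closing_se", "dilation_se"))
    lst[[f]] <- list(shape = lst[[f]]$shape,
                     radius = as.integer(lst[[f]]$radius))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'",
                               call. = FALSE)
  lst <- yaml::read_yaml(path)
  config_from_list(lst)
}

config_from_list <- function(lst) {
  defaults <- pipeline_config()
  known <- names(unclass(defaults))
  unknown <- setdiff(names(lst), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  merged <- modifyList(unclass(defaults), lst)
  do.call(pipeline_config, merged)
}

## ---- pipeline runners --------------------------------------------------

stage_stats <- function(x) {
  if (inherits(x, "binary_mask") || is.logical(as_volume_data(x))) {
    m <- as_volume_data(x)
    data.frame(min = 0, max = 1, mean = mean(m), sd = sd(as.numeric(m)),
               n_fg = sum(m))
  } else {
    v <- as_volume_data(x)
    data.frame(min = min(v), max = max(v), mean = mean(v), sd = sd(v),
               n_fg = NA_integer_)
  }
}

run_stage <- function(report, stage, fun, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(fun(), error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  elapsed <- proc.time()[["elapsed"]] - t0
  row <- cbind(data.frame(stage = stage, seconds = round(elapsed, 3)),
               stage_stats(out))
  if (verbose)
    message(sprintf("  [%s] %.2fs (mean %.5f)", stage, elapsed, row$mean))
  list(out = out, report = rbind(report, row))
}

#' Run the 2D-visualization noise-reduction chain
#'
#' Applies, in order: per-slice histogram matching to a reference slice,
#' `block_iterations` repeats of the (guided filter, bilateral filter,
#' guided filter) triplet, and unsharp-mask sharpening.  Deterministic: the
#' same input and configuration give a bit-identical output.
#'
#' @param vol an [intensity_volume()].
#' @param cfg a [pipeline_config()].
#' @param verbose log per-stage progress to stderr.
#' @return An object of class `otoct_run_2d` with fields `volume` (the
#'   processed [intensity_volume()]), `report` (per-stage data.frame:
#'   duration in seconds, min/max/mean/sd) and `config`.
#' @export
run_pipeline_2d <- function(vol, cfg = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(vol, "intensity_volume"))
  cfg <- validate_config(cfg)
  report <- NULL
  st <- run_stage(report, "load", function() vol, verbose)
  report <- st$report
  cur <- st$out
  st <- run_stage(report, "histogram_match", function()
    histogram_match_slices(cur, cfg$histogram$reference_slice,
                           cfg$histogram$n_quantiles), verbose)
  report <- st$report; cur <- st$out
  if (cfg$block_iterations > 0) {
    for (it in seq_len(cfg$block_iterations)) {
      st <- run_stage(report, sprintf("guided_filter_%da", it), function()
        guided_filter(cur, cfg$guided$r, cfg$guided$eps), verbose)
      report <- st$report; cur <- st$out
      st <- run_stage(report, sprintf("bilateral_filter_%d", it), function()
        bilateral_filter(cur, cfg$bilateral$sigma, cfg$bilateral$mu,
                         cfg$bilateral$support_radius %||%
                           ceiling(2 * cfg$bilateral$sigma)), verbose)
      report <- st$report; cur <- st$out
      st <- run_stage(report, sprintf("guided_filter_%db", it), function()
        guided_filter(cur, cfg$guided$r, cfg$guided$eps), verbose)
      report <- st$report; cur <- st$out
    }
  }
  st <- run_stage(report, "sharpen", function()
    sharpen(cur, cfg$sharpen$amount, cfg$sharpen$blur_sigma), verbose)
  report <- st$report; cur <- st$out
  structure(list(volume = cur, report = report, config = cfg),
            class = "otoct_run_2d")
}

#' Run the 3D-visualization noise-reduction and segmentation chain
#'
#' Applies guided filtering, a white top-hat with a large cross element to
#' extract thin bright (hyperdense neural) structures, binarization at an
#' absolute threshold, geodesic opening to delete small unconnected
#' components, morphological closing and a one-voxel cross dilation to pad
#' the mask, and finally multiplies the top-hat volume by the mask.  If a
#' manual mask is supplied it is intersected (logical AND) with the
#' automatic mask before application, excluding circumjacent structures.
#' Deterministic end to end.
#'
#' @param vol an [intensity_volume()].
#' @param cfg a [pipeline_config()].
#' @param manual_mask optional [binary_mask()] of the same shape.
#' @param verbose log per-stage progress to stderr.
#' @return An object of class `otoct_run_3d` with fields `denoised` (the
#'   top-hat-processed [intensity_volume()]), `mask` (final
#'   [binary_mask()]), `segmented` (`denoised * mask`), `report`, `config`.
#' @export
run_pipeline_3d <- function(vol, cfg = pipeline_config(), manual_mask = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(vol, "intensity_volume"))
  cfg <- validate_config(cfg)
  if (!is.null(manual_mask)) {
    if (!inherits(manual_mask, "binary_mask"))
      stop("manual_mask must be a binary_mask", call. = FALSE)
    if (!same_shape(vol, manual_mask))
      stop("manual mask shape (",
           paste(dim(manual_mask), collapse = "x"),
           ") does not match volume shape (",
           paste(dim(vol), collapse = "x"), ") (dimension error)",
           call. = FALSE)
  }
  report <- NULL
  st <- run_stage(report, "load", function() vol, verbose)
  report <- st$report; cur <- st$out
  st <- run_stage(report, "guided_filter", function()
    guided_filter(cur, cfg$guided$r, cfg$guided$eps), verbose)
  report <- st$report; cur <- st$out
  st <- run_stage(report, "tophat", function()
    white_tophat(cur, cfg$tophat_se), verbose)
  report <- st$report
  denoised <- st$out
  st <- run_stage(report, "binarize", function()
    binarize(denoised, cfg$binarize_threshold), verbose)
  report <- st$report; mask <- st$out
  st <- run_stage(report, "geodesic_opening", function()
    geodesic_opening(mask, cfg$geodesic_size, cfg$connectivity), verbose)
  report <- st$report; mask <- st$out
  st <- run_stage(report, "closing", function()
    closing(mask, cfg$closing_se), verbose)
  report <- st$report; mask <- st$out
  st <- run_stage(report, "dilation", function()
    dilate(mask, cfg$dilation_se), verbose)
  report <- st$report; mask <- st$out
  if (!is.null(manual_mask)) {
    st <- run_stage(report, "manual_mask_intersect", function()
      binary_mask(mask$data & manual_mask$data, spacing = mask$spacing),
      verbose)
    report <- st$report; mask <- st$out
  }
  st <- run_stage(report, "image_multiply", function()
    apply_mask(denoised, mask), verbose)
  report <- st$report
  structure(list(denoised = denoised, mask = mask, segmented = st$out,
                 report = report, config = cfg),
            class = "otoct_run_3d")
}

#' @export
print.otoct_run_2d <- function(x, ...) {
  cat("<otoct 2D noise-reduction run>\n")
  cat(sprintf("  %d stages, %.2f s total\n", nrow(x$report),
              sum(x$report$seconds)))
  print(x$volume)
  invisible(x)
}

#' @export
print.otoct_run_3d <- function(x, ...) {
  cat("<otoct 3D segmentation run>\n")
  cat(sprintf("  %d stages, %.2f s total\n", nrow(x$report),
              sum(x$report$seconds)))
  cat(sprintf("  final mask: %d foreground voxels (%.3f%%)\n",
              sum(x$mask$data), 100 * mean(x$mask$data)))
  invisible(x)
}

#' Save pipeline outputs, configuration echo and report
#'
#' Writes the run's volumes (NRRD, float32), the echoed configuration
#' (`config.yaml`) and the per-stage report (`report.json`) into `out_dir`.
#' Re-running the pipeline from the echoed configuration on the same input
#' reproduces the outputs bit-identically.
#'
#' @param run an `otoct_run_2d` or `otoct_run_3d` object.
#' @param out_dir output directory; created if missing, but its parent must
#'   exist.
#' @return `out_dir`, invisibly.
#' @export
save_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) {
    if (!dir.exists(dirname(out_dir)))
      stop("cannot create '", out_dir, "': parent directory '",
           dirname(out_dir), "' does not exist", call. = FALSE)
    dir.create(out_dir)
  }
  if (inherits(run, "otoct_run_2d")) {
    write_volume(run$volume, file.path(out_dir, "denoised.nrrd"))
  } else if (inherits(run, "otoct_run_3d")) {
    write_volume(run$denoised, file.path(out_dir, "denoised.nrrd"))
    write_volume(run$mask, file.path(out_dir, "mask.nrrd"))
    write_volume(run$segmented, file.path(out_dir, "segmented.nrrd"))
  } else stop("run must be an otoct_run_2d or otoct_run_3d", call. = FALSE)
  write_config(run$config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(out_dir)
}
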