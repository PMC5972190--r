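## Synthetic inner-ear phantom.
##
## Emulates an osmium-stained micro-CT volume: a bright (hyperdense) neural
## compartment — a solid central trunk (modiolus/ganglion) with thin fibers
## fanning out along a helix — inside a less radiodense bone annulus, with a
## thin membranous shell between them, plus small unconnected bright speckle
## blobs, partial-volume Gaussian blur, slice-to-slice intensity drift along
## the scan axis, and additive sensor noise.  Ground-truth labels are
## recorded before blur/noise.

#' Label codes of the phantom ground truth
#'
#' @return Named integer vector: background 0, bone 1, membrane 2, nerve 3,
#'   speckle 4.
#' @export
phantom_labels <- function() c(background = 0L, bone = 1L, membrane = 2L,
                               nerve = 3L, speckle = 4L)

#' Phantom specification
#'
#' The geometry scales with the volume: radial extents are fractions of the
#' smallest axis, while thin-feature sizes (fiber radius, membrane
#' half-thickness, speckle radii) are absolute voxel counts.  Defaults
#' describe a 160^3 phantom whose nerve trunk admits an inscribed 31^3 box
#' (so a size-15 geodesic opening must preserve the whole nerve component)
#' and whose intensity ordering nerve > membrane > bone > background encodes
#' the contrast the stain provides.
#'
#' @param shape `(nz, ny, nx)` voxel counts.
#' @param seed RNG seed (Mersenne-Twister / inversion; fixed so results are
#'   reproducible across runs and platforms).
#' @param intensities named mean normalized intensities per tissue class.
#' @param helix_turns turns of the fiber fan around the trunk axis.
#' @param fiber_count number of nerve fibers fanning out of the trunk.
#' @param fiber_radius fiber half-thickness in voxels.
#' @param trunk_radius_frac trunk radius as a fraction of the smallest axis.
#' @param fiber_reach_frac radial reach of fibers at base and apex
#'   (fractions; decreasing toward the apex).
#' @param membrane_radius_frac membrane shell radius at base and apex
#'   (fractions; decreasing toward the apex).
#' @param bone_outer_frac outer radius of the bone annulus (fraction).
#' @param speckle_count number of isolated bright speckle blobs.
#' @param speckle_radius range (min, max) of speckle radii in voxels.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param z_drift peak-to-peak linear per-slice intensity offset along z.
#' @param blur_sigma partial-volume Gaussian blur in voxels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 160, 160), seed = 42,
                         intensities = c(background = 0.02, bone = 0.15,
                                         membrane = 0.25, nerve = 0.55,
                                         speckle = 0.55),
                         helix_turns = 2.5, fiber_count = 20,
                         fiber_radius = 2.5,
                         trunk_radius_frac = 0.175,
                         fiber_reach_frac = c(0.3125, 0.2625),
                         membrane_radius_frac = c(0.375, 0.325),
                         bone_outer_frac = 0.475,
                         speckle_count = 60, speckle_radius = c(1, 3),
                         noise_sigma = 0.02, z_drift = 0.02,
                         blur_sigma = 0.7) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 16L))
    stop("phantom shape must be three axis lengths >= 16", call. = FALSE)
  req <- c("background", "bone", "membrane", "nerve", "speckle")
  if (!all(req %in% names(intensities)))
    stop("intensities must name all of: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(intensities < 0 | intensities > 1))
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (fiber_radius >= trunk_radius_frac * min(shape))
    stop("fiber radius must be smaller than the trunk radius", call. = FALSE)
  if (noise_sigma < 0 || z_drift < 0 || blur_sigma < 0)
    stop("noise_sigma, z_drift and blur_sigma must be >= 0", call. = FALSE)
  if (bone_outer_frac >= 0.5)
    stop("bone annulus must fit inside the volume (bone_outer_frac < 0.5)",
         call. = FALSE)
  structure(list(shape = shape, seed = seed,
                 intensities = intensities[req], helix_turns = helix_turns,
                 fiber_count = as.integer(fiber_count),
                 fiber_radius = fiber_radius,
                 trunk_radius_frac = trunk_radius_frac,
                 fiber_reach_frac = fiber_reach_frac,
                 membrane_radius_frac = membrane_radius_frac,
                 bone_outer_frac = bone_outer_frac,
                 speckle_count = as.integer(speckle_count),
                 speckle_radius = speckle_radius,
                 noise_sigma = noise_sigma, z_drift = z_drift,
                 blur_sigma = blur_sigma),
            class = "phantom_spec")
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a synthetic inner-ear phantom with ground truth
#'
#' Construction order: bone annulus and membrane shell, nerve trunk, nerve
#' fibers rasterized along a helix, isolated speckle blobs (placed at least
#' 2 voxels from any labeled structure, so they are truly unconnected), then
#' partial-volume Gaussian blur, linear z-drift and additive Gaussian noise
#' on the intensity volume, clipped to `[0, 1]`.  Ground-truth labels are
#' recorded before blur/noise.  Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (an [intensity_volume()]) and `truth`
#'   (class `phantom_truth`: integer `labels` array plus the spec echo).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48),
#'                                     speckle_count = 10))
#' table(ph$truth$labels)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$shape
    nz <- d[1]; ny <- d[2]; nx <- d[3]
    smin <- min(d)
    cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
    rho2d <- sqrt(outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+"))

    labels <- array(0L, dim = d)
    z_lo <- round(0.1875 * nz); z_hi <- round(0.8125 * nz)
    trunk_zlo <- round(0.225 * nz); trunk_zhi <- round(0.7875 * nz)
    trunk_r <- spec$trunk_radius_frac * smin
    memb_r <- spec$membrane_radius_frac * smin
    reach <- spec$fiber_reach_frac * smin
    bone_outer <- spec$bone_outer_frac * smin

    # bone annulus and membrane shell, radius shrinking toward the apex
    for (k in z_lo:z_hi) {
      u <- (k - z_lo) / max(1, z_hi - z_lo)
      rk <- memb_r[1] - (memb_r[1] - memb_r[2]) * u
      sl <- labels[k, , ]
      sl[rho2d >= rk + 4 & rho2d <= bone_outer] <- 1L
      sl[abs(rho2d - rk) <= 1] <- 2L
      labels[k, , ] <- sl
    }
    # nerve trunk (modiolus / ganglion): solid central cylinder
    trunk2d <- rho2d <= trunk_r
    for (k in trunk_zlo:trunk_zhi) {
      sl <- labels[k, , ]
      sl[trunk2d] <- 3L
      labels[k, , ] <- sl
    }
    # nerve fibers fanning out of the trunk along a helix, radial reach
    # decreasing toward the apex
    pts <- NULL
    for (j in seq_len(spec$fiber_count)) {
      u <- (j - 0.5) / spec$fiber_count
      theta0 <- 2 * pi * spec$helix_turns * u
      zj <- trunk_zlo + u * (trunk_zhi - trunk_zlo)
      r_end <- reach[1] - (reach[1] - reach[2]) * u
      tt <- seq(0, 1, length.out = ceiling(2 * (r_end - 0.6 * trunk_r)) + 8)
      rr <- 0.6 * trunk_r + tt * (r_end - 0.6 * trunk_r)
      th <- theta0 + 0.35 * tt            # gentle spiral twist
      zz <- zj + 3 * tt                   # slight climb
      pts <- rbind(pts, cbind(zz, cy + rr * sin(th), cx + rr * cos(th)))
    }
    labels <- stamp_balls(labels, pts, spec$fiber_radius, 3L)

    # isolated speckle blobs, rejection-sampled into unlabeled space with a
    # clearance of 4 voxels beyond their own radius (comfortably more than
    # the 2-voxel minimum, so partial-volume blur cannot bridge them to any
    # structure above the binarization threshold)
    placed <- 0L; tries <- 0L
    while (placed < spec$speckle_count && tries < 20000L) {
      tries <- tries + 1L
      rad <- runif(1, spec$speckle_radius[1], spec$speckle_radius[2])
      margin <- ceiling(rad) + 4L
      ctr <- c(sample(seq(margin + 1L, nz - margin), 1),
               sample(seq(margin + 1L, ny - margin), 1),
               sample(seq(margin + 1L, nx - margin), 1))
      box <- labels[(ctr[1] - margin):(ctr[1] + margin),
                    (ctr[2] - margin):(ctr[2] + margin),
                    (ctr[3] - margin):(ctr[3] + margin)]
      if (any(box != 0L)) next
      labels <- stamp_balls(labels, matrix(ctr, 1), rad, 4L)
      placed <- placed + 1L
    }
    if (placed < spec$speckle_count)
      warning("placed only ", placed, " of ", spec$speckle_count,
              " speckle blobs", call. = FALSE)

    vol <- array(spec$intensities[labels + 1L], dim = d)
    if (spec$blur_sigma > 0) vol <- gaussian_blur3(vol, spec$blur_sigma)
    if (spec$z_drift > 0) {
      drift <- spec$z_drift * ((seq_len(nz) - 1) / max(1, nz - 1) - 0.5)
      vol <- vol + array(drift, dim = d)  # z varies fastest in dim 1
    }
    if (spec$noise_sigma > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sigma), dim = d)
    vol <- clip01(vol)

    list(volume = intensity_volume(vol, name = "synthetic inner-ear phantom"),
         truth = structure(list(labels = labels, spec = spec),
                           class = "phantom_truth"))
  })
}

# Stamp balls of the given radius around each (z, y, x) point, writing
# `value` into `labels`; callers keep classes disjoint by geometry.
stamp_balls <- function(labels, pts, radius, value) {
  d <- dim(labels)
  r <- ceiling(radius)
  offs <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  ctr <- round(pts)
  idx_z <- rep(ctr[, 1], each = nrow(offs)) + rep(offs[, 1], nrow(ctr))
  idx_y <- rep(ctr[, 2], each = nrow(offs)) + rep(offs[, 2], nrow(ctr))
  idx_x <- rep(ctr[, 3], each = nrow(offs)) + rep(offs[, 3], nrow(ctr))
  ok <- idx_z >= 1 & idx_z <= d[1] & idx_y >= 1 & idx_y <= d[2] &
    idx_x >= 1 & idx_x <= d[3]
  lin <- (idx_x[ok] - 1) * d[1] * d[2] + (idx_y[ok] - 1) * d[1] + idx_z[ok]
  labels[unique(lin)] <- value
  labels
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  tab <- table(factor(x$labels, levels = 0:4,
                      labels = names(phantom_labels())))
  print(tab)
  invisible(x)
}

#' Flat noisy test block
#'
#' A homogeneous volume with i.i.d. additive Gaussian noise, clipped to
#' `[0, 1]`; the substrate for quantifying noise reduction.  The mean must
#' sit at least four standard deviations from both ends of the intensity
#' range so clipping is negligible.
#'
#' @param shape `(nz, ny, nx)` voxel counts.
#' @param mean flat intensity level.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return An [intensity_volume()].
#' @export
generate_flat_noise_block <- function(shape = c(128, 128, 128), mean = 0.4,
                                      noise_sigma = 0.05, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive axis lengths", call. = FALSE)
  if (mean - 4 * noise_sigma < 0 || mean + 4 * noise_sigma > 1)
    stop("mean +/- 4*noise_sigma must stay within [0, 1]", call. = FALSE)
  with_seed(seed, {
    v <- array(mean + rnorm(prod(shape), 0, noise_sigma), dim = shape)
    intensity_volume(clip01(v), name = "flat noise block")
  })
}
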