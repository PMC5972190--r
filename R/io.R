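#' Read a 3D volume from TIFF stack, NRRD or NIfTI-1
#'
#' Reads a 3D scalar volume and normalizes it to `[0, 1]`.  Integer sample
#' types are divided by their type maximum (65535 for unsigned 16-bit, the
#' convention under which an absolute binarization threshold such as 0.035
#' keeps a fixed physical meaning across volumes); floating-point samples are
#' clipped to `[0, 1]`.  The returned axis order is `(z, y, x)` with `z` the
#' slice/stack axis, so slice `k` of a TIFF stack is `data[k, , ]`.
#'
#' A directory path is read as a stack of single-page TIFFs ordered by
#' lexicographic filename.  When the container carries no voxel-size
#' metadata, spacing defaults to 1 um isotropic with a warning; spacing is
#' descriptive only, every filter works in voxel units.
#'
#' @param path file (or, for TIFF stacks, directory) to read.
#' @param format one of `"auto"`, `"tiff"`, `"nrrd"`, `"nifti"`; `"auto"`
#'   picks by file extension.
#' @return An [intensity_volume()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nrrd", "nifti")) {
  format <- match.arg(format)
  raw <- read_raw_volume(path, format)
  data <- normalize_samples(raw$data, raw$dtype, path)
  if (is.null(raw$spacing)) {
    warning("no voxel spacing metadata in '", path,
            "'; defaulting to (1, 1, 1) um", call. = FALSE)
    raw$spacing <- c(1, 1, 1)
  }
  intensity_volume(data, spacing = raw$spacing, source_dtype = raw$dtype,
                   name = basename(path))
}

#' Read a binary mask volume
#'
#' Reads a 3D array in any supported container and maps every sample greater
#' than zero to foreground.  Used to import manual segmentations made in
#' external GUI tools.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, format = c("auto", "tiff", "nrrd", "nifti")) {
  format <- match.arg(format)
  raw <- read_raw_volume(path, format)
  if (anyNA(raw$data) || any(!is.finite(raw$data)))
    stop("mask file '", path, "' contains non-finite values", call. = FALSE)
  binary_mask(raw$data > 0,
              spacing = if (is.null(raw$spacing)) c(1, 1, 1) else raw$spacing)
}

#' Write a 3D volume to TIFF, NRRD or NIfTI-1
#'
#' Writing as `float32` round-trips exactly through [read_volume()]; writing
#' as `uint16` stores `round(v * 65535)` and round-trips within `1/65535`
#' per voxel.  Voxel spacing is stored in NRRD (`spacings` field) and NIfTI
#' (`pixdim`) containers; plain TIFF written here carries no spacing.
#'
#' @param vol an [intensity_volume()] (or a [binary_mask()], stored as 0/1).
#' @param path output file path; parent directory must exist.
#' @param format `"auto"` (by extension), `"tiff"`, `"nrrd"` or `"nifti"`.
#' @param dtype on-disk sample type, `"float32"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "nrrd", "nifti"),
                         dtype = c("float32", "uint16")) {
  format <- match.arg(format)
  dtype <- match.arg(dtype)
  if (inherits(vol, "binary_mask"))
    vol <- intensity_volume(vol$data * 1, spacing = vol$spacing,
                            source_dtype = "uint8", name = "mask")
  if (!inherits(vol, "intensity_volume"))
    stop("vol must be an intensity_volume or binary_mask", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': parent directory does not exist",
         call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         tiff = write_tiff_stack(vol, path, dtype),
         nrrd = write_nrrd(vol, path, dtype),
         nifti = write_nifti_vol(vol, path, dtype))
  invisible(path)
}

#' @noRd
guess_format <- function(path) {
  if (dir.exists(path)) return("tiff")
  low <- tolower(path)
  if (grepl("\\.(tif|tiff)$", low)) return("tiff")
  if (grepl("\\.(nrrd|nhdr)$", low)) return("nrrd")
  if (grepl("\\.(nii|nii\\.gz|hdr)$", low)) return("nifti")
  stop("cannot infer volume format from extension of '", path,
       "'; pass format= explicitly", call. = FALSE)
}

# Returns list(data = 3D array (z,y,x) of raw sample values,
#              dtype = character, spacing = numeric(3) or NULL).
read_raw_volume <- function(path, format = "auto") {
  if (format == "auto") format <- guess_format(path)
  if (!dir.exists(path) && !file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  switch(format,
         tiff = read_tiff_stack(path),
         nrrd = read_nrrd(path),
         nifti = read_nifti_vol(path))
}

normalize_samples <- function(data, dtype, path) {
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume '", path, "' contains non-finite values", call. = FALSE)
  denom <- switch(dtype, uint8 = 255, uint16 = 65535, int16 = 32767,
                  uint32 = 4294967295, NULL)
  if (!is.null(denom)) data <- data / denom else data <- clip01(data)
  if (min(data) < 0)
    stop("volume '", path, "' contains negative integer samples",
         call. = FALSE)
  data
}

## ---- TIFF --------------------------------------------------------------

read_tiff_stack <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0)
      stop("directory '", path, "' contains no TIFF files", call. = FALSE)
    files <- files[order(basename(files))]
    pages <- unlist(lapply(files, function(f)
      tiff::readTIFF(f, all = TRUE, as.is = TRUE)), recursive = FALSE)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  if (length(pages) < 1) stop("no TIFF pages in '", path, "'", call. = FALSE)
  first <- pages[[1]]
  if (length(dim(first)) == 3L && dim(first)[3] > 1)
    stop("multi-channel TIFF in '", path,
         "' is not a 3D scalar volume (dimensionality error)", call. = FALSE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("TIFF pages in '", path, "' have inconsistent dimensions",
         call. = FALSE)
  if (length(pages) == 1L)
    stop("'", path, "' holds a single 2D page, not a 3D volume ",
         "(dimensionality error)", call. = FALSE)
  data <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (k in seq_along(pages)) data[k, , ] <- pages[[k]]
  bps <- attr(pages[[1]], "bits.per.sample")
  # readTIFF(as.is = TRUE) returns integers for uint TIFFs, floats otherwise
  dtype <- if (max(data) <= 1 && min(data) >= 0 && !all(data == round(data)))
    "float32"
  else if (!is.null(bps)) paste0("uint", bps)
  else if (max(data) > 255) "uint16" else "uint8"
  if (!all(data == round(data))) dtype <- "float32"
  list(data = data, dtype = dtype, spacing = NULL)
}

write_tiff_stack <- function(vol, path, dtype) {
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(k) vol$data[k, , ])
  bps <- if (dtype == "uint16") 16L else 32L
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bps), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF '", path, "': ", attr(ok, "condition")$message,
         call. = FALSE)
  invisible(path)
}

## ---- NRRD --------------------------------------------------------------
## Minimal NRRD0004 support: attached or detached headers, raw/gzip/ascii
## encodings, little/big endian, the sample types used in micro-CT work.

nrrd_type_map <- function(type) {
  type <- tolower(trimws(type))
  if (type %in% c("float")) return(list(dtype = "float32", size = 4,
                                        what = "numeric", signed = TRUE))
  if (type %in% c("double")) return(list(dtype = "float64", size = 8,
                                         what = "numeric", signed = TRUE))
  if (type %in% c("unsigned short", "ushort", "uint16", "uint16_t"))
    return(list(dtype = "uint16", size = 2, what = "integer", signed = FALSE))
  if (type %in% c("short", "signed short", "int16", "int16_t"))
    return(list(dtype = "int16", size = 2, what = "integer", signed = TRUE))
  if (type %in% c("unsigned char", "uchar", "uint8", "uint8_t"))
    return(list(dtype = "uint8", size = 1, what = "integer", signed = FALSE))
  stop("unsupported NRRD sample type '", type, "'", call. = FALSE)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic))
    stop("'", path, "' is not an NRRD file (bad magic '", magic, "')",
         call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !nzchar(line)) break
    if (startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("'", path, "' holds a ", fields[["dimension"]],
         "D payload, expected 3D (dimensionality error)", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])  # fastest first
  tm <- nrrd_type_map(fields[["type"]])
  n <- prod(sizes)
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"

  data_con <- con
  if (!is.null(fields[["data file"]])) {
    data_path <- file.path(dirname(path), fields[["data file"]])
    data_con <- file(data_path, "rb")
    on.exit(close(data_con), add = TRUE)
  }
  vals <- switch(encoding,
    raw = readBin(data_con, tm$what, n = n, size = tm$size,
                  signed = tm$signed || tm$size > 2, endian = endian),
    gzip = {
      comp <- readBin(data_con, "raw", n = file.size(path))
      bytes <- memDecompress(comp, type = "gzip")
      readBin(bytes, tm$what, n = n, size = tm$size,
              signed = tm$signed || tm$size > 2, endian = endian)
    },
    ascii = scan(data_con, what = double(), n = n, quiet = TRUE),
    text = scan(data_con, what = double(), n = n, quiet = TRUE),
    stop("unsupported NRRD encoding '", encoding, "'", call. = FALSE))
  if (length(vals) != n)
    stop("NRRD '", path, "' is truncated: expected ", n, " samples, read ",
         length(vals), call. = FALSE)

  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    if (length(sp) == 3 && all(is.finite(sp))) spacing <- rev(sp)
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    if (length(vecs) == 3) {
      norms <- vapply(vecs, function(v) {
        xyz <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(xyz^2))
      }, numeric(1))
      if (all(is.finite(norms)) && all(norms > 0)) spacing <- rev(norms)
    }
  }
  # NRRD sizes are fastest-axis first (x, y, z); reorder to (z, y, x)
  data <- aperm(array(as.double(vals), dim = sizes), c(3, 2, 1))
  list(data = data, dtype = tm$dtype, spacing = spacing)
}

write_nrrd <- function(vol, path, dtype) {
  d <- dim(vol$data)
  type_str <- if (dtype == "uint16") "unsigned short" else "float"
  header <- c(
    "NRRD0004",
    "# written by otoct",
    paste0("type: ", type_str),
    "dimension: 3",
    paste0("sizes: ", d[3], " ", d[2], " ", d[1]),
    paste0("spacings: ", vol$spacing[3], " ", vol$spacing[2], " ",
           vol$spacing[1]),
    "endian: little",
    "encoding: raw",
    "")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  vals <- aperm(vol$data, c(3, 2, 1))  # back to x fastest
  if (dtype == "uint16") {
    iv <- as.integer(round(as.vector(vals) * 65535))
    # little-endian 16-bit unsigned, written bytewise to allow values > 32767
    writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
  } else {
    writeBin(as.vector(vals), con, size = 4, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- NIfTI -------------------------------------------------------------

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("'", path, "' holds a ", length(dim(arr)),
         "D payload, expected 3D (dimensionality error)", call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  dtype <- switch(as.character(hdr$datatype),
                  "2" = "uint8", "4" = "int16", "8" = "int32",
                  "16" = "float32", "64" = "float64", "256" = "int8",
                  "512" = "uint16", "768" = "uint32", "float32")
  # RNifti applies scl_slope/inter; if scaled, treat as float
  if (!is.null(hdr$scl_slope) && isTRUE(hdr$scl_slope != 0) &&
      isTRUE(hdr$scl_slope != 1)) dtype <- "float32"
  pd <- RNifti::pixdim(img)[1:3]
  spacing <- if (all(is.finite(pd)) && all(pd > 0)) rev(pd) else NULL
  list(data = aperm(arr, c(3, 2, 1)), dtype = dtype, spacing = spacing)
}

write_nifti_vol <- function(vol, path, dtype) {
  arr <- aperm(vol$data, c(3, 2, 1))  # (x, y, z)
  if (dtype == "uint16") {
    arr <- array(as.integer(round(arr * 65535)), dim = dim(arr))
    out_dtype <- "uint16"
  } else {
    out_dtype <- "float"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path, datatype = out_dtype)
  invisible(path)
}

## ---- label volumes -----------------------------------------------------

#' Read / write integer label volumes
#'
#' Small-integer label grids (e.g. phantom ground truth) stored as NRRD
#' with 8-bit unsigned samples, without intensity normalization.
#'
#' @param labels integer 3D array with values in 0..255.
#' @param path NRRD file path.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns an
#'   integer 3D array in `(z, y, x)` order.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "phantom_truth")) labels <- labels$labels
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (min(labels) < 0 || max(labels) > 255)
    stop("labels must lie in 0..255", call. = FALSE)
  d <- dim(labels)
  header <- c("NRRD0004", "# written by otoct (label volume)",
              "type: unsigned char", "dimension: 3",
              paste0("sizes: ", d[3], " ", d[2], " ", d[1]),
              "endian: little", "encoding: raw", "")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  writeBin(as.raw(as.vector(aperm(labels, c(3, 2, 1)))), con)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  raw <- read_raw_volume(path, "nrrd")
  out <- raw$data
  storage.mode(out) <- "integer"
  out
}
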