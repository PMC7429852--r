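#' 3D grayscale image volume
#'
#' The universal raster currency of the pipeline: a 3D scalar array with an
#' isotropic voxel size.  Axes are fixed as (z, y, x), indices are 0-based in
#' all voxel-coordinate arguments, and coordinates refer to voxel centers.
#'
#' @param data 3D numeric array, axes (z, y, x).
#' @param voxel_size isotropic voxel edge length in micrometres (> 0).
#' @param origin integer 3-vector, offset of this volume within a parent
#'   volume (voxels, 0-based); defaults to `c(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size, origin = c(0L, 0L, 0L)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all three voxel dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.integer(origin)),
            class = "image_volume")
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels (z,y,x), %.4g um/voxel, origin (%s)\n",
              d[1], d[2], d[3], x$voxel_size, paste(x$origin, collapse = ",")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Region of interest in voxel coordinates
#'
#' @param start integer 3-vector, 0-based start voxel (z, y, x).
#' @param shape integer 3-vector, extent in voxels.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(start, shape) {
  start <- as.integer(start); shape <- as.integer(shape)
  if (length(start) != 3L || length(shape) != 3L)
    stop("`start` and `shape` must have length 3")
  if (any(start < 0L)) stop("`start` must be >= 0")
  if (any(shape < 1L)) stop("`shape` must be >= 1")
  structure(list(start = start, shape = shape), class = "roi_spec")
}

#' Crop a volume to a region of interest
#'
#' The returned volume's `origin` is the parent origin plus `roi$start`, so
#' nested crops compose.
#'
#' @param volume an [image_volume].
#' @param roi an [roi_spec]; must lie within `volume`.
#' @return The cropped [image_volume].
#' @export
crop <- function(volume, roi) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_spec"))
  d <- dim(volume$data)
  if (any(roi$start + roi$shape > d))
    stop("roi exceeds volume bounds")
  i <- lapply(1:3, function(a) seq.int(roi$start[a] + 1L, roi$start[a] + roi$shape[a]))
  image_volume(volume$data[i[[1]], i[[2]], i[[3]], drop = FALSE],
               volume$voxel_size, volume$origin + roi$start)
}

#' Read a 3D volume from TIFF
#'
#' Accepts either a multipage TIFF file (one page per z slice) or a directory
#' of single-page TIFF slices (read in lexicographic filename order).  Integer
#' sample values are preserved bit-exactly.
#'
#' @param path multipage TIFF file or directory of slice TIFFs.
#' @param voxel_size isotropic voxel size in micrometres.
#' @return An [image_volume] with axes (z, y, x).
#' @export
read_volume <- function(path, voxel_size) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices in directory: ", path)
    slices <- lapply(files, function(f) {
      s <- tiff::readTIFF(f, as.is = TRUE)
      if (is.list(s)) s <- s[[1]]
      s
    })
  } else {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  shp <- dim(slices[[1]])
  if (length(shp) != 2L) stop("TIFF slices must be single-channel grayscale")
  ok <- vapply(slices, function(s) identical(dim(s), shp), logical(1))
  if (!all(ok)) stop("inconsistent slice shapes in ", path)
  data <- array(0, dim = c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  image_volume(data, voxel_size)
}

#' Write a 3D volume to a multipage TIFF
#'
#' Integer-valued data are written losslessly at 8 or 16 bits per sample
#' (chosen from the value range); floating data must already lie in
#' `[0, 1]` and are written as 32-bit float.
#'
#' @param volume an [image_volume].
#' @param path output file path (`.tif`).
#' @param bits bits per sample for integer data, 8 or 16; chosen
#'   automatically when `NULL`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  d <- volume$data
  if (length(d) == 0L) stop("empty volume")
  slices <- lapply(seq_len(dim(d)[1]), function(i) d[i, , ])
  if (all(d == round(d)) && min(d) >= 0) {
    if (is.null(bits)) bits <- if (max(d) <= 255) 8L else 16L
    if (max(d) > 2^bits - 1) stop("integer data exceed ", bits, "-bit range")
    slices <- lapply(slices, function(s) s / (2^bits - 1))
    tiff::writeTIFF(slices, path, bits.per.sample = bits)
  } else {
    if (min(d) < 0 || max(d) > 1)
      stop("floating data must lie in [0, 1] for TIFF output")
    tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  }
  invisible(path)
}
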