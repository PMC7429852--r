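#' Mineralized-bone mask from a gray-level range
#'
#' The operating point for 8-bit reconstructions assigns 115-255 to
#' mineralized tissue (corresponding to 833-1746 mg/cc mineral density).
#'
#' @param volume an [image_volume].
#' @param gray_range length-2 numeric, inclusive (low, high).
#' @return Logical 3D array.
#' @export
bone_mask <- function(volume, gray_range = c(115, 255)) {
  stopifnot(inherits(volume, "image_volume"), length(gray_range) == 2L)
  m <- volume$data >= gray_range[1] & volume$data <= gray_range[2]
  if (!any(m)) stop("empty bone mask")
  m
}

#' Bone volume fraction BV/TV
#'
#' @param mask logical bone mask.
#' @param total_region optional logical mask of the total region; defaults
#'   to the whole array.
#' @return Bone voxels over total voxels.
#' @export
bvtv <- function(mask, total_region = NULL) {
  if (is.null(total_region)) return(mean(mask))
  if (!any(total_region)) stop("empty total region")
  sum(mask & total_region) / sum(total_region)
}

#' Local thickness map (largest inscribed sphere)
#'
#' For each bone voxel, the diameter of the largest sphere fully contained
#' in the bone phase that covers the voxel (sphere-fitting local thickness:
#' distance transform plus sphere marking).  The sphere radius at a center
#' voxel is its center-to-center Euclidean distance to the nearest
#' background voxel, and a sphere of radius r covers voxels strictly closer
#' than r; a laterally extended slab of n voxels therefore reads
#' `n * voxel_size` in its interior.
#'
#' @param mask logical bone mask; must contain some background.
#' @param voxel_size voxel size in micrometres.
#' @param method `"exact"` marks every sphere; `"fast"` skips spheres
#'   already covered by an equal-or-larger sphere (standard pruning, used
#'   for pipeline-scale volumes); `"auto"` picks `"exact"` for volumes up
#'   to 40^3.
#' @return A `thickness_map`: list with `map` (um per bone voxel, NA
#'   outside bone), `mean_um`, `sd_um` over bone voxels.
#' @export
local_thickness <- function(mask, voxel_size = 3.6,
                            method = c("auto", "exact", "fast")) {
  method <- match.arg(method)
  if (!any(mask)) stop("empty mask")
  if (all(mask)) stop("mask has no background: thickness undefined")
  exact <- switch(method, exact = TRUE, fast = FALSE,
                  auto = length(mask) <= 40^3)
  th <- array(cpp_local_thickness(mask, dim(mask), exact), dim = dim(mask))
  th <- th * voxel_size
  th[!mask] <- NA_real_
  v <- th[mask]
  structure(list(map = th, mean_um = mean(v), sd_um = sd(v),
                 voxel_size = voxel_size),
            class = "thickness_map")
}

#' Grayscale-to-density calibration from phantoms
#'
#' Least-squares line `density = slope * gray + intercept` through the
#' (mean gray, known density) pairs of uniform calibration phantoms.
#'
#' @param phantom_volumes list of [image_volume]s of uniform density
#'   phantoms; each may carry an `inside` attribute masking the phantom
#'   material.
#' @param densities_mg_cc known densities (mg/cc), same length.
#' @return A `tmd_calibration`: `slope` (mg/cc per gray), `intercept`
#'   (mg/cc), `residual` (RMS, mg/cc), and the calibration points.
#' @export
calibrate_tmd <- function(phantom_volumes, densities_mg_cc) {
  stopifnot(length(phantom_volumes) == length(densities_mg_cc),
            length(phantom_volumes) >= 2L)
  grays <- vapply(phantom_volumes, function(v) {
    inside <- attr(v, "inside")
    if (is.null(inside)) mean(v$data) else mean(v$data[inside])
  }, numeric(1))
  if (max(grays) - min(grays) < 1e-9) stop("identical phantom mean grays")
  fit <- lm(densities_mg_cc ~ grays)
  res <- sqrt(mean(fit$residuals^2))
  new_tmd_calibration(unname(coef(fit)[2]), unname(coef(fit)[1]), res,
                      grays, densities_mg_cc)
}

new_tmd_calibration <- function(slope, intercept, residual = 0,
                                grays = NULL, densities = NULL) {
  if (slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept, residual = residual,
                 grays = grays, densities = densities),
            class = "tmd_calibration")
}

#' Default gray-to-density calibration
#'
#' The line through the printed 8-bit operating points 115 -> 833 mg/cc and
#' 255 -> 1746 mg/cc, for use when no phantom scans are available.
#'
#' @return A `tmd_calibration`.
#' @export
default_tmd_calibration <- function() {
  slope <- (1746 - 833) / (255 - 115)
  new_tmd_calibration(slope, 833 - slope * 115, 0,
                      c(115, 255), c(833, 1746))
}

#' Voxelwise tissue mineral density map
#'
#' Affine transform of gray values on bone voxels; non-bone voxels are
#' missing.
#'
#' @param volume an [image_volume].
#' @param calibration a `tmd_calibration`.
#' @param mask logical bone mask.
#' @return 3D array of densities (mg/cc), NA outside bone.
#' @export
tmd_map <- function(volume, calibration, mask) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(calibration, "tmd_calibration"),
            identical(dim(mask), dim(volume$data)))
  out <- calibration$slope * volume$data + calibration$intercept
  out[!mask] <- NA_real_
  out
}
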