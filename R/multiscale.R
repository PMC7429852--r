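#' Run the DVC chain on one image pair at one scale
#'
#' Downscales the (already filtered) pair by `factor`, runs DVC with the
#' per-scale protocol settings, filters the displacement field, computes
#' Green strain, gates by CC, and interpolates volumetric strain back onto
#' the voxel grid of that scale.
#'
#' @param ref_volume,def_volume filtered [image_volume]s at full resolution.
#' @param bone full-resolution logical bone mask.
#' @param cfg a [dvc_config] (typically from [scale_config()]).
#' @param factor integer downscaling factor (1 = native).
#' @param extrapolate passed to [interpolate_strain_to_voxels()]; the
#'   multiscale comparison sets it so all scales cover the same regions.
#' @return List with `strain_map` (voxel array at this scale), `field`,
#'   `strain_field`, `bone` (scale bone mask), and `factor`.
#' @export
run_scale <- function(ref_volume, def_volume, bone, cfg, factor = 1L,
                      extrapolate = FALSE) {
  if (factor > 1L) {
    ref_volume <- downscale(ref_volume, factor)
    def_volume <- downscale(def_volume, factor)
    bone <- block_vote(bone, factor)
  }
  field <- run_dvc(ref_volume, def_volume, bone, cfg)
  field <- filter_displacement_field(field, cfg$outlier_factor,
                                     cfg$field_median_radius, cfg$outlier_floor)
  sf <- green_strain(field)
  sf <- mask_by_correlation(sf, cfg$cc_min)
  smap <- interpolate_strain_to_voxels(sf, dim(ref_volume$data),
                                       extrapolate = extrapolate)
  list(strain_map = smap, field = field, strain_field = sf, bone = bone,
       factor = factor)
}

#' Voxel-size study: identical pipeline at native and downscaled resolution
#'
#' Runs the DVC/strain chain on the same (filtered) image sequence at the
#' requested downscaling factors with the per-factor protocol settings
#' (CW +/-10 / NS 10 native, +/-7 / 7 at factor 4, +/-5 / 5 at factor 8),
#' downscales the crack-region partition by block vote, and reports
#' region summaries and strain histograms per scale.  Strains are compared
#' in the same physical regions across scales.
#'
#' @param volumes list of filtered [image_volume]s (consecutive load
#'   steps, >= 2).
#' @param region_mask full-resolution `region_mask` (crack/non-crack).
#' @param bone full-resolution logical bone mask.
#' @param base_config a [dvc_config] for the native scale.
#' @param factors integer vector of downscaling factors.
#' @return Named list (one entry per factor) with `summary`, `histogram`,
#'   `abs_map` (final-step absolute cumulative voxel strains), `region`,
#'   and `crack_values` (absolute cumulative strains of crack-region
#'   voxels).
#' @export
run_multiscale <- function(volumes, region_mask, bone,
                           base_config = dvc_config(), factors = c(1L, 4L, 8L)) {
  stopifnot(length(volumes) >= 2L, inherits(region_mask, "region_mask"))
  out <- list()
  for (f in factors) {
    cfg <- if (f == 1L) base_config else scale_config(f, base = base_config)
    region <- if (f > 1L) downscale_region(region_mask, f, bone) else region_mask
    bone_f <- if (f > 1L) block_vote(bone, f) else bone
    maps <- vector("list", length(volumes) - 1L)
    for (k in seq_len(length(volumes) - 1L)) {
      rs <- run_scale(volumes[[k]], volumes[[k + 1L]], bone, cfg, f,
                      extrapolate = TRUE)
      maps[[k]] <- rs$strain_map
    }
    cum <- accumulate_strain(maps)
    amap <- cum$absolute[[length(maps)]]
    vals <- amap[region$crack_region]
    out[[as.character(f)]] <- list(
      factor = f,
      summary = summarize_regions(amap, region),
      histogram = strain_histogram(amap, region$crack_region),
      abs_map = amap, region = region,
      crack_values = vals[is.finite(vals)])
  }
  out
}
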