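#' DVC pipeline configuration
#'
#' Bundles the tunable parameters of the block-matching DVC chain.  `cw` is a
#' half-width: the correlation window spans `(2*cw + 1)^3` voxels ("+/- cw
#' voxels").  At full resolution the protocol uses `cw = 10`, `ns = 10`
#' (50% window overlap); downscaled data use the scaled settings from
#' [scale_config()].
#'
#' @param cw correlation-window half-width in voxels (>= 1).
#' @param ns node spacing in voxels (>= 1).
#' @param search_range integer displacement search bound, voxels.
#' @param cc_min correlation-coefficient gate in (0, 1]; only nodes/elements
#'   above this enter strain statistics.
#' @param min_bone_fraction minimum fraction of in-mask (bone) voxels a
#'   window needs to be correlated at all.  Bone-poor windows are weakly
#'   constrained (estimates pulled toward the nearest dense structure,
#'   compressing recovered strain gradients), while an aggressive cut
#'   starves the element grid of valid corners; the default 0.2 was
#'   calibrated on known affine deformations of the synthetic phantom.
#' @param median_half_width half-width of the image-space 3D median filter.
#' @param outlier_factor displacement-outlier factor (deviation from the
#'   neighborhood median beyond `outlier_factor * max(|median|, floor)`).
#' @param outlier_floor absolute floor (voxels) protecting near-zero medians.
#' @param field_median_radius radius of the displacement median filter.
#' @param prefilter_sigma SD (voxels) of a Gaussian low-pass applied to both
#'   volumes before correlation.  Sub-voxel matching through cubic
#'   interpolation carries a systematic, lattice-periodic bias ("peak
#'   locking") driven by the image's high-frequency content; a mild
#'   low-pass suppresses it.  0 disables.
#' @return An object of class `dvc_config`.
#' @export
dvc_config <- function(cw = 10L, ns = 10L, search_range = 10L, cc_min = 0.95,
                       min_bone_fraction = 0.2, median_half_width = 3L,
                       outlier_factor = 2, outlier_floor = 0.1,
                       field_median_radius = 1L, prefilter_sigma = 1) {
  stopifnot(cw >= 1, ns >= 1, search_range >= 0,
            cc_min > 0, cc_min <= 1, min_bone_fraction >= 0,
            median_half_width >= 0, outlier_factor > 0, outlier_floor >= 0,
            field_median_radius >= 0, prefilter_sigma >= 0)
  structure(list(cw = as.integer(cw), ns = as.integer(ns),
                 search_range = as.integer(search_range), cc_min = cc_min,
                 min_bone_fraction = min_bone_fraction,
                 median_half_width = as.integer(median_half_width),
                 outlier_factor = outlier_factor, outlier_floor = outlier_floor,
                 field_median_radius = as.integer(field_median_radius),
                 prefilter_sigma = prefilter_sigma),
            class = "dvc_config")
}

#' Per-scale DVC settings for the voxel-size study
#'
#' Downscaling factor 1 keeps the full-resolution protocol (CW +/-10, NS 10);
#' factor 4 uses CW +/-7 / NS 7 and factor 8 uses CW +/-5 / NS 5.  Other
#' factors are accepted but must supply `cw` and `ns` explicitly and are
#' flagged non-standard.
#'
#' @param factor integer downscaling factor (>= 1).
#' @param cw,ns overrides for the window half-width and node spacing.
#' @param base a [dvc_config] providing the remaining settings.
#' @return A `dvc_config` with an added `factor` field and `standard` flag.
#' @export
scale_config <- function(factor, cw = NULL, ns = NULL, base = dvc_config()) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  defaults <- list(`1` = c(10L, 10L), `4` = c(7L, 7L), `8` = c(5L, 5L))
  key <- as.character(factor)
  standard <- key %in% names(defaults)
  if (is.null(cw) || is.null(ns)) {
    if (!standard)
      stop("no standard CW/NS for factor ", factor, "; supply `cw` and `ns`")
    cw <- defaults[[key]][1]; ns <- defaults[[key]][2]
  }
  cfg <- dvc_config(cw = cw, ns = ns,
                    search_range = max(1L, base$search_range %/% factor),
                    cc_min = base$cc_min,
                    min_bone_fraction = base$min_bone_fraction,
                    median_half_width = base$median_half_width,
                    outlier_factor = base$outlier_factor,
                    outlier_floor = base$outlier_floor,
                    field_median_radius = base$field_median_radius,
                    # fixed physical bandwidth: the anti-peak-locking
                    # low-pass shrinks with the voxel size
                    prefilter_sigma = base$prefilter_sigma / factor)
  cfg$factor <- factor
  cfg$standard <- standard
  cfg
}

# Deterministic child seeds from one global seed, one per pipeline stage.
# Keeps independently reproducible stages below 2^31.
derive_seed <- function(seed, stage) {
  s <- (as.numeric(seed) %% 1937191) * 1103 + sum(utf8ToInt(stage)) * 7919
  as.integer(s %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
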