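#' Interpolate element-center strains onto a voxel grid
#'
#' Trilinear interpolation of the per-element volumetric strain from the
#' element-center grid onto every voxel of the target volume, so strain,
#' thickness, and density maps live on the same raster.  Voxels outside the
#' element-center hull, and voxels whose surrounding centers include an
#' invalid element, are missing.
#'
#' @param strain_field a `strain_field`.
#' @param target_shape integer 3-vector, voxels of the target grid (same
#'   resolution as the strain field's source volume).
#' @param extrapolate if `TRUE`, voxels outside the element-center hull
#'   take the value of the nearest hull face (clamped coordinates) and
#'   interpolation weights are renormalized over finite corners, so every
#'   voxel near at least one valid element gets a value.  Used when the
#'   same physical region must be covered at every resolution of the
#'   voxel-size study, where coarse grids' margins would otherwise clip
#'   the region.  The default keeps strict hull/validity semantics.
#' @return 3D array of volumetric strain per voxel (NA = missing).
#' @export
interpolate_strain_to_voxels <- function(strain_field, target_shape,
                                         extrapolate = FALSE) {
  stopifnot(inherits(strain_field, "strain_field"))
  ctr <- strain_field$centers
  if (any(vapply(ctr, length, 1L) < 2L)) stop("need >= 2 valid elements per axis")
  vals <- strain_field$volumetric
  d <- as.integer(target_shape)
  pos <- lapply(1:3, function(a) {
    cs <- ctr[[a]]
    p <- (0:(d[a] - 1) - cs[1]) / (cs[2] - cs[1])  # fractional index into centers
    if (extrapolate) p <- pmin(pmax(p, 0), length(cs) - 1)
    p
  })
  idx <- lapply(1:3, function(a) {
    i0 <- floor(pos[[a]])
    inside <- pos[[a]] >= 0 & pos[[a]] <= length(ctr[[a]]) - 1
    i0 <- pmin(pmax(i0, 0), length(ctr[[a]]) - 2)
    list(i0 = i0 + 1L, f = pos[[a]] - i0, inside = inside)
  })
  out <- array(0, dim = d)
  wsum <- array(0, dim = d)
  nasum <- array(FALSE, dim = d)
  fz <- idx[[1]]$f; fy <- idx[[2]]$f; fx <- idx[[3]]$f
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    vv <- vals[idx[[1]]$i0 + cz, idx[[2]]$i0 + cy, idx[[3]]$i0 + cx, drop = FALSE]
    wz <- if (cz == 1) fz else 1 - fz
    wy <- if (cy == 1) fy else 1 - fy
    wx <- if (cx == 1) fx else 1 - fx
    w <- outer(outer(wz, wy), wx)
    nasum <- nasum | (is.na(vv) & w > 1e-12)
    keep <- !is.na(vv)
    vv[!keep] <- 0
    if (extrapolate) w <- w * keep   # renormalize over finite corners
    out <- out + w * vv
    wsum <- wsum + w
  }
  out <- out / wsum                  # wsum = 1 unless renormalizing
  if (!extrapolate) {
    out[nasum] <- NA_real_
    outside <- !(outer(outer(idx[[1]]$inside, idx[[2]]$inside),
                       idx[[3]]$inside))
    out[outside] <- NA_real_
  } else {
    out[wsum <= 1e-12] <- NA_real_   # no finite corner at all
  }
  out
}

#' Accumulate per-step voxel strain maps
#'
#' Signed voxelwise cumulation (`cumulative[k] = sum of steps 1..k`)
#' followed by absolute maps; a voxel missing at any step stays missing
#' from that step onward.  Only pre-yield steps belong in the input:
#' strains after global yield, or where a crack is already visible, are not
#' meaningful under the continuity assumption of DVC.
#'
#' @param step_maps list of aligned 3D arrays (per-step voxel volumetric
#'   strain, NA = missing).
#' @return A `cumulative_strain` object: lists `cumulative` and `absolute`
#'   of per-step 3D arrays.
#' @export
accumulate_strain <- function(step_maps) {
  stopifnot(length(step_maps) >= 1)
  d <- dim(step_maps[[1]])
  ok <- vapply(step_maps, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("misaligned step maps")
  cum <- vector("list", length(step_maps))
  acc <- array(0, dim = d)
  for (k in seq_along(step_maps)) {
    acc <- acc + step_maps[[k]]   # NA propagates from first missing step on
    cum[[k]] <- acc
  }
  structure(list(cumulative = cum, absolute = lapply(cum, abs)),
            class = "cumulative_strain")
}

#' Resample a per-step series onto the normalized load axis
#'
#' Piecewise-linear interpolation of a per-step summary series onto a fixed
#' grid of fractional load, 0 = first DVC step and 1 = global yield, so
#' samples with different step counts can be averaged.
#'
#' @param values numeric per-step values (steps up to and including yield).
#' @param n_grid number of grid points (default 101).
#' @return data.frame with `load_fraction` and `value`.
#' @export
normalize_to_yield <- function(values, n_grid = 101L) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need >= 2 steps up to yield")
  x <- seq(0, 1, length.out = length(values))
  xo <- seq(0, 1, length.out = n_grid)
  data.frame(load_fraction = xo, value = approx(x, values, xout = xo)$y)
}

#' Summary statistics per region
#'
#' Means, SDs and voxel counts of the absolute cumulative volumetric
#' strain, trabecular thickness, and tissue mineral density, split into
#' crack and non-crack regions.
#'
#' @param absolute_map 3D array of absolute cumulative strain (NA allowed).
#' @param region_mask a `region_mask`.
#' @param thickness_map,tmd_map optional aligned maps (um, mg/cc).
#' @return data.frame with one row per region and quantity.
#' @export
summarize_regions <- function(absolute_map, region_mask,
                              thickness_map = NULL, tmd_map = NULL) {
  stopifnot(inherits(region_mask, "region_mask"))
  one <- function(map, sel, quantity, region) {
    v <- map[sel]
    v <- v[is.finite(v)]
    if (length(v) == 0L) stop("empty ", region, " region for ", quantity)
    data.frame(quantity = quantity, region = region, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_, n = length(v))
  }
  rows <- list(
    one(absolute_map, region_mask$crack_region, "abs_cum_strain", "crack"),
    one(absolute_map, region_mask$non_crack_region, "abs_cum_strain", "non_crack"))
  if (!is.null(thickness_map)) {
    rows <- c(rows, list(
      one(thickness_map, region_mask$crack_region, "tbth_um", "crack"),
      one(thickness_map, region_mask$non_crack_region, "tbth_um", "non_crack")))
  }
  if (!is.null(tmd_map)) {
    rows <- c(rows, list(
      one(tmd_map, region_mask$crack_region, "tmd_mg_cc", "crack"),
      one(tmd_map, region_mask$non_crack_region, "tmd_mg_cc", "non_crack")))
  }
  do.call(rbind, rows)
}

#' Normalized histogram of strain magnitudes in a region
#'
#' Counts are divided by the total number of (non-missing) region voxels,
#' which makes frequencies comparable across resolutions with different
#' voxel counts.
#'
#' @param absolute_map 3D array of absolute strains.
#' @param region logical array selecting the region.
#' @param bin_edges increasing numeric vector of bin edges; the default
#'   covers 0-20% strain in 0.5% bins.
#' @return data.frame with `lower`, `upper`, `frequency`.
#' @export
strain_histogram <- function(absolute_map, region,
                             bin_edges = seq(0, 0.20, by = 0.005)) {
  v <- absolute_map[region]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty region")
  counts <- graphics::hist(pmin(v, max(bin_edges)), breaks = bin_edges,
                           plot = FALSE, include.lowest = TRUE, right = FALSE)$counts
  data.frame(lower = bin_edges[-length(bin_edges)], upper = bin_edges[-1],
             frequency = counts / length(v))
}

#' Paired Wilcoxon signed-rank test of region means
#'
#' Exact two-sided signed-rank p-value for small samples (n <= 25, no ties
#' or zero differences), normal approximation otherwise; the effect size is
#' the 95% t-interval of the mean paired difference.  Per-sample region
#' means are the exchangeable unit (pooled voxels would be spatially
#' autocorrelated).
#'
#' @param crack_means,non_crack_means per-sample region means (>= 5 pairs).
#' @return List with `p_value`, `conf_int` (95% CI of mean difference) and
#'   `mean_difference`.
#' @export
paired_wilcoxon <- function(crack_means, non_crack_means) {
  stopifnot(length(crack_means) == length(non_crack_means),
            length(crack_means) >= 5L)
  d <- crack_means - non_crack_means
  ci <- if (sd(d) > 0) as.numeric(t.test(d)$conf.int) else c(mean(d), mean(d))
  if (all(d == 0))
    return(list(p_value = 1, conf_int = ci, mean_difference = 0))
  n <- length(d)
  exact <- n <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    wilcox.test(crack_means, non_crack_means, paired = TRUE,
                exact = exact, correct = FALSE)$p.value)
  list(p_value = min(1, p), conf_int = ci, mean_difference = mean(d))
}
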