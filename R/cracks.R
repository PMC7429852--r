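# Euclidean ball dilation of a logical mask: distance to the nearest true
# voxel <= radius (voxel centers).
dilate_ball <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  d2 <- array(cpp_edt2(mask, dim(mask)), dim = dim(mask))
  d2 <= radius^2
}

# Boundary voxels of a binary mask: 6-neighbor gradient is nonzero.
binary_edges <- function(mask) {
  g <- dim(mask)
  m <- mask + 0
  edge <- array(FALSE, dim = g)
  for (a in 1:3) {
    lo <- lapply(1:3, function(k) seq_len(g[k])); hi <- lo
    lo[[a]] <- pmax(lo[[a]] - 1L, 1L)
    hi[[a]] <- pmin(hi[[a]] + 1L, g[a])
    edge <- edge |
      (m != m[lo[[1]], lo[[2]], lo[[3]]]) |
      (m != m[hi[[1]], hi[[2]], hi[[3]]])
  }
  edge
}

#' Automated crack segmentation by dual thresholds and edge subtraction
#'
#' Reproduces the BS1/BS2/BS1e construction: `BS1` keeps everything at or
#' above the low threshold (bone tissue plus the intermediate-gray cracks
#' and pores); `BS1e` is the dilated edge band of `BS1` (structure surfaces,
#' whose partial-volume grays would otherwise read as cracks); `BS2` keeps
#' only confident bone at the high threshold.  The candidate crack set is
#' `BSc = clip(BS1 - BS2 - BS1e, 0)`, i.e. intermediate-gray voxels away
#' from structure surfaces, from which connected components smaller than
#' `min_crack_voxels` are removed.  Thresholds are dataset-specific.
#'
#' @param volume an [image_volume].
#' @param low_threshold gray level above which a voxel is tissue or crack.
#' @param high_threshold gray level above which a voxel is confident bone;
#'   must exceed `low_threshold`.
#' @param edge_dilation_radius ball radius (voxels) of the edge band.
#' @param min_crack_voxels minimum connected-component size kept.
#' @return A `crack_mask` object: logical array `mask`, integer `components`
#'   labels, and per-component `provenance` (`"auto"`).
#' @export
auto_segment_cracks <- function(volume, low_threshold, high_threshold,
                                edge_dilation_radius = 12L,
                                min_crack_voxels = 27L) {
  stopifnot(inherits(volume, "image_volume"))
  if (low_threshold >= high_threshold)
    stop("`low_threshold` must be below `high_threshold`")
  v <- volume$data
  bs1 <- v >= low_threshold
  if (!any(bs1)) stop("empty BS1: low threshold above all intensities")
  bs2 <- v >= high_threshold
  bs1e <- dilate_ball(binary_edges(bs1), edge_dilation_radius)
  bsc <- bs1 & !bs2 & !bs1e        # clip(BS1 - BS2 - BS1e, 0)
  lab <- array(cpp_label3(bsc, dim(bsc), 26L), dim = dim(bsc))
  if (any(bsc)) {
    sizes <- tabulate(lab[bsc])
    keep <- which(sizes >= min_crack_voxels)
    bsc <- bsc & lab %in% keep
    lab[!bsc] <- 0L
    lab <- array(cpp_label3(bsc, dim(bsc), 26L), dim = dim(bsc))
  }
  new_crack_mask(bsc, lab, volume$voxel_size)
}

new_crack_mask <- function(mask, components, voxel_size,
                           provenance = NULL) {
  ncomp <- max(components, 0L)
  if (is.null(provenance)) provenance <- rep("auto", ncomp)
  structure(list(mask = mask, components = components,
                 provenance = provenance, voxel_size = voxel_size),
            class = "crack_mask")
}

#' Apply manual corrections to an automated crack mask
#'
#' `(auto \ remove) U add`; idempotent, with provenance recorded per
#' connected component (`"auto"` or `"manual-added"`).  Supplying masks as
#' files keeps the human step reproducible and scriptable.
#'
#' @param auto_mask a `crack_mask` from [auto_segment_cracks()].
#' @param add_mask,remove_mask logical arrays of the same shape (or `NULL`).
#' @return The corrected `crack_mask`.
#' @export
apply_manual_corrections <- function(auto_mask, add_mask = NULL,
                                     remove_mask = NULL) {
  stopifnot(inherits(auto_mask, "crack_mask"))
  m <- auto_mask$mask
  if (!is.null(remove_mask)) {
    stopifnot(identical(dim(remove_mask), dim(m)))
    m <- m & !remove_mask
  }
  auto_part <- m
  if (!is.null(add_mask)) {
    stopifnot(identical(dim(add_mask), dim(m)))
    m <- m | add_mask
  }
  lab <- array(cpp_label3(m, dim(m), 26L), dim = dim(m))
  ncomp <- max(lab, 0L)
  prov <- character(ncomp)
  for (cmp in seq_len(ncomp)) {
    sel <- lab == cmp
    prov[cmp] <- if (any(sel & auto_part)) "auto" else "manual-added"
  }
  new_crack_mask(m, lab, auto_mask$voxel_size, prov)
}

#' Crack and non-crack analysis regions
#'
#' The crack region is the segmented crack mask dilated by a Euclidean ball
#' of `radius` voxels (5 voxels at 3.6 um = ~18 um margin), intersected with
#' the analyzed bone set; the non-crack region is the remaining analyzed
#' bone.  The two regions partition the analyzed bone exactly.
#'
#' @param crack_mask a `crack_mask` or logical array.
#' @param radius dilation radius, voxels (>= 0).
#' @param bone_mask logical array of analyzed bone voxels.
#' @return A `region_mask` object with logical arrays `crack_region` and
#'   `non_crack_region`, and the dilation `radius`.
#' @export
dilate_crack_region <- function(crack_mask, radius = 5L, bone_mask) {
  m <- if (inherits(crack_mask, "crack_mask")) crack_mask$mask else crack_mask
  stopifnot(is.array(m), identical(dim(m), dim(bone_mask)), radius >= 0)
  cr <- dilate_ball(m, radius)
  crack_region <- (cr | m) & (bone_mask | m)
  structure(list(crack_region = crack_region,
                 non_crack_region = bone_mask & !crack_region,
                 radius = radius),
            class = "region_mask")
}

#' Downscale a region partition by block vote
#'
#' A coarse voxel is crack-region when at least half of its `factor^3` block
#' is; the non-crack region is recomputed as the complement within the
#' downscaled bone set so the partition invariant is preserved.
#'
#' @param region_mask a `region_mask`.
#' @param factor integer downscaling factor >= 2.
#' @param bone_mask optional full-resolution bone mask to re-derive the
#'   analyzed set; defaults to the union of the two regions.
#' @return The downscaled `region_mask`.
#' @export
downscale_region <- function(region_mask, factor, bone_mask = NULL) {
  stopifnot(inherits(region_mask, "region_mask"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("`factor` must be an integer >= 2")
  if (is.null(bone_mask))
    bone_mask <- region_mask$crack_region | region_mask$non_crack_region
  cr <- block_vote(region_mask$crack_region, factor)
  bone <- block_vote(bone_mask, factor)
  structure(list(crack_region = cr & (bone | cr),
                 non_crack_region = bone & !cr,
                 radius = region_mask$radius / factor),
            class = "region_mask")
}
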