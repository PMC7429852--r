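#' Rigid (translation-only) alignment of two volumes
#'
#' Estimates the integer shift maximizing the cross-correlation between
#' `moving` and `reference` by 3D phase correlation, refines it by an
#' exhaustive +/-1 voxel check of the zero-normalized cross-correlation on
#' the overlap, and returns `moving` translated by that shift.  Residual
#' sub-voxel motion is left to the DVC stage.  Rotation is intentionally not
#' modeled: the loading rig constrains it.
#'
#' @param moving,reference [image_volume]s of identical shape and voxel size.
#' @param max_shift sanity bound on the recovered shift, voxels.
#' @param fill intensity for voxels vacated by the translation.
#' @return List with `aligned` ([image_volume]) and `shift` (integer
#'   3-vector, voxels, applied to `moving`).
#' @export
rigid_align <- function(moving, reference, max_shift = 20L, fill = 0) {
  stopifnot(inherits(moving, "image_volume"), inherits(reference, "image_volume"),
            identical(dim(moving$data), dim(reference$data)))
  a <- reference$data; b <- moving$data
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance image")
  d <- dim(a)
  Fa <- fft(a - mean(a)); Fb <- fft(b - mean(b))
  cps <- Fa * Conj(Fb)
  mag <- Mod(cps)
  cps <- cps / pmax(mag, 1e-12)
  corr <- Re(fft(cps, inverse = TRUE))
  peak <- which.max(corr)
  pk <- arrayInd(peak, d) - 1L
  shift <- ifelse(pk > d / 2, pk - d, pk)  # wrap to signed shift
  # refine by +/-1 hill climbing on the direct overlap correlation (the
  # phase peak can be off by a voxel or two under heavy noise)
  best_s <- shift
  best <- overlap_corr(a, b, best_s)
  if (!is.finite(best)) best <- -Inf
  for (it in 1:10) {
    improved <- FALSE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      s <- best_s + c(dz, dy, dx)
      if (any(abs(s) > max_shift)) next
      v <- overlap_corr(a, b, s)
      if (is.finite(v) && v > best) { best <- v; best_s <- s; improved <- TRUE }
    }
    if (!improved) break
  }
  aligned <- apply_deformation(moving, deformation_uniform(best_s), fill = fill)
  list(aligned = aligned, shift = as.integer(best_s))
}

# Pearson correlation of the overlap of a and b translated by s.
overlap_corr <- function(a, b, s) {
  d <- dim(a)
  ia <- lapply(1:3, function(k) {
    i <- seq_len(d[k])
    i[(i - s[k]) >= 1 & (i - s[k]) <= d[k]]
  })
  if (any(vapply(ia, length, 1L) < 4)) return(NA_real_)
  ib <- lapply(1:3, function(k) ia[[k]] - s[k])
  av <- a[ia[[1]], ia[[2]], ia[[3]]]
  bv <- b[ib[[1]], ib[[2]], ib[[3]]]
  if (sd(av) == 0 || sd(bv) == 0) return(NA_real_)
  stats::cor(as.vector(av), as.vector(bv))
}

#' 3D median filter
#'
#' Each voxel is replaced by the median of its `(2*half_width + 1)^3`
#' neighborhood with reflective (mirrored) boundary handling; `half_width =
#' 0` is the identity.  The protocol default of +/-3 voxels suppresses scan
#' noise while preserving the intra-trabecular intensity texture the
#' correlation relies on.
#'
#' @param volume an [image_volume].
#' @param half_width neighborhood half-width, voxels (>= 0).
#' @return The filtered [image_volume].
#' @export
median_filter3 <- function(volume, half_width = 3L) {
  stopifnot(inherits(volume, "image_volume"), half_width >= 0)
  out <- cpp_median_filter3(volume$data, dim(volume$data), as.integer(half_width))
  image_volume(array(out, dim = dim(volume$data)), volume$voxel_size,
               volume$origin)
}

#' Mask the bone phase / background of a volume
#'
#' Voxels at or above `bone_low_threshold` are flagged as bone; the largest
#' connected below-threshold component is additionally labeled as the
#' exterior background.  Windows dominated by background are excluded from
#' the correlation analysis downstream.
#'
#' @param volume an [image_volume] (typically median-filtered).
#' @param bone_low_threshold intensity threshold.
#' @return List with `bone` (logical array), `exterior` (logical array of
#'   the largest background component), and the threshold used.
#' @export
mask_background <- function(volume, bone_low_threshold) {
  stopifnot(inherits(volume, "image_volume"))
  bone <- volume$data >= bone_low_threshold
  if (!any(bone)) stop("all voxels below threshold: nothing to analyze")
  bg <- !bone
  exterior <- array(FALSE, dim = dim(bone))
  if (any(bg)) {
    lab <- array(cpp_label3(bg, dim(bone), 6L), dim = dim(bone))
    tab <- tabulate(lab[bg])
    exterior <- lab == which.max(tab)
  }
  list(bone = bone, exterior = exterior, threshold = bone_low_threshold)
}

#' Downscale a volume by block averaging
#'
#' Non-overlapping `factor^3` blocks are averaged (the anti-aliased analogue
#' of detector binning); trailing partial blocks are dropped and the voxel
#' size is multiplied by `factor`.
#'
#' @param volume an [image_volume].
#' @param factor integer factor >= 2.
#' @return The downscaled [image_volume].
#' @export
downscale <- function(volume, factor) {
  stopifnot(inherits(volume, "image_volume"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("`factor` must be an integer >= 2")
  if (any(dim(volume$data) < factor)) stop("factor larger than a dimension")
  out <- block_reduce(volume$data, factor)
  image_volume(out, volume$voxel_size * factor, volume$origin %/% factor)
}

# Mean over non-overlapping f^3 blocks, fully vectorized one axis at a time.
block_reduce <- function(arr, f) {
  for (ax in 1:3) {
    d <- dim(arr)
    n <- (d[ax] %/% f) * f
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- seq_len(n)
    arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    arr <- aperm(arr, c(ax, setdiff(1:3, ax)))
    dd <- dim(arr)
    m <- matrix(arr, nrow = f)
    arr <- array(colMeans(m), dim = c(dd[1] / f, dd[2], dd[3]))
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Block reduce for logical masks by majority vote (>= half true).
block_vote <- function(mask, f) {
  block_reduce(mask + 0, f) >= 0.5
}
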