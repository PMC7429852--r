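#' Ground-truth deformations for validating the DVC chain
#'
#' Three families with analytically known displacement and volumetric strain:
#' a uniform translation, an affine map about a center point, and a localized
#' radially decaying divergence field ("strain concentration") with
#' closed-form det(F).
#'
#' For the localized kind the displacement is `u(X) = a(r) (X - center)` with
#' `a(r) = p exp(-r^2 / (2 radius^2))` and `p = (1 + peak)^(1/3) - 1`, so the
#' volumetric strain at the center equals `peak` and
#' `det(F) - 1 = (1+a)^2 (1 + a - a r^2 / radius^2) - 1` everywhere.
#'
#' @param t translation, voxels (z, y, x).
#' @param A 3x3 matrix with positive determinant.
#' @param center center of the affine map / concentration, voxels (0-based).
#' @param radius Gaussian decay scale of the concentration, voxels (> 0).
#' @param peak volumetric strain at the concentration center (signed).
#' @return An object of class `deformation` (kinds `uniform`, `affine`,
#'   `localized`).
#' @name deformation
NULL

#' @rdname deformation
#' @export
deformation_uniform <- function(t) {
  stopifnot(length(t) == 3L)
  structure(list(kind = "uniform", t = as.numeric(t)), class = "deformation")
}

#' @rdname deformation
#' @export
deformation_affine <- function(A, t = c(0, 0, 0), center = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (det(A) <= 0) stop("det(A) must be > 0")
  structure(list(kind = "affine", A = A, t = as.numeric(t),
                 center = as.numeric(center)), class = "deformation")
}

#' @rdname deformation
#' @export
deformation_localized <- function(center, radius, peak) {
  stopifnot(length(center) == 3L, radius > 0)
  p <- (1 + peak)^(1 / 3) - 1
  structure(list(kind = "localized", center = as.numeric(center),
                 radius = radius, peak = peak, p = p), class = "deformation")
}

#' True displacement of a deformation at given material points
#'
#' @param deformation a [deformation].
#' @param coords N x 3 matrix of 0-based voxel coordinates (z, y, x).
#' @return N x 3 matrix of displacements in voxels.
#' @export
true_displacement <- function(deformation, coords) {
  coords <- matrix(coords, ncol = 3)
  switch(deformation$kind,
    uniform = matrix(deformation$t, nrow(coords), 3, byrow = TRUE),
    affine = {
      Xc <- sweep(coords, 2, deformation$center)
      Xc %*% t(deformation$A - diag(3)) +
        matrix(deformation$t, nrow(coords), 3, byrow = TRUE)
    },
    localized = {
      Xc <- sweep(coords, 2, deformation$center)
      r2 <- rowSums(Xc^2)
      a <- deformation$p * exp(-r2 / (2 * deformation$radius^2))
      Xc * a
    })
}

#' True volumetric strain det(F) - 1 at given material points
#'
#' @inheritParams true_displacement
#' @return Numeric vector of volumetric strains.
#' @export
true_volumetric_strain <- function(deformation, coords) {
  coords <- matrix(coords, ncol = 3)
  switch(deformation$kind,
    uniform = rep(0, nrow(coords)),
    affine = rep(det(deformation$A) - 1, nrow(coords)),
    localized = {
      Xc <- sweep(coords, 2, deformation$center)
      r2 <- rowSums(Xc^2)
      a <- deformation$p * exp(-r2 / (2 * deformation$radius^2))
      (1 + a)^2 * (1 + a - a * r2 / deformation$radius^2) - 1
    })
}

# Inverse material mapping X(x) for the deformed-image resampling.
inverse_map <- function(deformation, coords) {
  switch(deformation$kind,
    uniform = sweep(coords, 2, deformation$t),
    affine = {
      Ainv <- solve(deformation$A)
      xc <- sweep(coords, 2, deformation$center + deformation$t)
      sweep(xc %*% t(Ainv), 2, deformation$center, `+`)
    },
    localized = {
      X <- coords
      for (it in 1:12) X <- coords - true_displacement(deformation, X)
      X
    })
}

#' Warp a volume by a known deformation
#'
#' The deformed image is sampled by inverse mapping with tricubic
#' (Catmull-Rom) interpolation; material points falling outside the source
#' domain are filled with `fill`.  A uniform translation by an integer vector
#' reduces to an exact array shift.
#'
#' @param volume an [image_volume].
#' @param deformation a [deformation].
#' @param fill intensity for out-of-domain voxels (background gray).
#' @return The deformed [image_volume].
#' @export
apply_deformation <- function(volume, deformation, fill = 0) {
  stopifnot(inherits(volume, "image_volume"), inherits(deformation, "deformation"))
  d <- dim(volume$data)
  if (deformation$kind == "uniform" &&
      all(deformation$t == round(deformation$t))) {
    out <- array(fill, dim = d)
    t <- as.integer(round(deformation$t))
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a]) - t[a]
      i[i >= 1 & i <= d[a]]
    })
    dst <- lapply(1:3, function(a) src[[a]] + t[a])
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      volume$data[src[[1]], src[[2]], src[[3]]]
    return(image_volume(out, volume$voxel_size, volume$origin))
  }
  grid <- as.matrix(expand.grid(z = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                x = 0:(d[3] - 1)))
  X <- inverse_map(deformation, grid)
  inside <- X[, 1] >= 0 & X[, 1] <= d[1] - 1 &
            X[, 2] >= 0 & X[, 2] <= d[2] - 1 &
            X[, 3] >= 0 & X[, 3] <= d[3] - 1
  vals <- rep(fill, nrow(X))
  vals[inside] <- cpp_tricubic_sample(volume$data, dim(volume$data),
                                      X[inside, , drop = FALSE])
  image_volume(array(vals, dim = d), volume$voxel_size, volume$origin)
}

#' Specification of a planar crack slit
#'
#' @param center 0-based voxel coordinates (z, y, x) of the slit seed; must
#'   lie in the bone phase.
#' @param normal slit plane normal (any nonzero 3-vector).
#' @param thickness slit opening across the normal, voxels (>= 1).
#' @param extent lateral slit extent within the plane, voxels.
#' @param gray gray value written into the slit; must sit below the bone
#'   threshold so the slit reads as a discontinuity.
#' @return An object of class `crack_spec`.
#' @export
crack_spec <- function(center, normal, thickness = 2, extent = 12, gray = 90) {
  stopifnot(length(center) == 3L, length(normal) == 3L, thickness >= 1,
            extent >= 1, sum(normal^2) > 0)
  structure(list(center = as.numeric(center),
                 normal = normal / sqrt(sum(normal^2)),
                 thickness = thickness, extent = extent, gray = gray),
            class = "crack_spec")
}

#' Insert planar crack slits into a phantom
#'
#' Voxels within `thickness/2` of the slit plane and `extent/2` of the seed
#' (in-plane), restricted to the bone phase, are set to the slit gray value.
#' The returned mask marks exactly the modified voxels, so crack/bone mask
#' arithmetic is exact.
#'
#' @param volume an [image_volume].
#' @param crack_specs list of [crack_spec]s (may be empty).
#' @param bone_mask logical array of the bone phase.
#' @return List with `volume` (modified copy) and `crack_mask` (logical).
#' @export
insert_cracks <- function(volume, crack_specs, bone_mask) {
  stopifnot(inherits(volume, "image_volume"),
            identical(dim(bone_mask), dim(volume$data)))
  d <- dim(volume$data)
  img <- volume$data
  mask <- array(FALSE, dim = d)
  for (cs in crack_specs) {
    stopifnot(inherits(cs, "crack_spec"))
    ci <- round(cs$center) + 1
    if (any(ci < 1) || any(ci > d)) stop("crack seed outside volume")
    if (!bone_mask[ci[1], ci[2], ci[3]]) stop("crack seed not in bone")
    half <- ceiling(cs$extent / 2 + cs$thickness / 2) + 1
    lo <- pmax(ci - half, 1); hi <- pmin(ci + half, d)
    sub <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2],
                                 x = lo[3]:hi[3]))
    dd <- sweep(sub - 1, 2, cs$center)
    dn <- dd %*% cs$normal
    inplane2 <- rowSums(dd^2) - dn^2
    hit <- abs(dn) <= cs$thickness / 2 & inplane2 <= (cs$extent / 2)^2
    hit <- hit & bone_mask[sub]
    if (any(hit)) {
      idx <- sub[hit, , drop = FALSE]
      img[idx] <- cs$gray
      mask[idx] <- TRUE
    }
  }
  list(volume = image_volume(img, volume$voxel_size, volume$origin),
       crack_mask = mask)
}

#' Suggest crack sites in thin struts
#'
#' Picks seed voxels in struts whose local thickness is below the phantom
#' median, mirroring the observation that thin trabeculae crack.  Sites are
#' chosen greedily from the thinnest interior strut voxels with a minimum
#' mutual separation.
#'
#' @param bone_mask logical bone-phase array.
#' @param n number of sites.
#' @param margin border margin to stay clear of, voxels.
#' @param min_separation minimum distance between sites, voxels.
#' @param min_local_bvtv minimum local bone fraction (Gaussian-averaged at
#'   `bvtv_scale` voxels) around a site, so inserted cracks sit where
#'   correlation windows have enough bone to be analyzable; relaxed
#'   automatically if no candidate qualifies.
#' @param bvtv_scale averaging scale (voxels) of the local bone fraction.
#' @return N x 3 matrix of 0-based voxel coordinates.
#' @export
suggest_crack_sites <- function(bone_mask, n = 1L, margin = 16L,
                                min_separation = 20, min_local_bvtv = 0.25,
                                bvtv_scale = 7) {
  th <- cpp_local_thickness(bone_mask, dim(bone_mask), FALSE)
  th <- array(th, dim = dim(bone_mask))
  med <- median(th[bone_mask & th > 0])
  d <- dim(bone_mask)
  local_bv <- array(cpp_gauss_smooth3(bone_mask + 0, d, bvtv_scale), dim = d)
  cand <- which(bone_mask & th > 2 & th < med, arr.ind = TRUE)
  inb <- cand[, 1] > margin & cand[, 1] <= d[1] - margin &
         cand[, 2] > margin & cand[, 2] <= d[2] - margin &
         cand[, 3] > margin & cand[, 3] <= d[3] - margin
  cand <- cand[inb, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no thin-strut candidates inside the margin")
  dense <- local_bv[cand] >= min_local_bvtv
  if (any(dense)) cand <- cand[dense, , drop = FALSE]
  o <- order(th[cand])
  cand <- cand[o, , drop = FALSE]
  picked <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(picked) == 0L ||
        min(sqrt(rowSums(sweep(picked, 2, p)^2))) >= min_separation) {
      picked <- rbind(picked, p)
      if (nrow(picked) == n) break
    }
  }
  unname(picked - 1)
}
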