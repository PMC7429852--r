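#' Specification of a synthetic trabecular phantom
#'
#' The phantom is a thresholded Gaussian random field: white noise smoothed
#' with a Gaussian kernel whose width sets the strut scale, thresholded at
#' the intensity quantile that realizes the target bone volume fraction.
#' Bone voxels carry a smooth intra-trabecular intensity texture (required
#' for image correlation) plus optional additive Gaussian noise.
#'
#' @param shape integer 3-vector, voxels (z, y, x).
#' @param voxel_size voxel size in micrometres; default 3.6.
#' @param target_bvtv target bone volume fraction in (0, 1); default 0.3.
#' @param correlation_length Gaussian kernel FWHM-like scale in micrometres
#'   controlling strut thickness; must exceed `voxel_size`.  The default
#'   (120 um at 3.6 um voxels) yields struts of roughly 100-200 um.
#' @param texture_amplitude intra-trabecular texture amplitude as a fraction
#'   of `bone_gray`.
#' @param noise_sd additive Gaussian image noise SD, intensity units.
#' @param bone_gray,background_gray mean 8-bit gray levels of bone and
#'   marrow/background; `bone_gray` must exceed `background_gray`.
#' @param seed integer seed; identical specs with identical seeds generate
#'   identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L), voxel_size = 3.6,
                         target_bvtv = 0.3, correlation_length = 120,
                         texture_amplitude = 0.15, noise_sd = 5,
                         bone_gray = 180, background_gray = 60, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L), voxel_size > 0)
  if (!(target_bvtv > 0 && target_bvtv < 1))
    stop("`target_bvtv` must be in (0, 1)")
  if (correlation_length <= voxel_size)
    stop("`correlation_length` must exceed `voxel_size`")
  if (bone_gray <= background_gray)
    stop("`bone_gray` must exceed `background_gray`")
  structure(list(shape = shape, voxel_size = voxel_size,
                 target_bvtv = target_bvtv,
                 correlation_length = correlation_length,
                 texture_amplitude = texture_amplitude, noise_sd = noise_sd,
                 bone_gray = bone_gray, background_gray = background_gray,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Periodic FFT Gaussian smoothing of a 3D array, kernel SD in voxels.
gauss_smooth3 <- function(arr, sigma) {
  d <- dim(arr)
  k1 <- function(n) {
    t <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-0.5 * (t / sigma)^2)
    k / sum(k)
  }
  fz <- fft(k1(d[1])); fy <- fft(k1(d[2])); fx <- fft(k1(d[3]))
  K <- outer(outer(fz, fy), fx)
  Re(fft(fft(arr) * K, inverse = TRUE)) / prod(d)
}

#' Generate a trabecular-like phantom with ground truth
#'
#' @param spec a [phantom_spec].
#' @return A list with elements
#'   * `volume`: the [image_volume] (double-precision gray values),
#'   * `bone_mask`: logical 3D array of the bone phase,
#'   * `bvtv`: realized bone volume fraction,
#'   * `spec`: the input spec.
#' @export
generate_trabecular_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sigma <- spec$correlation_length / (2 * spec$voxel_size)  # voxels
  out <- with_seed(derive_seed(spec$seed, "phantom"), {
    field <- gauss_smooth3(array(rnorm(prod(d)), dim = d), sigma)
    thr <- quantile(field, 1 - spec$target_bvtv, names = FALSE)
    bone <- field >= thr
    # texture: a second, finer GRF normalized to unit SD
    tex <- gauss_smooth3(array(rnorm(prod(d)), dim = d), max(1, sigma / 4))
    tex <- tex / sd(tex)
    img <- array(spec$background_gray, dim = d)
    img[bone] <- spec$bone_gray * (1 + spec$texture_amplitude * pmax(-2, pmin(2, tex[bone])) / 2)
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
    img <- pmin(pmax(img, 0), 255)
    list(img = img, bone = bone)
  })
  bvtv <- mean(out$bone)
  if (abs(bvtv - spec$target_bvtv) > 0.02)
    stop("unreachable target BV/TV for this shape")
  list(volume = image_volume(out$img, spec$voxel_size),
       bone_mask = out$bone, bvtv = bvtv, spec = spec)
}

#' Generate uniform density-calibration phantoms
#'
#' One noisy uniform cylinder per density, mimicking the hydroxyapatite
#' calibration phantoms used to map grayscale to tissue mineral density.
#'
#' @param densities_mg_cc numeric vector of >= 2 distinct densities (mg/cc).
#' @param gray_of_density function mapping density to mean gray value.
#' @param noise_sd additive Gaussian noise SD.
#' @param shape phantom volume shape in voxels.
#' @param voxel_size voxel size in micrometres.
#' @param seed integer seed.
#' @return A list of [image_volume]s, one per density, each with attributes
#'   `density` (mg/cc) and `inside` (logical cylinder mask).
#' @export
generate_density_phantoms <- function(densities_mg_cc,
                                      gray_of_density = function(d) 50 + d / 10,
                                      noise_sd = 2, shape = c(24L, 32L, 32L),
                                      voxel_size = 3.6, seed = 1L) {
  if (length(unique(densities_mg_cc)) < 2L)
    stop("need at least 2 distinct densities")
  d <- as.integer(shape)
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2); cx <- (seq_len(d[3]) - (d[3] + 1) / 2)
  r2 <- outer(cy^2, cx^2, `+`)
  inside2d <- r2 <= (0.4 * min(d[2], d[3]))^2
  inside <- aperm(array(inside2d, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  with_seed(derive_seed(seed, "density-phantoms"), {
    lapply(seq_along(densities_mg_cc), function(i) {
      g <- gray_of_density(densities_mg_cc[i])
      img <- array(0, dim = d)
      img[inside] <- g
      if (noise_sd > 0) img[inside] <- img[inside] + rnorm(sum(inside), sd = noise_sd)
      v <- image_volume(img, voxel_size)
      attr(v, "density") <- densities_mg_cc[i]
      attr(v, "inside") <- inside
      v
    })
  })
}

#' Generate a synthetic compressive load curve
#'
#' Strain-controlled curve with a quadratic toe (slope-continuous with the
#' linear branch), a linear branch of slope `modulus`, a post-yield branch of
#' slope `hardening_ratio * modulus` up to the ultimate point, then linear
#' softening.  With `toe_strain = 0` and `noise_sd = 0` the pre-ultimate part
#' is exactly bilinear.
#'
#' @param modulus apparent modulus of the linear branch, MPa.
#' @param yield_strain strain at the yield knee (absolute, same axis as
#'   `toe_strain`); must exceed `toe_strain`.
#' @param hardening_ratio post-yield slope as a fraction of `modulus`.
#' @param toe_strain extent of the quadratic toe region.
#' @param noise_sd additive Gaussian stress noise SD, MPa.
#' @param n_points number of strain samples.
#' @param ultimate_strain strain at ultimate stress; default
#'   `yield_strain + 0.01`.
#' @param max_strain final strain of the record; default
#'   `ultimate_strain + 0.005`.
#' @param seed integer seed for the noise.
#' @return A data.frame with columns `strain` and `stress` (MPa).
#' @export
generate_load_curve <- function(modulus, yield_strain, hardening_ratio = 0.1,
                                toe_strain = 0, noise_sd = 0, n_points = 400L,
                                ultimate_strain = yield_strain + 0.01,
                                max_strain = ultimate_strain + 0.005,
                                seed = 1L) {
  stopifnot(modulus > 0, yield_strain > 0, hardening_ratio >= 0,
            toe_strain >= 0, n_points >= 10)
  if (yield_strain <= toe_strain) stop("`yield_strain` must exceed `toe_strain`")
  stopifnot(ultimate_strain > yield_strain, max_strain >= ultimate_strain)
  eps <- seq(0, max_strain, length.out = n_points)
  s_at <- function(e) {
    s_toe <- if (toe_strain > 0) modulus * toe_strain / 2 else 0
    s_y <- s_toe + modulus * (yield_strain - toe_strain)
    s_u <- s_y + hardening_ratio * modulus * (ultimate_strain - yield_strain)
    ifelse(e <= toe_strain,
           if (toe_strain > 0) modulus * e^2 / (2 * toe_strain) else modulus * e,
    ifelse(e <= yield_strain, s_toe + modulus * (e - toe_strain),
    ifelse(e <= ultimate_strain, s_y + hardening_ratio * modulus * (e - yield_strain),
           pmax(0, s_u - 0.5 * modulus * (e - ultimate_strain)))))
  }
  stress <- s_at(eps)
  if (noise_sd > 0)
    stress <- stress + with_seed(derive_seed(seed, "load-curve"),
                                 rnorm(length(eps), sd = noise_sd))
  data.frame(strain = eps, stress = stress)
}
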