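#' Virtual shift of a volume
#'
#' Exact integer array translation (no interpolation); vacated voxels are
#' filled with `fill` and excluded from analysis by the DVC margins.  Used
#' to measure the zero-strain noise floor of the whole DVC chain: any
#' nonzero strain recovered from a pair related by a pure translation is
#' error.
#'
#' @param volume an [image_volume].
#' @param shift integer 3-vector (z, y, x), voxels; the protocol value is
#'   2 voxels along all three axes.
#' @param fill intensity for vacated voxels.
#' @return The shifted [image_volume].
#' @export
virtual_shift <- function(volume, shift = c(2L, 2L, 2L), fill = 0) {
  stopifnot(inherits(volume, "image_volume"), length(shift) == 3L,
            all(shift == round(shift)))
  if (any(abs(shift) >= dim(volume$data))) stop("shift exceeds volume extent")
  apply_deformation(volume, deformation_uniform(as.integer(shift)), fill = fill)
}

#' Accuracy and precision of a nominally zero-strain field
#'
#' For each valid element the scalar `s = mean(|E11|, |E22|, |E33|, |E12|,
#' |E13|, |E23|)` is formed; accuracy is the mean and precision the sample
#' SD of `s` over elements whose correlation coefficient exceeds `cc_min`,
#' reported in microstrain.
#'
#' @param strain_field a `strain_field` from a virtual-shift or repeated
#'   pair.
#' @param cc_min CC gate (default 0.95).
#' @return An `accuracy_report`: list with `accuracy_ue`, `precision_ue`,
#'   `n`.
#' @export
accuracy_precision <- function(strain_field, cc_min = 0.95) {
  stopifnot(inherits(strain_field, "strain_field"))
  sel <- strain_field$valid & !is.na(strain_field$cc) & strain_field$cc > cc_min
  if (!any(sel)) stop("no elements pass the CC gate")
  Eabs <- abs(strain_field$E)
  s <- apply(Eabs, 1:3, mean)[sel]
  structure(list(accuracy_ue = mean(s) * 1e6,
                 precision_ue = if (length(s) > 1) sd(s) * 1e6 else 0,
                 n = length(s)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> accuracy %.1f ue, precision %.1f ue (n = %d elements)\n",
              x$accuracy_ue, x$precision_ue, x$n))
  invisible(x)
}

#' Noise floor of the full DVC chain
#'
#' Runs the complete protocol - rigid alignment, 3D median filter,
#' background masking, DVC, displacement filtering, Green strain, CC gating
#' - on a nominally zero-strain pair and reports [accuracy_precision()].
#' Protocol `"shift"` correlates a volume against its virtually shifted
#' copy; `"repeat"` correlates two independent noise realizations of the
#' same underlying volume (isolating the image-noise contribution that the
#' repeated-scan protocol is meant to bound).
#'
#' @param volume an [image_volume] (noise-free for `"repeat"`).
#' @param config a [dvc_config].
#' @param bone_threshold intensity threshold for the bone mask.
#' @param protocol `"shift"` or `"repeat"`.
#' @param shift integer shift for the `"shift"` protocol.
#' @param noise_sd image noise SD added to both copies under `"repeat"`.
#' @param seed seed for the `"repeat"` noise.
#' @return List with the `accuracy_report`, the `strain_field`, and the
#'   `displacement_field`.
#' @export
dvc_noise_floor <- function(volume, config = dvc_config(),
                            bone_threshold = 115,
                            protocol = c("shift", "repeat"),
                            shift = c(2L, 2L, 2L), noise_sd = 5, seed = 1L) {
  protocol <- match.arg(protocol)
  if (protocol == "shift") {
    ref <- volume
    def <- virtual_shift(volume, shift)
  } else {
    d <- dim(volume$data)
    ref <- volume; def <- volume
    ref$data <- with_seed(derive_seed(seed, "repeat-a"),
                          volume$data + array(rnorm(prod(d), sd = noise_sd), d))
    def$data <- with_seed(derive_seed(seed, "repeat-b"),
                          volume$data + array(rnorm(prod(d), sd = noise_sd), d))
  }
  al <- rigid_align(def, ref)
  ref_f <- median_filter3(ref, config$median_half_width)
  def_f <- median_filter3(al$aligned, config$median_half_width)
  msk <- mask_background(ref_f, bone_threshold)
  field <- run_dvc(ref_f, def_f, msk$bone, config)
  field <- filter_displacement_field(field, config$outlier_factor,
                                     config$field_median_radius,
                                     config$outlier_floor)
  sf <- green_strain(field)
  sf <- mask_by_correlation(sf, config$cc_min)
  list(report = accuracy_precision(sf, config$cc_min), strain_field = sf,
       displacement_field = field, residual_shift = al$shift)
}
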