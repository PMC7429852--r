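#' Simulate one in situ compression sample
#'
#' Emulates the imaging side of a stepwise compression experiment on one
#' trabecular sample: a textured phantom, a growing localized strain
#' concentration centered on a thin strut (the region that will crack),
#' per-step independent image noise, a final post-yield image with an
#' inserted crack slit at the concentration site, and a matching load
#' curve whose yield point falls at the last pre-yield step.
#'
#' @param seed integer seed.
#' @param shape phantom shape, voxels.
#' @param n_steps number of pre-yield loading steps (>= 2).
#' @param peak cumulative volumetric strain at the concentration center at
#'   the last pre-yield step (signed; negative = compressive).
#' @param radius Gaussian decay scale of the concentration, voxels.
#' @param noise_sd per-scan additive image noise SD.
#' @param site_margin border margin for the crack site, voxels.
#' @param correlation_length phantom strut scale, micrometres.  The study
#'   default (70 um) is finer than the single-phantom default so that a
#'   desk-scale volume holds several struts per side, as a full-size
#'   region of interest would.
#' @return List with the reference volume, per-step deformed volumes, the
#'   post-yield cracked volume, true crack mask, bone mask, concentration
#'   site/deformations, and the load curve.
#' @export
simulate_compression_sample <- function(seed = 1L, shape = c(112L, 112L, 112L),
                                        n_steps = 4L, peak = -0.08,
                                        radius = 10, noise_sd = 2,
                                        site_margin = 30L,
                                        correlation_length = 70) {
  spec <- phantom_spec(shape = shape, noise_sd = 0, seed = seed,
                       correlation_length = correlation_length)
  ph <- generate_trabecular_phantom(spec)
  clean <- ph$volume
  site <- drop(suggest_crack_sites(ph$bone_mask, n = 1L, margin = site_margin))
  add_noise <- function(vol, tag) {
    if (noise_sd <= 0) return(vol)
    vol$data <- vol$data + with_seed(derive_seed(seed, tag),
                                     array(rnorm(length(vol$data), sd = noise_sd),
                                           dim = dim(vol$data)))
    vol
  }
  deformations <- lapply(seq_len(n_steps), function(k)
    deformation_localized(site, radius, peak * k / n_steps))
  steps <- vector("list", n_steps + 1L)
  steps[[1]] <- add_noise(clean, "scan-0")
  for (k in seq_len(n_steps)) {
    dk <- apply_deformation(clean, deformations[[k]], fill = spec$background_gray)
    steps[[k + 1L]] <- add_noise(dk, paste0("scan-", k))
  }
  cs <- crack_spec(center = site, normal = c(1, 0, 0), thickness = 2,
                   extent = 12, gray = 90)
  # post-yield scan: the deformed structure with a visible discontinuity
  deformed_bone <- steps[[n_steps + 1L]]$data >= 115
  cracked <- insert_cracks(steps[[n_steps + 1L]], list(cs), deformed_bone)
  yield_strain <- 0.0085 * n_steps
  curve <- generate_load_curve(modulus = 250, yield_strain = yield_strain,
                               hardening_ratio = 0.05, toe_strain = 0.002,
                               noise_sd = 0.02, seed = derive_seed(seed, "curve"))
  list(steps = steps, final = cracked$volume, true_crack = cracked$crack_mask,
       bone_mask = ph$bone_mask, site = site, deformations = deformations,
       load_curve = curve, spec = spec, bvtv = ph$bvtv)
}

#' Analyze one simulated compression sample
#'
#' The full analysis chain for one sample: median filtering, background
#' masking, consecutive-step DVC, displacement filtering, Green strain,
#' CC gating, voxel interpolation, signed cumulation, crack segmentation
#' (automatic plus ground-truth-scripted manual correction), 5-voxel crack
#' region dilation, thickness and TMD maps, and per-step region means of
#' absolute cumulative volumetric strain.
#'
#' @param sample output of [simulate_compression_sample()].
#' @param config a [dvc_config]; the study default uses the full-resolution
#'   protocol window/spacing with a small search range matched to the
#'   sub-voxel step motions.
#' @param bone_threshold gray threshold of the mineralized phase.
#' @return List with per-step crack/non-crack mean absolute cumulative
#'   strains, the final-step `summary` (strain, Tb.Th, TMD), the region
#'   partition, and the segmentation Dice before manual correction.
#' @export
analyze_compression_sample <- function(sample,
                                       config = dvc_config(search_range = 2L,
                                                           median_half_width = 1L),
                                       bone_threshold = 115) {
  filt <- lapply(sample$steps, median_filter3, half_width = config$median_half_width)
  msk <- mask_background(filt[[1]], bone_threshold)
  n_steps <- length(filt) - 1L
  maps <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    field <- run_dvc(filt[[k]], filt[[k + 1L]], msk$bone, config)
    field <- filter_displacement_field(field, config$outlier_factor,
                                       config$field_median_radius,
                                       config$outlier_floor)
    sf <- mask_by_correlation(green_strain(field), config$cc_min)
    maps[[k]] <- interpolate_strain_to_voxels(sf, dim(filt[[1]]$data))
  }
  cum <- accumulate_strain(maps)
  auto <- auto_segment_cracks(sample$final, low_threshold = 80,
                              high_threshold = bone_threshold,
                              edge_dilation_radius = 3L, min_crack_voxels = 10L)
  dice <- dice_coefficient(auto$mask, sample$true_crack)
  corrected <- apply_manual_corrections(auto,
                                        add_mask = sample$true_crack & !auto$mask,
                                        remove_mask = auto$mask & !sample$true_crack)
  region <- dilate_crack_region(corrected, 5L, msk$bone)
  th <- local_thickness(msk$bone, sample$steps[[1]]$voxel_size, method = "fast")
  tmd <- tmd_map(filt[[1]], default_tmd_calibration(), msk$bone)
  step_means <- t(vapply(cum$absolute, function(a) {
    c(crack = mean(a[region$crack_region], na.rm = TRUE),
      non_crack = mean(a[region$non_crack_region], na.rm = TRUE))
  }, numeric(2)))
  summary <- summarize_regions(cum$absolute[[n_steps]], region,
                               thickness_map = th$map, tmd_map = tmd)
  list(step_means = step_means, summary = summary, region = region,
       cumulative = cum, dice_auto = dice, site = sample$site)
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2 |a & b| / (|a| + |b|)`; 1 for two empty masks.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' The canonical multi-sample crack study
#'
#' Simulates and analyzes `n_samples` independent samples and tests the
#' crack versus non-crack contrasts with the paired Wilcoxon signed-rank
#' test: per-sample region means of absolute cumulative volumetric strain
#' at the yield step, and region means of trabecular thickness.
#'
#' @param n_samples number of samples (>= 5 for the exact test).
#' @param seed global seed; sample k uses a derived child seed.
#' @param ... passed to [simulate_compression_sample()].
#' @return A `crack_study`: per-sample analyses, per-step mean matrices,
#'   Wilcoxon results for strain and thickness, and normalized
#'   cumulative-strain curves.
#' @export
run_crack_study <- function(n_samples = 6L, seed = 1L, ...) {
  analyses <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    smp <- simulate_compression_sample(seed = derive_seed(seed, paste0("sample-", i)), ...)
    analyses[[i]] <- analyze_compression_sample(smp)
  }
  yield_crack <- vapply(analyses, function(a) a$step_means[nrow(a$step_means), "crack"], 1)
  yield_non <- vapply(analyses, function(a) a$step_means[nrow(a$step_means), "non_crack"], 1)
  th_crack <- vapply(analyses, function(a)
    a$summary$mean[a$summary$quantity == "tbth_um" & a$summary$region == "crack"], 1)
  th_non <- vapply(analyses, function(a)
    a$summary$mean[a$summary$quantity == "tbth_um" & a$summary$region == "non_crack"], 1)
  curves <- lapply(analyses, function(a)
    normalize_to_yield(a$step_means[, "crack"]))
  structure(list(analyses = analyses,
                 strain_crack = yield_crack, strain_non_crack = yield_non,
                 tbth_crack = th_crack, tbth_non_crack = th_non,
                 wilcoxon_strain = paired_wilcoxon(yield_crack, yield_non),
                 wilcoxon_tbth = paired_wilcoxon(th_crack, th_non),
                 normalized_curves = curves),
            class = "crack_study")
}
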