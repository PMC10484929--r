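# 3D voxel classification: brain masking on a heavily blurred image,
# noise-sigma estimation from the 16th/84th percentiles of in-brain voxel
# values, difference-of-Gaussians band-pass, thresholding at k noise sigmas,
# and per-region positive volume fractions. All Gaussian sigmas are in-plane
# (2D filtering per z-slice): the z step (3.5 um) differs from the xy pitch,
# so filtering is kept strictly within acquisition planes.

#' Parameters of the voxel classifier
#'
#' @param sigma_mask_vx in-plane Gaussian sigma (voxels) of the blur used for
#'   brain masking. Default 10.
#' @param mask_threshold user-defined intensity threshold separating brain
#'   from background on the blurred image. No default: it depends on the
#'   acquisition and must be set explicitly (or see `auto_otsu` in
#'   [brain_mask()]).
#' @param noise_percentiles percentile pair bracketing +/- 1 sigma of the
#'   in-brain intensity distribution. Default c(16, 84).
#' @param sigma_hp_vx sigma (voxels) of the high-pass blur (subtracted).
#'   Default 6.
#' @param sigma_lp_vx sigma (voxels) of the low-pass blur. Default 1.
#' @param k_sigma positivity threshold in units of noise sigma. Default 2.
#' @return object of class `voxel_classifier_params`.
#' @export
voxel_classifier_params <- function(sigma_mask_vx = 10, mask_threshold = NULL,
                                    noise_percentiles = c(16, 84),
                                    sigma_hp_vx = 6, sigma_lp_vx = 1,
                                    k_sigma = 2) {
  assert_that(sigma_mask_vx > 0 && sigma_hp_vx > 0 && sigma_lp_vx > 0,
              "sigmas must be positive")
  assert_that(length(noise_percentiles) == 2 &&
                noise_percentiles[1] > 0 && noise_percentiles[2] < 100 &&
                noise_percentiles[1] < noise_percentiles[2],
              "noise_percentiles must satisfy 0 < p_low < p_high < 100")
  assert_that(k_sigma > 0, "k_sigma must be positive")
  structure(list(sigma_mask_vx = sigma_mask_vx, mask_threshold = mask_threshold,
                 noise_percentiles = as.numeric(noise_percentiles),
                 sigma_hp_vx = sigma_hp_vx, sigma_lp_vx = sigma_lp_vx,
                 k_sigma = k_sigma),
            class = "voxel_classifier_params")
}

#' Segment the brain from the background
#'
#' The stack is Gaussian-blurred slicewise (sigma `sigma_mask_vx`),
#' thresholded at `mask_threshold`, and the largest connected component
#' (6-connectivity in 3D) is retained.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param params a [voxel_classifier_params()]; `mask_threshold` must be set
#'   unless `auto_otsu = TRUE`.
#' @param auto_otsu if TRUE and no threshold is set, use Otsu's method on the
#'   blurred intensities as a fallback.
#' @return logical (y, x, z) array.
#' @export
brain_mask <- function(stack, params = voxel_classifier_params(),
                       auto_otsu = FALSE) {
  v <- stack_data(stack)
  thr <- params$mask_threshold
  blurred <- gblur_slicewise(v, params$sigma_mask_vx)
  if (is.null(thr)) {
    if (!auto_otsu)
      stop_brainfrac("mask_threshold is user-defined and must be set (or use auto_otsu = TRUE)")
    thr <- otsu_threshold(blurred)
  }
  m <- blurred > thr
  if (!any(m))
    stop_brainfrac("brain mask is empty: lower mask_threshold")
  largest_component_3d(m)
}

# Otsu threshold on a numeric array (256-bin histogram).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  bins <- findInterval(as.numeric(v), breaks, rightmost.closed = TRUE)
  counts <- tabulate(bins, nbins = 256)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p); mu <- cumsum(p * mids); mut <- mu[length(mu)]
  between <- (mut * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Estimate the noise sigma from in-brain percentiles
#'
#' Returns (P_high - P_low) / 2 of the raw voxel values inside the mask; with
#' the default 16th/84th percentiles this brackets +/- 1 sigma of the
#' intensity distribution. Percentiles use linear interpolation between order
#' statistics (quantile type 7).
#'
#' @param stack an [image_stack()] or 3D array (raw, unfiltered values).
#' @param mask logical array of in-brain voxels.
#' @param params a [voxel_classifier_params()].
#' @return noise sigma (scalar).
#' @export
estimate_noise_sigma <- function(stack, mask, params = voxel_classifier_params()) {
  v <- stack_data(stack)
  assert_that(identical(dim(v), dim(mask)), "stack and mask shapes differ")
  vals <- v[mask]
  assert_that(length(vals) > 0, "mask is empty")
  q <- quantile(vals, params$noise_percentiles / 100, type = 7, names = FALSE)
  (q[2] - q[1]) / 2
}

#' Difference-of-Gaussians band-pass filter
#'
#' Computes `G_lp * (I - G_hp * I)` slicewise in the (y, x) plane: the
#' high-pass removes the smooth autofluorescent background (subtraction of a
#' sigma-`sigma_hp_vx` blur), the low-pass (sigma `sigma_lp_vx`) suppresses
#' single-voxel noise. Linear in the input; constants map to 0.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param params a [voxel_classifier_params()].
#' @return numeric (y, x, z) array of filtered values.
#' @export
bandpass <- function(stack, params = voxel_classifier_params()) {
  v <- stack_data(stack)
  hp <- v - gblur_slicewise(v, params$sigma_hp_vx)
  gblur_slicewise(hp, params$sigma_lp_vx)
}

#' Classify voxels as positive
#'
#' A voxel is positive when its band-pass value exceeds
#' `k_sigma * noise_sigma` (one-sided, bright) and it lies inside the brain
#' (atlas label > 0, or a logical mask).
#'
#' @param filtered band-pass filtered array (from [bandpass()]).
#' @param noise_sigma scalar noise sigma (from [estimate_noise_sigma()]).
#' @param atlas_or_mask a [brain_atlas()] or a logical array.
#' @param params a [voxel_classifier_params()].
#' @return logical (y, x, z) array.
#' @export
classify_positive <- function(filtered, noise_sigma, atlas_or_mask,
                              params = voxel_classifier_params()) {
  assert_that(noise_sigma >= 0, "noise_sigma must be nonnegative")
  inb <- if (inherits(atlas_or_mask, "brain_atlas")) atlas_or_mask$labels > 0L
  else atlas_or_mask != 0
  assert_that(identical(dim(filtered), dim(inb)),
              "filtered volume and atlas/mask shapes differ")
  (filtered > params$k_sigma * noise_sigma) & inb
}

#' Per-region positive volume fractions
#'
#' Divides positive voxels by total voxels in each atlas region; a
#' "whole brain" row (the union of all regions) is appended, so its positive
#' count is the sum of the per-region counts.
#'
#' @param positive logical (y, x, z) array of positive voxels.
#' @param atlas a [brain_atlas()].
#' @return data.frame (region_id, region_name, positive_voxels, total_voxels,
#'   volume_fraction_pct); fractions are percentages.
#' @export
regional_volume_fraction <- function(positive, atlas) {
  assert_that(inherits(atlas, "brain_atlas"), "expected a brain_atlas")
  assert_that(identical(dim(positive), dim(atlas$labels)),
              "positive volume and atlas shapes differ")
  ids <- atlas$regions$id
  nb <- max(ids)
  tot <- tabulate(atlas$labels, nbins = nb)[ids]
  lab_pos <- atlas$labels[positive]
  pos <- tabulate(lab_pos[lab_pos > 0L], nbins = nb)[ids]
  out <- data.frame(region_id = ids, region_name = atlas$regions$name,
                    positive_voxels = pos, total_voxels = tot)
  out <- rbind(out, data.frame(region_id = 0L, region_name = "whole brain",
                               positive_voxels = sum(pos),
                               total_voxels = sum(tot)))
  out$volume_fraction_pct <- ifelse(out$total_voxels > 0,
                                    100 * out$positive_voxels / out$total_voxels,
                                    NA_real_)
  out
}

#' Full voxel quantification of one stack
#'
#' Convenience composition: brain mask (on the autofluorescence channel when
#' provided, else on the antibody channel), noise sigma from raw in-brain
#' values of the antibody channel, band-pass, classification restricted to
#' atlas-labelled voxels, and per-region volume fractions.
#'
#' @param antibody antibody-channel [image_stack()] or array.
#' @param atlas a [brain_atlas()].
#' @param params a [voxel_classifier_params()] with `mask_threshold` set.
#' @param autofluo optional autofluorescence channel for masking.
#' @param sigma_on_filtered estimate the noise sigma on the band-passed
#'   volume instead of the raw one (sensitivity analysis; default FALSE).
#' @return list with `table` (see [regional_volume_fraction()]),
#'   `noise_sigma`, `mask`, `positive`.
#' @export
quantify_stack <- function(antibody, atlas, params, autofluo = NULL,
                           sigma_on_filtered = FALSE) {
  mask <- brain_mask(if (is.null(autofluo)) antibody else autofluo, params)
  filtered <- bandpass(antibody, params)
  sigma <- if (sigma_on_filtered) estimate_noise_sigma(filtered, mask, params)
  else estimate_noise_sigma(antibody, mask, params)
  positive <- classify_positive(filtered, sigma, atlas, params)
  list(table = regional_volume_fraction(positive, atlas),
       noise_sigma = sigma, mask = mask, positive = positive)
}
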