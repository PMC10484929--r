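test_that("brain masking: empty, constant and ellipsoid cases", {
  zero <- array(0, c(32, 32, 8))
  expect_error(brain_mask(zero, voxel_classifier_params(mask_threshold = 1)),
               "empty")
  expect_error(brain_mask(zero, voxel_classifier_params()), "user-defined")
  # blur of a constant is the constant: full-volume mask
  const <- array(100, c(32, 32, 8))
  m <- brain_mask(const, voxel_classifier_params(mask_threshold = 50))
  expect_true(all(m))
  # phantom ellipsoid at study size: mask volume within 5% of (4/3) pi a b c
  # (the sigma = 10 mask blur needs the structure to be large against it)
  spec <- phantom_spec_3d(noise_sigma = 0, autofluo_level = 1000)
  v <- generate_brain_volume(spec)
  m <- brain_mask(v$autofluo, voxel_classifier_params(mask_threshold = 500))
  analytic <- 4 / 3 * pi * prod(spec$brain_semiaxes_vx)
  expect_lt(abs(sum(m) - analytic) / analytic, 0.05)
})

test_that("auto-Otsu fallback separates a bright ellipsoid from background", {
  spec <- phantom_spec_3d(noise_sigma = 2)
  v <- generate_brain_volume(spec)
  m <- brain_mask(v$autofluo, voxel_classifier_params(), auto_otsu = TRUE)
  analytic <- 4 / 3 * pi * prod(spec$brain_semiaxes_vx)
  expect_lt(abs(sum(m) - analytic) / analytic, 0.10)
})

test_that("percentile noise sigma: constant, enumerated, Gaussian", {
  m <- array(TRUE, c(101, 1, 1))
  const <- array(7, c(101, 1, 1))
  expect_equal(estimate_noise_sigma(const, m), 0)
  ramp <- array(0:100, c(101, 1, 1))
  expect_equal(estimate_noise_sigma(ramp, m), 34)  # (P84 - P16) / 2 on 0..100
  set.seed(31)
  g <- array(rnorm(1e6, sd = 5), c(100, 100, 100))
  est <- estimate_noise_sigma(g, array(TRUE, dim(g)))
  # analytic: half the 16-84 spread of N(0, 5) is 5 * qnorm(0.84) = 4.9725
  expect_lt(abs(est - 5 * qnorm(0.84)) / (5 * qnorm(0.84)), 0.03)
  expect_error(estimate_noise_sigma(g, array(FALSE, dim(g))), "empty")
})

test_that("band-pass removes DC, is linear, and matches a dense-convolution oracle", {
  p <- voxel_classifier_params()
  const <- array(123.4, c(40, 40, 3))
  out <- bandpass(const, p)
  expect_lt(max(abs(out)), 1e-9 * 123.4)
  set.seed(6)
  v <- array(rnorm(40 * 40 * 3), c(40, 40, 3))
  expect_equal(bandpass(v * 3.7, p), 3.7 * bandpass(v, p), tolerance = 1e-12)
  # impulse response peak against an independent dense convolution
  n <- 129; c0 <- 65
  imp <- array(0, c(n, n, 1)); imp[c0, c0, 1] <- 1
  got <- bandpass(imp, p)[c0, c0, 1]
  gk <- function(sigma) {
    r <- ceiling(4 * sigma); x <- seq(-r, r)
    k <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
    k / sum(k)
  }
  k1 <- gk(1); k6 <- gk(6)
  # (G1 * (delta - G6 * delta))(0) = G1(0,0) - sum(G1 .* G6) on common support
  r1 <- (nrow(k1) - 1) / 2; r6 <- (nrow(k6) - 1) / 2
  k6c <- k6[(r6 - r1 + 1):(r6 + r1 + 1), (r6 - r1 + 1):(r6 + r1 + 1)]
  oracle <- k1[r1 + 1, r1 + 1] - sum(k1 * k6c)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("classification: null case, blob recovery, threshold monotonicity", {
  p <- voxel_classifier_params()
  atlasmask <- array(TRUE, c(32, 32, 8))
  expect_equal(sum(classify_positive(array(0, c(32, 32, 8)), 1, atlasmask, p)), 0)

  # sparse planted blobs at 50 x noise sigma on a signal-free background:
  # every center recovered
  spec <- small_phantom_spec(c("5" = 0.01), noise_sigma = 1,
                             blob_amplitude = 50, background_level = 0,
                             background_gradient = c(0, 0, 0), seed = 9)
  v <- generate_brain_volume(spec)
  filt <- bandpass(v$antibody, p)
  mask <- v$truth$brain_mask
  sigma <- estimate_noise_sigma(v$antibody, mask, p)
  pos <- classify_positive(filt, sigma, mask, p)
  centers <- v$truth$blob_centers
  expect_true(all(pos[centers[, 1:3, drop = FALSE]]))
  # false positives among pure-noise voxels stay near the nominal tail rate;
  # exclude a box halo around every blob (their filtered tails are signal)
  halo <- array(FALSE, dim(pos))
  r <- 8L
  d <- dim(pos)
  for (b in seq_len(nrow(centers))) {
    c0 <- centers[b, 1:3]
    halo[max(1, c0[1] - r):min(d[1], c0[1] + r),
         max(1, c0[2] - r):min(d[2], c0[2] + r),
         max(1, c0[3] - r):min(d[3], c0[3] + r)] <- TRUE
  }
  pure <- mask & !halo
  fp <- sum(pos & pure) / sum(pure)
  # band-pass concentrates noise; the 2-sigma threshold on the raw-intensity
  # scale is far in the filtered-noise tail, so false positives are rare
  expect_lt(fp, 1.5 * pnorm(-2 / qnorm(0.84)))

  p3 <- voxel_classifier_params(k_sigma = 3)
  pos3 <- classify_positive(filt, sigma, mask, p3)
  expect_true(all(which(pos3) %in% which(pos)))  # k=3 positives nest in k=2
})

test_that("regional volume fractions: full region, none, checkerboard, additivity", {
  atlas <- seven_region_truth_atlas()
  lab <- atlas$labels
  full3 <- lab == 3L
  tab <- regional_volume_fraction(full3, atlas)
  expect_equal(tab$volume_fraction_pct[tab$region_id == 3], 100)
  expect_equal(tab$volume_fraction_pct[tab$region_id == 1], 0)

  none <- regional_volume_fraction(array(FALSE, dim(lab)), atlas)
  expect_true(all(none$volume_fraction_pct == 0))

  chk <- array((seq_along(lab) %% 2) == 0, dim(lab)) & (lab == 5L)
  tab2 <- regional_volume_fraction(chk, atlas)
  n5 <- sum(lab == 5L)
  expect_lte(abs(tab2$volume_fraction_pct[tab2$region_id == 5] - 50), 100 / n5 + 1e-9)

  wb <- tab2[tab2$region_id == 0, ]
  expect_equal(wb$positive_voxels,
               sum(tab2$positive_voxels[tab2$region_id != 0]))
  expect_equal(wb$total_voxels, sum(lab > 0))
  expect_error(regional_volume_fraction(array(FALSE, c(2, 2, 2)), atlas),
               "shapes differ")
})

test_that("volume fractions are invariant under an exact 90-degree rotation", {
  spec <- phantom_spec_3d(shape_vx = c(64, 64, 48),
                          brain_semiaxes_vx = c(24, 24, 18),
                          region_fractions = uniform_fractions(0.01),
                          seed = 14)
  v <- generate_brain_volume(spec)
  params <- voxel_classifier_params(mask_threshold = spec$autofluo_level / 2)
  q <- quantify_stack(v$antibody, v$truth$atlas, params, autofluo = v$autofluo)
  n <- dim(v$antibody$data)[1]
  rot <- pose_z(pi / 2, 1, c(0, n - 1, 0))
  ab_r <- apply_pose(v$antibody$data, rot, order = 0L)
  af_r <- apply_pose(v$autofluo$data, rot, order = 0L)
  lab_r <- apply_pose(v$truth$atlas$labels, rot, order = 0L)
  atlas_r <- brain_atlas(array(as.integer(round(lab_r)), dim(lab_r)),
                         v$truth$atlas$regions)
  q_r <- quantify_stack(ab_r, atlas_r, params, autofluo = af_r)
  expect_equal(q_r$table$volume_fraction_pct, q$table$volume_fraction_pct,
               tolerance = 1e-6)
})

test_that("stack TIFF round trip preserves values and metadata", {
  spec <- small_phantom_spec(uniform_fractions(0.01), seed = 2)
  v <- generate_brain_volume(spec)
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(v$antibody, f, extra = list(seed = spec$seed))
  back <- read_stack_tiff(f)
  expect_equal(back$spacing_um, v$antibody$spacing_um)
  expect_equal(back$channel, "antibody")
  rng <- diff(range(v$antibody$data))
  expect_lt(max(abs(back$data - v$antibody$data)), 1e-6 * rng)
  unlink(c(f, paste0(f, ".json")))
})
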