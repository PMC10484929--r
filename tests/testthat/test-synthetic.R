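test_that("zero requested fractions give an empty truth mask and pure background", {
  spec <- small_phantom_spec(noise_sigma = 0)
  v <- generate_brain_volume(spec)
  expect_equal(sum(v$truth$positive_mask), 0)
  expect_equal(sum(v$truth$region_fractions$positive_voxels), 0)
  # antibody = flat background (+ gradient) inside the brain, 0 outside
  expect_true(all(v$antibody$data[!v$truth$brain_mask] == 0))
  inb <- v$antibody$data[v$truth$brain_mask]
  expect_true(all(abs(inb - spec$background_level) <= 0.02 * 64))
})

test_that("generation is bit-identical for identical seeds", {
  spec <- small_phantom_spec(uniform_fractions(0.01), seed = 77)
  a <- generate_brain_volume(spec)
  b <- generate_brain_volume(spec)
  expect_identical(a$antibody$data, b$antibody$data)
  expect_identical(a$autofluo$data, b$autofluo$data)
  expect_identical(a$truth$positive_mask, b$truth$positive_mask)
  spec2 <- spec; spec2$seed <- 78L
  expect_false(identical(generate_brain_volume(spec2)$antibody$data,
                         a$antibody$data))
})

test_that("planted fractions hit their targets within one blob volume", {
  spec <- small_phantom_spec(c("5" = 0.025, "6" = 0.014), seed = 5)
  v <- generate_brain_volume(spec)
  ball <- nrow(brainfrac:::blob_ball_offsets(spec$blob_sigma_vx))
  tr <- v$truth$region_fractions
  lab <- v$truth$atlas$labels
  for (rid in c(5, 6)) {
    target <- spec$region_fractions[[as.character(rid)]]
    n_region <- sum(lab == rid)
    # oracle: exhaustive voxel count of the returned mask
    n_pos <- sum(v$truth$positive_mask & lab == rid)
    expect_equal(tr$positive_voxels[tr$region_id == rid], n_pos)
    expect_lte(abs(n_pos - target * n_region), ball)
    expect_equal(tr$true_fraction[tr$region_id == rid], n_pos / n_region)
  }
  # regions with no requested signal stay empty
  expect_equal(sum(v$truth$positive_mask & lab == 1), 0)
  # whole-brain row adds up
  wb <- tr[tr$region_id == 0, ]
  expect_equal(wb$positive_voxels, sum(tr$positive_voxels[tr$region_id != 0]))
})

test_that("planted positives grow monotonically with the requested fraction", {
  planted <- vapply(c(0.005, 0.01, 0.02, 0.04), function(f) {
    v <- generate_brain_volume(small_phantom_spec(c("5" = f), seed = 3))
    sum(v$truth$positive_mask)
  }, numeric(1))
  expect_true(all(diff(planted) >= 0))
})

test_that("unreachable fractions raise an error naming the region", {
  spec <- small_phantom_spec(c("4" = 0.9))
  expect_error(generate_brain_volume(spec), "region 4.*hippocampus")
})

test_that("annotation sampling is evenly spaced and identity at full density", {
  atlas <- seven_region_truth_atlas()
  nz <- dim(atlas$labels)[3]
  full <- generate_annotation_stack(atlas, nz, "z")
  expect_length(full, nz)
  for (k in c(1, nz %/% 2, nz))
    expect_identical(full[[k]]$label_image, atlas$labels[, , k])
  half <- generate_annotation_stack(atlas, 24, "z")
  planes <- vapply(half, function(a) a$plane_index, integer(1))
  expect_length(planes, 24)
  expect_true(all(diff(planes) >= 1) && max(abs(diff(diff(planes)))) <= 1)
  expect_error(generate_annotation_stack(atlas, 1, "z"), "at least 2")
  expect_error(generate_annotation_stack(atlas, nz + 1, "z"), "more slices")
})

test_that("atlas interpolated from 24 sparse planes matches the dense truth", {
  atlas <- seven_region_truth_atlas()
  anns <- generate_annotation_stack(atlas, 24, "z")
  rec <- interpolate_atlas(anns, dim(atlas$labels), atlas$regions)
  inb <- atlas$labels > 0
  agreement <- mean(rec$labels[inb] == atlas$labels[inb])
  expect_gte(agreement, 0.95)
})

test_that("cohorts are deterministic and jitter medians stay near group targets", {
  ctrl <- small_phantom_spec(uniform_fractions(0.005))
  trt <- small_phantom_spec(uniform_fractions(0.016))
  co1 <- generate_group_experiment(ctrl, trt, 6, 10, seed = 123)
  co2 <- generate_group_experiment(ctrl, trt, 6, 10, seed = 123)
  expect_identical(co1$specs, co2$specs)
  # sigma_log = 0: every animal carries the group target exactly
  co0 <- generate_group_experiment(ctrl, trt, 3, 3, seed = 1, sigma_log = 0)
  for (i in 1:3) expect_equal(co0$specs[[i]]$region_fractions,
                              ctrl$region_fractions)
  for (i in 4:6) expect_equal(co0$specs[[i]]$region_fractions,
                              trt$region_fractions)
  # materialized whole-brain truth medians within 20% of the group targets.
  # Needs the study-size geometry: in the small test phantom whole blobs are
  # coarse against the region sizes and quantization dominates.
  ctrl_f <- phantom_spec_3d(region_fractions = uniform_fractions(0.005))
  trt_f <- phantom_spec_3d(region_fractions = uniform_fractions(0.016))
  cof <- generate_group_experiment(ctrl_f, trt_f, 6, 10, seed = 123)
  wb_truth <- vapply(seq_len(16), function(i) {
    v <- generate_brain_volume(cof$specs[[i]])
    tr <- v$truth$region_fractions
    tr$true_fraction[tr$region_id == 0]
  }, numeric(1))
  expect_lt(abs(median(wb_truth[1:6]) - 0.005) / 0.005, 0.20)
  expect_lt(abs(median(wb_truth[7:16]) - 0.016) / 0.016, 0.20)
})

test_that("2D slices: empty specs, exact disk areas, planted colocalization", {
  blank <- phantom_spec_2d(shape_px = c(64, 64), noise_sigma = 0)
  s0 <- generate_cortex_slice(blank)
  expect_equal(nrow(s0$truth), 0)
  expect_true(all(s0$channels$ccasp3 == 0))

  one <- phantom_spec_2d(shape_px = c(64, 64),
                         cells = data.frame(y = 30, x = 30, radius_px = 4),
                         noise_sigma = 0)
  s1 <- generate_cortex_slice(one)
  expect_equal(s1$truth$area_px, disk_pixel_count(4))  # 49 px
  expect_gte(s1$truth$area_um2, 20.3)
  expect_lte(s1$truth$area_um2, 21.2)
  expect_equal(sum(s1$channels$ccasp3 > 0), s1$truth$area_px)

  cells <- grid_cells(10)
  cells$markers <- c(rep(list("NeuN"), 7), rep(list(character(0)), 3))
  sl <- generate_cortex_slice(phantom_spec_2d(cells = cells, seed = 2))
  with_marker <- sl$truth$markers == "NeuN"
  expect_equal(mean(with_marker), 0.7)
  expect_true("NeuN" %in% names(sl$channels))
})

test_that("overlapping planted cells are rejected", {
  cells <- data.frame(y = c(50, 55), x = c(50, 50), radius_px = 4)
  expect_error(phantom_spec_2d(cells = cells), "separation")
})
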