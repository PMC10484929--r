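test_that("blank images yield zero detections and bad input errors", {
  det <- detect_cells(matrix(0, 128, 128))
  expect_equal(nrow(det$cells), 0)
  expect_error(detect_cells(array(0, c(8, 8, 2))), "2D matrix")
})

test_that("well-separated in-range disks are all recovered, exactly once", {
  cells <- grid_cells(12)
  sl <- generate_cortex_slice(phantom_spec_2d(cells = cells, seed = 3))
  det <- detect_cells(sl$channels$ccasp3)
  expect_equal(nrow(det$cells), 12)
  # precision = recall = 1: every detection matches exactly one planted cell
  dmat <- sqrt(outer(det$cells$centroid_y_px, sl$truth$center_y_px, "-")^2 +
                 outer(det$cells$centroid_x_px, sl$truth$center_x_px, "-")^2)
  matches <- apply(dmat, 1, function(r) sum(r < 3))
  expect_true(all(matches == 1))
  expect_equal(length(unique(apply(dmat, 1, which.min))), 12)
  # detected areas close to the exact planted pixel count
  expect_true(all(abs(det$cells$area_px - disk_pixel_count(4)) <= 8))
})

test_that("the area filter excludes a radius-2 disk and keeps a radius-4 disk", {
  cells <- data.frame(y = c(60, 180), x = c(60, 180), radius_px = c(2, 4))
  sl <- generate_cortex_slice(phantom_spec_2d(shape_px = c(256, 256),
                                              cells = cells, seed = 4))
  # truth: 13 px * 0.645^2 = 5.4 um^2 < 15; 49 px = 20.4 um^2 in range
  expect_lt(sl$truth$area_um2[1], 15)
  expect_gt(sl$truth$area_um2[2], 15)
  det <- detect_cells(sl$channels$ccasp3)
  expect_equal(nrow(det$cells), 1)
  expect_lt(abs(det$cells$centroid_y_px - 180), 2)
})

test_that("detection count is invariant to a constant intensity offset", {
  sl <- generate_cortex_slice(phantom_spec_2d(cells = grid_cells(8), seed = 5))
  d0 <- detect_cells(sl$channels$ccasp3)
  d1 <- detect_cells(sl$channels$ccasp3 + 500)
  expect_equal(nrow(d1$cells), nrow(d0$cells))
  expect_equal(d1$cells$area_px, d0$cells$area_px)
})

test_that("shrinking the area or circularity window never adds detections", {
  sl <- generate_cortex_slice(phantom_spec_2d(cells = grid_cells(10), seed = 6))
  img <- sl$channels$ccasp3
  n_base <- nrow(detect_cells(img)$cells)
  tighter_area <- detect_cells(img, cell_counter_params(area_range_um2 = c(18, 25)))
  expect_lte(nrow(tighter_area$cells), n_base)
  tighter_circ <- detect_cells(img, cell_counter_params(circularity_range = c(0.95, 1)))
  expect_lte(nrow(tighter_circ$cells), n_base)
  # nested windows nest detections
  expect_lte(nrow(detect_cells(img, cell_counter_params(area_range_um2 = c(19, 22)))$cells),
             nrow(detect_cells(img, cell_counter_params(area_range_um2 = c(16, 30)))$cells))
})

test_that("the perimeter estimator ranks disks as round and lines as elongated", {
  disk <- function(r) {
    x <- seq(-r - 2, r + 2)
    outer(x^2, x^2, "+") <= r^2
  }
  expect_gte(brainfrac:::mask_circularity(disk(4)), 0.85)
  expect_gte(brainfrac:::mask_circularity(disk(10)), 0.85)
  expect_lte(brainfrac:::mask_circularity(disk(10)), 1)
  line <- matrix(FALSE, 5, 44); line[3, 3:42] <- TRUE
  expect_lt(brainfrac:::mask_circularity(line), 0.1)
})

test_that("minimum-distance suppression keeps the larger of two close detections", {
  img <- matrix(0, 128, 128)
  big <- brainfrac:::rasterize_disk(60, 60, 4.5, c(128, 128))
  small <- brainfrac:::rasterize_disk(60, 74, 3.5, c(128, 128))
  img[big] <- 200; img[small] <- 200
  # default min distance 1 um (< 14 px): both kept
  p0 <- cell_counter_params()
  expect_equal(nrow(detect_cells(img, p0)$cells), 2)
  # min distance above the 14-px spacing: only the larger survives
  p1 <- cell_counter_params(min_distance_um = 15 * 0.645)
  det <- detect_cells(img, p1)
  expect_equal(nrow(det$cells), 1)
  expect_lt(abs(det$cells$centroid_x_px - 60), 2)
})

test_that("laminar assignment uses half-open bands, a sentinel, and sums to 100", {
  b <- c(0, 100, 250, 512)
  cells <- grid_cells(12, step = 40)
  sl <- generate_cortex_slice(phantom_spec_2d(cells = cells, seed = 7,
                                              layer_boundaries_px = b))
  det <- detect_cells(sl$channels$ccasp3)
  tab <- assign_layers(det, b)
  expect_equal(sum(tab$fraction_pct), 100)
  expect_equal(sum(tab$count), nrow(det$cells))
  # oracle: the generator's own truth layers
  truth_counts <- table(factor(sl$truth$layer, levels = tab$layer))
  expect_equal(tab$count, as.integer(truth_counts))
  # all cells in one band
  one <- data.frame(centroid_y_px = c(10, 50, 99), centroid_x_px = 1:3)
  t1 <- assign_layers(one, b)
  expect_equal(t1$fraction_pct[t1$layer == "1"], 100)
  # boundary pixel belongs to the upper band (half-open)
  t2 <- assign_layers(data.frame(centroid_y_px = 100, centroid_x_px = 0), b)
  expect_equal(t2$count[t2$layer == "2"], 1)
  # outside sentinel
  t3 <- assign_layers(data.frame(centroid_y_px = 600, centroid_x_px = 0), b)
  expect_equal(t3$count[t3$layer == "outside"], 1)
  # empty input: empty table, no division by zero
  t4 <- assign_layers(detect_cells(matrix(0, 64, 64)), b)
  expect_equal(nrow(t4), 0)
})

test_that("a planted 51/100 split is reported as a 51% layer fraction", {
  # two bands; 51 cells in band 2 (the superficial-layer scenario)
  b <- c(0, 330, 660)
  g <- expand.grid(y = seq(15, 645, by = 30), x = seq(15, 645, by = 30))
  ord <- order(g$y)
  g <- g[ord, ]
  in2 <- g$y >= 330
  stopifnot(sum(!in2) >= 49, sum(in2) >= 51)
  cells <- rbind(head(g[!in2, ], 49), head(g[in2, ], 51))
  sl <- generate_cortex_slice(phantom_spec_2d(shape_px = c(660, 660),
                                              cells = data.frame(cells, radius_px = 4),
                                              layer_boundaries_px = b, seed = 8))
  det <- detect_cells(sl$channels$ccasp3)
  expect_equal(nrow(det$cells), 100)
  tab <- assign_layers(det, b)
  expect_equal(tab$fraction_pct[tab$layer == "2"], 51)
})

test_that("colocalization: blank, saturated and planted marker channels", {
  cells <- grid_cells(10)
  cells$markers <- c(rep(list("NeuN"), 7), rep(list(character(0)), 3))
  sl <- generate_cortex_slice(phantom_spec_2d(cells = cells, seed = 9))
  det <- detect_cells(sl$channels$ccasp3)
  expect_equal(nrow(det$cells), 10)
  blank <- matrix(0, 512, 512)
  sat <- matrix(1000, 512, 512)
  co <- colocalize(det, list(NeuN = sl$channels$NeuN, blank = blank))
  expect_equal(co$fraction_pct[co$marker == "NeuN"], 70)
  expect_equal(co$fraction_pct[co$marker == "blank"], 0)
  # saturated channel has no local contrast, so no pixel exceeds mean + 30
  co_sat <- colocalize(det, list(sat = sat))
  expect_equal(co_sat$fraction_pct, 0)
  # a uniformly bright channel with contrast at the cells: all positive
  co_all <- colocalize(det, list(all = sl$channels$ccasp3))
  expect_equal(co_all$fraction_pct, 100)
  expect_error(colocalize(det, list(bad = matrix(0, 10, 10))), "shape")
})
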