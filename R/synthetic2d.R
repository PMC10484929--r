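# Synthetic 2D cortical slices: disk-shaped "cells" of known rasterized
# area planted on a noisy background across cortical layers, with optional
# membership in additional marker channels (NeuN, GAD67, ...). Truth tables
# carry the exact pixel-counted area so detector tests have an unambiguous
# reference.

#' Specification of a 2D cortical slice phantom
#'
#' @param shape_px integer pair (rows, cols).
#' @param pixel_size_um pixel pitch in micrometres (default 0.645).
#' @param layer_boundaries_px increasing row coordinates (0-based) of the
#'   cortical layer boundaries, as delineated on a nuclear stain; layer i
#'   spans rows [b_i, b_{i+1}).
#' @param cells data.frame with columns `y`, `x` (0-based center pixel
#'   coordinates), `radius_px`, and optionally `markers` (list column of
#'   character vectors naming the extra channels each cell appears in).
#' @param cell_amplitude intensity of a planted cell above background.
#' @param noise_sigma additive Gaussian noise s.d.
#' @param min_separation_px minimum allowed gap between disk rims; closer
#'   pairs are rejected so the truth stays unambiguous. Default 3.
#' @param seed integer seed.
#' @return object of class `phantom_spec_2d`.
#' @export
phantom_spec_2d <- function(shape_px = c(512, 512), pixel_size_um = 0.645,
                            layer_boundaries_px = numeric(0),
                            cells = data.frame(y = numeric(0), x = numeric(0),
                                               radius_px = numeric(0)),
                            cell_amplitude = 200, noise_sigma = 5,
                            min_separation_px = 3, seed = 1L) {
  assert_that(length(shape_px) == 2 && all(shape_px >= 8),
              "shape_px must be a pair of image dimensions")
  assert_that(pixel_size_um > 0, "pixel_size_um must be positive")
  assert_that(!is.unsorted(layer_boundaries_px, strictly = TRUE),
              "layer boundaries must be strictly increasing")
  cells <- as.data.frame(cells)
  if (nrow(cells)) {
    assert_that(all(c("y", "x", "radius_px") %in% names(cells)),
                "cells needs columns y, x, radius_px")
    assert_that(all(cells$radius_px > 0), "cell radii must be positive")
    assert_that(all(cells$y >= 0 & cells$y <= shape_px[1] - 1 &
                      cells$x >= 0 & cells$x <= shape_px[2] - 1),
                "cell centers must lie inside the image")
    dmat <- as.matrix(dist(cells[, c("y", "x")]))
    need <- outer(cells$radius_px, cells$radius_px, "+") + min_separation_px
    diag(dmat) <- Inf
    if (any(dmat < need))
      stop_brainfrac("planted cells closer than the minimum separation")
  }
  structure(list(shape_px = as.integer(shape_px), pixel_size_um = pixel_size_um,
                 layer_boundaries_px = as.numeric(layer_boundaries_px),
                 cells = cells, cell_amplitude = cell_amplitude,
                 noise_sigma = noise_sigma,
                 min_separation_px = min_separation_px, seed = as.integer(seed)),
            class = "phantom_spec_2d")
}

# 1-based index matrix of the rasterized disk: pixels whose center lies
# within radius of the (0-based) center.
rasterize_disk <- function(cy, cx, r, shape) {
  ys <- max(0, floor(cy - r)):min(shape[1] - 1, ceiling(cy + r))
  xs <- max(0, floor(cx - r)):min(shape[2] - 1, ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= r^2, ]
  cbind(g$y + 1L, g$x + 1L)
}

#' Generate a multi-channel 2D cortical slice with known cell truth
#'
#' Every planted cell is drawn as a filled disk of `cell_amplitude` in the
#' main channel ("ccasp3") and in each marker channel it belongs to;
#' additive Gaussian noise is applied to every channel. Truth areas are the
#' exact rasterized pixel count times `pixel_size_um^2`.
#'
#' @param spec a [phantom_spec_2d()].
#' @return list with `channels` (named list of matrices; "ccasp3" first) and
#'   `truth` (data.frame cell, center_y_px, center_x_px, radius_px, area_px,
#'   area_um2, circularity, layer, markers).
#' @export
generate_cortex_slice <- function(spec) {
  assert_that(inherits(spec, "phantom_spec_2d"), "expected a phantom_spec_2d")
  shape <- spec$shape_px
  cells <- spec$cells
  marker_names <- unique(unlist(cells$markers))
  channels <- c("ccasp3", marker_names)
  imgs <- setNames(lapply(channels, function(ch) matrix(0, shape[1], shape[2])),
                   channels)
  truth <- NULL
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      pix <- rasterize_disk(cells$y[i], cells$x[i], cells$radius_px[i], shape)
      imgs[["ccasp3"]][pix] <- spec$cell_amplitude
      mk <- if (!is.null(cells$markers)) cells$markers[[i]] else character(0)
      for (m in mk) imgs[[m]][pix] <- spec$cell_amplitude
      mask <- matrix(FALSE, shape[1], shape[2]); mask[pix] <- TRUE
      circ <- mask_circularity(mask)
      layer <- layer_of_row(cells$y[i], spec$layer_boundaries_px)
      truth <- rbind(truth, data.frame(
        cell = i, center_y_px = cells$y[i], center_x_px = cells$x[i],
        radius_px = cells$radius_px[i], area_px = nrow(pix),
        area_um2 = nrow(pix) * spec$pixel_size_um^2,
        circularity = circ, layer = layer,
        markers = paste(mk, collapse = ";"),
        stringsAsFactors = FALSE))
    }
  } else {
    truth <- data.frame(cell = integer(0), center_y_px = numeric(0),
                        center_x_px = numeric(0), radius_px = numeric(0),
                        area_px = integer(0), area_um2 = numeric(0),
                        circularity = numeric(0), layer = character(0),
                        markers = character(0), stringsAsFactors = FALSE)
  }
  if (spec$noise_sigma > 0) {
    imgs <- with_seed(spec$seed, {
      lapply(imgs, function(im) im + rnorm(length(im), 0, spec$noise_sigma))
    })
  }
  list(channels = imgs, truth = truth)
}

layer_of_row <- function(y, boundaries) {
  if (length(boundaries) < 2) return(NA_character_)
  if (y < boundaries[1] || y >= boundaries[length(boundaries)]) return("outside")
  as.character(findInterval(y, boundaries))
}
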