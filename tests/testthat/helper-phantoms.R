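# Shared fixture builders. Unit-test phantoms are kept small (64 x 64 x 48)
# so the default suite stays fast; the acceptance tests use the full-size
# study geometry.

small_phantom_spec <- function(fractions = NULL, seed = 1L, ...) {
  rf <- if (is.null(fractions)) numeric(0) else fractions
  phantom_spec_3d(shape_vx = c(64, 64, 48), brain_semiaxes_vx = c(24, 26, 18),
                  region_fractions = rf, seed = seed, ...)
}

uniform_fractions <- function(f) setNames(rep(f, 7), as.character(1:7))

seven_region_truth_atlas <- function(spec = small_phantom_spec()) {
  lab <- brainfrac:::phantom_region_labels(spec)
  brain_atlas(lab, data.frame(id = 1:7, name = brainfrac:::region_names_for(7)),
              spacing_um = spec$spacing_um)
}

# Well-separated grid of disk cells for 2D detector tests.
grid_cells <- function(n, radius_px = 4, shape = c(512, 512), step = 100) {
  g <- expand.grid(y = seq(60, shape[1] - 60, by = step),
                   x = seq(60, shape[2] - 60, by = step))
  stopifnot(nrow(g) >= n)
  data.frame(y = g$y[seq_len(n)], x = g$x[seq_len(n)], radius_px = radius_px)
}

# Rasterized-disk pixel count (the 2D truth oracle).
disk_pixel_count <- function(r) {
  x <- seq(-ceiling(r), ceiling(r))
  sum(outer(x^2, x^2, "+") <= r^2)
}
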