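# Synthetic 3D phantoms with exact ground truth. The "brain" is an
# ellipsoid partitioned into 7 connected regions (anterior-posterior bands
# plus a central core), carrying punctate Gaussian blobs on a smooth
# autofluorescent background with additive Gaussian noise. "Positive" ground
# truth is the set of voxels where the noise-free blob signal exceeds half
# its peak amplitude, which makes the truth mask unambiguous and countable.

REGION_NAMES_7 <- c("myelencephalon", "metencephalon/midbrain", "diencephalon",
                    "hippocampus", "neocortex", "striatum", "cerebellum")

#' Specification of a 3D brain phantom
#'
#' @param shape_vx integer triple (y, x, z), voxel grid size.
#' @param spacing_um voxel spacing (y, x, z) in micrometres; default
#'   c(5, 5, 3.5) (low-magnification light-sheet pitch, 3.5 um z-step).
#' @param brain_semiaxes_vx ellipsoid semi-axes (y, x, z) in voxels; the
#'   ellipsoid must fit inside the grid with a margin for blob placement.
#' @param region_count number of regions (default 7; the canonical perinatal
#'   set of names is used for 7).
#' @param region_fractions named numeric vector mapping region id
#'   ("1".."7") to the target positive volume fraction in [0, 1]; missing
#'   regions default to 0.
#' @param blob_sigma_vx isotropic Gaussian sigma of a planted blob (voxels).
#' @param blob_amplitude peak intensity of a blob above the local background.
#' @param background_level in-brain baseline intensity of the antibody
#'   channel. Kept dim relative to `blob_amplitude` (default 20, vs noise
#'   sigma 8): the far-red antibody channel of cleared tissue carries little
#'   nonspecific signal, and a dim, flat background is what makes the
#'   percentile-based noise estimate and the band-pass classifier applicable.
#' @param background_gradient per-axis intensity slope (units per voxel,
#'   y/x/z) of the smooth background.
#' @param autofluo_level in-brain intensity of the autofluorescence channel.
#' @param noise_sigma standard deviation of the additive Gaussian noise on
#'   both channels.
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `phantom_spec_3d`.
#' @export
phantom_spec_3d <- function(shape_vx = c(128, 128, 96),
                            spacing_um = c(5, 5, 3.5),
                            brain_semiaxes_vx = c(52, 56, 40),
                            region_count = 7L,
                            region_fractions = numeric(0),
                            blob_sigma_vx = 2,
                            blob_amplitude = 45,
                            background_level = 20,
                            background_gradient = c(0, 0.02, 0),
                            autofluo_level = 120,
                            noise_sigma = 8,
                            seed = 1L) {
  shape_vx <- as.integer(as_triple(shape_vx, "shape_vx"))
  brain_semiaxes_vx <- as_triple(brain_semiaxes_vx, "brain_semiaxes_vx")
  assert_that(all(brain_semiaxes_vx > 0), "semi-axes must be positive")
  rhalf <- blob_sigma_vx * sqrt(2 * log(2))
  assert_that(all(shape_vx / 2 > brain_semiaxes_vx + ceiling(rhalf) + 1),
              "shape too small to contain the ellipsoid (plus blob margin)")
  assert_that(region_count >= 2, "need at least 2 regions")
  rf <- rep(0, region_count)
  names(rf) <- as.character(seq_len(region_count))
  if (length(region_fractions)) {
    ids <- names(region_fractions)
    if (is.null(ids)) ids <- as.character(seq_along(region_fractions))
    assert_that(all(ids %in% names(rf)),
                "region_fractions keys must be region ids")
    assert_that(all(region_fractions >= 0 & region_fractions <= 1),
                "fractions must lie in [0, 1]")
    rf[ids] <- region_fractions
  }
  assert_that(blob_sigma_vx > 0 && blob_amplitude > 0, "blob parameters must be positive")
  assert_that(background_level >= 0 && noise_sigma >= 0 && autofluo_level >= 0,
              "levels and noise must be nonnegative")
  structure(list(shape_vx = shape_vx, spacing_um = as_triple(spacing_um, "spacing_um"),
                 brain_semiaxes_vx = brain_semiaxes_vx,
                 region_count = as.integer(region_count),
                 region_fractions = rf,
                 blob_sigma_vx = blob_sigma_vx, blob_amplitude = blob_amplitude,
                 background_level = background_level,
                 background_gradient = as_triple(background_gradient, "background_gradient"),
                 autofluo_level = autofluo_level,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec_3d")
}

region_names_for <- function(k) {
  if (k == 7L) REGION_NAMES_7 else paste0("region_", seq_len(k))
}

# Normalized coordinate grids of the phantom: rho2 (ellipsoidal radius^2),
# ux (normalized x in [-1, 1] inside the brain).
phantom_geometry <- function(spec) {
  d <- spec$shape_vx
  ctr <- (d - 1) / 2
  a <- spec$brain_semiaxes_vx
  uy2 <- ((seq_len(d[1]) - 1 - ctr[1]) / a[1])^2
  ux <- (seq_len(d[2]) - 1 - ctr[2]) / a[2]
  uz2 <- ((seq_len(d[3]) - 1 - ctr[3]) / a[3])^2
  rho2 <- outer(outer(uy2, ux^2, "+"), uz2, "+")
  list(rho2 = rho2, ux = ux, center = ctr)
}

# Geometry (labels, in-region coordinates) is deterministic given shape,
# semi-axes and region count; cohorts share it across animals, so the last
# computed geometry is memoised.
.geom_cache <- new.env(parent = emptyenv())

geometry_key <- function(spec) {
  paste(c(spec$shape_vx, spec$brain_semiaxes_vx, spec$region_count),
        collapse = "|")
}

# Deterministic 7-region partition: core ball (region 4) plus
# anterior-posterior bands of the ellipsoid; generic equal bands otherwise.
phantom_region_labels <- function(spec) {
  key <- geometry_key(spec)
  hit <- .geom_cache$labels
  if (!is.null(hit) && identical(.geom_cache$key, key)) return(hit)
  lab <- phantom_region_labels_impl(spec)
  .geom_cache$key <- key
  .geom_cache$labels <- lab
  .geom_cache$coords <- NULL
  lab
}

# Per-region (y, x, z) index matrices, memoised alongside the labels.
phantom_region_coords <- function(spec, lab) {
  key <- geometry_key(spec)
  if (!is.null(.geom_cache$coords) && identical(.geom_cache$key, key))
    return(.geom_cache$coords)
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dim(lab))
  coords <- split.data.frame(co, lab[idx])
  coords <- lapply(coords, as.matrix)
  if (identical(.geom_cache$key, key)) .geom_cache$coords <- coords
  coords
}

phantom_region_labels_impl <- function(spec) {
  g <- phantom_geometry(spec)
  d <- spec$shape_vx
  brain <- g$rho2 <= 1
  lab <- array(0L, d)
  if (spec$region_count == 7L) {
    edges <- c(-1, -0.55, -0.25, 0, 0.3, 0.6, 1.000001)
    band_ids <- c(1L, 2L, 3L, 5L, 6L, 7L)
    core_id <- 4L
  } else {
    k <- spec$region_count
    edges <- seq(-1, 1.000001, length.out = k)
    band_ids <- seq_len(k - 1L)
    core_id <- k
  }
  ux_vol <- aperm(array(g$ux, c(d[2], d[1], d[3])), c(2, 1, 3))
  band <- findInterval(ux_vol[brain], edges, rightmost.closed = TRUE)
  lab[brain] <- band_ids[band]
  lab[g$rho2 <= 0.35^2] <- core_id
  lab
}

# All integer offsets strictly inside the half-maximum radius, as an
# n x 3 matrix of (dy, dx, dz).
blob_ball_offsets <- function(blob_sigma_vx) {
  rhalf2 <- 2 * blob_sigma_vx^2 * log(2)
  r <- ceiling(sqrt(rhalf2))
  s <- -r:r
  g <- expand.grid(dy = s, dx = s, dz = s)
  g <- g[g$dy^2 + g$dx^2 + g$dz^2 < rhalf2, ]
  as.matrix(g)
}

#' Generate a two-channel 3D brain phantom with known ground truth
#'
#' Blob centers are drawn uniformly inside each region (whole half-maximum
#' ball inside the region, no overlap between balls) until the planted
#' positive-voxel count reaches the requested fraction of the region to
#' within half a blob volume. The antibody channel is
#' background + gradient + blobs + noise; the autofluorescence channel is a
#' uniform in-brain level + noise.
#'
#' @param spec a [phantom_spec_3d()].
#' @return list with `autofluo` and `antibody` ([image_stack()]s) and
#'   `truth`: a list holding `atlas` ([brain_atlas()]), `brain_mask`,
#'   `positive_mask`, and `region_fractions` (data.frame region_id,
#'   region_name, positive_voxels, total_voxels, true_fraction, including a
#'   whole-brain row with region_id 0).
#' @export
generate_brain_volume <- function(spec) {
  assert_that(inherits(spec, "phantom_spec_3d"), "expected a phantom_spec_3d")
  d <- spec$shape_vx
  lab <- phantom_region_labels(spec)
  region_coords <- phantom_region_coords(spec, lab)
  brain <- lab > 0L
  offs <- blob_ball_offsets(spec$blob_sigma_vx)
  ball_n <- nrow(offs)
  rmax <- max(abs(offs))
  pos <- array(FALSE, d)
  centers <- NULL

  with_seed(spec$seed, {
    for (rid in seq_len(spec$region_count)) {
      f <- spec$region_fractions[[as.character(rid)]]
      if (f <= 0) next
      coords <- region_coords[[as.character(rid)]]
      n_region <- nrow(coords)
      target <- round(f * n_region)
      n_blobs <- round(target / ball_n)
      if (n_blobs == 0) next
      if (n_blobs * ball_n > 0.5 * n_region)
        stop_brainfrac(sprintf(
          "region %d (%s): requested fraction %.3g cannot be reached by non-overlapping blobs",
          rid, region_names_for(spec$region_count)[rid], f))
      placed <- 0L
      tries <- 0L
      max_tries <- 200L * n_blobs
      while (placed < n_blobs) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop_brainfrac(sprintf(
            "region %d (%s): unable to place %d blobs after %d tries",
            rid, region_names_for(spec$region_count)[rid], n_blobs, max_tries))
        i <- sample.int(nrow(coords), 1L)
        c0 <- coords[i, ]
        if (any(c0 <= rmax) || any(c0 > d - rmax)) next
        by <- c0[1] + offs[, 1]; bx <- c0[2] + offs[, 2]; bz <- c0[3] + offs[, 3]
        idx <- cbind(by, bx, bz)
        if (any(lab[idx] != rid) || any(pos[idx])) next
        pos[idx] <- TRUE
        centers <- rbind(centers, c(c0, rid))
        placed <- placed + 1L
      }
    }

    # antibody channel: smooth background inside the brain + blobs + noise
    ctr <- (d - 1) / 2
    grad <- spec$background_gradient
    bgy <- grad[1] * (seq_len(d[1]) - 1 - ctr[1])
    bgx <- grad[2] * (seq_len(d[2]) - 1 - ctr[2])
    bgz <- grad[3] * (seq_len(d[3]) - 1 - ctr[3])
    bg <- outer(outer(bgy, bgx, "+"), bgz, "+") + spec$background_level
    antibody <- array(0, d)
    antibody[brain] <- bg[brain]
    if (!is.null(centers)) {
      rbox <- ceiling(4 * spec$blob_sigma_vx)
      s <- -rbox:rbox
      prof <- exp(-s^2 / (2 * spec$blob_sigma_vx^2))
      patch <- spec$blob_amplitude *
        outer(outer(prof, prof, "*"), prof, "*")
      for (b in seq_len(nrow(centers))) {
        c0 <- centers[b, 1:3]
        ys <- pmax(1, c0[1] - rbox):pmin(d[1], c0[1] + rbox)
        xs <- pmax(1, c0[2] - rbox):pmin(d[2], c0[2] + rbox)
        zs <- pmax(1, c0[3] - rbox):pmin(d[3], c0[3] + rbox)
        antibody[ys, xs, zs] <- antibody[ys, xs, zs] +
          patch[ys - c0[1] + rbox + 1, xs - c0[2] + rbox + 1, zs - c0[3] + rbox + 1]
      }
    }
    autofluo <- array(0, d)
    autofluo[brain] <- spec$autofluo_level
    if (spec$noise_sigma > 0) {
      antibody <- antibody + rnorm(length(antibody), 0, spec$noise_sigma)
      autofluo <- autofluo + rnorm(length(autofluo), 0, spec$noise_sigma)
    }

    atlas <- brain_atlas(lab,
                         data.frame(id = seq_len(spec$region_count),
                                    name = region_names_for(spec$region_count)),
                         spacing_um = spec$spacing_um)
    truth_tab <- regional_volume_fraction(pos, atlas)
    truth_tab$true_fraction <- truth_tab$positive_voxels / truth_tab$total_voxels
    truth_tab$volume_fraction_pct <- NULL

    list(autofluo = image_stack(autofluo, spec$spacing_um, "autofluorescence"),
         antibody = image_stack(antibody, spec$spacing_um, "antibody"),
         truth = list(atlas = atlas, brain_mask = brain, positive_mask = pos,
                      region_fractions = truth_tab,
                      blob_centers = centers))
  })
}

#' Sample sparse per-slice annotations from a dense atlas
#'
#' Extracts the labels of `n_slices` evenly spaced planes along `axis`, for
#' round-tripping through [interpolate_atlas()] — the synthetic counterpart
#' of manually outlining regions on a subset of slices.
#'
#' @param atlas a [brain_atlas()] (e.g. `truth$atlas` of a phantom).
#' @param n_slices number of annotated planes (>= 2, <= extent along axis).
#' @param axis "z" (default; horizontal slices), "y" or "x".
#' @return list of [slice_annotation()] objects.
#' @export
generate_annotation_stack <- function(atlas, n_slices, axis = "z") {
  assert_that(inherits(atlas, "brain_atlas"), "expected a brain_atlas")
  ax_i <- match(axis, c("y", "x", "z"))
  assert_that(!is.na(ax_i), "axis must be 'y', 'x' or 'z'")
  extent <- dim(atlas$labels)[ax_i]
  assert_that(n_slices >= 2, "need at least 2 annotated slices")
  assert_that(n_slices <= extent, "more slices requested than planes available")
  planes <- unique(round(seq(0, extent - 1, length.out = n_slices)))
  lapply(planes, function(k)
    slice_annotation(axis, k, extract_plane(atlas$labels, axis, k)))
}

#' Generate a labelled two-group cohort of phantoms
#'
#' Produces `n_control + n_treated` independent phantom specifications whose
#' per-animal regional target fractions are the group targets jittered by
#' multiplicative lognormal noise (`exp(rnorm(0, sigma_log))`), emulating
#' animal-to-animal variability of a right-skewed positive quantity. Stacks
#' are materialized lazily with [generate_brain_volume()] to keep memory
#' bounded.
#'
#' @param control_spec,treated_spec [phantom_spec_3d()] templates carrying
#'   each group's target `region_fractions`.
#' @param n_control,n_treated group sizes (>= 1).
#' @param seed integer seed for the whole cohort.
#' @param sigma_log standard deviation of the log-multiplier (default 0.15;
#'   0 reproduces the targets exactly).
#' @return object of class `phantom_cohort`: list with `animals`
#'   (data.frame id, group, seed) and `specs` (list of per-animal
#'   [phantom_spec_3d()]).
#' @export
generate_group_experiment <- function(control_spec, treated_spec,
                                      n_control, n_treated, seed,
                                      sigma_log = 0.15) {
  assert_that(n_control >= 1 && n_treated >= 1, "group sizes must be >= 1")
  assert_that(inherits(control_spec, "phantom_spec_3d") &&
                inherits(treated_spec, "phantom_spec_3d"),
              "group templates must be phantom_spec_3d objects")
  n <- n_control + n_treated
  seeds <- derive_seeds(seed, n + 1L)
  groups <- rep(c("control", "treated"), c(n_control, n_treated))
  specs <- vector("list", n)
  jitters <- with_seed(seeds[n + 1L], {
    lapply(seq_len(n), function(i)
      exp(rnorm(control_spec$region_count, 0, sigma_log)))
  })
  for (i in seq_len(n)) {
    tmpl <- if (groups[i] == "control") control_spec else treated_spec
    fr <- pmin(tmpl$region_fractions * jitters[[i]], 1)
    specs[[i]] <- tmpl
    specs[[i]]$region_fractions <- fr
    specs[[i]]$seed <- seeds[i]
  }
  structure(list(animals = data.frame(id = sprintf("%s_%02d", substr(groups, 1, 4),
                                                   seq_len(n)),
                                      group = groups, seed = seeds[seq_len(n)],
                                      stringsAsFactors = FALSE),
                 specs = specs, sigma_log = sigma_log, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d animals (%d control, %d treated), seed %d\n",
              nrow(x$animals), sum(x$animals$group == "control"),
              sum(x$animals$group == "treated"), x$seed))
  invisible(x)
}
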