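# Dense regional atlas built from sparse per-slice manual annotations.
# Region shapes are interpolated between annotated planes through their
# signed distance maps (negative inside), the standard shape-based
# interpolation for reconstructing a label volume from sparse outlines.

#' Construct a brain atlas
#'
#' @param labels integer 3D array (y, x, z); 0 = outside brain, values >= 1
#'   are region ids listed in `regions`.
#' @param regions data.frame with columns `id` (>= 1) and `name`.
#' @param spacing_um voxel spacing (y, x, z) in micrometres.
#' @return object of class `brain_atlas`.
#' @export
brain_atlas <- function(labels, regions, spacing_um = c(5, 5, 3.5)) {
  assert_that(is.array(labels) && length(dim(labels)) == 3L,
              "labels must be a 3D array")
  assert_that(is.data.frame(regions) && all(c("id", "name") %in% names(regions)),
              "regions must be a data.frame with columns id, name")
  assert_that(all(regions$id >= 1) && !anyDuplicated(regions$id),
              "region ids must be unique and >= 1")
  present <- setdiff(unique(as.integer(labels)), 0L)
  assert_that(all(present %in% regions$id),
              "labels contain ids missing from the region table")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, regions = regions[order(regions$id), ],
                 spacing_um = as_triple(spacing_um, "spacing_um")),
            class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<brain_atlas> %d x %d x %d, %d regions, %d in-brain voxels\n",
              d[1], d[2], d[3], nrow(x$regions), sum(x$labels > 0)))
  invisible(x)
}

#' Construct a per-slice annotation
#'
#' @param axis one of "z", "y", "x": the axis perpendicular to the annotated
#'   plane ("z" corresponds to horizontal slices).
#' @param plane_index 0-based index of the annotated plane along `axis`.
#' @param label_image 2D integer image of region labels on that plane. For
#'   axis "z" its dimensions are (y, x); for "y", (x, z); for "x", (y, z).
#' @return object of class `slice_annotation`.
#' @export
slice_annotation <- function(axis, plane_index, label_image) {
  assert_that(axis %in% c("y", "x", "z"), "axis must be 'y', 'x' or 'z'")
  assert_that(plane_index >= 0 && plane_index == round(plane_index),
              "plane_index must be a nonnegative integer")
  assert_that(is.matrix(label_image), "label_image must be a matrix")
  structure(list(axis = axis, plane_index = as.integer(plane_index),
                 label_image = label_image),
            class = "slice_annotation")
}

BIG_DIST <- 1e6

# Signed Euclidean distance of a binary mask: negative inside, positive
# outside; empty masks are "far outside" everywhere, full masks "far inside".
signed_distance <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(matrix(BIG_DIST, nrow(mask), ncol(mask)))
  if (all(m)) return(matrix(-BIG_DIST, nrow(mask), ncol(mask)))
  d_in <- as.matrix(EBImage::distmap(m * 1))
  d_out <- as.matrix(EBImage::distmap((!m) * 1))
  d_out - d_in
}

# Extract the plane at 0-based index k along axis from a (y, x, z) volume.
extract_plane <- function(vol, axis, k) {
  switch(axis,
         z = vol[, , k + 1L],
         y = vol[k + 1L, , ],
         x = vol[, k + 1L, ])
}

# Interpolated label volume from one axis group of annotations.
interpolate_axis_group <- function(anns, out_shape, region_ids) {
  axis <- anns[[1]]$axis
  ax_i <- match(axis, c("y", "x", "z"))
  n_ax <- out_shape[ax_i]
  planes <- vapply(anns, function(a) a$plane_index, integer(1))
  o <- order(planes)
  anns <- anns[o]; planes <- planes[o]
  assert_that(!anyDuplicated(planes), "duplicate annotated planes")
  assert_that(all(planes < n_ax), "plane_index outside the output volume")
  assert_that(length(planes) >= 2, "need at least 2 annotated planes per axis")
  plane_dim <- out_shape[-ax_i]
  # for every output plane t: bracketing annotated planes and weight
  t_all <- seq_len(n_ax) - 1L
  idx_hi <- findInterval(t_all, planes, left.open = TRUE) + 1L
  idx_hi <- pmin(pmax(idx_hi, 2L), length(planes))
  idx_lo <- idx_hi - 1L
  w_hi <- (t_all - planes[idx_lo]) / (planes[idx_hi] - planes[idx_lo])
  w_hi <- pmin(pmax(w_hi, 0), 1)  # clamp beyond the annotated range

  best_val <- array(BIG_DIST, c(plane_dim, n_ax))
  best_lab <- array(0L, c(plane_dim, n_ax))
  for (rid in region_ids) {
    sd_planes <- lapply(anns, function(a) signed_distance(a$label_image == rid))
    for (t in seq_len(n_ax)) {
      sdt <- (1 - w_hi[t]) * sd_planes[[idx_lo[t]]] + w_hi[t] * sd_planes[[idx_hi[t]]]
      better <- sdt < best_val[, , t]
      if (any(better)) {
        bv <- best_val[, , t]; bl <- best_lab[, , t]
        bv[better] <- sdt[better]; bl[better] <- rid
        best_val[, , t] <- bv; best_lab[, , t] <- bl
      }
    }
  }
  best_lab[array(best_val, dim(best_lab)) >= 0] <- 0L
  # reorder plane-stacked array back to (y, x, z)
  lab <- switch(axis,
                z = best_lab,
                y = aperm(best_lab, c(3, 1, 2)),
                x = aperm(best_lab, c(1, 3, 2)))
  list(labels = lab, axis = axis, lo = min(planes), hi = max(planes), ax_i = ax_i)
}

#' Reconstruct a dense atlas from sparse per-slice annotations
#'
#' For each region and each annotated plane a signed distance map is
#' computed (negative inside the region); distances are linearly
#' interpolated between consecutive annotated planes along the annotation
#' axis, and each voxel takes the region with the most-negative interpolated
#' distance (ties broken towards the lower region id), or 0 if none is
#' negative. Beyond the first/last annotated plane the nearest annotated
#' plane is used. Annotations on different axes form groups (in order of
#' first appearance); later groups override earlier ones inside the slab
#' spanned by their annotated planes.
#'
#' @param annotations list of [slice_annotation()] objects (>= 2 per axis).
#' @param out_shape integer triple (y, x, z).
#' @param regions region table (data.frame id, name).
#' @param brain_mask optional logical array; labels outside it are cleared.
#' @param spacing_um voxel spacing passed through to the atlas.
#' @return a [brain_atlas()].
#' @export
interpolate_atlas <- function(annotations, out_shape, regions,
                              brain_mask = NULL, spacing_um = c(5, 5, 3.5)) {
  assert_that(length(annotations) >= 2, "need at least 2 annotations")
  assert_that(all(vapply(annotations, inherits, logical(1), "slice_annotation")),
              "annotations must be slice_annotation objects")
  out_shape <- as.integer(as_triple(out_shape, "out_shape"))
  ann_labels <- unique(unlist(lapply(annotations, function(a)
    unique(as.integer(a$label_image)))))
  assert_that(all(setdiff(ann_labels, 0L) %in% regions$id),
              "annotation labels are inconsistent with the region table")
  axes <- vapply(annotations, function(a) a$axis, character(1))
  region_ids <- sort(regions$id)
  lab <- NULL
  for (ax in unique(axes)) {
    grp <- interpolate_axis_group(annotations[axes == ax], out_shape, region_ids)
    if (is.null(lab)) {
      lab <- grp$labels
    } else {
      # override inside the slab covered by this group's annotated planes
      idx <- (grp$lo:grp$hi) + 1L
      if (grp$ax_i == 1L) lab[idx, , ] <- grp$labels[idx, , ]
      else if (grp$ax_i == 2L) lab[, idx, ] <- grp$labels[, idx, ]
      else lab[, , idx] <- grp$labels[, , idx]
    }
  }
  if (!is.null(brain_mask)) lab[!brain_mask] <- 0L
  brain_atlas(lab, regions, spacing_um = spacing_um)
}

#' Voxel counts per atlas region
#'
#' @param atlas a [brain_atlas()].
#' @return data.frame (id, name, voxel_count), one row per region actually
#'   present in the label volume; counts sum to the in-brain voxel count.
#' @export
region_fraction_table <- function(atlas) {
  assert_that(inherits(atlas, "brain_atlas"), "expected a brain_atlas")
  if (nrow(atlas$regions) == 0 || !any(atlas$labels > 0L))
    return(data.frame(id = integer(0), name = character(0),
                      voxel_count = integer(0)))
  counts <- tabulate(atlas$labels, nbins = max(atlas$regions$id))
  out <- data.frame(id = atlas$regions$id, name = atlas$regions$name,
                    voxel_count = counts[atlas$regions$id])
  out[out$voxel_count > 0, , drop = FALSE]
}
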