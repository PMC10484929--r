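# Multi-page TIFF I/O. Stacks are written as one 32-bit float page per
# z-slice, linearly rescaled to [0, 1]; the affine rescaling, voxel spacing
# and channel tag go to a JSON sidecar ("<file>.json") so reads restore the
# original values exactly (up to float precision).

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @param extra named list merged into the sidecar (e.g. seed, spec).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, extra = list()) {
  v <- stack_data(stack)
  rng <- range(v)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(v)[3]), function(z) (v[, , z] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- c(list(spacing_um = stack$spacing_um, channel = stack$channel,
                 offset = rng[1], scale = scale, dim = dim(v)), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#' @param path TIFF path.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else
    list(spacing_um = c(5, 5, 3.5), channel = "unknown", offset = 0, scale = 1)
  v <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  v <- v * meta$scale + meta$offset
  image_stack(v, spacing_um = unlist(meta$spacing_um), channel = meta$channel)
}

#' Write an atlas as integer TIFF plus regions CSV
#' @param atlas a [brain_atlas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- atlas$labels
  mx <- max(1L, max(lab))
  pages <- lapply(seq_len(dim(lab)[3]), function(z) lab[, , z] / mx)
  tiff::writeTIFF(pages, file.path(dir, "labels.tif"), bits.per.sample = 16L)
  write.csv(atlas$regions, file.path(dir, "regions.csv"), row.names = FALSE)
  jsonlite::write_json(list(max_label = mx, spacing_um = atlas$spacing_um,
                            dim = dim(lab)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an atlas written by [write_atlas()]
#' @param dir atlas directory.
#' @return A [brain_atlas()].
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "labels.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lab <- array(as.integer(round(unlist(pages) * meta$max_label)),
               dim = c(dim(pages[[1]]), length(pages)))
  regions <- read.csv(file.path(dir, "regions.csv"), stringsAsFactors = FALSE)
  brain_atlas(lab, regions, spacing_um = unlist(meta$spacing_um))
}

#' Read landmark line(s) from JSON
#'
#' The JSON format is `{"p0": [y, x, z], "p1": [y, x, z]}` in 0-based voxel
#' coordinates.
#' @param path JSON file.
#' @return A [landmark_line()].
#' @export
read_landmarks_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_line(unlist(j$p0), unlist(j$p1))
}

#' @rdname read_landmarks_json
#' @param line a [landmark_line()].
#' @export
write_landmarks_json <- function(line, path) {
  jsonlite::write_json(list(p0 = line$p0, p1 = line$p1), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
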