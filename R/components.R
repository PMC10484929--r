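# Connected-component labelling. EBImage::bwlabel is 4-connected in 2D;
# 8-connectivity is obtained by merging labels that touch diagonally, and
# 3D (6-connected) labelling by merging per-slice labels that overlap in
# consecutive slices. Merging uses a small union-find.

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

uf_merge_pairs <- function(n, pairs) {
  parent <- seq_len(n)
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- uf_find(parent, pairs[r, 1])
      b <- uf_find(parent, pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# Unique label pairs (both > 0, different) between two equally shaped arrays.
adjacent_label_pairs <- function(a, b) {
  sel <- a > 0L & b > 0L & a != b
  if (!any(sel)) return(matrix(integer(0), ncol = 2))
  p <- cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  unique(p)
}

#' Label connected components of a 2D binary mask
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels 1..K (0 = background).
#' @keywords internal
label_components_2d <- function(mask, connectivity = 8L) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  n <- max(lab)
  if (n == 0L) return(lab)
  if (connectivity == 8L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      adjacent_label_pairs(lab[-nr, -nc], lab[-1, -1]),   # down-right
      adjacent_label_pairs(lab[-nr, -1], lab[-1, -nc])    # down-left
    )
    root <- uf_merge_pairs(n, pairs)
    dense <- match(root, sort(unique(root)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  lab
}

# 3D labelling (6-connectivity) of a (y, x, z) logical array.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    l2 <- label_components_2d(mask[, , z], connectivity = 4L)
    k <- max(l2)
    if (k > 0L) {
      l2[l2 > 0L] <- l2[l2 > 0L] + offset
      lab[, , z] <- l2
      offset <- offset + k
    }
  }
  if (offset == 0L) return(lab)
  pairs <- NULL
  for (z in seq_len(d[3] - 1L)) {
    p <- adjacent_label_pairs(lab[, , z], lab[, , z + 1L])
    if (nrow(p)) pairs <- rbind(pairs, p)
  }
  if (!is.null(pairs)) pairs <- unique(pairs)
  root <- uf_merge_pairs(offset, if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs)
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

# Keep only the largest 3D connected component of a logical array.
largest_component_3d <- function(mask) {
  lab <- label_components_3d(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}
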