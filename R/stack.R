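#' Construct a 3D image stack
#'
#' Light container for a scalar voxel grid with physical spacing and a
#' channel tag. The array is ordered (y, x, z): row, column, slice.
#'
#' @param data numeric 3D array, dimensions (y, x, z).
#' @param spacing_um positive numeric triple, micrometres per voxel along
#'   (y, x, z). Default c(5, 5, 3.5): in-plane pitch of a low-magnification
#'   light-sheet acquisition and the 3.5 um z-step between planes.
#' @param channel character tag, e.g. "autofluorescence" or "antibody".
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, spacing_um = c(5, 5, 3.5), channel = "antibody") {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "data must be a 3D array (y, x, z)")
  spacing_um <- as_triple(spacing_um, "spacing_um")
  assert_that(all(spacing_um > 0), "spacing_um must be positive")
  structure(list(data = data, spacing_um = spacing_um,
                 channel = as.character(channel)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d (y,x,z), spacing %s um, channel '%s'\n",
              d[1], d[2], d[3], paste(signif(x$spacing_um, 3), collapse = "x"),
              x$channel))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

# Accept either an image_stack or a bare array; return the array.
stack_data <- function(x) {
  if (inherits(x, "image_stack")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop_brainfrac("expected an image_stack or a 3D array")
}
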