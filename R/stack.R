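# The multi-channel 3D stack container shared by every stage.

#' Create a multi-channel 3D stack
#'
#' The fundamental container of the package: calibrated, photon-count-like
#' voxel data for one or more fluorescence channels sharing dimensions and
#' voxel size. Arrays are indexed `[y, x, z]` (image convention, y increases
#' downward); pixel coordinates used throughout the package are 0-based with
#' pixel centers at integer coordinates.
#'
#' @param voxels named list of numeric 3D arrays `[y, x, z]`, one per
#'   channel; all must share dimensions and be finite and non-negative.
#'   Canonical channel names are `"total"`, `"tyr"`, `"ac"`.
#' @param voxel_size numeric length-3, named `c(x=, y=, z=)`, in micrometres
#'   (physical/imaged units, i.e. post-expansion for expanded samples).
#' @param expansion_factor physical expansion of the sample (>= 1); 1 for
#'   non-expanded data. Biological lengths are physical lengths divided by
#'   this factor.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(voxels, voxel_size, expansion_factor = 1) {
  stopifnot(is.list(voxels), length(voxels) >= 1)
  if (is.null(names(voxels)) || any(!nzchar(names(voxels))))
    stop("voxels must be a named list of channel arrays")
  dims <- lapply(voxels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop("all channels must share dimensions")
  for (nm in names(voxels)) {
    v <- voxels[[nm]]
    if (!all(is.finite(v))) stop("non-finite intensities in channel ", nm)
    if (any(v < 0)) stop("negative intensities in channel ", nm)
  }
  voxel_size <- .check_voxel_size(voxel_size)
  if (!is.finite(expansion_factor) || expansion_factor < 1)
    stop("expansion_factor must be finite and >= 1")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 expansion_factor = expansion_factor),
            class = "channel_stack")
}

#' @keywords internal
.check_voxel_size <- function(voxel_size) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (is.null(names(voxel_size)) || !all(c("x", "y", "z") %in% names(voxel_size))) {
    names(voxel_size) <- c("x", "y", "z")
  }
  voxel_size <- voxel_size[c("x", "y", "z")]
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size components must be finite and > 0")
  voxel_size
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels[[1]])
  cat("channel_stack:", paste(names(x$voxels), collapse = ", "), "\n")
  cat(sprintf("  dims [y x z]: %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size (um): x=%.4g y=%.4g z=%.4g, expansion %.3g\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"],
              x$expansion_factor))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$voxels[[1]])

#' Number of channels / channel names of a stack
#' @param stack a `channel_stack`
#' @return character vector of channel names
#' @export
channel_names <- function(stack) names(stack$voxels)
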