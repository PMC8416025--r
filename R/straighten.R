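# Straightening along a polyline and reslicing into planes perpendicular to
# the dendrite axis (YZ) — the geometry step feeding the radial analysis.

#' Straighten a stack along a polyline and reslice perpendicular to it
#'
#' The XY path is spline-smoothed and resampled at arc steps equal to the
#' in-plane pixel size; at each sample the perpendicular line is
#' interpolated (bilinear in-plane) across all z planes, producing one YZ
#' cross-section per arc sample. With `interpolate_z = TRUE` (default) the
#' z axis is additionally resampled linearly to the in-plane pixel size, so
#' cross-section images are isotropic — the form the boundary/radial
#' machinery expects.
#'
#' @param stack a [channel_stack()].
#' @param path a [polyline_roi()] in XY (0-based pixel centers).
#' @param half_width half-width of the sampled perpendicular line, pixels.
#' @param interpolate_z resample z to the in-plane pixel size.
#' @return object of class `resliced_stack`: for each channel a 3D array
#'   `[z', y', slice]` (one YZ image per arc sample; rows z, columns the
#'   perpendicular coordinate), plus `pixel_size` (um per pixel in the
#'   cross-section), `slice_spacing` (um between cross-sections),
#'   `expansion_factor`, `axis_xy` (sampled centerline) and `normals`.
#' @export
straighten_and_reslice <- function(stack, path, half_width,
                                   interpolate_z = TRUE) {
  stopifnot(inherits(stack, "channel_stack"), inherits(path, "polyline_roi"))
  d <- dim(stack$voxels[[1]])
  vs <- stack$voxel_size
  if (abs(vs["x"] - vs["y"]) > 1e-9)
    stop("straighten_and_reslice assumes square in-plane pixels")
  v <- path$vertices
  seglen <- sqrt(rowSums(diff(v)^2))
  arc <- c(0, cumsum(seglen))
  L <- arc[length(arc)]
  if (L < 1) stop("path too short to straighten")
  n_s <- max(2L, as.integer(floor(L)) + 1L)
  s <- seq(0, L, length.out = n_s)
  # smooth path: interpolating spline through vertices, parametrized by arc
  cx <- if (nrow(v) > 2) stats::spline(arc, v[, 1], xout = s)$y else
    stats::approx(arc, v[, 1], xout = s)$y
  cy <- if (nrow(v) > 2) stats::spline(arc, v[, 2], xout = s)$y else
    stats::approx(arc, v[, 2], xout = s)$y
  # tangents by central differences
  tx <- c(cx[2] - cx[1], (cx[-(1:2)] - cx[1:(n_s - 2)]) / 2,
          cx[n_s] - cx[n_s - 1])
  ty <- c(cy[2] - cy[1], (cy[-(1:2)] - cy[1:(n_s - 2)]) / 2,
          cy[n_s] - cy[n_s - 1])
  tn <- sqrt(tx^2 + ty^2)
  nxv <- -ty / tn
  nyv <- tx / tn
  offs <- seq(-half_width, half_width)
  n_w <- length(offs)
  # bounds check on the actually sampled perpendicular endpoints
  for (sgn in c(-1, 1)) {
    ex <- cx + sgn * half_width * nxv
    ey <- cy + sgn * half_width * nyv
    bad <- which(ex < -0.5 | ex > d[2] - 0.5 | ey < -0.5 | ey > d[1] - 0.5)
    if (length(bad)) {
      i <- bad[1]
      vi <- which.min((v[, 1] - cx[i])^2 + (v[, 2] - cy[i])^2)
      stop("perpendicular sampling exits the stack XY bounds near path ",
           "vertex ", vi, " (", round(v[vi, 1], 2), ", ",
           round(v[vi, 2], 2), "); reduce half_width")
    }
  }
  nz <- d[3]
  out <- lapply(stack$voxels, function(a) array(0, c(nz, n_w, n_s)))
  px <- outer(nxv, offs) + cx  # [slice, offset]
  py <- outer(nyv, offs) + cy
  for (ch in names(stack$voxels)) {
    a <- stack$voxels[[ch]]
    for (z in seq_len(nz)) {
      sampled <- bilinear(a[, , z], as.vector(px), as.vector(py))
      out[[ch]][z, , ] <- t(matrix(sampled, n_s, n_w))
    }
  }
  pixel_size <- unname(vs["x"])
  if (interpolate_z && nz > 1) {
    z_old <- (seq_len(nz) - 1) * vs["z"]
    z_new <- seq(0, max(z_old), by = pixel_size)
    out <- lapply(out, function(a) {
      o <- array(0, c(length(z_new), n_w, n_s))
      for (i in seq_len(n_s)) {
        o[, , i] <- apply(a[, , i, drop = FALSE][, , 1], 2, function(col)
          stats::approx(z_old, col, xout = z_new)$y)
      }
      o
    })
  }
  structure(list(slices = out,
                 pixel_size = pixel_size,
                 slice_spacing = pixel_size,
                 z_interpolated = isTRUE(interpolate_z),
                 expansion_factor = stack$expansion_factor,
                 axis_xy = cbind(x = cx, y = cy),
                 normals = cbind(x = nxv, y = nyv)),
            class = "resliced_stack")
}

#' @export
print.resliced_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("resliced_stack: %d YZ slices of %d x %d px (%s)\n",
              d[3], d[1], d[2], paste(names(x$slices), collapse = ", ")))
  invisible(x)
}

#' Number of cross-section slices in a resliced stack
#' @param resliced a `resliced_stack`
#' @return integer count
#' @export
n_slices <- function(resliced) dim(resliced$slices[[1]])[3]

#' Extract one YZ cross-section image
#' @param resliced a `resliced_stack`
#' @param channel channel name
#' @param i slice index (1-based)
#' @return matrix `[z, y']`
#' @export
get_slice <- function(resliced, channel, i) resliced$slices[[channel]][, , i]
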