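# Channel registration by projection cross-correlation: each non-reference
# channel is aligned to the reference using phase correlation of XY and XZ
# maximum-intensity projections, with parabolic sub-voxel peak refinement.

#' @keywords internal
.phase_corr_shift <- function(a, b) {
  # shift (dy, dx) such that b approx a translated by (dy, dx)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  r <- fa * Conj(fb)
  mag <- Mod(r)
  mag[mag < 1e-12] <- 1e-12
  cc <- Re(stats::fft(r / mag, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  n <- dim(a)
  # parabolic interpolation per axis on the wrapped correlation surface
  sub <- numeric(2)
  for (ax in 1:2) {
    i0 <- pk[ax]
    im <- ((i0 - 2) %% n[ax]) + 1
    ip <- (i0 %% n[ax]) + 1
    idx <- function(i) if (ax == 1) cc[i, pk[2]] else cc[pk[1], i]
    y1 <- idx(im); y2 <- idx(i0); y3 <- idx(ip)
    den <- y1 - 2 * y2 + y3
    sub[ax] <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
  }
  d <- (pk - 1) + sub
  # wrap to signed shifts
  d <- ifelse(d > n / 2, d - n, d)
  -d # peak at +k means b is a shifted by -k under this fft convention
}

#' Translate a 3D array by a (possibly fractional) 3D shift
#'
#' Linear interpolation, zero fill outside.
#' @keywords internal
shift_array3d <- function(a, dy, dx, dz) {
  d <- dim(a)
  out <- array(0, d)
  gx <- rep(0:(d[2] - 1), each = d[1]) - dx
  gy <- rep(0:(d[1] - 1), d[2]) - dy
  z0 <- floor(dz)
  fz <- dz - z0
  for (z in seq_len(d[3])) {
    zi0 <- z - z0       # source slice indices (1-based)
    zi1 <- zi0 - 1
    sl <- matrix(0, d[1], d[2])
    if (zi0 >= 1 && zi0 <= d[3] && (1 - fz) > 0)
      sl <- sl + (1 - fz) * matrix(bilinear(a[, , zi0], gx, gy), d[1], d[2])
    if (fz > 0 && zi1 >= 1 && zi1 <= d[3])
      sl <- sl + fz * matrix(bilinear(a[, , zi1], gx, gy), d[1], d[2])
    out[, , z] <- sl
  }
  out
}

#' Register channels to a reference channel
#'
#' Estimates for each non-reference channel the 3D translation maximizing
#' the correlation of its XY and XZ maximum-intensity projections with the
#' reference channel's (phase correlation, parabolic sub-voxel refinement),
#' then resamples the channel onto the reference grid.
#'
#' @param stack a [channel_stack()] with >= 2 channels.
#' @param reference_channel channel name (default `"total"` if present,
#'   else the first channel).
#' @return the registered `channel_stack`; the applied per-channel shifts
#'   (in voxels, `c(dy, dx, dz)`) are in `attr(, "shifts")`.
#' @export
register_channels <- function(stack, reference_channel = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  if (length(stack$voxels) < 2) stop("need >= 2 channels to register")
  if (is.null(reference_channel)) {
    reference_channel <- if ("total" %in% names(stack$voxels)) "total" else
      names(stack$voxels)[1]
  }
  ref <- stack$voxels[[reference_channel]]
  mip_xy_r <- apply(ref, c(1, 2), max)
  mip_xz_r <- apply(ref, c(3, 2), max)
  shifts <- list()
  out <- stack$voxels
  for (nm in names(stack$voxels)) {
    if (nm == reference_channel) {
      shifts[[nm]] <- c(dy = 0, dx = 0, dz = 0)
      next
    }
    mov <- stack$voxels[[nm]]
    if (all(mov == 0)) {
      warning("channel '", nm, "' is all zero; zero shift applied")
      shifts[[nm]] <- c(dy = 0, dx = 0, dz = 0)
      next
    }
    sxy <- .phase_corr_shift(mip_xy_r, apply(mov, c(1, 2), max)) # (dy, dx)
    sxz <- .phase_corr_shift(mip_xz_r, apply(mov, c(3, 2), max)) # (dz, dx)
    # corrective shift = negative of the measured displacement
    sh <- -c(dy = sxy[1], dx = sxy[2], dz = sxz[1])
    out[[nm]] <- shift_array3d(mov, sh[1], sh[2], sh[3])
    shifts[[nm]] <- sh
  }
  res <- channel_stack(lapply(out, function(a) pmax(a, 0)),
                       voxel_size = stack$voxel_size,
                       expansion_factor = stack$expansion_factor)
  attr(res, "shifts") <- shifts
  res
}
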