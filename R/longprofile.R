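# Along-dendrite intensity analysis: perpendicular Gaussian fits at
# equidistant points of a traced dendrite, channel normalization to the
# first 5 um, spike exclusion, moving-average smoothing, and FWHM.

#' @keywords internal
.fit_gaussian_offset <- function(t, y) {
  off0 <- min(y)
  a0 <- max(y) - off0
  if (a0 <= 0) return(NULL)
  m0 <- sum((y - off0) * t) / max(sum(y - off0), .Machine$double.eps)
  s0 <- sqrt(max(sum((y - off0) * (t - m0)^2) /
                   max(sum(y - off0), .Machine$double.eps), 1e-6))
  lo <- c(0, min(t), diff(range(t)) / 200, 0)
  hi <- c(Inf, max(t), diff(range(t)), Inf)
  fit <- tryCatch(suppressWarnings(stats::nls(
    y ~ A * exp(-(t - m)^2 / (2 * s^2)) + off,
    start = list(A = a0, m = m0, s = s0, off = off0),
    lower = lo, upper = hi, algorithm = "port",
    control = stats::nls.control(maxiter = 100, warnOnly = TRUE))),
    error = function(e) NULL)
  p <- if (!is.null(fit)) as.list(stats::coef(fit)) else NULL
  if (is.null(p) || !all(is.finite(unlist(p))) || p$s <= 0) {
    # nls can hit a singular gradient on near-exact data; direct SSE descent
    sse <- function(th) {
      r <- y - th[1] * exp(-(t - th[2])^2 / (2 * th[3]^2)) - th[4]
      sum(r * r)
    }
    op <- tryCatch(stats::optim(c(a0, m0, s0, off0), sse,
                                method = "L-BFGS-B", lower = lo, upper = hi,
                                control = list(maxit = 300)),
                   error = function(e) NULL)
    if (is.null(op) || !all(is.finite(op$par)) || op$par[3] <= 0)
      return(NULL)
    p <- list(A = op$par[1], m = op$par[2], s = op$par[3], off = op$par[4])
  }
  if (p$A <= 0) return(NULL)
  p
}

#' Trace per-channel intensity along a dendrite
#'
#' At equidistant arc positions of the spline-fitted path, the
#' perpendicular 1D intensity profile is fitted per channel with a Gaussian
#' plus background offset; the local fluorescence content is recorded as
#' amplitude x SD (robust to focus/width changes). Failed fits are masked,
#' not fatal.
#'
#' @param sum_images named list of matrices per channel.
#' @param path a [polyline_roi()] along the dendrite.
#' @param pixel_size_um biological um per pixel.
#' @param step_um arc sampling step (default 0.2 um).
#' @param halfwidth_px perpendicular profile half-width, pixels.
#' @return data.frame of class `longitudinal_profile`: `position_um` plus,
#'   per channel, `A_<ch>`, `sigma_<ch>` (um), `offset_<ch>`,
#'   `intensity_<ch>` (= A sigma) and a logical `mask_<ch>` (TRUE = valid).
#' @export
trace_profile <- function(sum_images, path, pixel_size_um, step_um = 0.2,
                          halfwidth_px = 15) {
  v <- path$vertices
  seglen <- sqrt(rowSums(diff(v)^2))
  arc <- c(0, cumsum(seglen))
  L <- arc[length(arc)]
  step_px <- step_um / pixel_size_um
  n_s <- max(2L, as.integer(floor(L / step_px)) + 1L)
  s <- seq(0, (n_s - 1) * step_px, by = step_px)
  cx <- if (nrow(v) > 2) stats::spline(arc, v[, 1], xout = s)$y else
    stats::approx(arc, v[, 1], xout = s)$y
  cy <- if (nrow(v) > 2) stats::spline(arc, v[, 2], xout = s)$y else
    stats::approx(arc, v[, 2], xout = s)$y
  tx <- c(cx[2] - cx[1], (cx[-(1:2)] - cx[1:(n_s - 2)]) / 2, cx[n_s] - cx[n_s - 1])
  ty <- c(cy[2] - cy[1], (cy[-(1:2)] - cy[1:(n_s - 2)]) / 2, cy[n_s] - cy[n_s - 1])
  tn <- sqrt(tx^2 + ty^2)
  nxv <- -ty / tn
  nyv <- tx / tn
  offs <- seq(-halfwidth_px, halfwidth_px)
  out <- data.frame(position_um = s * pixel_size_um)
  for (ch in names(sum_images)) {
    img <- sum_images[[ch]]
    A <- sig <- off <- rep(NA_real_, n_s)
    for (i in seq_len(n_s)) {
      qx <- cx[i] + nxv[i] * offs
      qy <- cy[i] + nyv[i] * offs
      prof <- bilinear(img, qx, qy, fill = NA)
      ok <- is.finite(prof)
      if (sum(ok) < 7) next
      p <- .fit_gaussian_offset(offs[ok] * pixel_size_um, prof[ok])
      if (is.null(p)) next
      A[i] <- p$A; sig[i] <- p$s; off[i] <- p$off
    }
    out[[paste0("A_", ch)]] <- A
    out[[paste0("sigma_", ch)]] <- sig
    out[[paste0("offset_", ch)]] <- off
    out[[paste0("intensity_", ch)]] <- A * sig
    out[[paste0("mask_", ch)]] <- is.finite(A)
  }
  class(out) <- c("longitudinal_profile", "data.frame")
  out
}

#' Normalize, exclude spikes and smooth a longitudinal profile
#'
#' Per channel: intensities are divided by the mean over the first
#' `norm_window_um` (excluded points omitted from the mean), values above
#' `exclude_above` after normalization are masked as crossing-neurite
#' spikes (exclusion precedes smoothing, and excluded points are dropped
#' from smoothing windows rather than zero-filled), and the result is
#' smoothed with a `smooth_window_um` moving average. Adds
#' `norm_<ch>` and `smooth_<ch>` columns and updates `mask_<ch>`.
#'
#' @param profile a `longitudinal_profile`.
#' @param norm_window_um normalization window from the dendrite start.
#' @param smooth_window_um moving-average window.
#' @param exclude_above spike exclusion threshold on normalized intensity.
#' @return the augmented `longitudinal_profile`.
#' @export
normalize_and_smooth <- function(profile, norm_window_um = 5,
                                 smooth_window_um = 2, exclude_above = 1.25) {
  pos <- profile$position_um
  if (max(pos) <= norm_window_um)
    stop("profile shorter than the ", norm_window_um, " um normalization window")
  chans <- sub("^intensity_", "",
               grep("^intensity_", names(profile), value = TRUE))
  for (ch in chans) {
    raw <- profile[[paste0("intensity_", ch)]]
    mask <- profile[[paste0("mask_", ch)]] & is.finite(raw)
    first <- pos <= norm_window_um
    # iterate: the exclusion rule applies to normalized values, which
    # depend on which points were excluded from the normalization mean
    excl <- rep(FALSE, length(raw))
    for (it in 1:5) {
      m <- mean(raw[first & mask & !excl])
      if (!is.finite(m) || m <= 0) stop("cannot normalize channel ", ch)
      norm <- raw / m
      new_excl <- norm > exclude_above
      new_excl[!mask] <- FALSE
      if (identical(new_excl, excl)) break
      excl <- new_excl
    }
    ok <- mask & !excl
    smoothed <- rep(NA_real_, length(raw))
    hw <- smooth_window_um / 2
    for (i in seq_along(raw)) {
      win <- ok & abs(pos - pos[i]) <= hw
      if (any(win)) smoothed[i] <- mean(norm[win])
    }
    profile[[paste0("norm_", ch)]] <- ifelse(ok, norm, NA_real_)
    profile[[paste0("smooth_", ch)]] <- smoothed
    profile[[paste0("mask_", ch)]] <- ok
  }
  profile
}

#' Full width at half maximum along the profile
#'
#' FWHM of the total-tubulin perpendicular Gaussian:
#' `2 sqrt(2 ln 2) * sigma ~= 2.3548 sigma`. Masked points stay masked.
#'
#' @param profile a `longitudinal_profile`.
#' @param channel channel whose fitted sigma is used (default `"total"`).
#' @return numeric vector of FWHM values (um), NA where masked.
#' @export
fwhm_profile <- function(profile, channel = "total") {
  sig <- profile[[paste0("sigma_", channel)]]
  if (is.null(sig)) stop("no fitted sigma for channel ", channel)
  msk <- profile[[paste0("mask_", channel)]]
  out <- 2 * sqrt(2 * log(2)) * sig
  out[!msk] <- NA_real_
  out
}
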