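# Soma-stage single-filament analysis: curvilinear segment detection on
# maximum projections, dual-width background-corrected intensity
# quantification on sum projections (the 3 x 3 detection x quantification
# design), the two-Gaussian single-microtubule intensity model, the
# singles filter, and the crosstalk coefficients alpha and beta.

#' Build detection and quantification projections of a substack
#'
#' Detection uses maximum-intensity projections; intensity quantification
#' uses the sum over the same slices.
#'
#' @param stack a [channel_stack()].
#' @param z_range 1-based inclusive slice range, e.g. `c(3, 7)`.
#' @return list with `mip` and `sum` (named lists of matrices per channel),
#'   `pixel_size_um` (biological um per pixel) and `z_range`.
#' @export
select_substack <- function(stack, z_range) {
  d <- dim(stack$voxels[[1]])
  z_range <- as.integer(round(range(z_range)))
  if (z_range[1] < 1 || z_range[2] > d[3] || z_range[1] > z_range[2])
    stop("empty or out-of-range z_range")
  zs <- z_range[1]:z_range[2]
  mip <- lapply(stack$voxels, function(a)
    if (length(zs) == 1L) a[, , zs] else apply(a[, , zs, drop = FALSE], c(1, 2), max))
  sm <- lapply(stack$voxels, function(a)
    if (length(zs) == 1L) a[, , zs] else rowSums(a[, , zs, drop = FALSE], dims = 2))
  list(mip = mip, sum = sm,
       pixel_size_um = unname(stack$voxel_size["x"] / stack$expansion_factor),
       z_range = z_range)
}

#' Detect curvilinear filament segments in a projection image
#'
#' A simplified ridge detector standing in for full Steger-style curvilinear
#' detection: the image is smoothed with a Gaussian of SD `line_width`
#' pixels, thresholded, and 8-connected components are traced into sub-pixel
#' polylines by intensity-weighted binning along each component's principal
#' axis. The detection threshold emulates the user-chosen line contrast of
#' interactive detectors: by default a fraction `relative_threshold` of the
#' robust bright-filament level (99.5th percentile of the smoothed image
#' above background), which keeps crosstalk-level filaments (which carry
#' only a fraction of a single filament's brightness in this channel) below
#' detection, as when each channel's sparser subnetwork is traced.
#' Externally produced segments (e.g. imported ImageJ ROIs) can be used
#' instead via [segments_from_rois()].
#'
#' @param image 2D detection image (maximum projection).
#' @param pixel_size_um biological um per pixel.
#' @param line_width ridge SD in pixels (default 2.5).
#' @param min_length_um minimum segment length, um (default 0.6).
#' @param mask optional polygon (n x 2 matrix, 0-based x,y) limiting
#'   detection, or a logical matrix; vertices outside are clipped.
#' @param threshold absolute intensity threshold on the smoothed image;
#'   overrides `relative_threshold`.
#' @param relative_threshold fraction of the robust bright level (default
#'   0.55).
#' @param detection_channel label stored on the segments.
#' @return list of `filament_segment` objects (possibly empty), each with
#'   `vertices` (sub-pixel, 0-based), `length_um`, `detection_channel`,
#'   `source`.
#' @export
detect_segments <- function(image, pixel_size_um, line_width = 2.5,
                            min_length_um = 0.6, mask = NULL,
                            threshold = NULL, relative_threshold = 0.55,
                            detection_channel = "total") {
  stopifnot(is.matrix(image))
  sm <- gauss_blur2d(image, line_width)
  bg <- stats::median(sm)
  if (is.null(threshold)) {
    bright <- stats::quantile(sm, 0.995, names = FALSE)
    if (bright <= bg) return(list())
    threshold <- bg + relative_threshold * (bright - bg)
  }
  sel <- sm > threshold
  if (!is.null(mask)) {
    if (is.matrix(mask) && is.logical(mask)) {
      sel <- sel & mask
    } else {
      m <- as.matrix(mask)
      xs <- rep(0:(ncol(image) - 1), each = nrow(image))
      ys <- rep(0:(nrow(image) - 1), ncol(image))
      inside <- matrix(point_in_polygon(xs, ys, m[, 1], m[, 2]),
                       nrow(image), ncol(image))
      sel <- sel & inside
    }
  }
  if (!any(sel)) return(list())
  lab <- label_components(sel)
  segs <- list()
  min_px <- min_length_um / pixel_size_um
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < max(4, min_px)) next
    x <- px[, 2] - 1
    y <- px[, 1] - 1
    w <- sm[px]
    # principal axis (intensity-weighted)
    mx <- sum(w * x) / sum(w)
    my <- sum(w * y) / sum(w)
    cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
    cxy <- sum(w * (x - mx) * (y - my))
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy) / sum(w), 2, 2), symmetric = TRUE)
    ax <- ev$vectors[, 1]
    t <- (x - mx) * ax[1] + (y - my) * ax[2]
    ord <- order(t)
    # bin along the axis (2 px bins), intensity-weighted centroids
    brk <- seq(min(t) - 1e-9, max(t) + 1e-9, by = 2)
    if (length(brk) < 3) brk <- c(min(t) - 1e-9, stats::median(t), max(t) + 1e-9)
    bin <- findInterval(t, brk, rightmost.closed = TRUE)
    vx <- tapply(w * x, bin, sum) / tapply(w, bin, sum)
    vy <- tapply(w * y, bin, sum) / tapply(w, bin, sum)
    keep <- !is.na(vx)
    vx <- vx[keep]; vy <- vy[keep]
    if (length(vx) < 2) next
    # light smoothing of the traced path (ends kept unsmoothed)
    if (length(vx) >= 5) {
      sx <- stats::filter(vx, rep(1 / 3, 3))
      sy <- stats::filter(vy, rep(1 / 3, 3))
      keep_raw <- is.na(sx)
      sx[keep_raw] <- vx[keep_raw]
      sy[keep_raw] <- vy[keep_raw]
      vx <- sx; vy <- sy
    }
    verts <- cbind(x = as.numeric(vx), y = as.numeric(vy))
    L <- sum(sqrt(rowSums(diff(verts)^2))) * pixel_size_um
    if (L < min_length_um) next
    segs[[length(segs) + 1L]] <- structure(
      list(vertices = verts, length_um = L,
           detection_channel = detection_channel, source = "internal_detector"),
      class = "filament_segment")
  }
  segs
}

#' Wrap imported ROIs as filament segments
#'
#' Imported segments (ImageJ .roi/.zip or the JSON dialect) bypass the
#' internal detector — detection is pluggable.
#'
#' @param rois list of [polyline_roi()] (or a single one).
#' @param pixel_size_um biological um per pixel.
#' @param detection_channel label stored on the segments.
#' @param min_length_um drop shorter segments (default 0: keep all).
#' @return list of `filament_segment` objects with `source = "imported_roi"`.
#' @export
segments_from_rois <- function(rois, pixel_size_um,
                               detection_channel = "total",
                               min_length_um = 0) {
  if (inherits(rois, "polyline_roi")) rois <- list(rois)
  out <- list()
  for (r in rois) {
    L <- polyline_length(r) * pixel_size_um
    if (L < min_length_um) next
    out[[length(out) + 1L]] <- structure(
      list(vertices = r$vertices, length_um = L,
           detection_channel = detection_channel, source = "imported_roi"),
      class = "filament_segment")
  }
  out
}

#' @export
print.filament_segment <- function(x, ...) {
  cat(sprintf("filament_segment (%s, %s): %d vertices, %.2f um\n",
              x$detection_channel, x$source, nrow(x$vertices), x$length_um))
  invisible(x)
}

# pixels whose centers lie in the stroked width-w band of the polyline:
# within w/2 of a segment with an in-range projection (no end caps, as for
# ImageJ line ROIs, so the tube area is ~ L * w and the Eq. 2 and Eq. 5
# normalizations are commensurate); returns linear indices into the image
#' @keywords internal
.tube_pixels <- function(dim_img, verts, w) {
  r <- w / 2
  x0 <- max(0, floor(min(verts[, 1]) - r - 1))
  x1 <- min(dim_img[2] - 1, ceiling(max(verts[, 1]) + r + 1))
  y0 <- max(0, floor(min(verts[, 2]) - r - 1))
  y1 <- min(dim_img[1] - 1, ceiling(max(verts[, 2]) + r + 1))
  xs <- rep(x0:x1, each = y1 - y0 + 1)
  ys <- rep(y0:y1, x1 - x0 + 1)
  sel <- rep(FALSE, length(xs))
  for (i in seq_len(nrow(verts) - 1L)) {
    ax <- verts[i, 1]; ay <- verts[i, 2]
    bx <- verts[i + 1L, 1]; by <- verts[i + 1L, 2]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx * abx + aby * aby
    if (len2 == 0) next
    t <- ((xs - ax) * abx + (ys - ay) * aby) / len2
    perp <- abs((xs - ax) * (-aby) + (ys - ay) * abx) / sqrt(len2)
    sel <- sel | (t >= 0 & t <= 1 & perp <= r)
  }
  (ys[sel] + 1) + dim_img[1] * xs[sel]
}

# rectangular band of width w around the straight segment p0-p1: pixels
# whose center projects onto the segment (no end caps, ImageJ straight-line
# ROI semantics — widening must not extend along the line)
#' @keywords internal
.band_pixels <- function(dim_img, p0, p1, w) {
  r <- w / 2
  x0 <- max(0, floor(min(p0[1], p1[1]) - r - 1))
  x1 <- min(dim_img[2] - 1, ceiling(max(p0[1], p1[1]) + r + 1))
  y0 <- max(0, floor(min(p0[2], p1[2]) - r - 1))
  y1 <- min(dim_img[1] - 1, ceiling(max(p0[2], p1[2]) + r + 1))
  xs <- rep(x0:x1, each = y1 - y0 + 1)
  ys <- rep(y0:y1, x1 - x0 + 1)
  ab <- p1 - p0
  L2 <- sum(ab^2)
  t <- ((xs - p0[1]) * ab[1] + (ys - p0[2]) * ab[2]) / L2
  perp <- abs((xs - p0[1]) * (-ab[2]) + (ys - p0[2]) * ab[1]) / sqrt(L2)
  sel <- t >= 0 & t <= 1 & perp <= r
  (ys[sel] + 1) + dim_img[1] * xs[sel]
}

#' Measure dual-width background-corrected segment intensities
#'
#' For each quantification channel, integrates the sum-projection intensity
#' over the polyline tube of width `w_microtubule` (I_mid over area S_mid)
#' and width `w_wide` (I_wide over S_wide); the local background per pixel
#' is I_BG = (I_wide - I_mid) / (S_wide - S_mid) and the
#' background-corrected mean filament intensity is
#' I_segm = I_mid / S_mid - I_BG.
#'
#' @param sum_images named list of quantification images (sum projections).
#' @param seg a `filament_segment`.
#' @param w_microtubule tube width in pixels (default 6).
#' @param w_wide wide tube width in pixels (default 13).
#' @return data.frame, one row per quantification channel, with columns
#'   `channel`, `I_mid`, `I_wide`, `S_mid`, `S_wide`, `I_BG`, `I_segm`,
#'   `excluded` (TRUE when the wide tube touches the image border).
#' @export
measure_segment <- function(sum_images, seg, w_microtubule = 6, w_wide = 13) {
  stopifnot(w_wide > w_microtubule)
  img1 <- sum_images[[1]]
  dim_img <- dim(img1)
  v <- seg$vertices
  m <- w_wide / 2
  excluded <- any(v[, 1] < m | v[, 1] > dim_img[2] - 1 - m |
                    v[, 2] < m | v[, 2] > dim_img[1] - 1 - m)
  idx_mid <- .tube_pixels(dim_img, v, w_microtubule)
  idx_wide <- .tube_pixels(dim_img, v, w_wide)
  S_mid <- length(idx_mid)
  S_wide <- length(idx_wide)
  if (S_wide <= S_mid || S_mid == 0)
    stop("degenerate tube rasterization for segment")
  out <- lapply(names(sum_images), function(ch) {
    img <- sum_images[[ch]]
    I_mid <- sum(img[idx_mid])
    I_wide <- sum(img[idx_wide])
    I_BG <- (I_wide - I_mid) / (S_wide - S_mid)
    data.frame(channel = ch, I_mid = I_mid, I_wide = I_wide,
               S_mid = S_mid, S_wide = S_wide, I_BG = I_BG,
               I_segm = I_mid / S_mid - I_BG, excluded = excluded)
  })
  do.call(rbind, out)
}

#' Measure a set of segments into a wide segment table
#'
#' Convenience wrapper running [measure_segment()] over a segment list;
#' border-touching segments are flagged and excluded.
#'
#' @inheritParams measure_segment
#' @param segments list of `filament_segment`.
#' @return data.frame of class `segment_table`: one row per segment with
#'   `detection_channel`, `length_um`, `excluded` and per-channel
#'   `I_segm_<channel>` (plus `I_BG_<channel>`).
#' @export
measure_segments <- function(sum_images, segments, w_microtubule = 6,
                             w_wide = 13) {
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    m <- measure_segment(sum_images, seg, w_microtubule, w_wide)
    row <- data.frame(segment = i, detection_channel = seg$detection_channel,
                      length_um = seg$length_um, source = seg$source,
                      excluded = any(m$excluded))
    for (j in seq_len(nrow(m))) {
      row[[paste0("I_segm_", m$channel[j])]] <- m$I_segm[j]
      row[[paste0("I_BG_", m$channel[j])]] <- m$I_BG[j]
    }
    row
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame()
  class(tab) <- c("segment_table", "data.frame")
  tab
}

#' Fit the two-Gaussian single-filament intensity model
#'
#' The histogram of background-corrected total-channel segment intensities
#' is fitted with
#' `rho(I) = a1 exp(-(I - I_Tot)^2 / (2 s^2)) + a2 exp(-(I - 2 I_Tot)^2 / (4 s^2))`:
#' the first Gaussian is the single-microtubule intensity distribution, the
#' second its self-convolution (two-filament bundles, mean `2 I_Tot`,
#' variance `2 s^2`). Nonlinear least squares on Freedman-Diaconis binned
#' counts, bounded below at zero; initial values are the histogram mode
#' (I_Tot), half the interquartile range (s), and the mass above
#' `1.5 I_Tot` (a2).
#'
#' @param intensities numeric vector of segment intensities (one cell).
#' @param bin_width histogram bin width; default Freedman-Diaconis.
#' @return object of class `single_intensity_fit`: `a1`, `a2`, `I_Tot`,
#'   `sigma_Tot`, `single_threshold = I_Tot + sigma_Tot`, and diagnostics
#'   (`residual_norm`, `n`, `bin_width`).
#' @export
fit_single_intensity <- function(intensities, bin_width = NULL) {
  intensities <- intensities[is.finite(intensities)]
  n <- length(intensities)
  if (n < 10) stop("too few intensities to fit (n = ", n, ")")
  if (n < 100) warning("fewer than 100 intensities; fit may be unstable")
  if (stats::sd(intensities) < 1e-12 * max(abs(intensities), 1))
    stop("degenerate input: zero intensity spread")
  if (is.null(bin_width)) {
    iqr <- stats::IQR(intensities)
    bin_width <- if (iqr > 0) 2 * iqr / n^(1 / 3) else
      diff(range(intensities)) / 20
  }
  # extend the binned range to cover the doublet component (2 I_Tot) even
  # when no doublets are present: empty bins there constrain a2
  hi <- max(max(intensities), 2.4 * stats::median(intensities))
  brk <- seq(min(intensities) - bin_width, hi + bin_width, by = bin_width)
  h <- graphics::hist(intensities, breaks = brk, plot = FALSE)
  xb <- h$mids
  yb <- h$counts
  I0 <- xb[which.max(yb)]
  s0 <- max(stats::IQR(intensities) / 2, bin_width)
  a10 <- max(yb)
  frac_hi <- mean(intensities > 1.5 * I0)
  a20 <- max(a10 * frac_hi, 1e-3)
  model <- function(x, a1, a2, IT, s)
    a1 * exp(-(x - IT)^2 / (2 * s^2)) + a2 * exp(-(x - 2 * IT)^2 / (4 * s^2))
  lower <- c(a1 = 0, a2 = 0, IT = bin_width / 2, s = bin_width / 10)
  p <- NULL
  # port reports "false convergence" at active bounds (a2 = 0 is common and
  # legitimate); accept any finite bounded solution and fall back to a
  # direct least-squares minimization if nls fails outright
  fit <- tryCatch(suppressWarnings(
    stats::nls(yb ~ model(xb, a1, a2, IT, s),
               start = list(a1 = a10, a2 = a20, IT = I0, s = s0),
               lower = lower, algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    pc <- as.list(stats::coef(fit))
    if (all(is.finite(unlist(pc))) && pc$IT > 0 && pc$s > 0)
      p <- c(pc, list(rss = sum(stats::resid(fit)^2)))
  }
  if (is.null(p)) {
    sse <- function(th) {
      r <- yb - model(xb, th[1], th[2], th[3], th[4])
      sum(r * r)
    }
    op <- tryCatch(stats::optim(c(a10, a20, I0, s0), sse,
                                method = "L-BFGS-B", lower = lower,
                                control = list(maxit = 500)),
                   error = function(e) NULL)
    if (is.null(op) || !all(is.finite(op$par)) || op$par[3] <= 0 ||
        op$par[4] <= 0)
      stop("two-Gaussian fit did not converge (n = ", n,
           ", start I_Tot = ", signif(I0, 4), ")")
    p <- list(a1 = op$par[1], a2 = op$par[2], IT = op$par[3],
              s = op$par[4], rss = op$value)
  }
  structure(list(a1 = p$a1, a2 = p$a2, I_Tot = p$IT, sigma_Tot = p$s,
                 single_threshold = p$IT + p$s,
                 residual_norm = sqrt(p$rss),
                 n = n, bin_width = bin_width),
            class = "single_intensity_fit")
}

#' @export
print.single_intensity_fit <- function(x, ...) {
  cat(sprintf(
    "single_intensity_fit: I_Tot = %.4g, sigma_Tot = %.4g (n = %d)\n",
    x$I_Tot, x$sigma_Tot, x$n))
  cat(sprintf("  singles threshold I_Tot + sigma = %.4g; a2/a1 = %.3f\n",
              x$single_threshold, x$a2 / max(x$a1, 1e-12)))
  invisible(x)
}

#' Keep single-microtubule segments below the intensity threshold
#'
#' Retains segments whose total-channel background-corrected intensity is
#' strictly below `I_Tot + sigma_Tot` (segments at or above the threshold
#' are likely bundles and are discarded).
#'
#' @param table a `segment_table` from [measure_segments()].
#' @param fit a `single_intensity_fit`.
#' @return the filtered table; kept/discarded counts in
#'   `attr(, "filter_counts")`.
#' @export
filter_singles <- function(table, fit) {
  if (nrow(table) == 0) {
    attr(table, "filter_counts") <- c(kept = 0L, discarded = 0L)
    return(table)
  }
  ok <- !table$excluded & table$I_segm_total < fit$single_threshold
  out <- table[ok, , drop = FALSE]
  attr(out, "filter_counts") <- c(kept = sum(ok), discarded = sum(!ok))
  class(out) <- class(table)
  out
}

#' Estimate the crosstalk coefficients alpha and beta
#'
#' From single-microtubule segments (post [filter_singles()]):
#' `I_Tyr` is the mean tyr-channel intensity of tyr-detected singles and
#' `I_Ac` the mean ac-channel intensity of ac-detected singles;
#' `alpha` is the mean tyr-channel intensity of ac-detected singles
#' normalized by `I_Tyr` (the tyrosination level of stable microtubules)
#' and `beta` the mean ac-channel intensity of tyr-detected singles
#' normalized by `I_Ac`.
#'
#' @param singles a filtered `segment_table`.
#' @return object of class `crosstalk_coefficients` with `I_Tyr`, `I_Ac`,
#'   `alpha`, `beta` and per-detection-channel counts.
#' @export
estimate_crosstalk <- function(singles) {
  tyr_det <- singles[singles$detection_channel == "tyr", , drop = FALSE]
  ac_det <- singles[singles$detection_channel == "ac", , drop = FALSE]
  n <- c(tyr = nrow(tyr_det), ac = nrow(ac_det))
  if (any(n < 20))
    warning("fewer than 20 singles in a detection channel (tyr: ", n["tyr"],
            ", ac: ", n["ac"], "); estimates may be noisy")
  if (n["tyr"] == 0 || n["ac"] == 0)
    stop("need singles detected in both tyr and ac channels")
  I_Tyr <- mean(tyr_det$I_segm_tyr)
  I_Ac <- mean(ac_det$I_segm_ac)
  if (I_Tyr <= 0 || I_Ac <= 0)
    stop("non-positive single-microtubule channel intensity (I_Tyr = ",
         signif(I_Tyr, 4), ", I_Ac = ", signif(I_Ac, 4), ")")
  alpha <- mean(ac_det$I_segm_tyr) / I_Tyr
  beta <- mean(tyr_det$I_segm_ac) / I_Ac
  structure(list(I_Tyr = I_Tyr, I_Ac = I_Ac,
                 alpha = alpha, beta = beta,
                 n_segments = n),
            class = "crosstalk_coefficients")
}

#' @export
print.crosstalk_coefficients <- function(x, ...) {
  cat(sprintf(
    "crosstalk: alpha = %.3f, beta = %.3f (I_Tyr = %.4g, I_Ac = %.4g; n = %d/%d)\n",
    x$alpha, x$beta, x$I_Tyr, x$I_Ac, x$n_segments["tyr"], x$n_segments["ac"]))
  invisible(x)
}
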