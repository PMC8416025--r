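# FlipExM stage: microtubule cross-sections appear as fluorescent spots in
# YZ slices. Spots are detected per channel, filtered by roundness and by
# an MLE-normal area window, calibrated with the same two-Gaussian
# intensity model as the soma stage, and counted per slice via the linear
# unmixing system.

#' Detect microtubule cross-section spots in a YZ slice
#'
#' Approximate-Gaussian blob detection: the slice is smoothed, thresholded
#' at `noise_k` robust noise SDs above the median, and 8-connected
#' components become candidate spots. Width `w` and height `h` are the
#' bounding extents of the pixels above half the (background-subtracted)
#' component peak; the spot area is the count of those pixels. Integrated
#' intensities are quantified in all provided channels over the spot
#' pixels, background-corrected by the median of a 2-px annulus around the
#' spot box.
#'
#' @param slices named list of matrices, one per channel (same geometry);
#'   detection runs on `detect_channel`, quantification on all.
#' @param detect_channel channel used for detection.
#' @param smooth_sigma detection smoothing, pixels.
#' @param noise_k detection threshold in robust noise SDs.
#' @param min_area minimum component area, pixels.
#' @return data.frame of class `spot_table`: one row per spot with
#'   `detection_channel`, centroid `y`, `z` (0-based; `y` = column, `z` =
#'   row of the slice), `w_spot`, `h_spot`, `S_spot`, `roundness`, and
#'   `I_<channel>` background-corrected integrated intensities.
#' @export
detect_spots <- function(slices, detect_channel = "total",
                         smooth_sigma = 1, noise_k = 5, min_area = 4) {
  det <- slices[[detect_channel]]
  if (is.null(det)) stop("detection channel '", detect_channel, "' missing")
  sm <- gauss_blur2d(det, smooth_sigma)
  bg0 <- stats::median(sm)
  noise <- stats::mad(sm)
  thr <- bg0 + noise_k * max(noise, .Machine$double.eps)
  sel <- sm > thr
  empty <- data.frame(detection_channel = character(0), y = numeric(0),
                      z = numeric(0), w_spot = numeric(0),
                      h_spot = numeric(0), S_spot = numeric(0),
                      roundness = numeric(0))
  if (!any(sel)) {
    for (nm in names(slices)) empty[[paste0("I_", nm)]] <- numeric(0)
    class(empty) <- c("spot_table", "data.frame")
    return(empty)
  }
  lab0 <- label_components(sel)
  nr <- nrow(det); nc <- ncol(det)
  # split components containing several well-separated intensity maxima
  # (touching spots merge at permissive thresholds): each pixel joins its
  # nearest maximum
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  for (id in seq_len(max(lab0))) {
    px <- which(lab0 == id, arr.ind = TRUE)
    vals <- sm[px]
    peak <- max(vals)
    msk <- matrix(-Inf, nr, nc)
    msk[px] <- sm[px]
    mx <- local_maxima(msk, radius = 2L,
                       threshold = bg0 + 0.3 * (peak - bg0))
    # merge maxima not separated by a deep valley: two cross-sections only
    # count as distinct spots if the intensity between them drops below
    # half of the dimmer peak (above background); otherwise they stay one
    # elongated spot for the roundness filter to judge
    if (nrow(mx) > 1) {
      pk_v <- msk[mx]
      ord_m <- order(pk_v, decreasing = TRUE)
      acc <- ord_m[1]
      for (cand in ord_m[-1]) {
        distinct <- TRUE
        for (aidx in acc) {
          n_s <- max(abs(mx[cand, ] - mx[aidx, ])) + 1
          rr <- round(seq(mx[aidx, 1], mx[cand, 1], length.out = n_s))
          cc <- round(seq(mx[aidx, 2], mx[cand, 2], length.out = n_s))
          valley <- min(msk[cbind(rr, cc)])
          lim <- bg0 + 0.5 * (min(pk_v[cand], pk_v[aidx]) - bg0)
          if (valley >= lim) { distinct <- FALSE; break }
        }
        if (distinct) acc <- c(acc, cand)
      }
      mx <- mx[acc, , drop = FALSE]
    }
    if (nrow(mx) <= 1) {
      nlab <- nlab + 1L
      lab[px] <- nlab
    } else {
      d2 <- outer(px[, 1], mx[, 1], "-")^2 + outer(px[, 2], mx[, 2], "-")^2
      near <- max.col(-d2)
      for (m in seq_len(nrow(mx))) {
        nlab <- nlab + 1L
        lab[px[near == m, , drop = FALSE]] <- nlab
      }
    }
  }
  rows <- list()
  for (id in seq_len(nlab)) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    vals <- sm[px]
    peak <- max(vals)
    half <- bg0 + (peak - bg0) / 2
    core <- px[vals >= half, , drop = FALSE]
    if (nrow(core) < 2) next
    w_spot <- diff(range(core[, 2])) + 1 # extent along y' (columns)
    h_spot <- diff(range(core[, 1])) + 1 # extent along z (rows)
    S_spot <- nrow(core)
    theta <- w_spot * h_spot / max(w_spot, h_spot)^2
    wgt <- vals[vals >= half]
    cy <- sum(wgt * (core[, 2] - 1)) / sum(wgt)
    cz <- sum(wgt * (core[, 1] - 1)) / sum(wgt)
    # annulus background: 2-px ring outside the expanded bounding box
    r0 <- max(1, min(core[, 1]) - 3); r1 <- min(nr, max(core[, 1]) + 3)
    c0 <- max(1, min(core[, 2]) - 3); c1 <- min(nc, max(core[, 2]) + 3)
    boxmask <- matrix(FALSE, nr, nc)
    boxmask[r0:r1, c0:c1] <- TRUE
    boxmask[max(1, r0 + 2):min(nr, r1 - 2),
            max(1, c0 + 2):min(nc, c1 - 2)] <- FALSE
    ann <- which(boxmask & lab == 0)
    row <- data.frame(detection_channel = detect_channel,
                      y = cy, z = cz, w_spot = w_spot, h_spot = h_spot,
                      S_spot = S_spot, roundness = theta)
    lin <- (core[, 1]) + nr * (core[, 2] - 1)
    for (ch in names(slices)) {
      img <- slices[[ch]]
      bg_ch <- if (length(ann)) stats::median(img[ann]) else 0
      row[[paste0("I_", ch)]] <- sum(img[lin]) - bg_ch * S_spot
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    for (nm in names(slices)) empty[[paste0("I_", nm)]] <- numeric(0)
    empty
  }
  class(out) <- c("spot_table", "data.frame")
  out
}

#' Filter spots by roundness
#'
#' Roundness `theta = w h / max(w, h)^2` is 1 for symmetric spots and drops
#' for elongated detections (merged doublets); spots with
#' `theta >= threshold` are kept.
#'
#' @param spots a `spot_table`.
#' @param threshold lower roundness bound (default 0.8).
#' @return the filtered `spot_table`.
#' @export
roundness_filter <- function(spots, threshold = 0.8) {
  out <- spots[spots$roundness >= threshold, , drop = FALSE]
  class(out) <- class(spots)
  out
}

#' Filter spots by the MLE-normal area window
#'
#' An MLE fit of the normal distribution to the spot areas (sample mean,
#' population SD) defines the inclusion range
#' `[max(Q1, S_mean - sigma_area), S_mean + sigma_area]`, with Q1 the
#' linearly interpolated 25th percentile guarding against tiny
#' false-positive spots. When all areas are equal the range degenerates to
#' that value and every spot is kept.
#'
#' @param spots a `spot_table` (one channel, one dendrite).
#' @return list with `spots` (filtered table) and `params` (class
#'   `area_filter_params`: `S_mean`, `sigma_area`, `Q1`, `range`).
#' @export
area_filter <- function(spots) {
  n <- nrow(spots)
  if (n < 10) warning("fewer than 10 spots for the area fit (n = ", n, ")")
  if (n == 0) stop("no spots to filter")
  a <- spots$S_spot
  S_mean <- mean(a)
  sigma_area <- sqrt(mean((a - S_mean)^2)) # MLE (population) SD
  Q1 <- stats::quantile(a, 0.25, names = FALSE, type = 7)
  lo <- max(Q1, S_mean - sigma_area)
  hi <- S_mean + sigma_area
  if (lo > hi) lo <- hi
  keep <- a >= lo & a <= hi
  out <- spots[keep, , drop = FALSE]
  class(out) <- class(spots)
  params <- structure(list(S_mean = S_mean, sigma_area = sigma_area,
                           Q1 = Q1, range = c(lower = lo, upper = hi),
                           n = n, n_kept = sum(keep)),
                      class = "area_filter_params")
  list(spots = out, params = params)
}

#' Single cross-section intensity from filtered spots
#'
#' The two-Gaussian intensity model of [fit_single_intensity()] applied to
#' the background-corrected integrated intensities of roundness- and
#' area-filtered spots of one channel.
#'
#' @param intensities numeric vector of spot intensities.
#' @param ... passed to [fit_single_intensity()].
#' @return a `single_intensity_fit`.
#' @export
fit_single_crosssection <- function(intensities, ...) {
  fit_single_intensity(intensities, ...)
}

#' Estimate crosstalk from FlipExM spot detections
#'
#' Normalized crosstalk levels per spot: for ac-detected singles the
#' tyr-channel intensity divided by the single tyr cross-section intensity
#' (alpha), and vice versa for beta. Because the level distributions have
#' long tails, three estimators are provided: `pooled_mean` (plain mean),
#' `trimmed_mean` (mean over values below mean + SD of the same
#' distribution), and `two_gaussian_peak` (position of the dominant peak of
#' a two-Gaussian fit; falls back, flagged, to `trimmed_mean` when the fit
#' does not converge).
#'
#' @param ac_levels normalized tyrosination levels of ac-detected singles.
#' @param tyr_levels normalized acetylation levels of tyr-detected singles.
#' @param method one of `"pooled_mean"`, `"trimmed_mean"`,
#'   `"two_gaussian_peak"`.
#' @return named vector `c(alpha, beta)` with attribute `method` (and
#'   `fallback` when the peak fit fell back).
#' @export
estimate_crosstalk_flipexm <- function(ac_levels, tyr_levels,
                                       method = c("pooled_mean",
                                                  "trimmed_mean",
                                                  "two_gaussian_peak")) {
  method <- match.arg(method)
  est_one <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) stop("no crosstalk levels available")
    switch(method,
           pooled_mean = list(value = mean(v), fallback = FALSE),
           trimmed_mean = {
             cut <- mean(v) + stats::sd(v)
             list(value = mean(v[v < cut]), fallback = FALSE)
           },
           two_gaussian_peak = {
             p <- .two_gaussian_peak(v)
             if (is.na(p)) {
               cut <- mean(v) + stats::sd(v)
               list(value = mean(v[v < cut]), fallback = TRUE)
             } else list(value = p, fallback = FALSE)
           })
  }
  a <- est_one(ac_levels)
  b <- est_one(tyr_levels)
  out <- c(alpha = a$value, beta = b$value)
  attr(out, "method") <- method
  attr(out, "fallback") <- c(alpha = a$fallback, beta = b$fallback)
  out
}

# dominant-peak position of a free two-Gaussian histogram fit; NA on failure
#' @keywords internal
.two_gaussian_peak <- function(v) {
  if (length(v) < 30 || stats::sd(v) == 0) return(NA_real_)
  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
  if (bw <= 0) return(NA_real_)
  brk <- seq(min(v) - bw, max(v) + bw, by = bw)
  h <- graphics::hist(v, breaks = brk, plot = FALSE)
  xb <- h$mids; yb <- h$counts
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  st <- list(a1 = max(yb), m1 = q[1], s1 = bw * 2,
             a2 = max(yb) / 4, m2 = q[2], s2 = bw * 4)
  fit <- tryCatch(stats::nls(
    yb ~ a1 * exp(-(xb - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(xb - m2)^2 / (2 * s2^2)),
    start = st, algorithm = "port",
    lower = c(a1 = 0, a2 = 0, m1 = min(v), m2 = min(v),
              s1 = bw / 4, s2 = bw / 4),
    control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  p <- as.list(stats::coef(fit))
  if (p$a1 >= p$a2) p$m1 else p$m2
}

#' Count microtubules per YZ slice and per dendrite
#'
#' Per slice and channel, the normalized integrated intensity is the sum of
#' all detected spots' intensities divided by the single cross-section
#' intensity of that channel; the crosstalk unmixing system then yields
#' per-slice counts, and per-dendrite counts are means over slices.
#' Geometric filters are calibration-only: the slice sums deliberately
#' include bundles, which contribute multiple singles' worth of intensity.
#'
#' @param resliced a `resliced_stack` (YZ cross-sections).
#' @param fits named list of `single_intensity_fit` per channel
#'   (`total`, `tyr`, `ac`).
#' @param alpha,beta crosstalk coefficients.
#' @param slice_indices which slices to count (default all).
#' @param ... passed to [detect_spots()].
#' @return list with `per_slice` (data.frame: slice, n_tot, n_tyr, n_ac,
#'   n_other, n_spots, flags) and `per_dendrite` (mean counts over slices).
#' @export
count_per_slice <- function(resliced, fits, alpha, beta,
                            slice_indices = NULL, ...) {
  chans <- names(resliced$slices)
  if (is.null(slice_indices)) slice_indices <- seq_len(n_slices(resliced))
  rows <- lapply(slice_indices, function(i) {
    sl <- lapply(chans, function(ch) get_slice(resliced, ch, i))
    names(sl) <- chans
    theta <- numeric(0)
    n_spots <- 0L
    for (ch in chans) {
      spots <- detect_spots(sl, detect_channel = ch, ...)
      tot_I <- if (nrow(spots)) sum(spots[[paste0("I_", ch)]]) else 0
      theta[ch] <- tot_I / fits[[ch]]$I_Tot
      if (ch == "total") n_spots <- nrow(spots)
    }
    flag <- if (n_spots == 0) "zero_spots" else ""
    nn <- unmix_counts(theta["tyr"], theta["ac"], alpha, beta)
    data.frame(slice = i, n_tot = unname(theta["total"]),
               n_tyr = unname(nn["n_tyr"]), n_ac = unname(nn["n_ac"]),
               n_other = unname(theta["total"] - nn["n_tyr"] - nn["n_ac"]),
               n_spots = n_spots, flags = flag)
  })
  per_slice <- do.call(rbind, rows)
  per_dendrite <- colMeans(per_slice[, c("n_tot", "n_tyr", "n_ac", "n_other")])
  list(per_slice = per_slice, per_dendrite = per_dendrite)
}
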