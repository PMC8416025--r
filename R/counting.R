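# Dendrite-stage counting: background-corrected dendrite band intensities,
# conversion to total microtubule number via the single-filament intensity,
# and linear unmixing of tyrosinated/acetylated/other counts using the
# crosstalk coefficients alpha and beta.

#' Measure background-corrected dendrite intensities
#'
#' A straight line of length `L_dendrite` along the dendrite with width
#' `w_dendrite` (chosen to cover the dendrite's whole thickness) is
#' integrated per channel on sum projections (I_mid over S_mid); a band
#' widened by `widen_by` pixels yields the background
#' I_BG = (I_wide - I_mid) / (S_wide - S_mid). The dendrite intensity is
#' normalized so that dividing by the single-filament intensity yields a
#' count: I_dendrite = (I_mid - I_BG * S_mid) / (L_px * w_microtubule),
#' with `w_microtubule` the same 6-pixel width used in single-filament
#' quantification.
#'
#' @param sum_images named list of sum-projection matrices per channel.
#' @param line a [polyline_roi()] with exactly 2 vertices.
#' @param w_dendrite band width, pixels.
#' @param pixel_size_um biological um per pixel.
#' @param widen_by background band widening, pixels (default 10).
#' @param w_microtubule normalization width, pixels (default 6).
#' @return data.frame of class `dendrite_measurement`: one row per channel
#'   with `I_mid`, `I_wide`, `S_mid`, `S_wide`, `I_BG`, `I_dendrite`, plus
#'   `L_um` and `w_dendrite` in `attr(, "geometry")`.
#' @export
measure_dendrite <- function(sum_images, line, w_dendrite, pixel_size_um,
                             widen_by = 10, w_microtubule = 6) {
  stopifnot(inherits(line, "polyline_roi"))
  v <- line$vertices
  if (nrow(v) != 2) stop("dendrite line must have exactly 2 vertices")
  L_px <- sqrt(sum((v[2, ] - v[1, ])^2))
  L_um <- L_px * pixel_size_um
  if (L_um < 2 || L_um > 3)
    warning(sprintf("dendrite line length %.2f um outside preferred 2-3 um",
                    L_um))
  dim_img <- dim(sum_images[[1]])
  w_wide <- w_dendrite + widen_by
  m <- w_wide / 2
  # the band widens only perpendicular to the line (no end caps)
  ab <- v[2, ] - v[1, ]
  un <- c(-ab[2], ab[1]) / sqrt(sum(ab^2))
  corners <- rbind(v[1, ] + m * un, v[1, ] - m * un,
                   v[2, ] + m * un, v[2, ] - m * un)
  if (any(corners[, 1] < 0 | corners[, 1] > dim_img[2] - 1 |
          corners[, 2] < 0 | corners[, 2] > dim_img[1] - 1))
    stop("widened dendrite band exits the image")
  idx_mid <- .band_pixels(dim_img, v[1, ], v[2, ], w_dendrite)
  idx_wide <- .band_pixels(dim_img, v[1, ], v[2, ], w_wide)
  S_mid <- length(idx_mid)
  S_wide <- length(idx_wide)
  rows <- lapply(names(sum_images), function(ch) {
    img <- sum_images[[ch]]
    I_mid <- sum(img[idx_mid])
    I_wide <- sum(img[idx_wide])
    I_BG <- (I_wide - I_mid) / (S_wide - S_mid)
    data.frame(channel = ch, I_mid = I_mid, I_wide = I_wide,
               S_mid = S_mid, S_wide = S_wide, I_BG = I_BG,
               I_dendrite = (I_mid - I_BG * S_mid) / (L_px * w_microtubule))
  })
  out <- do.call(rbind, rows)
  attr(out, "geometry") <- list(L_um = L_um, L_px = L_px,
                                w_dendrite = w_dendrite,
                                w_microtubule = w_microtubule)
  class(out) <- c("dendrite_measurement", "data.frame")
  out
}

#' Total microtubule number from dendrite intensity
#'
#' n_Tot = I_Tot_dendrite / I_Tot, with the single-filament calibration
#' taken from the same cell/stack.
#'
#' @param measurement a `dendrite_measurement`.
#' @param fit the cell's `single_intensity_fit`.
#' @return n_Tot (numeric).
#' @export
count_total <- function(measurement, fit) {
  if (fit$I_Tot <= 0) stop("I_Tot must be positive")
  I_d <- measurement$I_dendrite[measurement$channel == "total"]
  if (length(I_d) != 1) stop("measurement lacks a 'total' channel row")
  I_d / fit$I_Tot
}

#' Unmix tyrosinated and acetylated microtubule counts
#'
#' Inverts the forward model
#' `I_Tyr_dendrite = (n_Tyr + alpha n_Ac) I_Tyr`,
#' `I_Ac_dendrite = (beta n_Tyr + n_Ac) I_Ac`
#' in its normalized form (theta_Tyr = I_Tyr_dendrite / I_Tyr, etc.):
#' `n_Tyr = (theta_Tyr - alpha theta_Ac) / (1 - alpha beta)`,
#' `n_Ac = theta_Ac - beta n_Tyr`.
#' Negative outputs are returned flagged, never clamped.
#'
#' @param theta_tyr,theta_ac normalized dendrite intensities.
#' @param alpha,beta crosstalk coefficients (`alpha * beta` must differ
#'   from 1).
#' @return named vector `c(n_tyr, n_ac)`; `attr(, "negative")` flags
#'   negative components.
#' @export
unmix_counts <- function(theta_tyr, theta_ac, alpha, beta) {
  det <- 1 - alpha * beta
  if (abs(det) < 1e-6)
    stop("crosstalk matrix is singular (alpha * beta = ",
         signif(alpha * beta, 6), "); counts are unidentifiable")
  n_tyr <- unname((theta_tyr - alpha * theta_ac) / det)
  n_ac <- unname(theta_ac - beta * n_tyr)
  out <- c(n_tyr = n_tyr, n_ac = n_ac)
  attr(out, "negative") <- out < 0
  out
}

#' Classify counts into subtype numbers, fractions and density
#'
#' n_Other = n_Tot - n_Tyr - n_Ac may legitimately be negative under noise;
#' it is reported with a flag, and fractions are computed over n_Tot with
#' the negative component clamped only in the fraction denominator.
#'
#' @param n_tot,n_tyr,n_ac real-valued counts.
#' @param area cross-sectional area, um^2 (> 0).
#' @return object of class `microtubule_counts`: counts, `n_other`,
#'   `fractions` (tyr, ac, other), `density` (MT/um^2), `flags`.
#' @export
classify_counts <- function(n_tot, n_tyr, n_ac, area) {
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  n_other <- n_tot - n_tyr - n_ac
  flags <- character(0)
  if (n_other < 0) flags <- c(flags, "negative_n_other")
  if (n_tyr < 0) flags <- c(flags, "negative_n_tyr")
  if (n_ac < 0) flags <- c(flags, "negative_n_ac")
  denom <- n_tyr + n_ac + max(n_other, 0)
  fractions <- c(tyr = n_tyr, ac = n_ac, other = max(n_other, 0)) /
    max(denom, .Machine$double.eps)
  structure(list(n_tot = n_tot, n_tyr = n_tyr, n_ac = n_ac,
                 n_other = n_other, fractions = fractions,
                 density = n_tot / area, area = area, flags = flags),
            class = "microtubule_counts")
}

#' @export
print.microtubule_counts <- function(x, ...) {
  cat(sprintf(
    "microtubule_counts: n_tot = %.1f (tyr %.1f, ac %.1f, other %.1f)\n",
    x$n_tot, x$n_tyr, x$n_ac, x$n_other))
  cat(sprintf("  fractions: tyr %.1f%%, ac %.1f%%, other %.1f%%; density %.1f MT/um^2\n",
              100 * x$fractions["tyr"], 100 * x$fractions["ac"],
              100 * x$fractions["other"], x$density))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Dendrite cross-sectional area from a resliced stack
#'
#' Builds the boundary contour (rectangle-scan + spline by default, convex
#' hull of local maxima as the alternative) on one YZ cross-section and
#' converts the enclosed area to biological um^2 via the pixel size and
#' expansion factor.
#'
#' @param resliced a `resliced_stack`.
#' @param slice_index which cross-section (default: middle slice).
#' @param channel reference channel for the contour (default `"total"`).
#' @param method `"spline"` (rectangle scan + 8-anchor spline) or `"hull"`.
#' @param params a [boundary_params()].
#' @return area in biological um^2; the contour is attached as
#'   `attr(, "contour")`.
#' @export
measure_cross_section_area <- function(resliced, slice_index = NULL,
                                       channel = "total",
                                       method = c("spline", "hull"),
                                       params = boundary_params()) {
  method <- match.arg(method)
  if (is.null(slice_index)) slice_index <- max(1L, n_slices(resliced) %/% 2L)
  sl <- get_slice(resliced, channel, slice_index)
  contour <- if (method == "spline") {
    rect <- initial_rectangle(sl, params)
    fit_contour(sl, rect, params)
  } else {
    convex_hull_contour(sl)
  }
  a_px <- polygon_area(contour$curve)
  area <- a_px * resliced$pixel_size^2 / resliced$expansion_factor^2
  attr(area, "contour") <- contour
  area
}
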