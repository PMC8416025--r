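test_that("select_substack projections follow their definitions", {
  a <- array(rep(1:4, each = 6), c(2, 3, 4))
  st <- channel_stack(list(total = a), voxel_size = c(x = 0.03, y = 0.03,
                                                      z = 0.15))
  one <- select_substack(st, c(2, 2))
  expect_equal(one$mip$total, a[, , 2])
  expect_equal(one$sum$total, a[, , 2])
  all4 <- select_substack(st, c(1, 4))
  expect_equal(all4$mip$total, matrix(4, 2, 3))
  expect_equal(all4$sum$total, matrix(10, 2, 3))
  expect_error(select_substack(st, c(5, 6)), "z_range")
})

test_that("detector finds isolated and parallel filaments, honors masks", {
  expect_length(detect_segments(matrix(0, 50, 50), 0.03), 0)
  s <- scene_spec("soma_sheet", n_microtubules = 1, field_size = 8, seed = 77)
  sim <- simulate_scene(s)
  sub <- select_substack(sim$stack, c(1, dim(sim$stack$voxels$total)[3]))
  segs <- detect_segments(sub$mip$total, sub$pixel_size_um)
  expect_length(segs, 1)
  tru <- sim$truth$centerlines[[1]][, 1:2] / 0.03
  ends <- segs[[1]]$vertices[c(1, nrow(segs[[1]]$vertices)), ]
  err <- vapply(1:2, function(i)
    min(sqrt(rowSums(sweep(tru, 2, ends[i, ])^2))), numeric(1))
  expect_true(all(err <= 2))
  expect_lt(abs(segs[[1]]$length_um - sim$truth$filaments$length_um) /
              sim$truth$filaments$length_um, 0.15)
  # two parallel filaments 10 px apart stay separate
  dims <- c(80, 80, 1)
  xs <- seq(15, 65, by = 0.25)
  a <- mtquant:::splat_points(dims, xs, rep(30, length(xs)), rep(0, length(xs)),
                              rep(50, length(xs))) +
    mtquant:::splat_points(dims, xs, rep(40, length(xs)), rep(0, length(xs)),
                           rep(50, length(xs)))
  img <- mtquant:::gauss_blur3d(a, c(1.2, 1.2, 0))[, , 1]
  set.seed(1)
  img <- img + matrix(rpois(6400, 3), 80, 80)
  expect_length(detect_segments(img, 0.03), 2)
  # empty mask polygon gives empty result, not an error
  msk <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_length(detect_segments(img, 0.03, mask = msk), 0)
})

test_that("flat-field null: I_segm is exactly zero on constant images", {
  img <- matrix(3.7, 60, 60)
  seg <- straight_segment(12, 30, 45, 30)
  m <- measure_segment(list(total = img, tyr = img * 2), seg)
  expect_equal(m$I_BG, c(3.7, 7.4))
  expect_equal(m$I_segm, c(0, 0))
  expect_true(all(m$S_wide > m$S_mid))
})

test_that("segment measurement matches a brute-force masked-pixel oracle", {
  set.seed(42)
  img <- matrix(rpois(90 * 70, 20), 90, 70) +
    mtquant:::gauss_blur2d(
      mtquant:::splat_points(c(90, 70, 1), seq(15, 55, by = 0.25),
                             seq(20, 60, by = 0.25) * 0.5 + 15,
                             rep(0, 161), rep(40, 161))[, , 1], 1.5)
  seg <- straight_segment(15, 25, 55, 45)
  m <- measure_segment(list(total = img), seg)
  # independent oracle: same tube-membership rule, separate implementation
  oracle_tube <- function(w) {
    v <- seg$vertices
    inside <- matrix(FALSE, nrow(img), ncol(img))
    for (yy in seq_len(nrow(img))) for (xx in seq_len(ncol(img))) {
      px <- xx - 1; py <- yy - 1
      ab <- v[2, ] - v[1, ]
      t <- ((px - v[1, 1]) * ab[1] + (py - v[1, 2]) * ab[2]) / sum(ab^2)
      if (t < 0 || t > 1) next # stroked band: no end caps
      q <- v[1, ] + t * ab
      if (sqrt((px - q[1])^2 + (py - q[2])^2) <= w / 2)
        inside[yy, xx] <- TRUE
    }
    inside
  }
  t6 <- oracle_tube(6); t13 <- oracle_tube(13)
  I_mid <- sum(img[t6]); S_mid <- sum(t6)
  I_wide <- sum(img[t13]); S_wide <- sum(t13)
  I_BG <- (I_wide - I_mid) / (S_wide - S_mid)
  expect_equal(m$I_mid, I_mid, tolerance = 1e-12)
  expect_equal(m$S_mid, S_mid)
  expect_equal(m$I_segm, I_mid / S_mid - I_BG, tolerance = 1e-9)
})

test_that("I_segm is invariant to a background plane", {
  dims <- c(70, 70, 1)
  xs <- seq(12, 58, by = 0.25)
  base <- mtquant:::gauss_blur3d(
    mtquant:::splat_points(dims, xs, rep(35, length(xs)), rep(0, length(xs)),
                           rep(60, length(xs))), c(1.2, 1.2, 0))[, , 1]
  seg <- straight_segment(14, 35, 56, 35)
  m0 <- measure_segment(list(total = base), seg)
  mb <- measure_segment(list(total = base + 50), seg)
  expect_lt(abs(mb$I_segm - m0$I_segm) / m0$I_segm, 0.02)
  expect_equal(mb$I_BG - m0$I_BG, 50, tolerance = 1e-9)
  # border-touching segments are flagged
  near <- straight_segment(2, 35, 30, 35)
  expect_true(all(measure_segment(list(total = base), near)$excluded))
})

test_that("two-Gaussian fit recovers the generator ground truth", {
  # identifiability across cv and doublet fraction (fixed seeds)
  errs <- c()
  for (cv in c(0.1, 0.15, 0.2)) for (df in c(0.1, 0.3, 0.5)) {
    v <- simulate_segment_intensities(2000, 100, cv, df,
                                      seed = 1000 + round(cv * 100) + df * 10)
    f <- fit_single_intensity(v)
    errs <- c(errs, abs(f$I_Tot - 100) / 100)
  }
  expect_lt(median(errs), 0.05)
  v <- simulate_segment_intensities(2000, 100, 0.15, 0.3, seed = 42)
  f <- fit_single_intensity(v)
  expect_gt(f$I_Tot, 95)
  expect_lt(f$I_Tot, 105)
  expect_equal(f$single_threshold, f$I_Tot + f$sigma_Tot)
  # doublet-free: second amplitude vanishes
  v0 <- simulate_segment_intensities(2000, 100, 0.15, 0, seed = 43)
  f0 <- fit_single_intensity(v0)
  expect_lt(f0$a2 / f0$a1, 0.05)
  expect_lt(abs(f0$I_Tot - 100) / 100, 0.02)
  # degenerate input rejected
  expect_error(fit_single_intensity(rep(5, 500)), "degenerate")
})

test_that("filter_singles applies a strict threshold", {
  tab <- data.frame(segment = 1:3, detection_channel = "total",
                    length_um = 1, source = "internal_detector",
                    excluded = FALSE,
                    I_segm_total = c(99, 100, 101),
                    I_BG_total = 0)
  class(tab) <- c("segment_table", "data.frame")
  fit <- structure(list(I_Tot = 90, sigma_Tot = 10, single_threshold = 100),
                   class = "single_intensity_fit")
  kept <- filter_singles(tab, fit)
  expect_equal(kept$segment, 1L) # exactly at threshold -> discarded
  expect_equal(unname(attr(kept, "filter_counts")), c(1L, 2L))
  empty <- tab[0, ]
  class(empty) <- class(tab)
  expect_equal(nrow(filter_singles(empty, fit)), 0)
})

test_that("labelled doublets are mostly removed by the singles filter", {
  v <- simulate_segment_intensities(3000, 100, 0.15, 0.3, seed = 7)
  lab <- attr(v, "is_doublet")
  f <- fit_single_intensity(v)
  keep <- v < f$single_threshold
  expect_gte(mean(!keep[lab]), 0.8)   # >= 80% of doublets removed
  expect_lte(mean(!keep[!lab]), 0.2)  # <= 20% of singles removed
})

test_that("crosstalk estimates are ratios: scale-invariant", {
  set.seed(3)
  n <- 60
  tab <- data.frame(
    segment = 1:(3 * n),
    detection_channel = rep(c("total", "tyr", "ac"), each = n),
    length_um = 1, source = "internal_detector", excluded = FALSE,
    I_segm_total = rnorm(3 * n, 100, 10),
    I_segm_tyr = c(rnorm(n, 60, 5), rnorm(n, 100, 8), rnorm(n, 53, 5)),
    I_segm_ac = c(rnorm(n, 70, 5), rnorm(n, 45, 5), rnorm(n, 100, 8)))
  class(tab) <- c("segment_table", "data.frame")
  ct <- estimate_crosstalk(tab)
  tab2 <- tab
  tab2$I_segm_tyr <- tab2$I_segm_tyr * 7.3
  ct2 <- estimate_crosstalk(tab2)
  expect_equal(ct2$alpha, ct$alpha, tolerance = 1e-12)
  expect_equal(ct2$beta, ct$beta, tolerance = 1e-12)
  expect_equal(ct$alpha, 0.53, tolerance = 0.05)
  expect_equal(ct$beta, 0.45, tolerance = 0.05)
  # identical ac/tyr sets push alpha * beta toward 1 => singular unmixing
  tab3 <- tab[tab$detection_channel != "total", ]
  tab3$I_segm_tyr <- rep(tab$I_segm_tyr[tab$detection_channel == "tyr"], 2)
  tab3$I_segm_ac <- rep(tab$I_segm_ac[tab$detection_channel == "tyr"], 2)
  class(tab3) <- class(tab)
  ct3 <- estimate_crosstalk(tab3)
  expect_equal(ct3$alpha * ct3$beta, 1, tolerance = 1e-6)
  expect_error(unmix_counts(10, 10, ct3$alpha, ct3$beta), "singular")
})

test_that("soma calibration recovers crosstalk on the synthetic sheet", {
  cal <- soma_calibration()
  sc <- soma_scene()
  expect_lt(abs(cal$crosstalk$alpha - sc$spec$true_alpha), 0.10)
  expect_lt(abs(cal$crosstalk$beta - sc$spec$true_beta), 0.10)
  expect_gt(nrow(cal$singles), 50)
  # zero-crosstalk control stays near the noise floor
  s0 <- scene_spec("soma_sheet", n_microtubules = 120, bundle_fraction = 0.1,
                   fraction_acetylated = 0.45, fraction_tyrosinated = 0.45,
                   fraction_other = 0.10, psf_sigma_axial = 0.1,
                   true_alpha = 0, true_beta = 0, seed = 55)
  cal0 <- suppressWarnings(calibrate_soma(simulate_scene(s0)$stack))
  expect_lte(abs(cal0$crosstalk$alpha), 0.05)
  expect_lte(abs(cal0$crosstalk$beta), 0.05)
})

test_that("imported ROIs bypass detection as first-class segments", {
  roi <- polyline_roi(cbind(c(5, 25), c(10, 10)))
  segs <- segments_from_rois(roi, pixel_size_um = 0.03,
                             detection_channel = "tyr")
  expect_length(segs, 1)
  expect_equal(segs[[1]]$source, "imported_roi")
  expect_equal(segs[[1]]$length_um, 0.6, tolerance = 1e-9)
  expect_length(segments_from_rois(roi, 0.03, min_length_um = 1), 0)
})
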