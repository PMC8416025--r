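test_that("spot detection: blanks, isolated puncta, merged pairs", {
  blank <- matrix(rpois(80 * 80, 4), 80, 80)
  expect_equal(nrow(detect_spots(list(total = blank))), 0)
  sim <- simulate_crosssection_slice(n_singles = 20, n_doublets = 0,
                                     size_px = 160, seed = 3)
  spots <- detect_spots(list(total = sim$image))
  expect_gte(nrow(spots), 19)
  expect_lte(nrow(spots), 21)
  # centroid accuracy <= 1 px
  err <- vapply(seq_len(nrow(spots)), function(i)
    min(sqrt((sim$truth$x - spots$y[i])^2 + (sim$truth$y - spots$z[i])^2)),
    numeric(1))
  expect_lt(max(err), 1)
  # two puncta 1.5 PSF widths apart merge into one elongated spot
  img <- array(0, c(64, 64, 1))
  sg <- 0.1 / 0.07
  off <- 1.5 * (2.3548 * sg) / 2  # 1.5 PSF widths (FWHM)
  img <- img + mtquant:::splat_points(dim(img), c(32 - off, 32 + off),
                                      c(32, 32), c(0, 0), c(3000, 3000))
  img <- mtquant:::gauss_blur3d(img, c(sg, sg, 0))[, , 1]
  img <- matrix(rpois(64 * 64, img + 4), 64, 64)
  pair <- detect_spots(list(total = img))
  expect_equal(nrow(pair), 1)
  expect_lt(pair$roundness, 1)
})

test_that("roundness theta = w h / max(w, h)^2 filters elongated spots", {
  spots <- data.frame(detection_channel = "total", y = 1:3, z = 1:3,
                      w_spot = c(4, 2, 5), h_spot = c(4, 1, 4.5),
                      S_spot = 10, roundness = c(1, 2 * 1 / 4, 5 * 4.5 / 25),
                      I_total = 1)
  class(spots) <- c("spot_table", "data.frame")
  kept <- roundness_filter(spots, 0.8)
  expect_equal(kept$w_spot, c(4, 5)) # theta = 1 and 0.9 kept, 0.5 removed
  # symmetry and scale invariance of the definition
  th <- function(w, h) w * h / max(w, h)^2
  expect_equal(th(3, 7), th(7, 3))
  expect_equal(th(3, 7), th(30, 70))
})

test_that("MLE area filter excludes doublet areas and the tiny-noise tail", {
  set.seed(4)
  singles <- rnorm(120, 40, 6)
  doublets <- rnorm(40, 80, 9)
  tail_noise <- runif(15, 2, 8)
  areas <- c(singles, doublets, tail_noise)
  spots <- data.frame(detection_channel = "total",
                      y = seq_along(areas), z = 1,
                      w_spot = 4, h_spot = 4, S_spot = areas,
                      roundness = 1, I_total = 1)
  class(spots) <- c("spot_table", "data.frame")
  af <- area_filter(spots)
  lab <- c(rep("s", 120), rep("d", 40), rep("n", 15))
  kept <- lab[spots$S_spot >= af$params$range["lower"] &
                spots$S_spot <= af$params$range["upper"]]
  expect_gte(mean(lab == "d") - mean(kept == "d") / 1, 0) # doublets depleted
  expect_lte(sum(kept == "d") / 40, 0.10)  # >= 90% of doublets excluded
  expect_equal(sum(kept == "n"), 0)       # Q1 lower bound kills the tail
  expect_equal(af$params$Q1,
               unname(quantile(areas, 0.25, type = 7)))
  # degenerate: all areas equal -> range collapses, all kept
  eq <- spots[1:12, ]; eq$S_spot <- 30
  class(eq) <- class(spots)
  af2 <- area_filter(eq)
  expect_equal(unname(af2$params$range), c(30, 30))
  expect_equal(nrow(af2$spots), 12)
})

test_that("roundness and area filters commute as per-spot predicates", {
  sim <- simulate_crosssection_slice(n_singles = 40, n_doublets = 15,
                                     size_px = 200, seed = 9)
  spots <- detect_spots(list(total = sim$image))
  r_then_a <- area_filter(roundness_filter(spots))$spots
  params <- area_filter(roundness_filter(spots))$params
  a_pred <- spots$S_spot >= params$range["lower"] &
    spots$S_spot <= params$range["upper"]
  r_pred <- spots$roundness >= 0.8
  both <- spots[a_pred & r_pred, ]
  expect_equal(r_then_a$y, both$y)
})

test_that("single cross-section fit reuses the two-Gaussian machinery", {
  v <- simulate_segment_intensities(1981, 250, 0.15, 0.25, seed = 12)
  f <- fit_single_crosssection(v)
  expect_equal(f$I_Tot, 250, tolerance = 0.05)
  expect_gt(f$a2 / f$a1, 0.1) # visible doublet component
  v0 <- simulate_segment_intensities(800, 250, 0.15, 0, seed = 13)
  f0 <- fit_single_crosssection(v0)
  expect_lt(f0$a2 / f0$a1, 0.05)
})

test_that("the three crosstalk estimators behave and order correctly", {
  set.seed(21)
  # zero-crosstalk scene: all methods at the noise floor
  lv0 <- abs(rnorm(200, 0, 0.02))
  for (m in c("pooled_mean", "trimmed_mean", "two_gaussian_peak")) {
    est <- estimate_crosstalk_flipexm(lv0, lv0, method = m)
    expect_lte(est["alpha"], 0.05)
    expect_lte(est["beta"], 0.05)
  }
  # heavy right tail: pooled > trimmed >= peak
  lv <- c(rnorm(300, 0.4, 0.05), 0.4 + rexp(60, rate = 2))
  p <- estimate_crosstalk_flipexm(lv, lv, "pooled_mean")["alpha"]
  t <- estimate_crosstalk_flipexm(lv, lv, "trimmed_mean")["alpha"]
  g <- estimate_crosstalk_flipexm(lv, lv, "two_gaussian_peak")["alpha"]
  expect_gt(p, t)
  expect_gte(round(t, 10), round(g, 10))
})

test_that("crosstalk recovery on a well-populated flipexm dendrite", {
  spec <- scene_spec("flipexm_dendrite", n_microtubules = 120,
                     dendrite_diameter = 2.7, dendrite_length = 1.5,
                     fraction_acetylated = 0.60, fraction_tyrosinated = 0.35,
                     fraction_other = 0.05,
                     true_alpha = 0.45, true_beta = 0.60,
                     psf_sigma_lateral = 0.1, psf_sigma_axial = 0.35,
                     voxel_size = c(x = 0.07, y = 0.07, z = 0.15),
                     expansion_factor = 4.15, seed = 71)
  sim <- simulate_scene(spec)
  resl <- reslice_dendrite(sim$stack, margin_x = 8)
  fa <- suppressWarnings(analyze_flipexm(
    resl, calib_slices = seq(3, n_slices(resl) - 3, by = 3),
    count_slices = seq(10, n_slices(resl) - 10, by = 6)))
  expect_lt(abs(fa$crosstalk["alpha"] - 0.45), 0.12)
  expect_lt(abs(fa$crosstalk["beta"] - 0.60), 0.12)
})

test_that("per-slice counting: exact on calibrated singles, flags empties", {
  # one synthetic slice whose spots sum to exactly 12 singles, alpha=beta=0
  img <- array(0, c(90, 90, 1))
  pos <- expand.grid(y = c(20, 45, 70), z = c(20, 45, 70))[1:9, ]
  for (i in 1:9) img <- img + mtquant:::splat_points(
    dim(img), pos$y[i], pos$z[i], 0, 1000)
  img <- img + mtquant:::splat_points(dim(img), c(12, 78, 12), c(78, 12, 12),
                                      c(0, 0, 0), rep(1000, 3))
  img <- mtquant:::gauss_blur3d(img, c(1.4, 1.4, 0))[, , 1]
  slices <- list(total = img, tyr = img * 0.5, ac = img * 0.5)
  resl <- structure(list(slices = lapply(slices, function(m)
    array(m, c(90, 90, 1))),
    pixel_size = 0.07, slice_spacing = 0.07, z_interpolated = TRUE,
    expansion_factor = 1), class = "resliced_stack")
  spots <- detect_spots(slices, "total", noise_k = 5)
  expect_equal(nrow(spots), 12)
  unit <- sum(spots$I_total) / 12
  fits <- list(total = structure(list(I_Tot = unit), class = "single_intensity_fit"),
               tyr = structure(list(I_Tot = unit / 2), class = "single_intensity_fit"),
               ac = structure(list(I_Tot = unit / 2), class = "single_intensity_fit"))
  cnt <- count_per_slice(resl, fits, alpha = 0, beta = 0)
  expect_equal(cnt$per_slice$n_tot, 12, tolerance = 1e-6)
  # empty slice flagged as zero
  resl0 <- resl
  resl0$slices <- lapply(resl0$slices, function(a) a * 0)
  cnt0 <- count_per_slice(resl0, fits, alpha = 0, beta = 0)
  expect_equal(cnt0$per_slice$n_tot, 0)
  expect_equal(cnt0$per_slice$flags, "zero_spots")
})

test_that("flipexm pipeline counts a 30-MT flipped dendrite", {
  resl <- flipexm_resliced()
  tr <- flipexm_scene()$truth
  fa <- suppressWarnings(analyze_flipexm(
    resl, calib_slices = seq(3, n_slices(resl) - 3, by = 2),
    count_slices = seq(5, n_slices(resl) - 5, by = 2)))
  pd <- fa$counts$per_dendrite
  expect_equal(unname(pd["n_tot"]), tr$n_tot, tolerance = 0.15)
  expect_lt(abs(pd["n_tyr"] / pd["n_tot"] - tr$n_tyr / tr$n_tot), 0.10)
  expect_lt(abs(pd["n_ac"] / pd["n_tot"] - tr$n_ac / tr$n_tot), 0.10)
  # little per-slice variability along the proximal dendrite
  ps <- fa$counts$per_slice
  expect_lt(sd(ps$n_tot) / mean(ps$n_tot), 0.1)
})
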