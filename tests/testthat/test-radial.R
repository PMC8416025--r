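test_that("boundary_params validates its ranges", {
  expect_error(boundary_params(I_thr = 0), "I_thr")
  expect_error(boundary_params(tracking_thresholds = c(0.3, 0.1)), "ascending")
  expect_error(boundary_params(diagonal_fraction = 1.2), "diagonal_fraction")
  expect_s3_class(boundary_params(), "boundary_params")
})

test_that("initial_rectangle finds a centered disk's bounding box", {
  sl <- disk_image(n = 121, r = 35, value = 100, background = 1)
  r <- initial_rectangle(sl, boundary_params())
  expect_lt(abs(r$x_lb - (60 - 35)), 2.5)
  expect_lt(abs(r$x_rb - (60 + 35)), 2.5)
  expect_lt(abs(r$y_tb - (60 - 35)), 2.5)
  expect_lt(abs(r$y_bb - (60 + 35)), 2.5)
  expect_error(initial_rectangle(matrix(0, 50, 50)), "all-zero")
  expect_error(initial_rectangle(matrix(1, 50, 50)), "threshold|boundary")
  # a distractor inside the inner half (outside the w/2..w scan range of
  # the right edge) is ignored
  sl2 <- sl
  sl2[55:70, 46:51] <- 160
  r2 <- initial_rectangle(sl2, boundary_params())
  expect_lt(abs(r2$x_rb - (60 + 35)), 3)
})

test_that("track_rectangle is a fixed point on identical slices and follows drift", {
  sl <- disk_image(n = 121, r = 30, value = 100, background = 1)
  r0 <- initial_rectangle(sl, boundary_params())
  r1 <- track_rectangle(sl, r0, boundary_params())
  expect_equal(c(r1$x_lb, r1$x_rb, r1$y_tb, r1$y_bb),
               c(r0$x_lb, r0$x_rb, r0$y_tb, r0$y_bb), tolerance = 1)
  # disk drifting 1 px/slice over 20 slices
  prev <- r0
  centers <- numeric(20)
  for (i in 1:20) {
    sli <- disk_image(n = 121, r = 30, value = 100, cx = 60 + i,
                      background = 1)
    prev <- track_rectangle(sli, prev, boundary_params())
    centers[i] <- (prev$x_lb + prev$x_rb) / 2
  }
  drift <- diff(centers)
  expect_lt(max(abs(drift - 1)), 1.01)
  expect_lte(abs(centers[20] - 80), 4)
  # an adjacent axon blob: tracking stays on the dendrite
  slax <- disk_image(n = 121, r = 30, value = 100, background = 1)
  slax[55:70, 100:112] <- 90 # bright blob to the right
  tracked <- track_rectangle(slax, r0, boundary_params())
  expect_lt(abs(tracked$x_rb - 90), 4)
})

test_that("8-anchor contours follow disks and ellipses", {
  sl <- mtquant:::gauss_blur2d(disk_image(n = 121, r = 35, value = 100), 1.5)
  r <- initial_rectangle(sl, boundary_params())
  ct <- fit_contour(sl, r, boundary_params())
  rad <- sqrt((ct$curve[, 1] - 60)^2 + (ct$curve[, 2] - 60)^2)
  expect_lt((max(rad) - min(rad)) / mean(rad), 0.2)
  expect_equal(mean(rad), 35, tolerance = 0.1)
  # 2:1 ellipse
  xs <- rep(0:120, each = 121); ys <- rep(0:120, 121)
  ell <- matrix(as.numeric(((xs - 60) / 40)^2 + ((ys - 60) / 20)^2 <= 1) * 100,
                121, 121)
  ell <- mtquant:::gauss_blur2d(ell, 1.5)
  re <- initial_rectangle(ell, boundary_params())
  cte <- fit_contour(ell, re, boundary_params())
  w <- diff(range(cte$curve[, 1]))
  h <- diff(range(cte$curve[, 2]))
  expect_equal(w / h, 2, tolerance = 0.15)
  # degenerate rectangle
  bad <- structure(list(x_lb = 10, x_rb = 12, y_tb = 10, y_bb = 12),
                   class = "bounding_rect")
  expect_error(fit_contour(sl, bad, boundary_params()), "degenerate")
})

test_that("convex hull contour circles a ring of puncta", {
  img <- matrix(0, 101, 101)
  th <- 2 * pi * (0:11) / 12
  for (i in 1:12) {
    img <- img + mtquant:::splat_points(c(101, 101, 1), 50 + 30 * cos(th[i]),
                                        50 + 30 * sin(th[i]), 0, 500)[, , 1]
  }
  img <- mtquant:::gauss_blur2d(img, 1.5)
  ct <- convex_hull_contour(img, threshold = 1)
  rad <- sqrt((ct$curve[, 1] - 50)^2 + (ct$curve[, 2] - 50)^2)
  expect_equal(mean(rad), 30, tolerance = 0.06)
  # degenerate: too few maxima
  expect_error(convex_hull_contour(matrix(0, 50, 50)), "maxima")
  # cross-method agreement on a clean disk
  sl <- mtquant:::gauss_blur2d(disk_image(n = 121, r = 45, value = 100), 1)
  a_spline <- fit_contour(sl, initial_rectangle(sl, boundary_params()),
                          boundary_params())$area_px
  set.seed(2)
  sl_pk <- sl + matrix(rnorm(121^2, 0, 1), 121, 121)
  a_hull <- convex_hull_contour(sl_pk, smooth_sigma = 0.8)$area_px
  expect_lt(abs(a_hull - a_spline) / a_spline, 0.15)
})

test_that("radial profile: flat disks, annuli, and the erosion invariants", {
  sl <- disk_image(n = 101, r = 40, value = 100)
  ct <- circle_contour(50, 50, 40.5)
  pr <- radial_profile(sl, ct)
  p <- pr$profile
  sel <- p$R >= 0.1 & p$R <= 0.9
  expect_true(all(abs(p$rho[sel] - 1) < 0.05))
  # erosion series monotonicity (over the rings; the final row repeats the
  # un-eroded core)
  rings <- p[order(p$k), ][seq_len(nrow(p) - 1L), ]
  expect_true(all(diff(rings$S) < 0))
  expect_true(all(diff(rings$IC) <= 0))
  # unit integral under the ring-coverage quadrature
  ordk <- order(p$k)
  S <- p$S[ordk]; R <- p$R[ordk]; rho <- p$rho[ordk]
  Rfull <- c(1, R[-length(R)])
  expect_equal(sum(rho[-length(rho)] * (Rfull[-length(R)] - R[-length(R)])) +
                 rho[length(rho)] * R[length(R) - 1], 1, tolerance = 1e-6)
  # annulus at 0.8 R
  ann <- matrix(0, 101, 101)
  xs <- rep(0:100, each = 101); ys <- rep(0:100, 101)
  rr <- sqrt((xs - 50)^2 + (ys - 50)^2)
  ann[rr >= 30.5 & rr <= 34.5] <- 100 # centered at 32.5 = 0.8 * 40.5
  pra <- radial_profile(matrix(ann, 101, 101), ct)
  expect_gt(pra$profile$R[which.max(pra$profile$rho)], 0.7)
  expect_lt(pra$profile$R[which.max(pra$profile$rho)], 0.9)
  expect_error(radial_profile(sl, circle_contour(50, 50, 0.8)), "area")
})

test_that("erosion series matches a brute-force distance-binning oracle", {
  set.seed(8)
  sl <- mtquant:::gauss_blur2d(disk_image(n = 101, r = 38, value = 100), 2) +
    matrix(rnorm(101^2, 0, 2), 101, 101)
  ct <- circle_contour(50, 50, 40)
  pr <- radial_profile(sl, ct)
  orc <- radial_oracle(sl, ct, 50, 50, 40)
  got <- approx(pr$profile$R, pr$profile$rho, xout = orc$R, rule = 2)$y
  expect_lt(mean(abs(got - orc$rho)), 0.05)
})

test_that("profile averaging: SD, SEM and grid interpolation", {
  mk <- function(rho) {
    structure(list(profile = data.frame(k = 1:5, S = 5:1, IC = 5:1,
                                        MI = rho, R = seq(0.1, 0.9, 0.2),
                                        rho = rho),
                   channel = "total", flags = character(0)),
              class = "radial_profile")
  }
  same <- list(mk(rep(1, 5)), mk(rep(1, 5)))
  av <- average_profiles(same)
  expect_true(all(av$sd == 0))
  two <- list(mk(rep(0.8, 5)), mk(rep(1.2, 5)))
  av2 <- average_profiles(two, dendrite = c(1, 2))
  expect_true(all(abs(av2$mean - 1) < 1e-9))
  expect_equal(av2$sd[1], sd(c(0.8, 1.2)), tolerance = 1e-9)
  expect_equal(av2$sem[1], sd(c(0.8, 1.2)) / sqrt(2), tolerance = 1e-9)
  expect_error(average_profiles(list()), "at least one")
})

test_that("core/shell dendrites order the subtype radial densities", {
  # population average (the reference ordering is a population statement)
  pop <- core_shell_population()
  wmean <- function(av) sum(av$R * av$mean) / sum(av$mean)
  expect_lt(wmean(pop$ac), wmean(pop$tyr))
  # peak ordering, excluding the innermost rings where tiny erosion areas
  # dominate (discretization at the extremes)
  argmax_R <- function(av) {
    keep <- av$R >= 0.15
    av$R[keep][which.max(av$mean[keep])]
  }
  expect_gt(argmax_R(pop$tyr), argmax_R(pop$ac))
  # a single biased dendrite still shows the intensity-weighted ordering
  sc <- dendrite_scene()
  resl <- reslice_dendrite(sc$stack, margin_x = 30)
  ra <- analyze_radial(resl, slice_indices = seq(5, n_slices(resl) - 5, by = 4))
  expect_lt(wmean(ra$average$ac), wmean(ra$average$tyr))
})

test_that("closed-form decomposition: exactness, collinearity, optimality", {
  R <- seq(0, 1, length.out = 50)
  tyr <- exp(-(R - 0.85)^2 / (2 * 0.12^2)); tyr <- tyr / trapz(R, tyr)
  ac <- exp(-(R - 0.3)^2 / (2 * 0.25^2)); ac <- ac / trapz(R, ac)
  tot <- 0.35 * tyr + 0.65 * ac
  d <- decompose_total(tot, tyr, ac)
  expect_lt(abs(d$w_tyr - 0.35), 1e-9)
  expect_lt(abs(d$w_ac - 0.65), 1e-9)
  expect_lt(d$mse, 1e-18)
  expect_error(decompose_total(tot, tyr, tyr), "collinear")
  # noisy mixture: weight sum near 1
  set.seed(5)
  tn <- tot * (1 + 0.05 * rnorm(50)); tn <- tn / trapz(R, tn)
  dn <- decompose_total(tn, tyr, ac)
  expect_gt(dn$weight_sum, 0.95)
  expect_lt(dn$weight_sum, 1.05)
  # optimality against a 50 x 50 grid search
  g <- seq(0, 2, length.out = 50)
  mse_grid <- outer(g, g, Vectorize(function(wt, wa)
    mean((tn - wt * tyr - wa * ac)^2)))
  expect_lte(dn$mse, min(mse_grid))
})
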