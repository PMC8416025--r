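# Shared fixtures, memoized per test session so heavy scenes render once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# the calibration soma sheet of the acceptance world: 200 filaments, 20%
# two-filament bundles, balanced tyr/ac subnetworks, 3D-STED-like PSF
soma_scene <- function() fixture("soma_scene", function() {
  spec <- scene_spec("soma_sheet", n_microtubules = 200, bundle_fraction = 0.2,
                     fraction_acetylated = 0.45, fraction_tyrosinated = 0.45,
                     fraction_other = 0.10, psf_sigma_axial = 0.1,
                     true_alpha = 0.53, true_beta = 0.45, seed = 101)
  sim <- simulate_scene(spec)
  list(spec = spec, stack = sim$stack, truth = sim$truth)
})

soma_calibration <- function() fixture("soma_calibration", function() {
  suppressWarnings(calibrate_soma(soma_scene()$stack))
})

# dendrite scene of the acceptance world (3 um^2, 53 MT/um^2)
dendrite_scene <- function(area_um2 = 3, seed = 202,
                           density = 53, length_um = 4) {
  key <- paste0("dend_", area_um2, "_", seed)
  fixture(key, function() {
    dia <- 2 * sqrt(area_um2 / pi)
    spec <- scene_spec("dendrite", n_microtubules = round(density * area_um2),
                       dendrite_diameter = dia, dendrite_length = length_um,
                       fraction_acetylated = 0.72, fraction_tyrosinated = 0.26,
                       fraction_other = 0.02, psf_sigma_axial = 0.1,
                       true_alpha = 0.53, true_beta = 0.45,
                       radial_bias = 0.8, seed = seed)
    sim <- simulate_scene(spec)
    list(spec = spec, stack = sim$stack, truth = sim$truth)
  })
}

# FlipExM dendrite (22 ac / 7 tyr / 1 other), confocal-ExM optics
flipexm_scene <- function() fixture("flipexm_scene", function() {
  spec <- scene_spec("flipexm_dendrite", n_microtubules = 30,
                     dendrite_diameter = 1.4, dendrite_length = 2,
                     fraction_acetylated = 22 / 30,
                     fraction_tyrosinated = 7 / 30, fraction_other = 1 / 30,
                     true_alpha = 0.45, true_beta = 0.60,
                     psf_sigma_lateral = 0.1, psf_sigma_axial = 0.35,
                     voxel_size = c(x = 0.07, y = 0.07, z = 0.15),
                     expansion_factor = 4.15, seed = 31)
  sim <- simulate_scene(spec)
  list(spec = spec, stack = sim$stack, truth = sim$truth)
})

flipexm_resliced <- function() fixture("flipexm_resliced", function() {
  st <- flipexm_scene()$stack
  d <- dim(st$voxels$total)
  yc <- (d[1] - 1) / 2
  path <- polyline_roi(rbind(c(8, yc), c(d[2] - 9, yc)))
  straighten_and_reslice(st, path,
                         half_width = floor(min(yc, d[1] - 1 - yc) - 1))
})

# horizontal-midline reslice of a dendrite stack
reslice_dendrite <- function(stack, margin_x = 20) {
  d <- dim(stack$voxels$total)
  yc <- (d[1] - 1) / 2
  path <- polyline_roi(rbind(c(margin_x, yc), c(d[2] - margin_x - 1, yc)))
  straighten_and_reslice(stack, path,
                         half_width = floor(min(yc, d[1] - 1 - yc) - 1))
}

# simple geometric fixtures ---------------------------------------------------

disk_image <- function(n = 101, r = 40, value = 100, cx = (n - 1) / 2,
                       cy = (n - 1) / 2, background = 0) {
  xs <- rep(0:(n - 1), each = n)
  ys <- rep(0:(n - 1), n)
  m <- matrix(background, n, n)
  m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- value
  matrix(m, n, n)
}

circle_contour <- function(cx, cy, r, n_out = 240) {
  th <- seq(0, 2 * pi, length.out = n_out + 1)[-(n_out + 1)]
  structure(list(anchors = NULL,
                 curve = cbind(x = cx + r * cos(th), y = cy + r * sin(th)),
                 area_px = pi * r^2, flags = character(0), method = "manual"),
            class = "closed_contour")
}

# a minimal filament_segment for measurement tests
straight_segment <- function(x0, y0, x1, y1, channel = "total",
                             length_um = 1) {
  structure(list(vertices = cbind(x = c(x0, x1), y = c(y0, y1)),
                 length_um = length_um, detection_channel = channel,
                 source = "internal_detector"),
            class = "filament_segment")
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# a small population of fully segregated core/shell dendrites (the
# reference radial ordering is a population-average statement); returns
# per-channel averaged profiles across the population
core_shell_population <- function() fixture("core_shell_pop", function() {
  profs <- list(tyr = list(), ac = list(), total = list())
  dend_id <- list(tyr = c(), ac = c(), total = c())
  for (seed in 401:403) {
    spec <- scene_spec("dendrite", n_microtubules = 100,
                       dendrite_diameter = 1.8, dendrite_length = 2.5,
                       fraction_acetylated = 0.5, fraction_tyrosinated = 0.5,
                       fraction_other = 0, radial_bias = 1,
                       psf_sigma_axial = 0.1, seed = seed)
    sim <- simulate_scene(spec)
    resl <- reslice_dendrite(sim$stack, margin_x = 20)
    ra <- analyze_radial(resl,
                         slice_indices = seq(5, n_slices(resl) - 5, by = 6))
    for (ch in names(profs)) {
      profs[[ch]] <- c(profs[[ch]], ra$profiles[[ch]])
      dend_id[[ch]] <- c(dend_id[[ch]],
                         rep(seed, length(ra$profiles[[ch]])))
    }
  }
  lapply(stats::setNames(names(profs), names(profs)), function(ch)
    average_profiles(profs[[ch]], dendrite = dend_id[[ch]]))
})

# Independent brute-force radial-density oracle: per-pixel continuous
# distance to the contour curve (no distance transform), ring binning by
# integer distance, same ring-coverage normalization as the definition.
radial_oracle <- function(img, contour, cx, cy, r_inside) {
  n <- nrow(img)
  xs <- rep(0:(ncol(img) - 1), each = n)
  ys <- rep(0:(n - 1), ncol(img))
  inside <- sqrt((xs - cx)^2 + (ys - cy)^2) < r_inside
  cv <- contour$curve
  dist_b <- rep(0, length(xs))
  for (i in which(inside)) {
    dist_b[i] <- min(sqrt((cv[, 1] - xs[i])^2 + (cv[, 2] - ys[i])^2))
  }
  kmax <- floor(max(dist_b))
  S <- IC <- numeric(0)
  for (k in 0:kmax) {
    m <- inside & dist_b > k
    if (!sum(m)) break
    S <- c(S, sum(m))
    IC <- c(IC, sum(img[cbind(ys[m] + 1, xs[m] + 1)]))
  }
  nk <- length(S)
  MI <- (IC[-nk] - IC[-1]) / (S[-nk] - S[-1])
  MI_core <- IC[nk] / S[nk]
  R <- sqrt(S / pi)
  R <- R / R[1]
  dR <- R[-nk] - R[-1]
  mass <- sum(pmax(MI, 0) * dR) + max(MI_core, 0) * R[nk]
  data.frame(R = c(R[-1], 0), rho = c(pmax(MI, 0), max(MI_core, 0)) / mass)
}
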