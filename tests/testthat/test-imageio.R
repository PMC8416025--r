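test_that("stacks round-trip through TIFF with metadata", {
  s <- scene_spec("dendrite", n_microtubules = 8, dendrite_diameter = 1,
                  dendrite_length = 1.5, seed = 2)
  sim <- simulate_scene(s)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, f)
  back <- read_stack(f)
  expect_identical(names(back$voxels), c("total", "tyr", "ac"))
  # photon counts are integers well below 2^24: float32 storage is exact
  expect_equal(back$voxels$total, sim$stack$voxels$total)
  expect_equal(back$voxel_size, sim$stack$voxel_size, tolerance = 1e-6)
  expect_equal(back$expansion_factor, sim$stack$expansion_factor)
})

test_that("channel naming config overrides and missing metadata errors", {
  a <- array(runif(4 * 5 * 2), c(4, 5, 2))
  st <- channel_stack(list(ch1 = a, ch2 = a * 2),
                      voxel_size = c(x = 0.1, y = 0.1, z = 0.3))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, f)
  named <- read_stack(f, channel_names = c("total", "tyr"))
  expect_identical(names(named$voxels), c("total", "tyr"))
  expect_error(read_stack(withr::local_tempfile(fileext = ".tif")),
               "not found")
  # corrupt file
  bad <- withr::local_tempfile(fileext = ".tif")
  writeBin(charToRaw("MMxx"), bad)
  expect_error(read_stack(bad), "byte order|not a TIFF|corrupt")
})

test_that("a TIFF without voxel size requires an explicit override", {
  # hand-build a single-page TIFF without resolution tags or description
  f <- withr::local_tempfile(fileext = ".tif")
  con <- file(f, "wb")
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little") # IFD right after header
  ntag <- 8L
  writeBin(ntag, con, size = 2, endian = "little")
  wtag <- function(id, type, count, val) {
    writeBin(id, con, size = 2, endian = "little")
    writeBin(type, con, size = 2, endian = "little")
    writeBin(count, con, size = 4, endian = "little")
    if (type == 3L) {
      writeBin(val, con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(val, con, size = 4, endian = "little")
  }
  data_off <- 8L + 2L + 12L * ntag + 4L
  wtag(256L, 4L, 1L, 4L); wtag(257L, 4L, 1L, 3L)
  wtag(258L, 3L, 1L, 8L); wtag(259L, 3L, 1L, 1L)
  wtag(262L, 3L, 1L, 1L); wtag(273L, 4L, 1L, data_off)
  wtag(278L, 4L, 1L, 3L); wtag(279L, 4L, 1L, 12L)
  writeBin(0L, con, size = 4, endian = "little") # next IFD = 0
  writeBin(as.raw(1:12), con)
  close(con)
  expect_error(read_stack(f), "voxel size")
  st <- read_stack(f, voxel_size = c(x = 0.1, y = 0.1, z = 0.2))
  expect_equal(dim(st$voxels[[1]]), c(3, 4, 1))
  expect_equal(st$voxels[[1]][1, , 1], c(1, 2, 3, 4))
})

test_that("ROIs round-trip through JSON and ImageJ formats", {
  roi <- polyline_roi(cbind(c(3.25, 10.5, 20), c(4, 8.75, 6)),
                      stroke_width = 3, name = "seg1")
  fj <- withr::local_tempfile(fileext = ".json")
  write_roi(roi, fj)
  back <- read_roi(fj)
  expect_equal(back$vertices, roi$vertices)
  expect_equal(back$stroke_width, 3)
  # binary ImageJ round trip (integer corner-grid: half-pixel conversion)
  fr <- withr::local_tempfile(fileext = ".roi")
  write_roi(roi, fr)
  back2 <- read_roi(fr)
  expect_lt(max(abs(back2$vertices - roi$vertices)), 0.51)
  expect_error(polyline_roi(cbind(1, 2)), ">= 2")
  expect_error(polyline_roi(cbind(c(1, NA), c(2, 3))), "finite")
})

test_that("register_channels recovers a known shift and is inverse-consistent", {
  st <- soma_scene()$stack
  small <- list(total = st$voxels$total[1:220, 1:220, , drop = FALSE],
                tyr = st$voxels$tyr[1:220, 1:220, , drop = FALSE])
  moved <- mtquant:::shift_array3d(small$total, -2, 3, 1)
  st2 <- channel_stack(list(total = small$total, tyr = moved),
                       voxel_size = st$voxel_size)
  reg <- register_channels(st2, "total")
  sh <- attr(reg, "shifts")$tyr
  expect_equal(unname(sh[1]), 2, tolerance = 0.5)
  expect_equal(unname(sh[2]), -3, tolerance = 0.5)
  expect_equal(unname(sh[3]), -1, tolerance = 0.5)
  # identical channels: zero shift
  st3 <- channel_stack(list(total = small$total, tyr = small$total),
                       voxel_size = st$voxel_size)
  sh3 <- attr(register_channels(st3, "total"), "shifts")$tyr
  expect_true(all(abs(sh3) <= 0.5))
  # inverse consistency A->B vs B->A
  stA <- channel_stack(list(total = small$total, tyr = moved),
                       voxel_size = st$voxel_size)
  stB <- channel_stack(list(total = moved, tyr = small$total),
                       voxel_size = st$voxel_size)
  shA <- attr(register_channels(stA, "total"), "shifts")$tyr
  shB <- attr(register_channels(stB, "total"), "shifts")$tyr
  expect_true(all(abs(shA + shB) <= 0.5))
  # all-zero channel warns and gets zero shift
  stz <- channel_stack(list(total = small$total,
                            tyr = array(0, dim(small$total))),
                       voxel_size = st$voxel_size)
  expect_warning(regz <- register_channels(stz, "total"), "all zero")
  expect_equal(unname(attr(regz, "shifts")$tyr), c(0, 0, 0))
})

test_that("straightening a straight path reproduces a crop", {
  s <- scene_spec("dendrite", n_microtubules = 12, dendrite_diameter = 1.2,
                  dendrite_length = 2.4, seed = 4)
  sim <- simulate_scene(s)
  a <- sim$stack$voxels$total
  d <- dim(a)
  yc <- 36 # integer row => exact pixel alignment
  resl <- straighten_and_reslice(sim$stack,
                                 polyline_roi(rbind(c(10, yc), c(50, yc))),
                                 half_width = 10, interpolate_z = FALSE)
  sl <- resl$slices$total[, , 5] # arc sample 5 => x = 14
  direct <- t(a[(yc - 10 + 1):(yc + 10 + 1), 15, ])
  expect_lt(max(abs(sl - direct)), 1e-6 * max(direct))
})

test_that("bent paths are straightened (center-of-mass track flattens)", {
  # render a quarter-circle tube directly
  dims <- c(120, 120, 5)
  th <- seq(0, pi / 2, length.out = 400)
  cx <- 10 + 90 * cos(th)
  cy <- 10 + 90 * sin(th)
  a <- mtquant:::splat_points(dims, cx, cy, rep(2, 400), rep(100, 400))
  a <- mtquant:::gauss_blur3d(a, c(1.5, 1.5, 0.5))
  st <- channel_stack(list(total = a), voxel_size = c(x = 0.03, y = 0.03,
                                                      z = 0.15))
  path <- polyline_roi(cbind(10 + 90 * cos(th[seq(1, 400, 40)]),
                             10 + 90 * sin(th[seq(1, 400, 40)])))
  resl <- straighten_and_reslice(st, path, half_width = 8,
                                 interpolate_z = FALSE)
  # center of mass across the perpendicular coordinate per slice
  com <- vapply(seq_len(n_slices(resl)), function(i) {
    sl <- get_slice(resl, "total", i)
    prof <- colSums(sl)
    sum(prof * seq_along(prof)) / sum(prof)
  }, numeric(1))
  # before straightening, the y center of mass tracks the bend
  com_before <- vapply(seq(10, 95, by = 5), function(x) {
    col <- rowSums(a[, round(x) + 1, ])
    sum(col * seq_along(col)) / sum(col)
  }, numeric(1))
  expect_lt(var(com), var(com_before) / 10)
})

test_that("reslicing a solid cylinder yields disks of the known diameter", {
  # solid cylinder along x, radius 15 px, isotropic voxels
  ny <- 61; nx <- 40; nz <- 61
  ys <- rep(0:(ny - 1), nz)
  zs <- rep(0:(nz - 1), each = ny)
  disk <- matrix(as.numeric((ys - 30)^2 + (zs - 30)^2 <= 15^2) * 100,
                 ny, nz)
  a <- array(0, c(ny, nx, nz))
  for (z in 1:nz) a[, , z] <- matrix(disk[, z], ny, nx)
  st <- channel_stack(list(total = a),
                      voxel_size = c(x = 0.05, y = 0.05, z = 0.05))
  resl <- straighten_and_reslice(st, polyline_roi(rbind(c(5, 30), c(34, 30))),
                                 half_width = 25, interpolate_z = FALSE)
  sl <- get_slice(resl, "total", n_slices(resl) %/% 2)
  thr <- 0.5 * max(sl)
  dia_y <- diff(range(which(apply(sl > thr, 2, any)))) + 1
  dia_z <- diff(range(which(apply(sl > thr, 1, any)))) + 1
  expect_lt(abs(dia_y - 31), 1.5)
  expect_lt(abs(dia_z - 31), 1.5)
})

test_that("straightening conserves integrated intensity within the tube", {
  s <- scene_spec("dendrite", n_microtubules = 40, dendrite_diameter = 1.2,
                  dendrite_length = 2.4, psf_sigma_axial = 0.1,
                  noise_model = "none", background_level = 0, seed = 8)
  sim <- simulate_scene(s)
  a <- sim$stack$voxels$total
  d <- dim(a)
  yc <- round((d[1] - 1) / 2)
  hw <- floor(min(yc, d[1] - 1 - yc) - 1)
  x0 <- 20; x1 <- d[2] - 21
  resl <- straighten_and_reslice(sim$stack,
                                 polyline_roi(rbind(c(x0, yc), c(x1, yc))),
                                 half_width = hw, interpolate_z = FALSE)
  got <- sum(resl$slices$total)
  want <- sum(a[(yc - hw + 1):(yc + hw + 1), (x0 + 1):(x1 + 1), ])
  expect_lt(abs(got - want) / want, 0.02)
})
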