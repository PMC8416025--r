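# Low-level numerics shared by every stage: separable Gaussian convolution,
# Euclidean distance transforms, connected components, interpolation and
# small geometry helpers. Images are matrices indexed [y, x] (row = y,
# image convention, y increases downward); stacks are arrays [y, x, z].
# Pixel coordinates are 0-based with pixel centers at integer coordinates.

#' @keywords internal
gauss_kernel1d <- function(sigma_px, truncate = 4) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma_px)))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Convolve a 3D array along one axis (1=y, 2=x, 3=z) with a 1D kernel,
# zero padding (emission leaving the field of view is lost, as in a camera).
#' @keywords internal
convolve_axis3d <- function(a, k, axis) {
  nk <- length(k)
  if (nk == 1L) return(a * k)
  r <- (nk - 1L) %/% 2L
  d <- dim(a)
  # move the convolution axis last so shifts are contiguous column blocks
  perm <- switch(axis, c(2L, 3L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))
  if (axis != 3L) a <- aperm(a, perm)
  da <- dim(a)
  n <- da[3]
  m <- matrix(a, prod(da[1:2]), n)
  out <- matrix(0, nrow(m), n)
  for (i in seq_len(nk)) {
    s <- i - r - 1L
    j1 <- max(1L, 1L - s)
    j2 <- min(n, n - s)
    if (j1 > j2) next
    out[, j1:j2] <- out[, j1:j2] + k[i] * m[, (j1 + s):(j2 + s)]
  }
  out <- array(out, da)
  if (axis != 3L) out <- aperm(out, order(perm))
  out
}

# Separable anisotropic Gaussian blur of a [y, x, z] array; sigmas in pixels
# as c(y, x, z). Kernels are normalized, so total intensity is conserved
# away from the borders.
#' @keywords internal
gauss_blur3d <- function(a, sigma_yxz, truncate = 4) {
  for (ax in 1:3) {
    if (sigma_yxz[ax] > 0) {
      a <- convolve_axis3d(a, gauss_kernel1d(sigma_yxz[ax], truncate), ax)
    }
  }
  a
}

#' @keywords internal
gauss_blur2d <- function(m, sigma_yx, truncate = 4) {
  if (length(sigma_yx) == 1L) sigma_yx <- c(sigma_yx, sigma_yx)
  a <- array(m, c(dim(m), 1L))
  a <- gauss_blur3d(a, c(sigma_yx, 0), truncate)
  a[, , 1L]
}

# --- Euclidean distance transform (exact, Felzenszwalb & Huttenlocher) -----

#' @keywords internal
.dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance transform of a logical mask
#'
#' Distance (in pixels) from every TRUE pixel to the nearest FALSE pixel;
#' the image border counts as outside.
#' @keywords internal
edt <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  big <- (nr + nc + 2)^2
  # pad with one FALSE ring so the border is "outside"
  f <- matrix(0, nr + 2L, nc + 2L)
  f[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(mask, big, 0)
  g <- apply(f, 2, .dt1d)
  d2 <- t(apply(g, 1, function(row) .dt1d(pmin(row, big))))
  sqrt(d2[2:(nr + 1L), 2:(nc + 1L), drop = FALSE])
}

# --- Connected components ---------------------------------------------------

#' Label 8-connected components of a logical mask
#'
#' Returns an integer matrix; 0 = background, components numbered from 1.
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  from <- integer(0)
  to <- integer(0)
  for (o in offs) {
    r1 <- max(1L, 1L - o[1]):min(nr, nr - o[1])
    c1 <- max(1L, 1L - o[2]):min(nc, nc - o[2])
    m1 <- mask[r1, c1, drop = FALSE] & mask[r1 + o[1], c1 + o[2], drop = FALSE]
    w <- which(m1)
    if (!length(w)) next
    rr <- ((w - 1L) %% length(r1)) + 1L
    cc <- ((w - 1L) %/% length(r1)) + 1L
    from <- c(from, id[cbind(r1[rr], c1[cc])])
    to <- c(to, id[cbind(r1[rr] + o[1], c1[cc] + o[2])])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# --- Interpolation ----------------------------------------------------------

#' Bilinear interpolation on a matrix at 0-based (x, y) positions
#'
#' Out-of-bounds positions return `fill`.
#' @keywords internal
bilinear <- function(img, x, y, fill = 0) {
  nr <- nrow(img)
  nc <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  # clamp sampling corners; mark fully outside
  out <- x < -0.5 | x > nc - 0.5 | y < -0.5 | y > nr - 0.5
  cx0 <- pmin(pmax(x0, 0), nc - 1)
  cx1 <- pmin(pmax(x0 + 1, 0), nc - 1)
  cy0 <- pmin(pmax(y0, 0), nr - 1)
  cy1 <- pmin(pmax(y0 + 1, 0), nr - 1)
  v00 <- img[cbind(cy0 + 1, cx0 + 1)]
  v01 <- img[cbind(cy0 + 1, cx1 + 1)]
  v10 <- img[cbind(cy1 + 1, cx0 + 1)]
  v11 <- img[cbind(cy1 + 1, cx1 + 1)]
  v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  v[out] <- fill
  v
}

# --- Geometry ---------------------------------------------------------------

#' Shoelace polygon area (vertices as two-column matrix, need not be closed)
#' @keywords internal
polygon_area <- function(xy) {
  x <- xy[, 1]
  y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Ray-casting point-in-polygon test, vectorized over points
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    hit <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

#' Minimum distance from points to a polyline (vertices vx, vy)
#' @keywords internal
dist_to_polyline <- function(px, py, vx, vy) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(length(vx) - 1L)) {
    ax <- vx[i]; ay <- vy[i]
    bx <- vx[i + 1L]; by <- vy[i + 1L]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx * abx + aby * aby
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * abx + (py - ay) * aby) / len2))
    dx <- px - (ax + t * abx)
    dy <- py - (ay + t * aby)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Closed periodic cubic spline through ordered anchor points
#'
#' Returns an n_out x 2 matrix tracing the closed curve.
#' @keywords internal
periodic_spline <- function(xy, n_out = 200L) {
  x <- c(xy[, 1], xy[1, 1])
  y <- c(xy[, 2], xy[1, 2])
  t <- seq(0, 1, length.out = length(x))
  tt <- seq(0, 1, length.out = n_out + 1L)[-(n_out + 1L)]
  sx <- stats::spline(t, x, method = "periodic", xout = tt)$y
  sy <- stats::spline(t, y, method = "periodic", xout = tt)$y
  cbind(x = sx, y = sy)
}

#' Local maxima of an image above a threshold
#'
#' A pixel is a maximum if it is >= all pixels within a square window of
#' radius `radius` and strictly above `threshold`.
#' @keywords internal
local_maxima <- function(img, radius = 2L, threshold = -Inf) {
  nr <- nrow(img)
  nc <- ncol(img)
  mx <- img
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr == 0L && dc == 0L) next
      sh <- matrix(-Inf, nr, nc)
      r1 <- max(1L, 1L - dr):min(nr, nr - dr)
      c1 <- max(1L, 1L - dc):min(nc, nc - dc)
      sh[r1, c1] <- img[r1 + dr, c1 + dc]
      mx <- pmax(mx, sh)
    }
  }
  which(img >= mx & img > threshold, arr.ind = TRUE)
}

# Trilinear deposition ("splatting") of weighted points into a [y, x, z]
# array; points given in 0-based voxel coordinates (x, y, z).
#' @keywords internal
splat_points <- function(dim_yxz, x, y, z, w) {
  out <- numeric(prod(dim_yxz))
  ny <- dim_yxz[1]; nx <- dim_yxz[2]; nz <- dim_yxz[3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  for (cz in 0:1) for (cx in 0:1) for (cy in 0:1) {
    xi <- x0 + cx; yi <- y0 + cy; zi <- z0 + cz
    wt <- w * (if (cx) fx else 1 - fx) *
      (if (cy) fy else 1 - fy) * (if (cz) fz else 1 - fz)
    ok <- xi >= 0 & xi < nx & yi >= 0 & yi < ny & zi >= 0 & zi < nz & wt > 0
    if (!any(ok)) next
    lin <- (yi[ok] + 1) + yi[ok] * 0 + ny * xi[ok] + ny * nx * zi[ok]
    acc <- rowsum(wt[ok], lin)
    out[as.numeric(rownames(acc))] <- out[as.numeric(rownames(acc))] + acc[, 1]
  }
  array(out, dim_yxz)
}
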