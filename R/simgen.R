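# Synthetic microscopy generator: ground-truth-labelled scenes emulating the
# statistical structure the downstream analysis assumes — a sparse
# sub-nuclear soma sheet of filaments (with two-filament bundles), dendrite
# volumes with stable/acetylated microtubules biased to the core and
# dynamic/tyrosinated ones to the periphery, channel crosstalk (alpha, beta),
# anisotropic PSF blur in regular or flipped orientation, and photon noise.

#' Specify a synthetic microscopy scene
#'
#' All geometry parameters are in biological micrometres; the scene is scaled
#' by `expansion_factor` before rendering, mimicking physically expanded
#' samples. Emission is in photons: each microtubule emits
#' `emission_per_um` photons per biological micrometre in channels where its
#' subtype level is 1.
#'
#' Channel model: stable (acetylated) filaments emit 1 in the ac channel and
#' `true_alpha` in the tyr channel; dynamic (tyrosinated) filaments emit 1 in
#' tyr and `true_beta` in ac; "other" filaments emit only in the total
#' channel. Every filament emits 1 in total. Per-filament, per-channel
#' staining variability is multiplicative with coefficient of variation
#' `intensity_cv`.
#'
#' @param scene_kind `"soma_sheet"` (thin sub-nuclear sheet of straight
#'   filaments, a fraction of which are unresolvable two-filament bundles),
#'   `"dendrite"` (cylinder along x filled with axial microtubules placed
#'   with a core/shell radial bias) or `"flipexm_dendrite"` (dendrite with a
#'   minimum cross-section separation between microtubules so individual
#'   cross-sections are resolvable; default orientation `"flipped"`).
#' @param dendrite_diameter,dendrite_length cylinder geometry, um.
#' @param n_microtubules number of microtubules (0 allowed: background-only).
#' @param fraction_acetylated,fraction_tyrosinated,fraction_other subtype
#'   fractions, must sum to 1.
#' @param radial_bias in `[0, 1]`: 0 places all subtypes uniformly over the
#'   cross-section; 1 fully segregates stable microtubules into the core and
#'   dynamic ones into the shell.
#' @param bundle_fraction probability that a soma-sheet filament is a
#'   two-filament bundle (soma_sheet only).
#' @param true_alpha,true_beta ground-truth mean crosstalk levels.
#' @param crosstalk_sdlog log-SD of the per-filament lognormal crosstalk
#'   level heterogeneity (mean preserved); per-microtubule modification
#'   levels are right-skewed and long-tailed in real data.
#' @param intensity_cv coefficient of variation of per-filament staining.
#' @param emission_per_um photons emitted per biological um at level 1.
#' @param psf_sigma_lateral,psf_sigma_axial Gaussian PSF sigmas, physical um.
#' @param orientation `"regular"` (PSF long axis along z) or `"flipped"`
#'   (PSF long axis along the dendrite axis, x — the FlipExM geometry).
#' @param background_level mean background, photons per voxel.
#' @param noise_model `"none"`, `"poisson"`, `"gaussian"` or
#'   `"poisson+gaussian"`.
#' @param read_noise_sd SD of additive Gaussian read noise (photons).
#' @param voxel_size physical voxel size, um, named `c(x=, y=, z=)`.
#' @param expansion_factor physical expansion factor (>= 1).
#' @param field_size soma-sheet XY extent, um (default chosen from
#'   `n_microtubules` to keep the sheet sparse).
#' @param circumferential if TRUE (flipexm_dendrite only), microtubules are
#'   placed equally spaced on the dendrite circumference — the arrangement
#'   used to contrast regular and flipped PSF orientations.
#' @param seed integer seed; all stochastic draws derive from it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(scene_kind = c("dendrite", "soma_sheet", "flipexm_dendrite"),
                       dendrite_diameter = 2,
                       dendrite_length = 4,
                       n_microtubules = 100,
                       fraction_acetylated = 0.72,
                       fraction_tyrosinated = 0.26,
                       fraction_other = 0.02,
                       radial_bias = 0.8,
                       bundle_fraction = 0,
                       true_alpha = 0.53,
                       true_beta = 0.45,
                       crosstalk_sdlog = 0.35,
                       intensity_cv = 0.15,
                       emission_per_um = 20000,
                       psf_sigma_lateral = 0.03,
                       psf_sigma_axial = 0.25,
                       orientation = NULL,
                       background_level = 5,
                       noise_model = c("poisson", "none", "gaussian", "poisson+gaussian"),
                       read_noise_sd = 2,
                       voxel_size = c(x = 0.03, y = 0.03, z = 0.15),
                       expansion_factor = 1,
                       field_size = NULL,
                       circumferential = FALSE,
                       seed = 1L) {
  scene_kind <- match.arg(scene_kind)
  noise_model <- match.arg(noise_model)
  if (is.null(orientation)) {
    orientation <- if (scene_kind == "flipexm_dendrite") "flipped" else "regular"
  }
  orientation <- match.arg(orientation, c("regular", "flipped"))
  if (is.null(field_size)) field_size <- max(8, sqrt(max(n_microtubules, 25) * 2.2))
  spec <- list(scene_kind = scene_kind,
               dendrite_diameter = dendrite_diameter,
               dendrite_length = dendrite_length,
               n_microtubules = as.integer(n_microtubules),
               fraction_acetylated = fraction_acetylated,
               fraction_tyrosinated = fraction_tyrosinated,
               fraction_other = fraction_other,
               radial_bias = radial_bias,
               bundle_fraction = bundle_fraction,
               true_alpha = true_alpha, true_beta = true_beta,
               crosstalk_sdlog = crosstalk_sdlog,
               intensity_cv = intensity_cv,
               emission_per_um = emission_per_um,
               psf_sigma_lateral = psf_sigma_lateral,
               psf_sigma_axial = psf_sigma_axial,
               orientation = orientation,
               background_level = background_level,
               noise_model = noise_model,
               read_noise_sd = read_noise_sd,
               voxel_size = .check_voxel_size(voxel_size),
               expansion_factor = expansion_factor,
               field_size = field_size,
               circumferential = isTRUE(circumferential),
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

#' Validate a scene specification
#' @param spec a `scene_spec`
#' @return the scene specification, invisibly; errors on violated invariants.
#' @export
validate_scene_spec <- function(spec) {
  num <- c("dendrite_diameter", "dendrite_length", "n_microtubules",
           "fraction_acetylated", "fraction_tyrosinated", "fraction_other",
           "radial_bias", "bundle_fraction", "true_alpha", "true_beta",
           "crosstalk_sdlog", "intensity_cv", "emission_per_um",
           "psf_sigma_lateral",
           "psf_sigma_axial", "background_level", "read_noise_sd",
           "expansion_factor", "field_size")
  for (f in num) {
    v <- spec[[f]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop("scene_spec field '", f, "' must be finite and non-negative")
  }
  fr <- spec$fraction_acetylated + spec$fraction_tyrosinated + spec$fraction_other
  if (abs(fr - 1) > 1e-9) stop("subtype fractions must sum to 1")
  for (f in c("fraction_acetylated", "fraction_tyrosinated", "fraction_other",
              "radial_bias", "bundle_fraction")) {
    if (spec[[f]] > 1) stop("scene_spec field '", f, "' must be in [0, 1]")
  }
  if (spec$psf_sigma_axial < spec$psf_sigma_lateral)
    stop("psf_sigma_axial must be >= psf_sigma_lateral")
  if (spec$expansion_factor < 1) stop("expansion_factor must be >= 1")
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: %s, %d microtubules, orientation %s, seed %d\n",
              x$scene_kind, x$n_microtubules, x$orientation, x$seed))
  invisible(x)
}

# run code with a local RNG state derived from `seed`
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic largest-remainder allocation of n items to subtype labels
#' @keywords internal
.allocate_subtypes <- function(n, fr_ac, fr_tyr, fr_other) {
  if (n == 0L) return(character(0))
  target <- c(ac = fr_ac, tyr = fr_tyr, other = fr_other) * n
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(base), times = base))
}

# Core/shell subtype assignment. Total microtubule packing across the
# cross-section is kept uniform (as in electron-microscopy cross-sections);
# radial_bias b controls how strongly the subtype identity follows the
# radius: each filament gets a score b * radial rank + (1 - b) * U(0,1),
# the lowest-scoring are labelled stable/ac (core), the highest dynamic/tyr
# (shell), the rest "other". b = 0 is random assignment, b = 1 perfect
# segregation; the mean radius of dynamic filaments increases, and of
# stable filaments decreases, monotonically with b.
#' @keywords internal
.assign_subtypes_radial <- function(r, n_ac, n_tyr, n_other, b) {
  n <- length(r)
  score <- b * (rank(r, ties.method = "random") / n) + (1 - b) * stats::runif(n)
  ord <- order(score)
  subtype <- character(n)
  subtype[ord[seq_len(n_ac)]] <- "ac"
  if (n_tyr > 0) subtype[ord[n - n_tyr + seq_len(n_tyr)]] <- "tyr"
  subtype[subtype == ""] <- "other"
  subtype
}

# proportionally shrink subtype counts to a smaller total
#' @keywords internal
.shrink_counts <- function(cnt, n) {
  if (sum(cnt) <= n) return(cnt)
  target <- cnt * n / sum(cnt)
  out <- floor(target)
  rem <- n - sum(out)
  if (rem > 0) {
    extra <- order(target - out, decreasing = TRUE)[seq_len(rem)]
    out[extra] <- out[extra] + 1
  }
  as.integer(out)
}

# Per-filament channel emission levels. Crosstalk levels are heterogeneous
# across filaments with a right-skewed, long-tailed distribution (lognormal
# with mean true_alpha / true_beta and log-SD crosstalk_sdlog), as observed
# for per-microtubule modification levels; the signal level in a subtype's
# own channel is 1.
#' @keywords internal
.subtype_levels <- function(subtype, alpha, beta, crosstalk_sdlog = 0.35) {
  n <- length(subtype)
  lv <- matrix(0, n, 3, dimnames = list(NULL, c("total", "tyr", "ac")))
  lv[, "total"] <- 1
  mean1 <- stats::rlnorm(n, -crosstalk_sdlog^2 / 2, crosstalk_sdlog)
  mean2 <- stats::rlnorm(n, -crosstalk_sdlog^2 / 2, crosstalk_sdlog)
  lv[subtype == "ac", "tyr"] <- alpha * mean1[subtype == "ac"]
  lv[subtype == "ac", "ac"] <- 1
  lv[subtype == "tyr", "tyr"] <- 1
  lv[subtype == "tyr", "ac"] <- beta * mean2[subtype == "tyr"]
  lv
}

#' Simulate a synthetic microscopy scene
#'
#' Renders the scene described by `spec` into a three-channel stack
#' (total, tyr, ac) and returns it together with the pre-noise ground truth.
#' Filament centerlines are sampled at arc steps of a quarter voxel and
#' deposited with trilinear sub-voxel precision; the deposit is smoothed by
#' an isotropic Gaussian of SD 0.3 x lateral PSF and convolved with the
#' anisotropic Gaussian PSF (long axis along z for `orientation = "regular"`,
#' along the dendrite axis x for `"flipped"`), both folded into a single
#' separable convolution. Background and noise are added last.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `stack` (a [channel_stack()]) and `truth`
#'   (class `ground_truth`: per-filament table, centerlines in biological um,
#'   aggregate counts, and for dendrite scenes the true density).
#' @export
simulate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    E <- spec$expansion_factor
    vs <- spec$voxel_size
    geom <- switch(spec$scene_kind,
                   soma_sheet = .geom_soma_sheet(spec),
                   dendrite = .geom_dendrite(spec),
                   flipexm_dendrite = .geom_dendrite(spec))
    # stack dimensions from physical extents
    ext <- geom$extent_phys # c(x, y, z) um
    dims <- c(y = max(4L, as.integer(ceiling(ext[2] / vs["y"]))),
              x = max(4L, as.integer(ceiling(ext[1] / vs["x"]))),
              z = max(3L, as.integer(ceiling(ext[3] / vs["z"]))))
    n_fil <- length(geom$centerlines)
    lv <- .subtype_levels(geom$subtype, spec$true_alpha, spec$true_beta,
                          spec$crosstalk_sdlog)
    # per-filament, per-channel staining variability
    if (n_fil > 0) {
      fac <- matrix(pmax(0.05, 1 + spec$intensity_cv *
                           stats::rnorm(3 * n_fil)), n_fil, 3)
      lv <- lv * fac
    }
    chans <- c("total", "tyr", "ac")
    raw <- lapply(chans, function(ch) array(0, unname(dims)))
    names(raw) <- chans
    step_phys <- min(vs) / 4
    lengths_um <- numeric(n_fil)
    emitted <- matrix(0, n_fil, 3, dimnames = list(NULL, chans))
    pts <- vector("list", n_fil) # sampled centerlines in voxel coordinates
    for (i in seq_len(n_fil)) {
      cl <- geom$centerlines[[i]] # biological um, columns x,y,z
      clp <- cl * E               # physical um
      seglen <- sqrt(rowSums(diff(clp)^2))
      arc <- c(0, cumsum(seglen))
      L <- arc[length(arc)]
      lengths_um[i] <- L / E
      n_s <- max(2L, as.integer(ceiling(L / step_phys)) + 1L)
      s <- seq(0, L, length.out = n_s)
      pts[[i]] <- cbind(
        x = stats::approx(arc, clp[, 1], xout = s)$y / vs["x"] + geom$origin_px[1],
        y = stats::approx(arc, clp[, 2], xout = s)$y / vs["y"] + geom$origin_px[2],
        z = stats::approx(arc, clp[, 3], xout = s)$y / vs["z"] + geom$origin_px[3],
        w0 = rep(spec$emission_per_um * (L / E) / n_s, n_s))
    }
    if (n_fil > 0) {
      allpts <- do.call(rbind, pts)
      fil_of <- rep(seq_len(n_fil), vapply(pts, nrow, integer(1)))
      for (ci in 1:3) {
        w <- allpts[, "w0"] * lv[fil_of, ci]
        keep <- w > 0
        if (any(keep)) {
          raw[[ci]] <- raw[[ci]] + splat_points(unname(dims),
                                                allpts[keep, "x"],
                                                allpts[keep, "y"],
                                                allpts[keep, "z"], w[keep])
        }
        emitted[, ci] <- rowsum(w, fil_of)[, 1]
      }
    }
    # blur: deposit smoothing + PSF, combined
    dep <- 0.3 * spec$psf_sigma_lateral
    sig_phys <- if (spec$orientation == "regular") {
      c(x = spec$psf_sigma_lateral, y = spec$psf_sigma_lateral,
        z = spec$psf_sigma_axial)
    } else {
      c(x = spec$psf_sigma_axial, y = spec$psf_sigma_lateral,
        z = spec$psf_sigma_lateral)
    }
    sig_tot <- sqrt(sig_phys^2 + dep^2)
    sig_px <- c(sig_tot["y"] / vs["y"], sig_tot["x"] / vs["x"],
                sig_tot["z"] / vs["z"])
    for (ci in 1:3) raw[[ci]] <- gauss_blur3d(raw[[ci]], sig_px)
    truth <- structure(list(
      filaments = if (n_fil > 0) data.frame(
        id = seq_len(n_fil), subtype = geom$subtype,
        bundle_id = geom$bundle_id, r_um = geom$r_um,
        length_um = lengths_um,
        em_total = emitted[, "total"], em_tyr = emitted[, "tyr"],
        em_ac = emitted[, "ac"]) else
          data.frame(id = integer(0), subtype = character(0),
                     bundle_id = integer(0), r_um = numeric(0),
                     length_um = numeric(0), em_total = numeric(0),
                     em_tyr = numeric(0), em_ac = numeric(0)),
      centerlines = geom$centerlines,
      n_tot = n_fil,
      n_tyr = sum(geom$subtype == "tyr"),
      n_ac = sum(geom$subtype == "ac"),
      n_other = sum(geom$subtype == "other"),
      cross_section_area_um2 = geom$area_um2,
      density_per_um2 = if (!is.na(geom$area_um2) && geom$area_um2 > 0)
        n_fil / geom$area_um2 else NA_real_,
      noiseless = raw,
      spec = spec), class = "ground_truth")
    # background + noise
    for (ci in 1:3) {
      sig <- raw[[ci]] + spec$background_level
      sig <- switch(spec$noise_model,
                    none = sig,
                    poisson = array(stats::rpois(length(sig), pmax(sig, 0)),
                                    dim(sig)),
                    gaussian = sig + stats::rnorm(length(sig),
                                                  sd = spec$read_noise_sd),
                    `poisson+gaussian` =
                      array(stats::rpois(length(sig), pmax(sig, 0)), dim(sig)) +
                      stats::rnorm(length(sig), sd = spec$read_noise_sd))
      raw[[ci]] <- pmax(sig, 0)
    }
    stack <- channel_stack(raw, voxel_size = vs, expansion_factor = E)
    list(stack = stack, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: n_tot=%d (tyr %d, ac %d, other %d)\n",
              x$n_tot, x$n_tyr, x$n_ac, x$n_other))
  if (!is.na(x$cross_section_area_um2))
    cat(sprintf("  cross-section area %.3g um^2, density %.3g MT/um^2\n",
                x$cross_section_area_um2, x$density_per_um2))
  invisible(x)
}

# ---- scene geometries ------------------------------------------------------

# Soma sheet: straight filaments in a thin z sheet; sequential placement with
# a minimum midline separation keeps the sheet sparse (as under the nucleus,
# where the density of the network is low). A bundle is rendered as two
# parallel filaments offset by 40 nm (unresolvable), sharing one subtype.
#' @keywords internal
.geom_soma_sheet <- function(spec, min_sep = 0.25, bundle_offset = 0.04) {
  E <- spec$expansion_factor
  vs <- spec$voxel_size
  fs <- spec$field_size
  margin <- max(0.5, 8 * spec$psf_sigma_lateral) / E
  sheet_z <- 0.1 # sheet half-thickness placement jitter, um
  margin_z <- 4.5 * spec$psf_sigma_axial / E # keep blur inside the stack
  n <- spec$n_microtubules
  subtype0 <- .allocate_subtypes(n, spec$fraction_acetylated,
                                 spec$fraction_tyrosinated, spec$fraction_other)
  is_bundle <- stats::runif(n) < spec$bundle_fraction
  placed <- list() # each: rbind(c(x0,y0), c(x1,y1))
  mids <- matrix(numeric(0), 0, 2)
  half <- numeric(0)
  centerlines <- list()
  subtype <- character(0)
  bundle_id <- integer(0)
  r_um <- numeric(0)
  zc <- margin_z + sheet_z # sheet center depth
  for (i in seq_len(n)) {
    len <- stats::runif(1, 1.5, 3)
    ok <- FALSE
    for (att in seq_len(80)) {
      ang <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, margin + len / 2, fs - margin - len / 2)
      cy <- stats::runif(1, margin + len / 2, fs - margin - len / 2)
      p0 <- c(cx, cy) - len / 2 * c(cos(ang), sin(ang))
      p1 <- c(cx, cy) + len / 2 * c(cos(ang), sin(ang))
      sep <- Inf
      if (length(placed)) {
        # cheap midpoint prefilter before exact segment distances
        dm <- sqrt((mids[, 1] - cx)^2 + (mids[, 2] - cy)^2)
        near <- which(dm < half + len / 2 + min_sep)
        if (length(near)) {
          smp <- seq(0, 1, length.out = 12)
          qx <- p0[1] + smp * (p1[1] - p0[1])
          qy <- p0[2] + smp * (p1[2] - p0[2])
          sep <- min(vapply(placed[near], function(s)
            min(dist_to_polyline(qx, qy, s[, 1], s[, 2])), numeric(1)))
        }
      }
      if (sep >= min_sep) { ok <- TRUE; break }
    }
    if (!ok) next # field saturated; place fewer filaments rather than overlap
    placed[[length(placed) + 1L]] <- rbind(p0, p1)
    mids <- rbind(mids, c(cx, cy))
    half <- c(half, len / 2)
    z <- zc + stats::runif(1, -sheet_z, sheet_z)
    n_copies <- if (is_bundle[i]) 2L else 1L
    bid <- i
    for (cpy in seq_len(n_copies)) {
      off <- if (cpy == 2L) {
        perp <- c(-(p1[2] - p0[2]), p1[1] - p0[1])
        perp / sqrt(sum(perp^2)) * bundle_offset
      } else c(0, 0)
      centerlines[[length(centerlines) + 1L]] <-
        cbind(x = c(p0[1], p1[1]) + off[1],
              y = c(p0[2], p1[2]) + off[2],
              z = c(z, z))
      subtype <- c(subtype, subtype0[i])
      bundle_id <- c(bundle_id, bid)
      r_um <- c(r_um, NA_real_)
    }
  }
  nz_phys <- 2 * zc * E
  list(centerlines = centerlines, subtype = subtype, bundle_id = bundle_id,
       r_um = r_um, area_um2 = NA_real_,
       extent_phys = c(fs * E, fs * E, nz_phys),
       origin_px = c(0, 0, 0))
}

# Dendrite: axial microtubules in a cylinder along x. Radial placement is
# biased (stable -> core, dynamic -> shell) by radial_bias; the
# flipexm_dendrite variant additionally enforces a minimum cross-section
# separation (0.12 um) so individual cross-sections are resolvable, and
# supports the circumferential arrangement of the PSF-orientation benchmark.
#' @keywords internal
.geom_dendrite <- function(spec, min_sep = 0.12) {
  E <- spec$expansion_factor
  R <- spec$dendrite_diameter / 2
  len <- spec$dendrite_length
  n <- spec$n_microtubules
  margin <- max(0.5, 8 * spec$psf_sigma_lateral) / E
  sig_z <- if (spec$orientation == "regular") spec$psf_sigma_axial else
    spec$psf_sigma_lateral
  margin_z <- max(0.5, 5 * sig_z) / E
  counts <- table(factor(.allocate_subtypes(
    n, spec$fraction_acetylated, spec$fraction_tyrosinated,
    spec$fraction_other), levels = c("ac", "tyr", "other")))
  if (spec$circumferential) {
    ang <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
    r <- rep(R, n)
  } else if (spec$scene_kind == "flipexm_dendrite") {
    # uniform placement with a minimum cross-section separation
    r <- numeric(0); ang <- numeric(0)
    yy <- numeric(0); zz <- numeric(0)
    for (i in seq_len(n)) {
      for (att in seq_len(200)) {
        ri <- R * 0.95 * sqrt(stats::runif(1))
        ai <- stats::runif(1, 0, 2 * pi)
        y <- ri * cos(ai); z <- ri * sin(ai)
        if (!length(yy) || min(sqrt((yy - y)^2 + (zz - z)^2)) >= min_sep) {
          r <- c(r, ri); ang <- c(ang, ai)
          yy <- c(yy, y); zz <- c(zz, z)
          break
        }
      }
    }
    n <- length(r)
  } else {
    r <- R * 0.97 * sqrt(stats::runif(n))
    ang <- stats::runif(n, 0, 2 * pi)
  }
  # subtype counts may shrink if placement saturated
  cnt <- .shrink_counts(as.integer(counts), n)
  subtype <- if (spec$circumferential)
    .assign_subtypes_radial(r + stats::runif(n, 0, 1e-6), cnt[1], cnt[2],
                            cnt[3], 0)
  else
    .assign_subtypes_radial(r, cnt[1], cnt[2], cnt[3], spec$radial_bias)
  cy <- r * cos(ang)
  cz <- r * sin(ang)
  centerlines <- vector("list", n)
  for (i in seq_len(n)) {
    centerlines[[i]] <- cbind(x = c(0, len),
                              y = c(cy[i], cy[i]) + R + margin,
                              z = c(cz[i], cz[i]) + R + margin_z)
  }
  ext <- c(len * E, (2 * R + 2 * margin) * E, (2 * R + 2 * margin_z) * E)
  list(centerlines = centerlines, subtype = subtype,
       bundle_id = seq_len(n), r_um = r,
       area_um2 = pi * R^2,
       extent_phys = ext, origin_px = c(0, 0, 0))
}

#' Simulate single-filament segment intensities
#'
#' Histogram-level fixture for the two-Gaussian single-intensity model:
#' singles are drawn from N(`mean_single`, (`cv` * `mean_single`)^2) and a
#' fraction `doublet_fraction` of the values are independent sums of two
#' singles (two-filament bundles).
#'
#' @param n number of values (>= 1).
#' @param mean_single mean single-filament intensity.
#' @param cv coefficient of variation of the single population (> 0).
#' @param doublet_fraction fraction of doublets, in `[0, 1]`.
#' @param seed integer seed.
#' @return numeric vector of length `n`, randomly ordered, with attribute
#'   `"is_doublet"` (logical ground-truth labels).
#' @export
simulate_segment_intensities <- function(n, mean_single = 100, cv = 0.15,
                                         doublet_fraction = 0, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(cv) || cv <= 0) stop("cv must be > 0")
  if (doublet_fraction < 0 || doublet_fraction > 1)
    stop("doublet_fraction must be in [0, 1]")
  with_seed(seed, {
    n_d <- stats::rbinom(1, n, doublet_fraction)
    n_s <- n - n_d
    sd1 <- cv * mean_single
    singles <- stats::rnorm(n_s, mean_single, sd1)
    doublets <- stats::rnorm(n_d, mean_single, sd1) +
      stats::rnorm(n_d, mean_single, sd1)
    v <- c(singles, doublets)
    lab <- c(rep(FALSE, n_s), rep(TRUE, n_d))
    ord <- sample.int(n)
    structure(v[ord], is_doublet = lab[ord])
  })
}

#' Simulate a FlipExM-style cross-section slice with labelled spots
#'
#' Direct slice-level fixture for the spot filters: round single-microtubule
#' cross-sections and elongated doublets (two merged cross-sections offset by
#' `doublet_offset`, physical um) rendered on a background with Poisson
#' noise.
#'
#' @param n_singles,n_doublets spot counts.
#' @param size_px slice side length, pixels.
#' @param pixel_size physical um per pixel.
#' @param psf_sigma lateral PSF sigma, physical um.
#' @param amplitude mean integrated intensity of a single cross-section.
#' @param cv coefficient of variation of spot intensities.
#' @param doublet_offset separation of the two cross-sections of a doublet.
#' @param background_level background photons per pixel.
#' @param min_sep minimum separation between spots, physical um.
#' @param seed integer seed.
#' @return list with `image` (matrix) and `truth` (data.frame: x, y, 0-based
#'   pixel centers, `is_doublet`).
#' @export
simulate_crosssection_slice <- function(n_singles = 30, n_doublets = 0,
                                        size_px = 128, pixel_size = 0.07,
                                        psf_sigma = 0.1, amplitude = 2000,
                                        cv = 0.15, doublet_offset = 0.2,
                                        background_level = 5, min_sep = 0.8,
                                        seed = 1L) {
  with_seed(seed, {
    n <- n_singles + n_doublets
    lab <- sample(rep(c(FALSE, TRUE), c(n_singles, n_doublets)))
    sep_px <- min_sep / pixel_size
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n)) {
      for (att in seq_len(400)) {
        x <- stats::runif(1, 8, size_px - 9)
        y <- stats::runif(1, 8, size_px - 9)
        if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= sep_px) break
      }
      xs <- c(xs, x); ys <- c(ys, y)
    }
    img <- array(0, c(size_px, size_px, 1L))
    amp <- pmax(0.05, 1 + cv * stats::rnorm(n)) * amplitude
    for (i in seq_len(n)) {
      if (lab[i]) {
        th <- stats::runif(1, 0, pi)
        d <- doublet_offset / pixel_size / 2
        px <- xs[i] + c(-d, d) * cos(th)
        py <- ys[i] + c(-d, d) * sin(th)
        a2 <- pmax(0.05, 1 + cv * stats::rnorm(2)) * amplitude
        img <- img + splat_points(dim(img), px, py, c(0, 0), a2)
      } else {
        img <- img + splat_points(dim(img), xs[i], ys[i], 0, amp[i])
      }
    }
    sig_px <- psf_sigma / pixel_size
    img <- gauss_blur3d(img, c(sig_px, sig_px, 0))[, , 1]
    img <- matrix(stats::rpois(length(img),
                               pmax(img + background_level, 0)),
                  size_px, size_px)
    list(image = img,
         truth = data.frame(x = xs, y = ys, is_doublet = lab))
  })
}
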