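# High-level workflows chaining the stages into the two counting pipelines
# (soma-calibrated STED and dendrite-intrinsic FlipExM), the radial
# analysis, and the longitudinal profile — plus a JSON-config runner and a
# small CLI.

#' Calibrate single-microtubule intensities and crosstalk from a soma sheet
#'
#' Detection runs per channel on maximum projections of a thin substack at
#' the bottom of the cell (the sparse sub-nuclear sheet); quantification
#' runs on the matching sum projections in all three channels (the 3 x 3
#' design). The pooled total-channel intensities are fitted with the
#' two-Gaussian model per cell, singles are filtered at
#' `I_Tot + sigma_Tot`, and alpha/beta estimated from the singles.
#'
#' @param stack a three-channel [channel_stack()] of the cell body.
#' @param z_range substack slice range; default: the 7 consecutive slices
#'   centered on the brightest total-channel slice (chosen so the substack
#'   captures nearly all axial PSF mass of the sheet, keeping the
#'   single-filament calibration commensurate with whole-depth dendrite
#'   sums).
#' @param mask optional detection mask polygon (cell-body area).
#' @param line_width,min_length_um,relative_threshold see
#'   [detect_segments()].
#' @param w_microtubule,w_wide quantification tube widths, pixels.
#' @return list of class `soma_calibration`: `fit`
#'   (`single_intensity_fit`), `crosstalk` (`crosstalk_coefficients`),
#'   `table` (all measured segments), `singles` (filtered table),
#'   `z_range`, `pixel_size_um`.
#' @export
calibrate_soma <- function(stack, z_range = NULL, mask = NULL,
                           line_width = 2.5, min_length_um = 0.6,
                           relative_threshold = 0.55,
                           w_microtubule = 6, w_wide = 13) {
  d <- dim(stack$voxels[[1]])
  if (is.null(z_range)) {
    zint <- vapply(seq_len(d[3]), function(z)
      sum(stack$voxels$total[, , z]), numeric(1))
    zc <- which.max(zint)
    z_range <- c(max(1, zc - 3), min(d[3], zc + 3))
  }
  sub <- select_substack(stack, z_range)
  segs <- list()
  for (ch in c("total", "tyr", "ac")) {
    segs <- c(segs, detect_segments(sub$mip[[ch]],
                                    pixel_size_um = sub$pixel_size_um,
                                    line_width = line_width,
                                    min_length_um = min_length_um,
                                    mask = mask,
                                    relative_threshold = relative_threshold,
                                    detection_channel = ch))
  }
  if (!length(segs)) stop("no filament segments detected in any channel")
  tab <- measure_segments(sub$sum, segs, w_microtubule, w_wide)
  pooled <- tab$I_segm_total[!tab$excluded]
  fit <- fit_single_intensity(pooled)
  singles <- filter_singles(tab, fit)
  crosstalk <- estimate_crosstalk(singles)
  structure(list(fit = fit, crosstalk = crosstalk, table = tab,
                 singles = singles, z_range = z_range,
                 pixel_size_um = sub$pixel_size_um),
            class = "soma_calibration")
}

#' @export
print.soma_calibration <- function(x, ...) {
  cat("soma_calibration\n")
  print(x$fit)
  print(x$crosstalk)
  cat(sprintf("  %d segments measured, %d singles kept\n",
              nrow(x$table), nrow(x$singles)))
  invisible(x)
}

#' Count microtubules in a dendrite with a soma calibration
#'
#' Sum-projects the dendrite stack, measures the background-corrected band
#' intensities along a straight line (auto-placed along the image center
#' when not given), converts to n_Tot via the calibration's I_Tot, unmixes
#' n_Tyr/n_Ac with the calibration's alpha/beta, and measures the
#' cross-sectional area from a YZ reslice contour.
#'
#' @param stack dendrite [channel_stack()] (dendrite roughly along x).
#' @param calibration a `soma_calibration` (same cell).
#' @param line optional [polyline_roi()] (2 vertices) along the dendrite.
#' @param w_dendrite band width, pixels; default auto from the y-profile
#'   spread of the total channel.
#' @param widen_by background band widening, pixels.
#' @param area_method `"spline"` or `"hull"` (see
#'   [measure_cross_section_area()]).
#' @param boundary a [boundary_params()].
#' @return list of class `dendrite_count`: `counts`
#'   (`microtubule_counts`), `measurement`, `theta`, `area_um2`, `line`.
#' @export
count_dendrite_sted <- function(stack, calibration, line = NULL,
                                w_dendrite = NULL, widen_by = 10,
                                area_method = "spline",
                                boundary = boundary_params()) {
  d <- dim(stack$voxels[[1]])
  px_um <- unname(stack$voxel_size["x"] / stack$expansion_factor)
  sums <- lapply(stack$voxels, function(a) rowSums(a, dims = 2))
  if (is.null(line)) {
    yprof <- rowSums(sums$total)
    ys <- 0:(d[1] - 1)
    ycm <- sum(yprof * ys) / sum(yprof)
    L_px <- 2.5 / px_um
    xc <- (d[2] - 1) / 2
    line <- polyline_roi(rbind(c(xc - L_px / 2, ycm), c(xc + L_px / 2, ycm)))
  }
  if (is.null(w_dendrite)) {
    # width covering the dendrite signal extent in y, plus margin
    yprof <- rowSums(sums$total)
    rel <- (yprof - min(yprof)) / max(max(yprof) - min(yprof), 1e-12)
    ext <- range(which(rel > 0.05))
    w_dendrite <- ceiling(diff(ext) + 1 + 8)
    ycm <- mean(line$vertices[, 2])
    w_max <- floor(2 * min(ycm, d[1] - 1 - ycm) - widen_by - 1)
    w_dendrite <- min(w_dendrite, w_max)
  }
  meas <- measure_dendrite(sums, line, w_dendrite, px_um,
                           widen_by = widen_by)
  n_tot <- count_total(meas, calibration$fit)
  theta <- c(
    tyr = meas$I_dendrite[meas$channel == "tyr"] / calibration$crosstalk$I_Tyr,
    ac = meas$I_dendrite[meas$channel == "ac"] / calibration$crosstalk$I_Ac)
  nn <- unmix_counts(theta["tyr"], theta["ac"],
                     calibration$crosstalk$alpha, calibration$crosstalk$beta)
  mid <- stats::approx(c(0, 1), c(line$vertices[1, 2], line$vertices[2, 2]),
                       xout = 0.5)$y
  path <- polyline_roi(rbind(c(line$vertices[1, 1], mid),
                             c(line$vertices[2, 1], mid)))
  vy <- path$vertices[, 2]
  hw_max <- floor(min(vy, d[1] - 1 - vy) - 1) # horizontal path: y margin only
  hw <- min(hw_max, ceiling(w_dendrite / 2 + widen_by))
  resl <- straighten_and_reslice(stack, path, half_width = hw)
  area <- measure_cross_section_area(resl, method = area_method,
                                     params = boundary)
  counts <- classify_counts(n_tot, unname(nn["n_tyr"]), unname(nn["n_ac"]),
                            as.numeric(area))
  structure(list(counts = counts, measurement = meas, theta = theta,
                 area_um2 = as.numeric(area), line = line,
                 w_dendrite = w_dendrite),
            class = "dendrite_count")
}

#' @export
print.dendrite_count <- function(x, ...) {
  cat(sprintf("dendrite_count (area %.2f um^2, band %d px):\n",
              x$area_um2, x$w_dendrite))
  print(x$counts)
  invisible(x)
}

#' Radial analysis of a dendrite
#'
#' Reslices (when given a raw stack) and walks the YZ series: bounding
#' rectangle on the first slice, tracked rectangles on the rest, 8-anchor
#' spline contours (or convex hulls), per-channel erosion profiles,
#' averages on a common grid, and the two-component decomposition of the
#' total density.
#'
#' @param x a `resliced_stack`, or a [channel_stack()] with `path`.
#' @param path polyline for straightening when `x` is a raw stack.
#' @param half_width reslice half-width, pixels (raw stack input).
#' @param slice_indices which slices to analyze (default all).
#' @param params a [boundary_params()].
#' @param contour_method `"spline"` or `"hull"`.
#' @return list of class `radial_analysis`: `profiles` (per channel, list
#'   of `radial_profile`), `average` (per channel data.frame),
#'   `decomposition` (`decomposition_result`), `contours`.
#' @export
analyze_radial <- function(x, path = NULL, half_width = NULL,
                           slice_indices = NULL,
                           params = boundary_params(),
                           contour_method = c("spline", "hull")) {
  contour_method <- match.arg(contour_method)
  resl <- if (inherits(x, "resliced_stack")) x else {
    if (is.null(path)) stop("need a path to reslice a raw stack")
    if (is.null(half_width))
      half_width <- floor((min(dim(x$voxels[[1]])[1:2]) - 3) / 2)
    straighten_and_reslice(x, path, half_width)
  }
  chans <- names(resl$slices)
  ref <- if (params$reference_channel %in% chans) params$reference_channel
  else chans[1]
  if (is.null(slice_indices)) slice_indices <- seq_len(n_slices(resl))
  contours <- list()
  profiles <- stats::setNames(lapply(chans, function(ch) list()), chans)
  prev_rect <- NULL
  for (i in slice_indices) {
    refsl <- get_slice(resl, ref, i)
    ct <- tryCatch({
      if (contour_method == "hull") {
        convex_hull_contour(refsl)
      } else {
        rect <- if (is.null(prev_rect)) initial_rectangle(refsl, params)
        else track_rectangle(refsl, prev_rect, params)
        prev_rect <- rect
        fit_contour(refsl, rect, params)
      }
    }, error = function(e) e)
    if (inherits(ct, "error")) {
      contours[[as.character(i)]] <- ct
      next
    }
    contours[[as.character(i)]] <- ct
    for (ch in chans) {
      pr <- tryCatch(radial_profile(get_slice(resl, ch, i), ct, channel = ch),
                     error = function(e) NULL)
      if (!is.null(pr)) profiles[[ch]][[length(profiles[[ch]]) + 1L]] <- pr
    }
  }
  if (!length(profiles[[1]])) stop("no usable cross-sections")
  average <- lapply(profiles, average_profiles)
  decomposition <- if (all(c("total", "tyr", "ac") %in% chans)) {
    tryCatch(decompose_total(average$total$mean, average$tyr$mean,
                             average$ac$mean),
             error = function(e) e)
  } else NULL
  structure(list(profiles = profiles, average = average,
                 decomposition = decomposition, contours = contours),
            class = "radial_analysis")
}

#' FlipExM dendrite-intrinsic counting
#'
#' Runs the full FlipExM pipeline on a resliced YZ series: a specific
#' (bright-spot) detection pass feeds the roundness and area filters and
#' the per-channel two-Gaussian calibration plus crosstalk estimation; an
#' inclusive detection pass then sums all spot intensities per slice for
#' counting (crosstalk-level spots must contribute to the channel sums, as
#' in the forward model).
#'
#' @param resliced a `resliced_stack`.
#' @param calib_slices slices used for calibration (default all).
#' @param count_slices slices used for counting (default all).
#' @param roundness_threshold see [roundness_filter()].
#' @param crosstalk_method see [estimate_crosstalk_flipexm()].
#' @param calib_bright_fraction calibration spots must reach this fraction
#'   of the channel's bright-population reference intensity (median of the
#'   top third of detections), keeping crosstalk-level detections out of
#'   the single-intensity calibration and out of the detected-in-channel
#'   crosstalk sets. Default 0.75, the approximate geometric midpoint
#'   between a worst-case crosstalk level (~0.6 of a single) and the
#'   single-microtubule level.
#' @param noise_k inclusive-detection threshold (robust noise SDs).
#' @return list of class `flipexm_analysis`: `fits`, `crosstalk`,
#'   `area_params`, `counts` (from [count_per_slice()]), `spot_tables`.
#' @export
analyze_flipexm <- function(resliced, calib_slices = NULL,
                            count_slices = NULL,
                            roundness_threshold = 0.8,
                            crosstalk_method = "pooled_mean",
                            calib_bright_fraction = 0.75,
                            noise_k = 5) {
  chans <- names(resliced$slices)
  if (is.null(calib_slices)) calib_slices <- seq_len(n_slices(resliced))
  if (is.null(count_slices)) count_slices <- seq_len(n_slices(resliced))
  # detection for calibration: inclusive detection, then a bright-reference
  # selection at the spot level so crosstalk-level spots do not enter the
  # channel's "detected" calibration population
  per_chan <- stats::setNames(vector("list", length(chans)), chans)
  for (ch in chans) {
    tabs <- list()
    for (i in calib_slices) {
      sl <- stats::setNames(lapply(chans, function(c2)
        get_slice(resliced, c2, i)), chans)
      tabs[[length(tabs) + 1L]] <-
        detect_spots(sl, detect_channel = ch, noise_k = noise_k)
    }
    tab <- do.call(rbind, tabs)
    I_det <- tab[[paste0("I_", ch)]]
    if (nrow(tab)) {
      top <- I_det[I_det >= stats::quantile(I_det, 2 / 3, names = FALSE)]
      bright_ref <- stats::median(top)
      tab <- tab[I_det >= calib_bright_fraction * bright_ref, , drop = FALSE]
    }
    class(tab) <- c("spot_table", "data.frame")
    per_chan[[ch]] <- tab
  }
  # roundness then area filters, then intensity fits
  fits <- list()
  area_params <- list()
  filtered <- list()
  for (ch in chans) {
    round_ok <- roundness_filter(per_chan[[ch]], roundness_threshold)
    af <- area_filter(round_ok)
    filtered[[ch]] <- af$spots
    area_params[[ch]] <- af$params
    fits[[ch]] <- fit_single_crosssection(af$spots[[paste0("I_", ch)]])
  }
  ac_levels <- filtered$ac[["I_tyr"]] / fits$tyr$I_Tot
  tyr_levels <- filtered$tyr[["I_ac"]] / fits$ac$I_Tot
  crosstalk <- estimate_crosstalk_flipexm(ac_levels, tyr_levels,
                                          method = crosstalk_method)
  counts <- count_per_slice(resliced, fits,
                            alpha = crosstalk["alpha"],
                            beta = crosstalk["beta"],
                            slice_indices = count_slices,
                            noise_k = noise_k)
  structure(list(fits = fits, crosstalk = crosstalk,
                 area_params = area_params, counts = counts,
                 spot_tables = filtered),
            class = "flipexm_analysis")
}

# ---- config runner ---------------------------------------------------------

#' Load and validate a JSON run configuration
#'
#' A single JSON file drives a whole run: `workflow` (one of `simulate`,
#' `soma_sted`, `radial`, `flipexm`, `profile`), `seed`, `output_dir`, a
#' `scene` block (passed to [scene_spec()]) and/or `input` paths, and
#' optional per-stage parameter blocks. Defaults follow the reference
#' protocol (6/13 px quantification widths, 2.5 px line width, 0.6 um
#' minimum length, 0.8 roundness, 10 px band widening, I_thr 0.3).
#'
#' @param path JSON file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$workflow) ||
      !cfg$workflow %in% c("simulate", "soma_sted", "radial", "flipexm",
                           "profile"))
    stop("config must name a workflow: simulate, soma_sted, radial, flipexm, profile")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "."
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("config input file does not exist: ", cfg$input)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' @keywords internal
.cfg_scene <- function(cfg) {
  sc <- cfg$scene %||% list()
  sc$seed <- sc$seed %||% cfg$seed
  if (!is.null(sc$voxel_size)) sc$voxel_size <- unlist(sc$voxel_size)
  do.call(scene_spec, sc)
}

#' Run a configured workflow
#'
#' Executes the stages of the configured workflow in dependency order and
#' writes result tables (CSV) and summaries (JSON) with provenance (config
#' hash, package version, seed) into `output_dir`. Stage failures abort
#' with the stage name.
#'
#' @param config a `run_config` (or path to one).
#' @return list of written file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit_json <- function(obj, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    written <<- c(written, p)
  }
  emit_csv <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  prov <- list(package = "mtquant",
               version = as.character(utils::packageVersion("mtquant")),
               seed = config$seed,
               workflow = config$workflow,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (config$workflow == "simulate") {
    spec <- stage("scene", .cfg_scene(config))
    sim <- stage("simulate", simulate_scene(spec))
    p <- file.path(out_dir, "scene.tif")
    stage("write", write_stack(sim$stack, p))
    written <- c(written, p)
    emit_csv(sim$truth$filaments, "ground_truth_filaments.csv")
    emit_json(list(provenance = prov,
                   n_tot = sim$truth$n_tot, n_tyr = sim$truth$n_tyr,
                   n_ac = sim$truth$n_ac, n_other = sim$truth$n_other,
                   density_per_um2 = sim$truth$density_per_um2),
              "ground_truth.json")
  } else if (config$workflow == "soma_sted") {
    soma_stack <- stage("input", .cfg_stack(config, "soma"))
    dend_stack <- stage("input", .cfg_stack(config, "dendrite"))
    calib <- stage("calibrate", calibrate_soma(soma_stack))
    res <- stage("count", count_dendrite_sted(dend_stack, calib))
    emit_csv(data.frame(
      area_um2 = res$area_um2,
      theta_tyr = res$theta["tyr"], theta_ac = res$theta["ac"],
      n_tot = res$counts$n_tot, n_tyr = res$counts$n_tyr,
      n_ac = res$counts$n_ac, n_other = res$counts$n_other,
      frac_tyr = res$counts$fractions["tyr"],
      frac_ac = res$counts$fractions["ac"],
      frac_other = res$counts$fractions["other"],
      density = res$counts$density,
      flags = paste(res$counts$flags, collapse = ";")), "counts.csv")
    emit_json(list(provenance = prov,
                   I_Tot = calib$fit$I_Tot, sigma_Tot = calib$fit$sigma_Tot,
                   alpha = calib$crosstalk$alpha,
                   beta = calib$crosstalk$beta), "calibration.json")
  } else if (config$workflow == "radial") {
    stk <- stage("input", .cfg_stack(config, "dendrite"))
    path <- stage("path", .cfg_path(config, stk))
    ra <- stage("radial", analyze_radial(stk, path = path))
    for (ch in names(ra$average))
      emit_csv(ra$average[[ch]], paste0("radial_", ch, ".csv"))
    dec <- ra$decomposition
    emit_json(list(provenance = prov,
                   w_tyr = dec$w_tyr, w_ac = dec$w_ac,
                   weight_sum = dec$weight_sum, mse = dec$mse),
              "decomposition.json")
  } else if (config$workflow == "flipexm") {
    stk <- stage("input", .cfg_stack(config, "dendrite"))
    path <- stage("path", .cfg_path(config, stk))
    resl <- stage("reslice", straighten_and_reslice(
      stk, path, half_width = floor((min(dim(stk$voxels[[1]])[1:2]) - 3) / 2)))
    fa <- stage("flipexm", analyze_flipexm(resl))
    emit_csv(fa$counts$per_slice, "counts_per_slice.csv")
    emit_json(list(provenance = prov,
                   alpha = unname(fa$crosstalk["alpha"]),
                   beta = unname(fa$crosstalk["beta"]),
                   per_dendrite = as.list(fa$counts$per_dendrite)),
              "flipexm_counts.json")
  } else if (config$workflow == "profile") {
    stk <- stage("input", .cfg_stack(config, "dendrite"))
    path <- stage("path", .cfg_path(config, stk))
    sums <- lapply(stk$voxels, function(a) rowSums(a, dims = 2))
    px_um <- unname(stk$voxel_size["x"] / stk$expansion_factor)
    pr <- stage("profile", trace_profile(sums, path, px_um))
    pr <- stage("normalize", normalize_and_smooth(pr))
    pr$fwhm_um <- fwhm_profile(pr)
    emit_csv(as.data.frame(pr), "longitudinal_profile.csv")
  }
  invisible(written)
}

#' @keywords internal
.cfg_stack <- function(cfg, role) {
  key <- paste0(role, "_input")
  if (!is.null(cfg[[key]])) return(read_stack(cfg[[key]]))
  if (!is.null(cfg$input)) return(read_stack(cfg$input))
  # fall back to simulating the configured scene
  sc <- cfg[[paste0(role, "_scene")]] %||% cfg$scene
  if (is.null(sc)) stop("no input file or scene for ", role)
  sc$seed <- sc$seed %||% cfg$seed
  if (!is.null(sc$voxel_size)) sc$voxel_size <- unlist(sc$voxel_size)
  simulate_scene(do.call(scene_spec, sc))$stack
}

#' @keywords internal
.cfg_path <- function(cfg, stk) {
  if (!is.null(cfg$roi)) {
    r <- read_roi(cfg$roi)
    return(if (inherits(r, "polyline_roi")) r else r[[1]])
  }
  # default: horizontal midline across the stack
  d <- dim(stk$voxels[[1]])
  y <- (d[1] - 1) / 2
  polyline_roi(rbind(c(2, y), c(d[2] - 3, y)))
}

#' Command-line entry point
#'
#' `Rscript -e 'mtquant::mtq_cli()' <verb> [--config file.json] [...]` with
#' verbs `simulate`, `filaments` (soma calibration), `count` (soma_sted),
#' `radial`, `flipexm`, `profile`, `run` (workflow from config).
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
mtq_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: mtquant <simulate|count|radial|flipexm|profile|run> --config file.json\n")
    return(invisible(1L))
  }
  verb <- args[1]
  cfg_i <- which(args == "--config")
  if (!length(cfg_i) || cfg_i == length(args))
    stop("--config file.json is required")
  cfg <- read_run_config(args[cfg_i + 1])
  if (verb != "run") {
    cfg$workflow <- switch(verb,
                           simulate = "simulate",
                           filaments = "soma_sted",
                           count = "soma_sted",
                           radial = "radial",
                           flipexm = "flipexm",
                           profile = "profile",
                           stop("unknown verb: ", verb))
  }
  files <- run_pipeline(cfg)
  cat("wrote:\n")
  for (f in files) cat("  ", f, "\n", sep = "")
  invisible(0L)
}
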