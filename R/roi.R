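# Region-of-interest I/O: a documented JSON dialect plus binary ImageJ .roi
# files (polyline/polygon/line/rect) and .zip archives of them.
#
# Package convention: 0-based pixel coordinates with pixel centers at
# integer positions, y increasing downward. ImageJ stores coordinates on a
# corner-based grid (integer = pixel's top-left edge), so .roi import
# subtracts 0.5 and export adds it back — the conversion is explicit here
# and nowhere else.

#' Create a polyline region of interest
#'
#' @param vertices n x 2 matrix (or data.frame) of (x, y), 0-based pixel
#'   centers; at least 2 rows, finite.
#' @param stroke_width optional stroke width in pixels.
#' @param z_range optional length-2 integer range of z slices (1-based).
#' @param name optional name.
#' @return object of class `polyline_roi`.
#' @export
polyline_roi <- function(vertices, stroke_width = NULL, z_range = NULL,
                         name = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2 || ncol(vertices) != 2)
    stop("polyline_roi needs >= 2 (x, y) vertices")
  if (!all(is.finite(vertices))) stop("polyline vertices must be finite")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, stroke_width = stroke_width,
                 z_range = z_range, name = name), class = "polyline_roi")
}

#' @export
print.polyline_roi <- function(x, ...) {
  cat(sprintf("polyline_roi '%s': %d vertices, length %.2f px\n",
              x$name %||% "", nrow(x$vertices), polyline_length(x)))
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polyline length in pixels
#' @param roi a `polyline_roi`
#' @return total arc length, pixels
#' @export
polyline_length <- function(roi) {
  sum(sqrt(rowSums(diff(roi$vertices)^2)))
}

#' Read a region of interest file
#'
#' Dispatches on extension: `.json` (the package's JSON dialect), `.roi`
#' (binary ImageJ), `.zip` (archive of .roi files; returns a list).
#'
#' @param path file path.
#' @return a `polyline_roi` (or list of them for .zip).
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = .read_roi_json(path),
         roi = .read_roi_ij(path),
         zip = {
           tmp <- tempfile("roizip")
           files <- utils::unzip(path, exdir = tmp)
           on.exit(unlink(tmp, recursive = TRUE))
           lapply(files[grepl("\\.roi$", files)], .read_roi_ij)
         },
         stop("unsupported ROI format: .", ext))
}

#' Write a region of interest file
#'
#' `.json` writes the JSON dialect; `.roi` writes a binary ImageJ polyline
#' ROI (coordinates rounded to ImageJ's integer corner-based grid).
#'
#' @param roi a `polyline_roi`.
#' @param path destination ending in `.json` or `.roi`.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "polyline_roi"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = .write_roi_json(roi, path),
         roi = .write_roi_ij(roi, path),
         stop("unsupported ROI format: .", ext))
  invisible(path)
}

#' @keywords internal
.read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "polyline") && !identical(j$type, "polygon"))
    stop("JSON ROI type must be 'polyline' or 'polygon'")
  pts <- j$points
  if (!is.matrix(pts)) pts <- do.call(rbind, pts)
  polyline_roi(pts, stroke_width = j$stroke_width,
               z_range = j$z_range, name = j$name)
}

#' @keywords internal
.write_roi_json <- function(roi, path) {
  j <- list(type = "polyline",
            points = lapply(seq_len(nrow(roi$vertices)),
                            function(i) unname(roi$vertices[i, ])),
            stroke_width = roi$stroke_width,
            z_range = roi$z_range, name = roi$name)
  jsonlite::write_json(j[!vapply(j, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
}

# Binary ImageJ .roi: big-endian, "Iout" magic; only the coordinate-carrying
# types needed here are handled.
#' @keywords internal
.read_roi_ij <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  be <- function(off, n = 1, size = 2)
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = "big", signed = TRUE)
  if (rawToChar(raw[1:4]) != "Iout") stop("not an ImageJ ROI file: ", path)
  type <- as.integer(raw[7])
  top <- be(8); left <- be(10); bottom <- be(12); right <- be(14)
  n <- be(16)
  stroke <- be(34)
  if (type %in% c(0L, 4L, 5L, 7L, 8L)) { # polygon/freeline/polyline/freehand
    xs <- be(64, n) + left
    ys <- be(64 + 2 * n, n) + top
  } else if (type == 3L) { # straight line: floats at 18..33
    f <- readBin(raw[19:34], "numeric", n = 4, size = 4, endian = "big")
    xs <- f[c(1, 3)]; ys <- f[c(2, 4)]
  } else if (type == 1L) { # rectangle -> its 4 corners as a polygon
    xs <- c(left, right, right, left)
    ys <- c(top, top, bottom, bottom)
  } else {
    stop("unsupported ImageJ ROI type code: ", type)
  }
  polyline_roi(cbind(xs, ys) - 0.5,
               stroke_width = if (stroke > 0) stroke else NULL,
               name = sub("\\.roi$", "", basename(path)))
}

#' @keywords internal
.write_roi_ij <- function(roi, path) {
  v <- round(roi$vertices + 0.5)
  xs <- as.integer(v[, 1]); ys <- as.integer(v[, 2])
  left <- min(xs); top <- min(ys)
  con <- file(path, "wb")
  on.exit(close(con))
  wbe <- function(x, size = 2) writeBin(as.integer(x), con, size = size,
                                        endian = "big")
  writeBin(charToRaw("Iout"), con)
  wbe(227)                        # version
  writeBin(as.raw(c(5L, 0L)), con) # type polyline
  wbe(top); wbe(left); wbe(max(ys)); wbe(max(xs))
  wbe(length(xs))                 # n coordinates
  writeBin(raw(16), con)          # x1,y1,x2,y2 floats (unused)
  wbe(round(roi$stroke_width %||% 0))
  writeBin(raw(28), con)          # pad header to the 64-byte coordinate block
  wbe(xs - left, size = 2)
  wbe(ys - top, size = 2)
}
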