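# Minimal baseline TIFF codec for multi-channel z-stacks.
#
# There is no TIFF package in the supported dependency set, so the package
# carries its own small codec: little-endian baseline TIFF, one strip per
# page, uncompressed, grayscale 8/16-bit unsigned or 32-bit float, pages
# ordered channel-fastest (c, z) as in ImageJ hyperstacks. Voxel size is
# stored in the X/YResolution tags (pixels per micron) plus an ImageJ-style
# ImageDescription carrying z spacing, channel names and expansion factor.
# Anything fancier (compression, tiles, big-endian files) is rejected with a
# clear error rather than mis-read.

.TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
                photometric = 262L, description = 270L, strip_offsets = 273L,
                spp = 277L, rows_per_strip = 278L, strip_counts = 279L,
                xres = 282L, yres = 283L, resunit = 296L, sampleformat = 339L)

#' Write a channel stack to a multi-page TIFF file
#'
#' Pages are ordered channel-fastest, matching ImageJ hyperstacks; pixel
#' data are 32-bit floats. Pixel size, z spacing, channel names and
#' expansion factor round-trip through the resolution tags and an
#' ImageJ-style description.
#'
#' @param stack a [channel_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$voxels[[1]])
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  nch <- length(stack$voxels)
  npage <- nch * nz
  desc <- paste0(
    "ImageJ=1.53t\nimages=", npage, "\nchannels=", nch, "\nslices=", nz,
    "\nhyperstack=true\nmode=grayscale\nunit=micron\nspacing=",
    format(stack$voxel_size["z"], digits = 10),
    "\nloop=false\nmtq_channels=", paste(names(stack$voxels), collapse = ","),
    "\nmtq_expansion=", format(stack$expansion_factor, digits = 10), "\n")
  desc_raw <- c(charToRaw(desc), as.raw(0))
  page_bytes <- nx * ny * 4L
  data_off <- 8L
  extra_off <- data_off + npage * page_bytes          # description + rationals
  desc_off <- extra_off
  xres_off <- desc_off + length(desc_raw)
  yres_off <- xres_off + 8L
  ifd0_off <- yres_off + 8L
  n_tags <- c(14L, rep(13L, npage - 1L))              # description on page 1
  ifd_sizes <- 2L + 12L * n_tags + 4L
  ifd_offs <- ifd0_off + cumsum(c(0L, ifd_sizes[-npage]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0_off, con, size = 4, endian = "little")
  # pixel data, channel-fastest
  for (z in seq_len(nz)) for (ch in seq_len(nch)) {
    # TIFF rows are image rows: row-major, our matrices are [y, x]
    writeBin(as.numeric(t(stack$voxels[[ch]][, , z])), con, size = 4,
             endian = "little")
  }
  writeBin(desc_raw, con)
  res_den <- 1000000L
  res_num <- as.integer(round(1 / stack$voxel_size[c("x", "y")] * res_den))
  writeBin(c(res_num[1], res_den), con, size = 4, endian = "little")
  writeBin(c(res_num[2], res_den), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) list(id = id, type = type,
                                               count = count, value = value)
  for (p in seq_len(npage)) {
    tags <- list(
      tag(256L, 4L, 1L, nx), tag(257L, 4L, 1L, ny),
      tag(258L, 3L, 1L, 32L), tag(259L, 3L, 1L, 1L),
      tag(262L, 3L, 1L, 1L))
    if (p == 1L) tags <- c(tags, list(tag(270L, 2L, length(desc_raw), desc_off)))
    tags <- c(tags, list(
      tag(273L, 4L, 1L, data_off + (p - 1L) * page_bytes),
      tag(277L, 3L, 1L, 1L), tag(278L, 4L, 1L, ny),
      tag(279L, 4L, 1L, page_bytes),
      tag(282L, 5L, 1L, xres_off), tag(283L, 5L, 1L, yres_off),
      tag(296L, 3L, 1L, 1L), tag(339L, 3L, 1L, 3L)))
    writeBin(length(tags), con, size = 2, endian = "little")
    for (tg in tags) {
      writeBin(tg$id, con, size = 2, endian = "little")
      writeBin(tg$type, con, size = 2, endian = "little")
      writeBin(tg$count, con, size = 4, endian = "little")
      if (tg$type == 3L && tg$count == 1L) {
        writeBin(as.integer(tg$value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(tg$value), con, size = 4, endian = "little")
      }
    }
    nxt <- if (p < npage) ifd_offs[p + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @keywords internal
.tiff_read_raw <- function(raw, off, n, size) {
  readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
          endian = "little", signed = size > 2)
}

#' Read a multi-page TIFF file into a channel stack
#'
#' Understands the files written by [write_stack()] and, more generally,
#' uncompressed little-endian grayscale TIFFs (8/16-bit unsigned or 32-bit
#' float, strip-organized). Channel count, z spacing, channel names and
#' expansion factor are taken from an ImageJ-style ImageDescription when
#' present; pixel size from the resolution tags. Metadata absent from the
#' file must be supplied via the arguments — there is no silent default.
#'
#' @param path TIFF file path.
#' @param channel_names optional character vector overriding/declaring
#'   channel names; its length sets the channel count when the file carries
#'   no channel metadata.
#' @param voxel_size optional `c(x=, y=, z=)` um override.
#' @param expansion_factor optional override (default from file, else 1).
#' @return a [channel_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, voxel_size = NULL,
                       expansion_factor = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("corrupt TIFF: ", path)
  if (rawToChar(raw[1:2]) != "II")
    stop("unsupported TIFF byte order (only little-endian 'II' supported)")
  if (.tiff_read_raw(raw, 2, 1, 2) != 42L) stop("not a TIFF file: ", path)
  off <- .tiff_read_raw(raw, 4, 1, 4)
  pages <- list()
  desc <- NULL
  xres <- yres <- NA_real_
  while (off != 0) {
    ntag <- .tiff_read_raw(raw, off, 1, 2)
    tags <- list()
    for (i in seq_len(ntag)) {
      toff <- off + 2 + (i - 1) * 12
      id <- .tiff_read_raw(raw, toff, 1, 2)
      type <- .tiff_read_raw(raw, toff + 2, 1, 2)
      count <- .tiff_read_raw(raw, toff + 4, 1, 4)
      val <- if (type == 3L && count <= 2L) {
        .tiff_read_raw(raw, toff + 8, count, 2)
      } else if (count == 1L && type == 4L) {
        .tiff_read_raw(raw, toff + 8, 1, 4)
      } else {
        voff <- .tiff_read_raw(raw, toff + 8, 1, 4)
        if (type == 2L) {
          rawToChar(raw[(voff + 1):(voff + count - 1)])
        } else if (type == 5L) {
          r <- .tiff_read_raw(raw, voff, 2 * count, 4)
          r[seq(1, 2 * count, 2)] / r[seq(2, 2 * count, 2)]
        } else if (type == 3L) {
          .tiff_read_raw(raw, voff, count, 2)
        } else {
          .tiff_read_raw(raw, voff, count, 4)
        }
      }
      tags[[as.character(id)]] <- val
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    if (!is.null(g(270)) && is.null(desc)) desc <- g(270)
    if (is.na(xres) && !is.null(g(282))) xres <- g(282)[1]
    if (is.na(yres) && !is.null(g(283))) yres <- g(283)[1]
    comp <- g(259, 1L)
    if (comp != 1L) stop("compressed TIFF not supported (compression=", comp, ")")
    bits <- g(258, 1L)[1]
    sfmt <- g(339, 1L)[1]
    nx <- g(256); ny <- g(257)
    if (is.null(nx) || is.null(ny)) stop("corrupt TIFF: missing dimensions")
    offs <- g(273); counts <- g(279)
    buf <- raw(0)
    for (i in seq_along(offs)) {
      buf <- c(buf, raw[(offs[i] + 1):(offs[i] + counts[i])])
    }
    n_px <- nx * ny
    px <- if (bits == 32L && sfmt == 3L) {
      readBin(buf, "numeric", n = n_px, size = 4, endian = "little")
    } else if (bits == 16L) {
      v <- readBin(buf, "integer", n = n_px, size = 2, endian = "little",
                   signed = FALSE)
      as.numeric(v)
    } else if (bits == 8L) {
      as.numeric(as.integer(buf[seq_len(n_px)]))
    } else {
      stop("unsupported TIFF pixel type: ", bits, "-bit, sampleformat ", sfmt)
    }
    pages[[length(pages) + 1L]] <- matrix(px, ny, nx, byrow = TRUE)
    off <- .tiff_read_raw(raw, off + 2 + ntag * 12, 1, 4)
  }
  npage <- length(pages)
  if (npage == 0) stop("corrupt TIFF: no pages")
  meta <- .parse_ij_description(desc)
  nch <- if (!is.null(channel_names)) length(channel_names) else
    if (!is.na(meta$channels)) meta$channels else 1L
  if (npage %% nch != 0)
    stop("page count ", npage, " not divisible by channel count ", nch)
  nz <- npage %/% nch
  nms <- if (!is.null(channel_names)) channel_names else
    if (!is.null(meta$channel_names) && length(meta$channel_names) == nch)
      meta$channel_names else paste0("ch", seq_len(nch))
  if (is.null(voxel_size)) {
    if (is.na(xres) || is.na(meta$spacing))
      stop("voxel size absent from file metadata; supply voxel_size=")
    voxel_size <- c(x = 1 / xres, y = 1 / ifelse(is.na(yres), xres, yres),
                    z = meta$spacing)
  }
  if (is.null(expansion_factor)) {
    expansion_factor <- if (!is.na(meta$expansion)) meta$expansion else 1
  }
  vox <- lapply(seq_len(nch), function(ch) {
    a <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), nz))
    for (z in seq_len(nz)) a[, , z] <- pages[[(z - 1L) * nch + ch]]
    a
  })
  names(vox) <- nms
  channel_stack(vox, voxel_size = voxel_size,
                expansion_factor = expansion_factor)
}

#' @keywords internal
.parse_ij_description <- function(desc) {
  out <- list(channels = NA_integer_, spacing = NA_real_,
              expansion = NA_real_, channel_names = NULL)
  if (is.null(desc)) return(out)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "=", fixed = TRUE)
  for (p in kv) {
    if (length(p) != 2) next
    key <- p[1]; val <- p[2]
    if (key == "channels") out$channels <- as.integer(val)
    if (key == "spacing") out$spacing <- as.numeric(val)
    if (key == "mtq_expansion") out$expansion <- as.numeric(val)
    if (key == "mtq_channels")
      out$channel_names <- strsplit(val, ",", fixed = TRUE)[[1]]
  }
  out
}
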