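# File formats. No image codec library is assumed: a minimal baseline TIFF
# implementation (uncompressed grayscale, 8/16-bit, multi-page, little-endian
# writer, either byte order on read) plus plain PGM cover the pipeline's
# needs. ROIs come from JSON vertex lists or ImageJ .roi polygon files.

#' Write a grayscale TIFF
#'
#' Baseline uncompressed TIFF, 8- or 16-bit, one page per slice for a
#' [zstack]. Pixel size is stored in the X/YResolution tags (pixels per cm).
#'
#' @param img a [raster_image], [binary_mask] (written as 0/255) or [zstack].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  if (is_binary_mask(img))
    img <- raster_image(img$foreground * 255, img$pixel_size_um, 8)
  pages <- if (inherits(img, "zstack")) img$slices else list(img)
  con <- file(path, "wb")
  on.exit(close(con))
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  n <- length(pages)
  n_tags <- 12L
  ifd_size <- 2L + 12L * n_tags + 4L
  # layout per page: [pixel data][resolution rationals (16 B)][IFD]
  data_off <- integer(n); rat_off <- integer(n); ifd_off <- integer(n)
  off <- 8L
  for (p in seq_len(n)) {
    im <- pages[[p]]
    nbytes <- img_width(im) * img_height(im) * (im$bit_depth / 8)
    data_off[p] <- off
    rat_off[p] <- off + nbytes
    ifd_off[p] <- rat_off[p] + 16L
    off <- ifd_off[p] + ifd_size
  }
  writeChar("II", con, eos = NULL); w_u16(42L); w_u32(ifd_off[1])
  for (p in seq_len(n)) {
    im <- pages[[p]]
    wd <- img_width(im); ht <- img_height(im)
    bps <- im$bit_depth
    nbytes <- wd * ht * (bps / 8)
    # pixel data, row-major
    writeBin(as.integer(round(t(im$values))), con, size = bps / 8,
             endian = "little")
    # X/Y resolution rationals: pixels per cm = 1e4 / pixel_size_um
    res_num <- as.integer(round(1e7 / im$pixel_size_um)); res_den <- 1000L
    w_u32(res_num); w_u32(res_den); w_u32(res_num); w_u32(res_den)
    entries <- list(
      c(256L, 3L, 1L, wd), c(257L, 3L, 1L, ht), c(258L, 3L, 1L, bps),
      c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, data_off[p]),
      c(277L, 3L, 1L, 1L), c(278L, 3L, 1L, ht), c(279L, 4L, 1L, nbytes),
      c(282L, 5L, 1L, rat_off[p]), c(283L, 5L, 1L, rat_off[p] + 8L),
      c(296L, 3L, 1L, 3L))
    w_u16(length(entries))
    for (e in entries) {
      w_u16(e[1]); w_u16(e[2]); w_u32(e[3])
      if (e[2] == 3L) { w_u16(e[4]); w_u16(0L) } else w_u32(e[4])
    }
    w_u32(if (p < n) ifd_off[p + 1] else 0L)
  }
  invisible(path)
}

#' Read a grayscale TIFF
#'
#' Reads baseline uncompressed grayscale TIFFs (either byte order, 8- or
#' 16-bit, multi-strip, multi-page). Returns a [raster_image] for single-page
#' files and a [zstack] otherwise.
#'
#' @param path file to read.
#' @param pixel_size_um optional calibration override (takes precedence over
#'   the file's resolution tags).
#' @param step_um slice spacing for multi-page files.
#' @return A [raster_image] or [zstack].
#' @export
read_tiff <- function(path, pixel_size_um = NULL, step_um = 1) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file")
  r_int <- function(off, size, n = 1)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = (size == 4))  # unsigned only for 1/2 B
  if (r_int(2, 2) != 42L) stop("not a TIFF file")
  ifd_off <- readBin(raw[5:8], "integer", size = 4, endian = endian)
  slices <- list()
  while (ifd_off > 0) {
    n_entries <- r_int(ifd_off, 2)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e_off <- ifd_off + 2 + (k - 1) * 12
      tag <- r_int(e_off, 2); typ <- r_int(e_off + 2, 2); cnt <- r_int(e_off + 4, 4)
      size <- c(1, 1, 2, 4, 8)[typ]
      val_off <- if (size * cnt <= 4) e_off + 8 else r_int(e_off + 8, 4)
      vals <- if (typ == 5) {  # RATIONAL
        num <- r_int(val_off, 4, cnt * 2)
        num[seq(1, 2 * cnt, 2)] / num[seq(2, 2 * cnt, 2)]
      } else r_int(val_off, size, cnt)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    if (g(259, 1L)[1] != 1L) stop("compressed TIFF not supported")
    wd <- g(256); ht <- g(257); bps <- g(258, 8L)[1]
    if (is.null(wd) || is.null(ht)) stop("malformed TIFF: missing dimensions")
    if (!bps %in% c(8L, 16L)) stop("only 8/16-bit grayscale TIFF supported")
    offs <- g(273); counts <- g(279, wd * ht * bps / 8)
    rps <- g(278, ht)[1]
    px <- numeric(0)
    for (s in seq_along(offs)) {
      nv <- counts[s] / (bps / 8)
      px <- c(px, r_int(offs[s], bps / 8, nv))
    }
    m <- matrix(px, nrow = ht, ncol = wd, byrow = TRUE)
    psz <- pixel_size_um
    if (is.null(psz)) {
      xres <- g(282)  # pixels per unit
      unit <- g(296, 2L)[1]
      psz <- if (!is.null(xres) && xres[1] > 0)
        (if (unit == 3L) 1e4 else 25.4e3) / xres[1] else 1
    }
    slices[[length(slices) + 1]] <- raster_image(m, psz, as.integer(bps))
    ifd_off <- r_int(ifd_off + 2 + n_entries * 12, 4)
  }
  if (length(slices) == 1) slices[[1]] else zstack(slices, step_um)
}

#' Write / read plain PGM (P2 ASCII)
#'
#' Text-only raster format used for small fixtures and debugging.
#'
#' @param img a [raster_image] or [binary_mask].
#' @param path file path.
#' @return `write_pgm`: `path` invisibly; `read_pgm`: a [raster_image].
#' @export
write_pgm <- function(img, path) {
  if (is_binary_mask(img))
    img <- raster_image(img$foreground * 255, img$pixel_size_um, 8)
  maxv <- 2^img$bit_depth - 1
  lines <- c("P2",
             sprintf("# pixel_size_um %.9g", img$pixel_size_um),
             sprintf("%d %d", img_width(img), img_height(img)),
             as.character(maxv),
             apply(round(img$values), 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pgm
#' @param pixel_size_um optional calibration override.
#' @export
read_pgm <- function(path, pixel_size_um = NULL) {
  lines <- readLines(path)
  if (lines[1] != "P2") stop("only ASCII PGM (P2) supported")
  psz <- 1
  body <- lines[-1]
  com <- grepl("^#", body)
  m <- regmatches(body[com], regexec("pixel_size_um\\s+([0-9.eE+-]+)", body[com]))
  for (mm in m) if (length(mm) == 2) psz <- as.numeric(mm[2])
  body <- body[!com]
  dims <- scan(text = body[1], quiet = TRUE)
  maxv <- scan(text = body[2], quiet = TRUE)
  px <- scan(text = paste(body[-(1:2)], collapse = " "), quiet = TRUE)
  m <- matrix(px, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  raster_image(m, if (is.null(pixel_size_um)) psz else pixel_size_um,
               if (maxv > 255) 16 else 8)
}

#' Read a polygon ROI
#'
#' Accepts a JSON file containing a list of `[x, y]` vertices, or an ImageJ
#' `.roi` file of polygon/freehand/polyline type (big-endian binary format).
#'
#' @param path `.json` or `.roi` file.
#' @return A [polygon_roi].
#' @export
read_roi <- function(path) {
  if (grepl("\\.roi$", path, ignore.case = TRUE)) return(read_imagej_roi(path))
  v <- jsonlite::fromJSON(path)
  polygon_roi(as.matrix(v))
}

read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (rawToChar(raw[1:4]) != "Iout") stop("not an ImageJ .roi file")
  u8 <- function(off) as.integer(raw[off + 1])
  s16 <- function(off, n = 1) readBin(raw[(off + 1):(off + 2 * n)], "integer",
                                      n = n, size = 2, endian = "big")
  type <- u8(6)
  if (!type %in% c(0L, 3L, 7L)) # polygon, freeline, freehand
    stop("only polygon-style .roi files supported")
  top <- s16(8); left <- s16(10)
  n <- s16(16)
  if (n < 3) stop("ROI has fewer than 3 vertices")
  xs <- s16(64, n)
  ys <- s16(64 + 2 * n, n)
  polygon_roi(cbind(left + xs, top + ys))
}

#' Write a polygon ROI as JSON
#'
#' @param roi a [polygon_roi].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  jsonlite::write_json(unname(apply(roi$vertices, 1, c, simplify = FALSE)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
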