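# Minimal baseline TIFF support: multi-page, single-sample, 16-bit
# unsigned, uncompressed, little-endian. Enough to exchange section images
# and label masks with ImageJ-style tooling without an external imaging
# dependency. Not a general TIFF reader.

.tif_u16_raw <- function(m) {
  # row-major (TIFF scanline) order, 16-bit little-endian
  v <- as.integer(round(t(m)))
  if (any(v < 0 | v > 65535)) stop("values outside 16-bit range")
  r <- raw(2 * length(v))
  r[seq(1, length(r), 2)] <- as.raw(v %% 256L)
  r[seq(2, length(r), 2)] <- as.raw(v %/% 256L)
  r
}

.tif_entry <- function(tag, type, count, value) {
  # returns 12 raw bytes; value must already fit inline (<= 4 bytes)
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    writeBin(as.integer(value), raw(), size = 4, endian = "little"))
}

#' Write matrices as a multi-page 16-bit TIFF
#'
#' @param pages a matrix or list of numeric matrices with integer values in
#'   \[0, 65535\]. Matrix rows are image rows.
#' @param path output file.
#' @export
write_tiff16 <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  offset <- 8L  # next free byte after header (IFD offset written below)
  # layout per page: pixel data then IFD
  ifd_offsets <- integer(length(pages))
  blobs <- list()
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    dat <- .tif_u16_raw(m)
    data_off <- offset
    ifd_off <- data_off + length(dat)
    if (ifd_off %% 2L == 1L) ifd_off <- ifd_off + 1L  # word-align IFD
    n_entries <- 9L
    entries <- c(
      .tif_entry(256, 3, 1, ncol(m)),              # ImageWidth
      .tif_entry(257, 3, 1, nrow(m)),              # ImageLength
      .tif_entry(258, 3, 1, 16),                   # BitsPerSample
      .tif_entry(259, 3, 1, 1),                    # Compression: none
      .tif_entry(262, 3, 1, 1),                    # Photometric: BlackIsZero
      .tif_entry(273, 4, 1, data_off),             # StripOffsets
      .tif_entry(277, 3, 1, 1),                    # SamplesPerPixel
      .tif_entry(278, 3, 1, nrow(m)),              # RowsPerStrip
      .tif_entry(279, 4, 1, length(dat)))          # StripByteCounts
    ifd <- c(writeBin(n_entries, raw(), size = 2, endian = "little"),
             entries)
    next_off <- ifd_off + 2L + 12L * n_entries + 4L
    blobs[[i]] <- list(dat = dat, pad = ifd_off - (data_off + length(dat)),
                       ifd = ifd, ifd_off = ifd_off)
    ifd_offsets[i] <- ifd_off
    offset <- next_off
  }
  writeBin(as.integer(ifd_offsets[1]), con, size = 4, endian = "little")
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    writeBin(b$dat, con)
    if (b$pad > 0) writeBin(raw(b$pad), con)
    writeBin(b$ifd, con)
    nxt <- if (i < length(blobs)) ifd_offsets[i + 1] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page 16-bit TIFF written by [write_tiff16()]
#'
#' Supports uncompressed little-endian baseline grayscale TIFFs with 8 or
#' 16 bits per sample.
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff16 <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF")
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2)
      val <- if (type == 3) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop("compressed TIFF not supported")
    off <- tags[["273"]]; nbytes <- tags[["279"]]
    bytes <- raw_all[off + seq_len(nbytes)]
    v <- if (bits == 16) {
      readBin(bytes, "integer", n = w * h, size = 2, signed = FALSE,
              endian = "little")
    } else if (bits == 8) {
      as.integer(bytes)
    } else stop("unsupported bit depth: ", bits)
    pages[[length(pages) + 1]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- u32(ifd_off + 2 + 12 * n)
  }
  pages
}

#' Write / read a multichannel section image as multi-page TIFF
#'
#' Pages in channel order DAPI, Fos, Drd1, Drd2 (remappable on read).
#'
#' @param image a [multichannel_image()].
#' @param path TIFF path.
#' @param channel_order names of the four pages on read.
#' @export
write_section_tiff <- function(image, path) {
  write_tiff16(list(image$dapi, image$fos, image$drd1, image$drd2), path)
}

#' @rdname write_section_tiff
#' @export
read_section_tiff <- function(path,
                              channel_order = c("dapi", "fos", "drd1", "drd2"),
                              pixel_size_um = 0.585) {
  pages <- read_tiff16(path)
  if (length(pages) != 4) stop("expected a 4-page TIFF")
  names(pages) <- channel_order
  multichannel_image(pages$dapi, pages$fos, pages$drd1, pages$drd2,
                     pixel_size_um)
}
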