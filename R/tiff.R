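# Minimal multi-page TIFF IO (grayscale, uncompressed, little-endian).
#
# The scientific R stack in this project carries no TIFF package, so movies
# are written with a small baseline-TIFF implementation: 32-bit IEEE float
# (default) or 16-bit unsigned samples, one strip per page. ImageJ/Fiji and
# tifffile read these files directly. The reader supports exactly this
# subset (uncompressed single-sample grayscale, any strip layout).

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_bytes = 279L, sample_format = 339L)

#' Write an image stack as a multi-page TIFF
#'
#' @param stack numeric array `[ny, nx, n_frames]` (or a matrix for a single
#'   page). Values are written as-is for `"float"`, or clamped/rounded to
#'   `0..65535` for `"uint16"`.
#' @param file output file path.
#' @param format `"float"` (32-bit IEEE) or `"uint16"`.
#' @return `file`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(file, stack, format = c("float", "uint16")) {
  format <- match.arg(format)
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stopf("'stack' must be a [ny, nx, n_frames] array")
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  bits <- if (format == "float") 32L else 16L
  bytes_pp <- bits %/% 8L
  page_bytes <- ny * nx * bytes_pp
  ifd_bytes <- 2L + 9L * 12L + 4L

  con <- file(file, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, offset of first IFD (right after all pixel data)
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  data_start <- 8L
  first_ifd <- data_start + nf * page_bytes
  w32(first_ifd)

  for (f in seq_len(nf)) {
    # TIFF rows are y-major: transpose so x varies fastest
    page <- t(stack[, , f])
    if (format == "float") {
      writeBin(as.numeric(page), con, size = 4, endian = "little")
    } else {
      v <- as.integer(pmin(65535, pmax(0, round(page))))
      # writeBin truncates int32 to the low 16 bits, which is exactly the
      # unsigned-short bit pattern for 0..65535
      writeBin(v, con, size = 2, endian = "little")
    }
  }

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    w32(count)
    if (type == 3L) {  # SHORT packed into 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else w32(value)
  }
  for (f in seq_len(nf)) {
    writeBin(9L, con, size = 2, endian = "little")
    entry(TIFF_TAGS["width"], 4L, 1L, nx)
    entry(TIFF_TAGS["height"], 4L, 1L, ny)
    entry(TIFF_TAGS["bits"], 3L, 1L, bits)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_start + (f - 1L) * page_bytes)
    entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, ny)
    entry(TIFF_TAGS["strip_bytes"], 4L, 1L, page_bytes)
    entry(TIFF_TAGS["sample_format"], 3L, 1L, if (format == "float") 3L else 1L)
    next_ifd <- if (f < nf) first_ifd + f * ifd_bytes else 0L
    w32(next_ifd)
  }
  invisible(file)
}

#' Read a multi-page grayscale TIFF into an array
#'
#' Supports the uncompressed single-sample files this package writes
#' (and equivalent files from other tools): 8/16/32-bit unsigned or 32-bit
#' float, little- or big-endian, arbitrary strips.
#'
#' @param file TIFF file path.
#' @return numeric array `[ny, nx, n_frames]`.
#' @export
read_tiff_stack <- function(file) {
  raw_all <- readBin(file, "raw", n = file.info(file)$size)
  endian <- if (rawToChar(raw_all[1:2]) == "II") "little" else "big"
  rint <- function(at, size)
    readBin(raw_all[(at + 1):(at + size)], "integer", size = size,
            endian = endian, signed = size > 2L)
  magic <- rint(2, 2)
  if (magic != 42L) stopf("'%s' is not a TIFF file", file)
  ifd_off <- rint(4, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_ent <- rint(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      at <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rint(at, 2); type <- rint(at + 2, 2); count <- rint(at + 4, 4)
      type_size <- c(1L, 1L, 2L, 4L, 8L)[type]
      if (is.na(type_size)) next
      val_at <- if (count * type_size <= 4L) at + 8L else rint(at + 8, 4)
      vals <- vapply(seq_len(count), function(i)
        rint(val_at + (i - 1L) * type_size, type_size), numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    nx <- g(256L); ny <- g(257L)
    bits <- g(258L, 8L)[1]
    if ((cmp <- g(259L, 1L)) != 1L) stopf("compressed TIFF not supported")
    fmt <- g(339L, 1L)[1]
    offs <- g(273L); cnts <- g(279L)
    buf <- unlist(lapply(seq_along(offs), function(i)
      raw_all[(offs[i] + 1):(offs[i] + cnts[i])]))
    px <- if (fmt == 3L) {
      readBin(buf, "numeric", n = nx * ny, size = 4, endian = endian)
    } else if (bits == 16L) {
      readBin(buf, "integer", n = nx * ny, size = 2, endian = endian,
              signed = FALSE)
    } else if (bits == 8L) {
      as.integer(readBin(buf, "raw", n = nx * ny))
    } else {
      readBin(buf, "integer", n = nx * ny, size = 4, endian = endian)
    }
    pages[[length(pages) + 1L]] <- t(matrix(as.numeric(px), nrow = nx))
    ifd_off <- rint(ifd_off + 2L + n_ent * 12L, 4)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  array(unlist(pages), c(ny, nx, length(pages)))
}
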