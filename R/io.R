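# Minimal uncompressed 8-bit grayscale TIFF I/O.
#
# No TIFF/PNG binding is assumed to be installed, so the baseline format is
# written directly: little-endian header, one IFD, one strip of raw pixel
# data.  The reader handles exactly this profile (uncompressed, 8-bit, single
# sample) which is what every file produced by this package uses.

.tiff_tags <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
                photometric = 262L, strip_offsets = 273L, samples = 277L,
                rows_per_strip = 278L, strip_bytes = 279L)

#' Write a matrix as an uncompressed 8-bit grayscale TIFF
#'
#' @param img numeric matrix; values in \[0, 1\] are scaled to 0..255,
#'   anything else is clamped to that byte range after rounding.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
tiff_write <- function(img, path) {
  img <- as.matrix(img)
  v <- if (max(img) <= 1) round(img * 255) else round(img)
  v[v < 0] <- 0; v[v > 255] <- 255
  h <- nrow(img); w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) { wr2(id); wr2(type); wr4(count); wr4(value) }
  writeChar("II", con, eos = NULL)          # little-endian marker
  wr2(42L)                                  # TIFF magic
  wr4(8L)                                   # offset of first IFD
  n_tags <- 9L
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  wr2(n_tags)                               # IFD entry count
  tag(256L, 4L, 1L, w)                      # ImageWidth
  tag(257L, 4L, 1L, h)                      # ImageLength
  tag(258L, 3L, 1L, 8L)                     # BitsPerSample
  tag(259L, 3L, 1L, 1L)                     # Compression = none
  tag(262L, 3L, 1L, 1L)                     # Photometric = BlackIsZero
  tag(273L, 4L, 1L, data_offset)            # StripOffsets
  tag(277L, 3L, 1L, 1L)                     # SamplesPerPixel
  tag(278L, 4L, 1L, h)                      # RowsPerStrip
  tag(279L, 4L, 1L, h * w)                  # StripByteCounts
  wr4(0L)                                   # no further IFD
  writeBin(as.raw(t(v)), con)               # row-major pixel data
  invisible(path)
}

#' Read an uncompressed 8-bit grayscale TIFF
#'
#' Supports the profile written by [tiff_write()] (and any equivalent
#' single-strip baseline grayscale file).
#'
#' @param path input file path.
#' @return numeric matrix with values in \[0, 1\].
#' @export
tiff_read <- function(path) {
  if (!file.exists(path)) stop("tiff_read: file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("tiff_read: not a TIFF file: ", path)
  endian <- if (raw[1] == as.raw(0x49)) "little" else "big"
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = endian)
  if (u16(2) != 42L) stop("tiff_read: bad TIFF magic in ", path)
  ifd <- u32(4)
  n <- u16(ifd)
  fields <- list()
  for (i in seq_len(n)) {
    off <- ifd + 2L + (i - 1L) * 12L
    id <- u16(off); type <- u16(off + 2L)
    fields[[as.character(id)]] <- if (type == 3L) u16(off + 8L) else u32(off + 8L)
  }
  need <- function(id, default = NULL) {
    v <- fields[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("tiff_read: missing tag ", id, " in ", path)
      default
    } else v
  }
  if (need(259L, 1L) != 1L) stop("tiff_read: only uncompressed TIFF is supported")
  if (need(258L, 8L) != 8L || need(277L, 1L) != 1L)
    stop("tiff_read: only 8-bit single-sample grayscale is supported")
  w <- need(256L); h <- need(257L); strip <- need(273L)
  px <- as.integer(raw[(strip + 1):(strip + h * w)])
  matrix(px, h, w, byrow = TRUE) / 255
}

# ---- flat "key: value" config text ------------------------------------------

#' Write a flat key/value configuration file
#'
#' One `key: value` line per entry (YAML-compatible subset); vectors are
#' comma-separated.
#'
#' @param config a named list (e.g. a [network_config()] or [train_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    paste0(nm, ": ", paste(config[[nm]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' @param path file of `key: value` lines; `#` starts a comment.
#' @return named list with numeric / logical / character values (comma-split
#'   vectors).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(m) != 3) stop("read_config: cannot parse line: ", ln)
    key <- trimws(m[2])
    vals <- trimws(strsplit(m[3], ",")[[1]])
    parsed <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!any(is.na(parsed))) parsed
    else if (all(toupper(vals) %in% c("TRUE", "FALSE"))) as.logical(toupper(vals))
    else vals
  }
  out
}
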