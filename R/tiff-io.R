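# Minimal baseline TIFF 6.0 support: uncompressed little-endian grayscale
# multi-page stacks, 32-bit float or 8/16-bit unsigned. Implemented here
# because no TIFF reader/writer package ships with the analysis stack;
# verified by round-trip tests.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_counts = 279L, sample_format = 339L)

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "little")

# One 12-byte IFD entry; `type` 3 = SHORT, 4 = LONG. Values occupying less
# than 4 bytes sit left-justified in the value field (little-endian).
write_entry <- function(con, tag, type, count, value) {
  write_u16(con, tag); write_u16(con, type); write_u32(con, count)
  if (type == 3L) { write_u16(con, value); write_u16(con, 0L) }
  else write_u32(con, value)
}

#' Write an image stack as a multi-page TIFF
#'
#' Writes one uncompressed grayscale page per frame, 32-bit IEEE float,
#' little-endian, single strip per page.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  n <- d[1]; h <- d[2]; w <- d[3]
  strip_bytes <- h * w * 4L
  n_entries <- 9L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  # layout: 8-byte header, n data strips, n IFDs
  strip_off <- 8L + (seq_len(n) - 1L) * strip_bytes
  ifd_off <- 8L + n * strip_bytes + (seq_len(n) - 1L) * ifd_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  write_u16(con, 42L)
  write_u32(con, ifd_off[1])
  for (f in seq_len(n)) {
    # row-major pixel order
    writeBin(as.numeric(t(matrix(stack$frames[f, , ], h, w))), con,
             size = 4, endian = "little")
  }
  for (f in seq_len(n)) {
    write_u16(con, n_entries)
    write_entry(con, TIFF_TAGS[["width"]], 4L, 1L, w)
    write_entry(con, TIFF_TAGS[["length"]], 4L, 1L, h)
    write_entry(con, TIFF_TAGS[["bits"]], 3L, 1L, 32L)
    write_entry(con, TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    write_entry(con, TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    write_entry(con, TIFF_TAGS[["strip_offsets"]], 4L, 1L, strip_off[f])
    write_entry(con, TIFF_TAGS[["rows_per_strip"]], 4L, 1L, h)
    write_entry(con, TIFF_TAGS[["strip_counts"]], 4L, 1L, strip_bytes)
    write_entry(con, TIFF_TAGS[["sample_format"]], 3L, 1L, 3L)
    write_u32(con, if (f < n) ifd_off[f + 1] else 0L)
  }
  invisible(path)
}

read_tag_values <- function(raw, pos, type, count) {
  # returns the entry's value(s); pos is the 0-based offset of the value field
  size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[[as.character(type)]]
  vals_at <- function(off) {
    vapply(seq_len(count), function(i) {
      b <- raw[(off + (i - 1L) * size + 1L):(off + i * size)]
      sum(as.integer(b) * 256^(seq_len(size) - 1L))
    }, numeric(1))
  }
  if (size * count <= 4L) vals_at(pos)
  else vals_at(sum(as.integer(raw[(pos + 1L):(pos + 4L)]) *
                     256^(0:3)))
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Supports the baseline subset this package writes: uncompressed,
#' little-endian, one sample per pixel, 8/16-bit unsigned or 32-bit float.
#'
#' @param path TIFF file path.
#' @param frame_interval seconds between frames (TIFF does not store it).
#' @return an [image_stack()].
#' @export
read_tiff_stack <- function(path, frame_interval = 1) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[(off + 1L):(off + 2L)]) * 256^(0:1))
  u32 <- function(off) sum(as.integer(raw[(off + 1L):(off + 4L)]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L) {
    stop("not a little-endian TIFF file", call. = FALSE)
  }
  ifd <- u32(4L)
  frames <- list()
  while (ifd != 0) {
    n_entries <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd + 2L + (e - 1L) * 12L
      tag <- u16(base); type <- u16(base + 2L); count <- u32(base + 4L)
      tags[[as.character(tag)]] <- read_tag_values(raw, base + 8L, type, count)
    }
    get_tag <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (is.null(default)) stop(sprintf("missing TIFF tag %d", id),
                                   call. = FALSE)
        default
      } else v
    }
    w <- get_tag(256L); h <- get_tag(257L)
    bits <- get_tag(258L, 8L)
    if (get_tag(259L, 1L) != 1L) {
      stop("compressed TIFF not supported", call. = FALSE)
    }
    fmt <- get_tag(339L, 1L)
    offs <- get_tag(273L); cnts <- get_tag(279L)
    payload <- unlist(lapply(seq_along(offs), function(i) {
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]
    }))
    px <- if (fmt == 3L && bits == 32L) {
      readBin(payload, "numeric", n = w * h, size = 4, endian = "little")
    } else if (fmt == 1L && bits %in% c(8L, 16L)) {
      readBin(payload, "integer", n = w * h, size = bits / 8L,
              signed = FALSE, endian = "little")
    } else {
      stop(sprintf("unsupported TIFF sample format %d / %d bits", fmt, bits),
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- matrix(px, h, w, byrow = TRUE)
    ifd <- u32(ifd + 2L + n_entries * 12L)
  }
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  arr <- array(0, dim = c(length(frames), h, w))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  image_stack(arr, frame_interval = frame_interval)
}
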