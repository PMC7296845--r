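# Minimal baseline TIFF codec: little-endian, uncompressed, 16-bit unsigned
# grayscale, one strip per page. Deliberately narrow — synthetic stacks only.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' Stores each frame as one uncompressed 16-bit unsigned grayscale page
#' (little-endian, single strip). Acquisition metadata (frame interval,
#' position id) goes to a JSON sidecar at `<path>.json`. Normalized
#' (floating, dimensionless) frames are not meant for this format; intensity
#' values must round into `0..65535`.
#'
#' @param stack A [FrameStack][frame_stack].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "FrameStack")) {
    mq_stop("`stack` must be a FrameStack", "mq_validation_error")
  }
  frames <- stack$frames
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  npix <- h * w
  vals <- lapply(frames, function(f) {
    v <- round(as.vector(t(f)))  # TIFF is row-major
    if (any(v < 0) || any(v > 65535)) {
      mq_stop("frame values outside the 16-bit range 0..65535", "mq_format_error")
    }
    as.integer(v)
  })
  n <- length(frames)
  data_off <- 8L + (seq_len(n) - 1L) * (npix * 2L)
  ifd_size <- 2L + 10L * 12L + 4L
  ifd_off <- 8L + n * npix * 2L + (seq_len(n) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wle(42L, 2L)
  wle(ifd_off[1], 4L)
  # pixel data
  for (v in vals) {
    wle(ifelse(v > 32767L, v - 65536L, v), 2L)
  }
  # IFDs
  entry_short <- function(tag, value) { wle(tag, 2L); wle(3L, 2L); wle(1L, 4L); wle(value, 2L); wle(0L, 2L) }
  entry_long <- function(tag, value) { wle(tag, 2L); wle(4L, 2L); wle(1L, 4L); wle(value, 4L) }
  for (p in seq_len(n)) {
    wle(10L, 2L)
    entry_short(TIFF_TAGS[["width"]], w)
    entry_short(TIFF_TAGS[["length"]], h)
    entry_short(TIFF_TAGS[["bits"]], 16L)
    entry_short(TIFF_TAGS[["compression"]], 1L)
    entry_short(TIFF_TAGS[["photometric"]], 1L)
    entry_long(TIFF_TAGS[["strip_offsets"]], data_off[p])
    entry_short(TIFF_TAGS[["samples"]], 1L)
    entry_short(TIFF_TAGS[["rows_per_strip"]], h)
    entry_long(TIFF_TAGS[["strip_bytes"]], npix * 2L)
    entry_short(TIFF_TAGS[["sample_format"]], 1L)
    wle(if (p < n) ifd_off[p + 1L] else 0L, 4L)
  }
  jsonlite::write_json(
    list(frame_interval = stack$frame_interval, position_id = stack$position_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' Counterpart of [write_stack()]: parses little-endian, uncompressed,
#' 16-bit unsigned grayscale multi-page TIFFs (one or more strips per
#' page). All pages must share dimensions. Metadata is taken from the
#' `<path>.json` sidecar when present. Malformed or truncated files raise a
#' format error naming the failing page; no partial stack is ever returned.
#'
#' @param path TIFF file path.
#' @param frame_interval,position_id Fallbacks when no sidecar exists.
#' @return A [FrameStack][frame_stack].
#' @export
read_stack <- function(path, frame_interval = 15, position_id = NULL) {
  if (!file.exists(path)) {
    mq_stop(sprintf("file not found: %s", path), "mq_format_error")
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) {
    if (off + 1L > length(raw)) mq_stop("truncated TIFF", "mq_format_error")
    as.integer(raw[off]) + 256L * as.integer(raw[off + 1L])
  }
  u32 <- function(off) {
    if (off + 3L > length(raw)) mq_stop("truncated TIFF", "mq_format_error")
    as.integer(raw[off]) + 256 * as.integer(raw[off + 1L]) +
      65536 * as.integer(raw[off + 2L]) + 16777216 * as.integer(raw[off + 3L])
  }
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" || u16(3L) != 42L) {
    mq_stop("not a little-endian TIFF", "mq_format_error")
  }
  frames <- list()
  ifd_off <- u32(5L)
  page <- 0L
  while (ifd_off != 0) {
    page <- page + 1L
    n_entries <- u16(ifd_off + 1L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2L + (e - 1L) * 12L + 1L
      tag <- u16(base); type <- u16(base + 2L); count <- u32(base + 4L)
      vals <- if (type == 3L && count <= 2L) {
        vapply(seq_len(count), function(i) u16(base + 8L + 2L * (i - 1L)), integer(1))
      } else if (type == 4L && count == 1L) {
        u32(base + 8L)
      } else if (type %in% c(3L, 4L)) {
        off <- u32(base + 8L)
        step <- if (type == 3L) 2L else 4L
        rd <- if (type == 3L) u16 else u32
        vapply(seq_len(count), function(i) as.integer(rd(off + step * (i - 1L) + 1L)),
               integer(1))
      } else NULL
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v) && is.null(default)) {
        mq_stop(sprintf("page %d: missing required TIFF tag %d", page, tag),
                "mq_format_error", page = page)
      }
      if (is.null(v)) default else v
    }
    w <- need(TIFF_TAGS[["width"]]); h <- need(TIFF_TAGS[["length"]])
    if (need(TIFF_TAGS[["compression"]], 1L)[1] != 1L) {
      mq_stop(sprintf("page %d: only uncompressed TIFF is supported", page),
              "mq_format_error", page = page)
    }
    if (any(need(TIFF_TAGS[["bits"]], 16L) != 16L)) {
      mq_stop(sprintf("page %d: only 16-bit samples are supported", page),
              "mq_format_error", page = page)
    }
    offs <- need(TIFF_TAGS[["strip_offsets"]])
    byts <- need(TIFF_TAGS[["strip_bytes"]])
    if (sum(byts) != 2L * w * h) {
      mq_stop(sprintf("page %d: strip byte counts do not match dimensions", page),
              "mq_format_error", page = page)
    }
    px <- integer(0)
    for (s in seq_along(offs)) {
      lo <- offs[s] + 1L; hi <- offs[s] + byts[s]
      if (hi > length(raw)) {
        mq_stop(sprintf("page %d: truncated pixel data", page), "mq_format_error",
                page = page)
      }
      seg <- raw[lo:hi]
      px <- c(px, readBin(seg, "integer", n = byts[s] / 2L, size = 2L,
                          signed = FALSE, endian = "little"))
    }
    frames[[page]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- u32(ifd_off + 2L + n_entries * 12L + 1L)
  }
  if (length(frames) == 0L) mq_stop("TIFF contains no pages", "mq_format_error")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    mq_stop("ragged TIFF: pages differ in dimensions", "mq_format_error")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$frame_interval)) frame_interval <- meta$frame_interval
    if (is.null(position_id) && !is.null(meta$position_id)) position_id <- meta$position_id
  }
  if (is.null(position_id)) position_id <- sub("\\.[^.]*$", "", basename(path))
  frame_stack(lapply(frames, function(f) f + 0.0), frame_interval, position_id)
}
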