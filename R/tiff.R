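## Minimal classic-TIFF reader/writer: little-endian, uncompressed,
## single-sample 32-bit IEEE float, multi-page, one strip per page. This is
## the interchange format for all image stacks in the package. No R TIFF
## binding is available in the supported environment, so the codec is
## implemented here against the TIFF 6.0 baseline; the reader accepts the
## writer's dialect plus single-strip/multi-strip variants of the same
## pixel format.

tiff_tag <- function(con, id, type, count, value) {
  ## type: 3 = SHORT, 4 = LONG, 2 = ASCII
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write an image or stack as a 32-bit float multi-page TIFF
#'
#' @param x Numeric matrix (y, x) or array (y, x, pages).
#' @param path Output file path.
#' @param description Optional character scalar stored in the
#'   ImageDescription tag of the first page (the package stores JSON
#'   metadata such as channel names and units here).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, description = NULL) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  ny <- dim(x)[1]; nx <- dim(x)[2]; np <- dim(x)[3]
  storage.mode(x) <- "double"
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  desc <- if (!is.null(description)) {
    d <- charToRaw(as.character(description))
    c(d, as.raw(0))
  } else NULL
  page_bytes <- ny * nx * 4
  n_desc <- if (is.null(desc)) 0L else length(desc)
  ## layout: header(8) | desc | page data ... | IFDs
  desc_off <- 8L
  data_off <- desc_off + n_desc
  ifd0_off <- data_off + np * page_bytes
  writeBin(as.integer(ifd0_off), con, size = 4, endian = "little")
  if (!is.null(desc)) writeBin(desc, con)
  for (k in seq_len(np))
    writeBin(as.numeric(t(x[, , k])), con, size = 4, endian = "little")
  n_tags_first <- if (is.null(desc)) 10L else 11L
  ifd_size <- function(ntags) 2L + ntags * 12L + 4L
  off <- ifd0_off
  for (k in seq_len(np)) {
    ntags <- if (k == 1L) n_tags_first else 10L
    writeBin(as.integer(ntags), con, size = 2, endian = "little")
    tiff_tag(con, 256, 4, 1, nx)
    tiff_tag(con, 257, 4, 1, ny)
    tiff_tag(con, 258, 3, 1, 32)
    tiff_tag(con, 259, 3, 1, 1)
    tiff_tag(con, 262, 3, 1, 1)
    if (k == 1L && !is.null(desc))
      tiff_tag(con, 270, 2, n_desc, desc_off)
    tiff_tag(con, 273, 4, 1, data_off + (k - 1L) * page_bytes)
    tiff_tag(con, 277, 3, 1, 1)
    tiff_tag(con, 278, 4, 1, ny)
    tiff_tag(con, 279, 4, 1, page_bytes)
    tiff_tag(con, 339, 3, 1, 3)
    nxt <- if (k < np) off + ifd_size(ntags) else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
    off <- off + ifd_size(ntags)
  }
  invisible(path)
}

read_u <- function(raw, off, size) {
  ## little-endian unsigned integer at byte offset `off` (0-based)
  b <- as.integer(raw[(off + 1):(off + size)])
  sum(b * 256^(0:(size - 1)))
}

#' Read a multi-page float TIFF written by [write_tiff()]
#'
#' Supports the package dialect: little-endian, uncompressed, one sample
#' per pixel, 32-bit IEEE float (SampleFormat 3), any number of strips.
#'
#' @param path TIFF file path.
#' @return Array (y, x, pages) with attribute `"description"` if present.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || read_u(raw, 2, 2) != 42)
    stop("not a little-endian classic TIFF: ", path)
  ifd_off <- read_u(raw, 4, 4)
  pages <- list(); desc <- NULL
  while (ifd_off != 0) {
    ntags <- read_u(raw, ifd_off, 2)
    tags <- list()
    for (i in seq_len(ntags)) {
      toff <- ifd_off + 2 + (i - 1) * 12
      id <- read_u(raw, toff, 2)
      type <- read_u(raw, toff + 2, 2)
      count <- read_u(raw, toff + 4, 4)
      tsize <- c(1, 1, 2, 4, 8)[type]
      nbytes <- tsize * count
      voff <- if (nbytes <= 4) toff + 8 else read_u(raw, toff + 8, 4)
      vals <- if (type == 2) {
        rawToChar(raw[(voff + 1):(voff + count - 1)])
      } else {
        vapply(seq_len(count), function(j)
          read_u(raw, voff + (j - 1) * tsize, tsize), numeric(1))
      }
      tags[[as.character(id)]] <- vals
    }
    need <- function(id) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) stop("missing TIFF tag ", id)
      v
    }
    nx <- need(256); ny <- need(257)
    bits <- tags[["258"]] %||% 1
    comp <- tags[["259"]] %||% 1
    fmt <- tags[["339"]] %||% 1
    if (comp != 1) stop("unsupported TIFF compression ", comp)
    if (!(bits == 32 && fmt == 3))
      stop("unsupported TIFF pixel format (need 32-bit float)")
    if ((tags[["277"]] %||% 1) != 1)
      stop("unsupported TIFF: multiple samples per pixel")
    offs <- need(273); cnts <- need(279)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    vals <- readBin(buf, what = "numeric", n = nx * ny, size = 4,
                    endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = ny, ncol = nx,
                                          byrow = TRUE)
    if (is.null(desc) && !is.null(tags[["270"]])) desc <- tags[["270"]]
    ifd_off <- read_u(raw, ifd_off + 2 + ntags * 12, 4)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- array(unlist(pages), c(ny, nx, length(pages)))
  if (!is.null(desc)) attr(out, "description") <- desc
  out
}

#' Write a five-channel polarization acquisition to TIFF
#'
#' Two on-disk dialects: `"single"` writes one multi-page file with pages
#' ordered channel-major (all z of RCP, then all z of 0, ...) and a JSON
#' ImageDescription recording dimensions and channel names; `"per_channel"`
#' writes one z-stack file per channel named `<stem>_<channel>.tif`.
#'
#' @param stack A `polarization_stack`, dim (ny, nx, nz, 5).
#' @param path Output path (for `"per_channel"`, the stem; `.tif` is
#'   appended per channel).
#' @param dialect "single" or "per_channel".
#' @return Character vector of file(s) written, invisibly.
#' @export
write_polarization_tiff <- function(stack, path,
                                    dialect = c("single", "per_channel")) {
  dialect <- match.arg(dialect)
  stack <- as_stack(stack, 5L, "polarization stack")
  d <- dim(stack)
  stopifnot(length(d) == 4L)
  if (dialect == "single") {
    pages <- array(stack, c(d[1], d[2], d[3] * 5L))
    meta <- jsonlite::toJSON(list(kind = "polarization_stack",
                                  ny = d[1], nx = d[2], nz = d[3],
                                  channels = channel_names(),
                                  page_order = "channel_major"),
                             auto_unbox = TRUE)
    write_tiff(pages, path, description = as.character(meta))
    return(invisible(path))
  }
  stem <- sub("\\.tiff?$", "", path)
  files <- character(5)
  for (ch in 1:5) {
    files[ch] <- paste0(stem, "_", channel_names()[ch], ".tif")
    meta <- jsonlite::toJSON(list(kind = "polarization_channel",
                                  channel = channel_names()[ch]),
                             auto_unbox = TRUE)
    write_tiff(array(stack[, , , ch], d[1:3]), files[ch],
               description = as.character(meta))
  }
  invisible(files)
}

#' Read a five-channel polarization acquisition from TIFF
#'
#' Accepts either dialect of [write_polarization_tiff()]: a single file
#' (channel-major pages, JSON metadata) or a character vector of five
#' per-channel files ordered RCP, 0, 45, 90, 135.
#'
#' @param path One file, or five per-channel files.
#' @return A `polarization_stack` (ny, nx, nz, 5).
#' @export
read_polarization_tiff <- function(path) {
  if (length(path) == 5L) {
    chans <- lapply(path, read_tiff)
    d <- dim(chans[[1]])
    out <- array(0, c(d, 5L))
    for (ch in 1:5) out[, , , ch] <- chans[[ch]]
    return(polarization_stack(out))
  }
  x <- read_tiff(path)
  desc <- attr(x, "description")
  if (is.null(desc)) stop("missing stack metadata in TIFF description")
  meta <- jsonlite::fromJSON(desc)
  if (!identical(meta$kind, "polarization_stack") ||
      !identical(as.character(meta$channels), channel_names()))
    stop("file does not contain a five-channel stack in RCP/0/45/90/135 ",
         "order")
  nz <- meta$nz
  polarization_stack(array(x, c(dim(x)[1], dim(x)[2], nz, 5L)))
}

#' Write a property map with units metadata
#'
#' Single-channel 32-bit float TIFF; `units` is recorded in the JSON
#' ImageDescription (e.g. "radians" for phase and retardance maps).
#'
#' @param x Matrix or (y, x, z) array.
#' @param path Output path.
#' @param units Units string.
#' @param name Quantity name.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(x, path, units = "dimensionless",
                           name = "map") {
  meta <- jsonlite::toJSON(list(kind = "map", name = name, units = units),
                           auto_unbox = TRUE)
  write_tiff(x, path, description = as.character(meta))
}
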