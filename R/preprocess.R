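#' Flat-field correction
#'
#' Divides an image by a normalized illumination estimate: a provided
#' blank (flat) image is used directly; absent one, a heavy Gaussian blur
#' (sigma = 50 px by default) of the image itself serves as the low-pass
#' estimate. The estimate is normalized to unit mean so the corrected
#' image keeps its intensity scale.
#'
#' @param img Matrix or (y, x, z) array.
#' @param flat Optional flat (blank) image, matrix.
#' @param sigma Blur scale in pixels for the self-estimate.
#' @return Corrected array, same shape.
#' @export
flat_field_correct <- function(img, flat = NULL, sigma = 50) {
  one <- function(im) {
    ff <- if (is.null(flat)) gauss_blur(im, sigma) else flat
    ff <- ff / mean(ff)
    im / pmax(ff, 1e-6)
  }
  if (is.matrix(img)) return(one(img))
  out <- img
  for (k in seq_len(dim(img)[3])) out[, , k] <- one(img[, , k])
  out
}

interp_matrix <- function(n, m) {
  ## linear interpolation matrix (m x n) with endpoints aligned
  pos <- seq(0, n - 1, length.out = m)
  lo <- pmin(floor(pos), n - 2); w <- pos - lo
  M <- matrix(0, m, n)
  M[cbind(seq_len(m), lo + 1)] <- M[cbind(seq_len(m), lo + 1)] + (1 - w)
  M[cbind(seq_len(m), lo + 2)] <- M[cbind(seq_len(m), lo + 2)] + w
  M
}

#' Linear z-upsampling of a volume
#'
#' Interpolates along z to `n_out` planes (endpoints aligned); used to
#' match the axial and lateral pixel sizes before 3D training.
#'
#' @param vol Array (y, x, z) with z >= 2.
#' @param n_out Target number of planes.
#' @return Array (y, x, n_out).
#' @export
upsample_z_linear <- function(vol, n_out) {
  stopifnot(length(dim(vol)) == 3L, dim(vol)[3] >= 2L, n_out >= 2L)
  apply_axis_mat(vol, interp_matrix(dim(vol)[3], n_out), 3L)
}

#' Cut a volume pair into training tiles with foreground filtering
#'
#' Tiles the input/target pair on the scheme's grid (50% overlap for
#' 2D/2.5D over XY per z-plane window, 25% XYZ overlap for 3D) and keeps a
#' tile iff the fraction of foreground pixels in its target is at least
#' the scheme threshold (inclusive). Foreground is an Otsu mask of the
#' whole target volume by default.
#'
#' @param input Array (ny, nx, nz, C).
#' @param target Array (ny, nx, nz).
#' @param scheme A [tiling_scheme()].
#' @param mask Optional logical foreground mask (ny, nx, nz); computed by
#'   Otsu thresholding of `target` when NULL.
#' @param n_slices z-window per tile for the 2.5D variant.
#' @return List with `x` (tiles, batch last), `y`, `mask` (tile foreground
#'   weights), `kept` (logical over candidate tiles), `positions` (data
#'   frame of tile origins).
#' @export
preprocess_dataset <- function(input, target, scheme, mask = NULL,
                               n_slices = 5L) {
  stopifnot(inherits(scheme, "tiling_scheme"))
  d <- dim(input); ny <- d[1]; nx <- d[2]; nz <- d[3]; C <- d[4]
  if (!all(dim(target) == d[1:3]))
    stop("input and target are not registered: shapes differ")
  if (is.null(mask)) mask <- foreground_mask(target, "otsu")
  tl <- scheme$tile
  stride <- pmax(1L, as.integer(round(tl * (1 - scheme$overlap_frac))))
  if (scheme$variant %in% c("2D", "2.5D")) {
    sy <- tile_positions(ny, tl[1], stride[1])
    sx <- tile_positions(nx, tl[2], stride[2])
    N <- if (scheme$variant == "2.5D") n_slices else 1L
    half <- (N - 1L) %/% 2L
    zc <- seq_len(nz)
    cand <- expand.grid(y = sy, x = sx, z = zc)
    xs <- list(); ysl <- list(); msl <- list(); kept <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      iy <- cand$y[r]:(cand$y[r] + tl[1] - 1L)
      ix <- cand$x[r]:(cand$x[r] + tl[2] - 1L)
      k <- cand$z[r]
      frac <- mean(mask[iy, ix, k])
      kept[r] <- frac >= scheme$foreground_fraction
      if (!kept[r]) next
      if (scheme$variant == "2D") {
        xs[[length(xs) + 1L]] <- array(input[iy, ix, k, ],
                                       c(tl[1], tl[2], C))
      } else {
        zp <- pad_reflect_axis(input, 3L, half, half)
        win <- zp[iy, ix, k:(k + N - 1L), , drop = FALSE]
        xs[[length(xs) + 1L]] <- array(win, c(tl[1], tl[2], N, C))
      }
      ysl[[length(ysl) + 1L]] <- array(target[iy, ix, k], c(tl[1], tl[2], 1L))
      msl[[length(msl) + 1L]] <- array(mask[iy, ix, k] * 1,
                                       c(tl[1], tl[2], 1L))
    }
    nkept <- sum(kept)
    if (nkept == 0L)
      return(list(x = NULL, y = NULL, mask = NULL, kept = kept,
                  positions = cand))
    xdim <- if (scheme$variant == "2D") c(tl[1], tl[2], C, nkept)
            else c(tl[1], tl[2], N, C, nkept)
    list(x = array(unlist(xs), xdim),
         y = array(unlist(ysl), c(tl[1], tl[2], 1L, nkept)),
         mask = array(unlist(msl), c(tl[1], tl[2], 1L, nkept)),
         kept = kept, positions = cand)
  } else {
    sy <- tile_positions(ny, min(tl[1], ny), max(1L, stride[1]))
    sx <- tile_positions(nx, min(tl[2], nx), max(1L, stride[2]))
    sz <- tile_positions(nz, min(tl[3], nz), max(1L, stride[3]))
    t1 <- min(tl[1], ny); t2 <- min(tl[2], nx); t3 <- min(tl[3], nz)
    cand <- expand.grid(y = sy, x = sx, z = sz)
    xs <- list(); ysl <- list(); msl <- list(); kept <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      iy <- cand$y[r]:(cand$y[r] + t1 - 1L)
      ix <- cand$x[r]:(cand$x[r] + t2 - 1L)
      iz <- cand$z[r]:(cand$z[r] + t3 - 1L)
      frac <- mean(mask[iy, ix, iz])
      kept[r] <- frac >= scheme$foreground_fraction
      if (!kept[r]) next
      xs[[length(xs) + 1L]] <- array(input[iy, ix, iz, ], c(t1, t2, t3, C))
      ysl[[length(ysl) + 1L]] <- array(target[iy, ix, iz],
                                       c(t1, t2, t3, 1L))
      msl[[length(msl) + 1L]] <- array(mask[iy, ix, iz] * 1,
                                       c(t1, t2, t3, 1L))
    }
    nkept <- sum(kept)
    if (nkept == 0L)
      return(list(x = NULL, y = NULL, mask = NULL, kept = kept,
                  positions = cand))
    list(x = array(unlist(xs), c(t1, t2, t3, C, nkept)),
         y = array(unlist(ysl), c(t1, t2, t3, 1L, nkept)),
         mask = array(unlist(msl), c(t1, t2, t3, 1L, nkept)),
         kept = kept, positions = cand)
  }
}

#' Per-dataset foreground median/IQR normalization statistics
#'
#' For each channel, computes the median and inter-quartile range (25% to
#' 75% quantiles) of the FOREGROUND pixel intensities pooled over the
#' dataset. Background pixels do not influence the statistics, and the
#' normalization is per dataset (not per image), which preserves relative
#' intensities across fields of view.
#'
#' @param volumes A single array (..., C) or a list of such arrays (the
#'   dataset).
#' @param masks Logical foreground mask(s) matching the spatial dims of
#'   each volume.
#' @param channels Optional channel names.
#' @return Object of class `normalization_stats`: list with `median`,
#'   `iqr` (per channel) and `channels`.
#' @export
fit_normalization <- function(volumes, masks, channels = NULL) {
  if (!is.list(volumes)) { volumes <- list(volumes); masks <- list(masks) }
  C <- dim(volumes[[1]])[length(dim(volumes[[1]]))]
  pool <- vector("list", C)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]; m <- as.logical(masks[[i]])
    d <- dim(v)
    vm <- matrix(v, ncol = C)
    for (ch in seq_len(C))
      pool[[ch]] <- c(pool[[ch]], vm[m, ch])
  }
  med <- vapply(pool, stats::median, numeric(1))
  iqr <- vapply(pool, function(v)
    diff(stats::quantile(v, c(0.25, 0.75), names = FALSE)), numeric(1))
  if (any(iqr == 0))
    stop("degenerate channel: zero inter-quartile range in channel(s) ",
         paste(which(iqr == 0), collapse = ", "))
  structure(list(median = med, iqr = iqr,
                 channels = channels %||% paste0("ch", seq_len(C))),
            class = "normalization_stats")
}

#' Apply (x - median) / IQR normalization per channel
#'
#' @param x Array with the channel axis last (or matching `stats` length 1
#'   for a single-channel volume without an explicit channel axis).
#' @param stats A `normalization_stats` (or a single-channel slice of one).
#' @return Normalized array, same shape.
#' @export
apply_normalization <- function(x, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  C <- length(stats$median)
  d <- dim(x)
  if (C == 1L && (is.null(d) || d[length(d)] != 1L)) {
    return((x - stats$median) / stats$iqr)
  }
  stopifnot(d[length(d)] == C)
  m <- matrix(x, ncol = C)
  m <- sweep(sweep(m, 2, stats$median), 2, stats$iqr, `/`)
  array(m, d)
}

#' Invert the median/IQR normalization exactly
#'
#' @param x Normalized array.
#' @param stats The `normalization_stats` used to normalize.
#' @return Array on the original intensity scale.
#' @export
invert_normalization <- function(x, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  C <- length(stats$median)
  d <- dim(x)
  if (C == 1L && (is.null(d) || d[length(d)] != 1L)) {
    return(x * stats$iqr + stats$median)
  }
  stopifnot(d[length(d)] == C)
  m <- matrix(x, ncol = C)
  m <- sweep(sweep(m, 2, stats$iqr, `*`), 2, stats$median, `+`)
  array(m, d)
}

#' Select one channel of a `normalization_stats`
#'
#' @param stats A `normalization_stats`.
#' @param channel Channel index or name.
#' @return Single-channel `normalization_stats`.
#' @export
stats_channel <- function(stats, channel) {
  stopifnot(inherits(stats, "normalization_stats"))
  i <- if (is.character(channel)) match(channel, stats$channels)
       else as.integer(channel)
  structure(list(median = stats$median[i], iqr = stats$iqr[i],
                 channels = stats$channels[i]),
            class = "normalization_stats")
}
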