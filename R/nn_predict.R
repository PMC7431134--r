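#' Tiling scheme for training patches and stitched inference
#'
#' Published defaults: 256 x 256 training tiles with 50% overlap for
#' 2D/2.5D and 128 x 128 x 96 tiles with 25% overlap for 3D; tiled
#' inference uses 512 x 512 XY tiles (full z) with a 32-pixel overlap and
#' linear blending.
#'
#' @param variant "2D", "2.5D" or "3D".
#' @param tile Training tile size (2 or 3 extents).
#' @param overlap_frac Training overlap fraction.
#' @param inference_tile XY tile for stitched inference.
#' @param inference_overlap Overlap in pixels for stitched inference.
#' @param foreground_fraction Minimum target-foreground fraction for a
#'   training tile to be kept (inclusive); 0.2 for 2D/2.5D, 0.5 for 3D.
#' @return Object of class `tiling_scheme`.
#' @export
tiling_scheme <- function(variant = c("2D", "2.5D", "3D"), tile = NULL,
                          overlap_frac = NULL, inference_tile = 512L,
                          inference_overlap = 32L,
                          foreground_fraction = NULL) {
  variant <- match.arg(variant)
  if (is.null(tile)) tile <- if (variant == "3D") c(128L, 128L, 96L)
                             else c(256L, 256L)
  if (is.null(overlap_frac)) overlap_frac <- if (variant == "3D") 0.25
                                             else 0.50
  if (is.null(foreground_fraction))
    foreground_fraction <- if (variant == "3D") 0.5 else 0.2
  stopifnot(overlap_frac >= 0, overlap_frac < 1)
  structure(list(variant = variant, tile = as.integer(tile),
                 overlap_frac = overlap_frac,
                 inference_tile = as.integer(inference_tile),
                 inference_overlap = as.integer(inference_overlap),
                 foreground_fraction = foreground_fraction),
            class = "tiling_scheme")
}

#' Tile start positions along one axis
#'
#' Regular grid with the given stride; a final clamped position is added
#' when needed so the last tile ends exactly at `n`.
#'
#' @param n Axis extent.
#' @param tile Tile extent (<= n).
#' @param stride Step between tile starts (tile - overlap).
#' @return Integer vector of 1-based start positions.
#' @export
tile_positions <- function(n, tile, stride) {
  stopifnot(tile <= n, stride >= 1L)
  starts <- seq(1L, n - tile + 1L, by = stride)
  if (starts[length(starts)] + tile - 1L < n)
    starts <- c(starts, n - tile + 1L)
  as.integer(starts)
}

tile_weight_1d <- function(tile, ov_left, ov_right) {
  w <- rep(1, tile)
  if (ov_left > 0)
    w[seq_len(ov_left)] <- seq_len(ov_left) / (ov_left + 1)
  if (ov_right > 0)
    w[tile - seq_len(ov_right) + 1L] <- seq_len(ov_right) / (ov_right + 1)
  w
}

#' Normalized linear blend-weight fields for a set of tiles
#'
#' Each tile gets a separable weight that ramps linearly across the overlap
#' with its neighbours; weights are then normalized so that at every pixel
#' the weights of all covering tiles sum exactly to 1 (partition of unity).
#'
#' @param full Full image extent per axis (integer vector).
#' @param tile Tile extent per axis.
#' @param starts List (per axis) of tile start positions, as from
#'   [tile_positions()].
#' @return List with `weights` (list over tiles, each an array of the tile
#'   shape) and `grid` (data frame of tile start coordinates, one row per
#'   tile, axes as columns).
#' @export
blend_weights <- function(full, tile, starts) {
  nd <- length(full)
  stopifnot(length(tile) == nd, length(starts) == nd)
  axis_w <- lapply(seq_len(nd), function(ax) {
    st <- starts[[ax]]
    lapply(seq_along(st), function(i) {
      ov_l <- if (i == 1L) 0L else max(0L, st[i - 1L] + tile[ax] - st[i])
      ov_r <- if (i == length(st)) 0L
              else max(0L, st[i] + tile[ax] - st[i + 1L])
      tile_weight_1d(tile[ax], ov_l, ov_r)
    })
  })
  grid <- do.call(expand.grid, lapply(starts, identity))
  names(grid) <- paste0("ax", seq_len(nd))
  gi <- do.call(expand.grid, lapply(starts, seq_along))
  weights <- lapply(seq_len(nrow(grid)), function(r) {
    w <- axis_w[[1L]][[gi[r, 1L]]]
    out <- w
    if (nd >= 2L) out <- outer(out, axis_w[[2L]][[gi[r, 2L]]])
    if (nd >= 3L) out <- outer(out, axis_w[[3L]][[gi[r, 3L]]])
    array(out, tile)
  })
  ## normalize to an exact partition of unity
  acc <- array(0, full)
  for (r in seq_len(nrow(grid))) {
    idx <- lapply(seq_len(nd), function(ax)
      grid[r, ax] + seq_len(tile[ax]) - 1L)
    acc <- do.call(`[<-`, c(list(acc), idx,
                            list(do.call(`[`, c(list(acc), idx)) +
                                   weights[[r]])))
  }
  for (r in seq_len(nrow(grid))) {
    idx <- lapply(seq_len(nd), function(ax)
      grid[r, ax] + seq_len(tile[ax]) - 1L)
    weights[[r]] <- weights[[r]] / do.call(`[`, c(list(acc), idx))
  }
  list(weights = weights, grid = grid)
}

#' Stitch overlapping tiles with linear blending
#'
#' @param tiles List of tile arrays (all of shape `tile`).
#' @param full Full extent per axis.
#' @param tile Tile extent per axis.
#' @param starts List (per axis) of start positions; tiles must be ordered
#'   as the rows of `expand.grid(starts)` (first axis fastest).
#' @return Stitched array of extent `full`.
#' @export
stitch_tiles <- function(tiles, full, tile, starts) {
  bw <- blend_weights(full, tile, starts)
  nd <- length(full)
  out <- array(0, full)
  for (r in seq_len(nrow(bw$grid))) {
    idx <- lapply(seq_len(nd), function(ax)
      bw$grid[r, ax] + seq_len(tile[ax]) - 1L)
    cur <- do.call(`[`, c(list(out), idx))
    out <- do.call(`[<-`, c(list(out), idx,
                            list(cur + tiles[[r]] * bw$weights[[r]])))
  }
  out
}

pad_reflect_axis <- function(x, axis, before, after) {
  d <- dim(x)
  n <- d[axis]
  if (before == 0 && after == 0) return(x)
  if (n == 1L) {
    idx <- rep(1L, before + n + after)
  } else {
    ## reflect without repeating the edge sample (period 2(n-1))
    refl <- function(k) {
      m <- 2L * (n - 1L)
      k <- ((k - 1L) %% m)
      ifelse(k < n, k + 1L, m - k + 1L)
    }
    idx <- refl(seq(1L - before, n + after))
  }
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

#' Predict a fluorescence volume from a label-free stack
#'
#' Runs a trained model over a full volume. 2D and 2.5D variants are fully
#' convolutional and run on whole XY planes (padded by reflection to the
#' next multiple the encoder depth supports, then cropped); the 2.5D
#' variant slides its N-slice window along z with reflect padding so the
#' output z-extent equals the input's. The 3D variant tiles XY with the
#' scheme's inference overlap, keeps the full z extent, and stitches with
#' linear blending. When normalization statistics are supplied the input
#' channels are normalized before the forward pass and the output is
#' mapped back to the original intensity scale.
#'
#' @param model A trained `unet_model`.
#' @param stack Label-free input, array (ny, nx, nz, C) with C equal to the
#'   model's input channels.
#' @param stats Optional [fit_normalization()] statistics: input channels
#'   are normalized with `stats$input`, and the output is de-normalized
#'   with `stats$target`.
#' @param scheme A [tiling_scheme()] (3D inference tiling); defaults to the
#'   variant's defaults.
#' @return Predicted volume, array (ny, nx, nz), on the original intensity
#'   scale when `stats` is given.
#' @export
predict_volume <- function(model, stack, stats = NULL, scheme = NULL) {
  spec <- model$spec
  d <- dim(stack)
  stopifnot(length(d) == 4L)
  if (d[4] != spec$in_channels)
    stop("stack has ", d[4], " channels but the model (and its ",
         "normalization statistics) expect ", spec$in_channels)
  if (is.null(scheme)) scheme <- tiling_scheme(spec$variant)
  if (!is.null(stats)) stack <- apply_normalization(stack, stats$input)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  L <- length(spec$filters); div <- 2L^(L - 1L)
  pad_to <- function(n) as.integer(ceiling(max(n, 2L * div) / div) * div)
  out <- array(0, c(ny, nx, nz))
  if (spec$variant == "2D") {
    py <- pad_to(ny) - ny; px <- pad_to(nx) - nx
    for (k in seq_len(nz)) {
      x <- array(stack[, , k, ], c(ny, nx, d[4], 1L))
      x <- pad_reflect_axis(pad_reflect_axis(x, 1L, 0L, py), 2L, 0L, px)
      pr <- nn_forward(model, x, training = FALSE)$out
      out[, , k] <- pr[seq_len(ny), seq_len(nx), 1L, 1L]
    }
  } else if (spec$variant == "2.5D") {
    N <- spec$n_slices; half <- (N - 1L) %/% 2L
    py <- pad_to(ny) - ny; px <- pad_to(nx) - nx
    zpad <- pad_reflect_axis(stack, 3L, half, half)
    for (k in seq_len(nz)) {
      win <- zpad[, , k:(k + N - 1L), , drop = FALSE]
      x <- array(win, c(ny, nx, N, d[4], 1L))
      x <- pad_reflect_axis(pad_reflect_axis(x, 1L, 0L, py), 2L, 0L, px)
      pr <- nn_forward(model, x, training = FALSE)$out
      out[, , k] <- pr[seq_len(ny), seq_len(nx), 1L, 1L]
    }
  } else {
    tl <- min(scheme$inference_tile, pad_to(ny), pad_to(nx))
    tl <- as.integer(floor(tl / div) * div)
    pz <- pad_to(nz) - nz
    ypad <- pad_to(ny) - ny; xpad <- pad_to(nx) - nx
    xs <- pad_reflect_axis(pad_reflect_axis(pad_reflect_axis(
      stack, 1L, 0L, ypad), 2L, 0L, xpad), 3L, 0L, pz)
    dp <- dim(xs)
    ov <- scheme$inference_overlap
    sy <- tile_positions(dp[1], min(tl, dp[1]), max(1L, min(tl, dp[1]) - ov))
    sx <- tile_positions(dp[2], min(tl, dp[2]), max(1L, min(tl, dp[2]) - ov))
    tiles <- list(); r <- 0L
    for (jx in sx) for (jy in sy) {
      r <- r + 1L
      xt <- xs[jy:(jy + min(tl, dp[1]) - 1L), jx:(jx + min(tl, dp[2]) - 1L),
               , , drop = FALSE]
      x <- array(xt, c(dim(xt)[1:3], d[4], 1L))
      pr <- nn_forward(model, x, training = FALSE)$out
      tiles[[r]] <- array(pr[, , , 1L, 1L], dim(pr)[1:3])
    }
    full <- stitch_tiles(tiles, dp[1:3],
                         c(min(tl, dp[1]), min(tl, dp[2]), dp[3]),
                         list(sy, sx, 1L))
    out <- full[seq_len(ny), seq_len(nx), seq_len(nz), drop = FALSE]
    dim(out) <- c(ny, nx, nz)
  }
  if (!is.null(stats)) out <- invert_normalization(out, stats$target)
  out
}
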