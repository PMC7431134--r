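#' Transform Mueller coefficients for background correction
#'
#' Computes the retardance-normalized coefficients and the degree of
#' polarization used by the background-correction scheme:
#' m1bar = m1/m3, m2bar = m2/m3, DOP = sqrt(m1^2+m2^2+m3^2)/m0.
#' The m1/m3 parameterization is singular near half-wave retardance
#' (m3 -> 0); voxels with |m3| below a relative guard, or with m0 <= 0, are
#' flagged invalid and carry NaN.
#'
#' @param m A `mueller_stack` (last dimension 4). An `"valid"` attribute, if
#'   present (from [invert_intensities()]), is AND-combined into the output
#'   mask.
#' @param eps_rel Relative division guard: voxels with
#'   |m3| < eps_rel * median(|m3|) are invalid. Default 1e-6.
#' @return Object of class `transformed_coefficients`: list with arrays
#'   `m1_bar`, `m2_bar`, `dop`, `m0` and logical `valid`, all over voxels.
#' @export
transform_coefficients <- function(m, eps_rel = 1e-6) {
  m <- as_stack(m, 4L, "Mueller coefficient stack")
  d <- dim(m)
  mm <- stack_mat(m)
  m0 <- mm[, 1]; m1 <- mm[, 2]; m2 <- mm[, 3]; m3 <- mm[, 4]
  eps_div <- eps_rel * stats::median(abs(m3))
  valid <- abs(m3) >= eps_div & abs(m3) > 0 & m0 > 0
  va <- attr(m, "valid")
  if (!is.null(va)) valid <- valid & as.logical(va)
  m1b <- m1 / m3; m2b <- m2 / m3
  dop <- sqrt(m1^2 + m2^2 + m3^2) / m0
  m1b[!valid] <- NaN; m2b[!valid] <- NaN; dop[!valid] <- NaN
  sd <- d[-length(d)]
  structure(list(m1_bar = array(m1b, sd),
                 m2_bar = array(m2b, sd),
                 dop = array(dop, sd),
                 m0 = array(m0, sd),
                 valid = array(valid, sd)),
            class = "transformed_coefficients")
}

#' Background-corrected specimen properties
#'
#' Combines transformed specimen and background coefficient sets into the
#' physical property maps:
#' \deqn{\bar m_1 = \bar m_1^{sm} - \bar m_1^{bg},\quad
#'   \bar m_2 = \bar m_2^{sm} - \bar m_2^{bg},\quad
#'   BF = m_0^{sm}/m_0^{bg},}
#' \deqn{\rho = \arctan\sqrt{\bar m_1^2+\bar m_2^2},\quad
#'   \omega = \tfrac12\,\mathrm{atan2}(\bar m_1, -\bar m_2) \bmod \pi,\quad
#'   DOP = DOP^{sm}/DOP^{bg}.}
#' The retardance branch follows from sqrt(m1b^2+m2b^2) = tan(rho) and is
#' non-negative in [0, pi/2); the orientation is an axis reported in
#' [0, pi), with the tie-break omega = 0 when m1bar = m2bar = 0.
#'
#' @param sm,bg `transformed_coefficients` on the same grid (bg may also be a
#'   single plane broadcast over z).
#' @return Object of class `specimen_properties`: list with arrays
#'   `brightfield`, `retardance`, `slow_axis`, `dop` and logical
#'   `valid_mask`.
#' @export
compute_properties <- function(sm, bg) {
  stopifnot(inherits(sm, "transformed_coefficients"),
            inherits(bg, "transformed_coefficients"))
  bge <- broadcast_bg(bg, dim(sm$m0))
  valid <- sm$valid & bge$valid & bge$m0 > 0 & is.finite(bge$dop) &
    bge$dop > 0
  m1b <- sm$m1_bar - bge$m1_bar
  m2b <- sm$m2_bar - bge$m2_bar
  rho <- atan(sqrt(m1b^2 + m2b^2))
  omega <- 0.5 * atan2(m1b, -m2b)
  omega <- omega %% pi
  tie <- !is.na(m1b) & m1b == 0 & m2b == 0
  omega[tie] <- 0
  bf <- sm$m0 / bge$m0
  dop <- sm$dop / bge$dop
  rho[!valid] <- NaN; omega[!valid] <- NaN; dop[!valid] <- NaN
  structure(list(brightfield = bf, retardance = rho, slow_axis = omega,
                 dop = dop, valid_mask = valid),
            class = "specimen_properties")
}

broadcast_bg <- function(bg, target_dim) {
  bd <- dim(bg$m0)
  if (identical(as.integer(bd), as.integer(target_dim))) return(bg)
  ## allow a single 2D background plane against a 3D specimen stack
  if (length(bd) == 2L && length(target_dim) == 3L &&
      all(bd == target_dim[1:2])) {
    nz <- target_dim[3]
    rep3 <- function(a) array(rep(a, nz), target_dim)
    return(structure(list(m1_bar = rep3(bg$m1_bar), m2_bar = rep3(bg$m2_bar),
                          dop = rep3(bg$dop), m0 = rep3(bg$m0),
                          valid = array(rep(bg$valid, nz), target_dim)),
                     class = "transformed_coefficients"))
  }
  stop("specimen and background grids are incompatible: ",
       paste(target_dim, collapse = "x"), " vs ", paste(bd, collapse = "x"))
}

#' Fit a low-order polynomial background surface to a 2D map
#'
#' Robust slowly-varying background estimation: the map is downsampled by
#' taking the median over bin x bin blocks (edge bins smaller than the full
#' bin size still contribute their median), a full bivariate polynomial of
#' the given total order is least-squares fitted to the downsampled grid
#' (unweighted), and the fitted surface is evaluated back at full
#' resolution. Median binning makes the fit insensitive to minority
#' structures (the specimen) inside each bin.
#'
#' @param map 2D numeric matrix; NA/NaN entries are ignored in the medians.
#' @param bin Bin size in pixels (default 32, i.e. 2048^2 -> 64^2).
#' @param order Total polynomial order (default 2: terms x^i y^j, i+j <= 2).
#' @return Matrix of the fitted surface, same dimensions as `map`.
#' @export
fit_background_surface <- function(map, bin = 32L, order = 2L) {
  stopifnot(is.matrix(map), bin >= 1L, order >= 0L)
  ny <- nrow(map); nx <- ncol(map)
  if (ny < bin && nx < bin && (ny * nx) < bin)
    stop("map smaller than one bin")
  if (ny < 1L || nx < 1L) stop("map smaller than one bin")
  yb <- ceiling(seq_len(ny) / bin)
  xb <- ceiling(seq_len(nx) / bin)
  nby <- max(yb); nbx <- max(xb)
  if (nby * nbx < choose(order + 2L, 2L))
    stop("map smaller than one bin: too few bins (", nby, "x", nbx,
         ") to fit an order-", order, " surface")
  ## median over each block
  g <- expand.grid(by = seq_len(nby), bx = seq_len(nbx))
  med <- matrix(NA_real_, nby, nbx)
  for (j in seq_len(nbx)) {
    cols <- which(xb == j)
    sub <- map[, cols, drop = FALSE]
    for (i in seq_len(nby)) {
      v <- sub[yb == i, ]
      med[i, j] <- stats::median(v[is.finite(v)])
    }
  }
  ## bin-center coordinates normalized to [-1, 1] for conditioning
  ycen <- (tapply(seq_len(ny), yb, mean) - (ny + 1) / 2) / (ny / 2)
  xcen <- (tapply(seq_len(nx), xb, mean) - (nx + 1) / 2) / (nx / 2)
  basis <- function(yv, xv) {
    cols <- list()
    for (i in 0:order) for (j in 0:(order - i))
      cols[[length(cols) + 1L]] <- yv^i * xv^j
    do.call(cbind, cols)
  }
  yy <- rep(ycen, times = nbx); xx <- rep(xcen, each = nby)
  keep <- is.finite(as.numeric(med))
  X <- basis(yy, xx)[keep, , drop = FALSE]
  beta <- qr.coef(qr(X), as.numeric(med)[keep])
  beta[is.na(beta)] <- 0
  yf <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  xf <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  Yf <- rep(yf, times = nx); Xf <- rep(xf, each = ny)
  matrix(basis(Yf, Xf) %*% beta, ny, nx)
}

#' One- or two-round background correction of a polarization measurement
#'
#' Round 1 transforms the specimen and the measured background acquisition
#' ([transform_coefficients()]) and extracts properties with
#' [compute_properties()]. Round 2 additionally estimates the residual
#' spatially varying background that the single background acquisition
#' missed: a low-order polynomial surface ([fit_background_surface()]) is
#' fitted to each background-subtracted transformed coefficient (m1bar,
#' m2bar, per z-plane) and subtracted before property extraction. Only the
#' retardance-bearing coefficients are refit; brightfield and DOP keep the
#' round-1 measured-background normalization.
#'
#' @param sm_raw,bg_raw `mueller_stack`s of the specimen and background
#'   acquisitions (e.g. from [invert_intensities()]). `bg_raw` may be a
#'   single plane.
#' @param rounds 1 or 2.
#' @param bin,order Passed to [fit_background_surface()].
#' @param eps_rel Division guard for [transform_coefficients()].
#' @return A `specimen_properties` object.
#' @export
correct_background <- function(sm_raw, bg_raw, rounds = 2L, bin = 32L,
                               order = 2L, eps_rel = 1e-6) {
  if (!rounds %in% c(1L, 2L)) stop("rounds must be 1 or 2")
  sm <- transform_coefficients(sm_raw, eps_rel)
  bg <- transform_coefficients(bg_raw, eps_rel)
  if (rounds == 1L) return(compute_properties(sm, bg))
  bge <- broadcast_bg(bg, dim(sm$m0))
  ## the default 32 px bin suits 2048^2 fields (64^2 bins); on smaller
  ## fields shrink the bin so the order-2 fit keeps >= 8 bins per axis
  d2 <- dim(sm$m0)[1:2]
  bin <- max(1L, min(as.integer(bin), as.integer(floor(min(d2) / 8))))
  res1 <- sm$m1_bar - bge$m1_bar
  res2 <- sm$m2_bar - bge$m2_bar
  fit_planes <- function(res) {
    d <- dim(res)
    if (length(d) == 2L) return(fit_background_surface(res, bin, order))
    out <- res
    for (k in seq_len(d[3]))
      out[, , k] <- fit_background_surface(res[, , k], bin, order)
    out
  }
  sm2 <- sm
  sm2$m1_bar <- sm$m1_bar - fit_planes(res1)
  sm2$m2_bar <- sm$m2_bar - fit_planes(res2)
  compute_properties(sm2, bg)
}

#' HSV composite rendering of slow axis and retardance
#'
#' Display convention for anisotropy maps: hue encodes the slow-axis
#' orientation over [0, pi), value (brightness) encodes retardance, and
#' saturation is 1. Returns an RGB array suitable for writing as a
#' three-channel float TIFF.
#'
#' @param props A `specimen_properties` object (2D maps or one z-plane).
#' @param rho_max Retardance mapped to full brightness; defaults to the 99th
#'   percentile of the valid retardance.
#' @return Array (y, x, 3) of RGB values in [0, 1].
#' @export
orientation_composite <- function(props, rho_max = NULL) {
  stopifnot(inherits(props, "specimen_properties"))
  rho <- props$retardance; omega <- props$slow_axis
  if (length(dim(rho)) == 3L) { rho <- rho[, , 1]; omega <- omega[, , 1] }
  if (is.null(rho_max))
    rho_max <- stats::quantile(rho[is.finite(rho)], 0.99, names = FALSE)
  if (!is.finite(rho_max) || rho_max <= 0) rho_max <- 1
  h <- (omega %% pi) / pi           # hue in [0, 1)
  v <- pmin(rho / rho_max, 1)
  h[!is.finite(h)] <- 0; v[!is.finite(v)] <- 0
  hsv_to_rgb(h, 1, v)
}

hsv_to_rgb <- function(h, s, v) {
  ## vectorized HSV -> RGB; h in [0,1), s,v in [0,1]
  n <- length(h)
  s <- rep_len(s, n); v <- rep_len(v, n)
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, c(dim(h) %||% length(h), 3L))
  d <- dim(h) %||% length(h)
  array(c(r, g, b), c(d, 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
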