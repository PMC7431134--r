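#' Pearson correlation between a target and a prediction
#'
#' r = cov(T, P) / (sd(T) sd(P)). Errors (rather than silently returning
#' NaN) when either image has zero variance.
#'
#' @param target,prediction Numeric arrays of identical shape.
#' @return Scalar correlation in [-1, 1].
#' @export
pearson <- function(target, prediction) {
  t <- as.numeric(target); p <- as.numeric(prediction)
  if (length(t) != length(p)) stop("shapes differ")
  if (length(t) < 2L) stop("need at least 2 values")
  if (stats::sd(t) == 0 || stats::sd(p) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(t, p)
}

slide_mean <- function(v, n) {
  c0 <- c(0, cumsum(v))
  (c0[(n + 1):length(c0)] - c0[1:(length(c0) - n)]) / n
}

box_mean <- function(x, n) {
  ## mean over all n^d sliding windows, 'valid' positions only
  out <- x
  for (ax in seq_along(dim(x)))
    out <- apply_axis_fun(out, ax, function(v) slide_mean(v, n))
  out
}

apply_axis_fun <- function(x, ax, f) {
  d <- dim(x)
  perm <- c(ax, seq_along(d)[-ax])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[ax])
  res <- apply(m, 2, f)
  if (is.null(dim(res))) res <- matrix(res, nrow = 1)
  nd <- c(nrow(res), d[-ax])
  out <- array(res, nd)
  aperm(out, order(perm))
}

#' Structural similarity index (SSIM) with a uniform sliding window
#'
#' Local statistic per window: (2 mu_t mu_p + c1)(2 cov + c2) /
#' ((mu_t^2 + mu_p^2 + c1)(var_t + var_p + c2)), with c1 = (0.01 L)^2,
#' c2 = (0.03 L)^2, window N x N for 2D inputs and N x N x N for volumes,
#' averaged over all fully contained windows. Variances and covariance use
#' the unbiased (n-1) normalization, matching the common reference
#' implementations. SSIM is sensitive to the intensity scale: predictions
#' must be mapped back to the original range before scoring.
#'
#' @param target,prediction Arrays of identical shape, at least N along
#'   every axis, on the original intensity scale.
#' @param window Window side N (default 7).
#' @param dynamic_range L; defaults to max(target) - min(target).
#' @return Scalar SSIM score.
#' @export
ssim <- function(target, prediction, window = 7L, dynamic_range = NULL) {
  t <- target; p <- prediction
  if (is.null(dim(t))) dim(t) <- length(t)
  if (is.null(dim(p))) dim(p) <- length(p)
  if (!identical(dim(t), dim(p))) stop("shapes differ")
  if (any(dim(t) < window)) stop("window larger than image")
  L <- dynamic_range %||% (max(t) - min(t))
  if (L <= 0) L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- as.integer(window)
  npix <- n^length(dim(t))
  cov_norm <- npix / (npix - 1)
  mt <- box_mean(t, n); mp <- box_mean(p, n)
  mtt <- box_mean(t * t, n); mpp <- box_mean(p * p, n)
  mtp <- box_mean(t * p, n)
  vt <- cov_norm * (mtt - mt^2)
  vp <- cov_norm * (mpp - mp^2)
  ctp <- cov_norm * (mtp - mt * mp)
  s <- ((2 * mt * mp + c1) * (2 * ctp + c2)) /
    ((mt^2 + mp^2 + c1) * (vt + vp + c2))
  mean(s)
}

#' Plane-wise and volumetric Pearson/SSIM report
#'
#' Computes one Pearson r and one SSIM per XY slice, per XZ slice, and for
#' the whole volume (cubic window for the volumetric SSIM), and aggregates
#' with the median. Slices with zero variance in either volume are skipped
#' and counted.
#'
#' @param target_vol,pred_vol Arrays (ny, nx, nz) of identical shape, on the
#'   original intensity scale.
#' @param window SSIM window (default 7).
#' @param dynamic_range L for SSIM; defaults to the target volume's range.
#' @return Object of class `metrics_report`: list with `slices` (data frame
#'   id, axis, r, ssim), `summary` (data frame axis, median_r, median_ssim,
#'   n, n_skipped).
#' @export
metrics_by_plane <- function(target_vol, pred_vol, window = 7L,
                             dynamic_range = NULL) {
  stopifnot(identical(dim(target_vol), dim(pred_vol)),
            length(dim(target_vol)) == 3L)
  L <- dynamic_range %||% (max(target_vol) - min(target_vol))
  d <- dim(target_vol)
  rows <- list(); skipped <- c(xy = 0L, xz = 0L, xyz = 0L)
  add <- function(axis, id, tt, pp) {
    ok <- stats::sd(as.numeric(tt)) > 0 && stats::sd(as.numeric(pp)) > 0 &&
      all(dim(tt) >= window)
    if (!ok) { skipped[[axis]] <<- skipped[[axis]] + 1L; return() }
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, axis = axis, r = pearson(tt, pp),
      ssim = ssim(tt, pp, window, L))
  }
  for (k in seq_len(d[3])) add("xy", k, target_vol[, , k], pred_vol[, , k])
  for (i in seq_len(d[1])) add("xz", i,
                               matrix(target_vol[i, , ], d[2], d[3]),
                               matrix(pred_vol[i, , ], d[2], d[3]))
  add("xyz", 1L, target_vol, pred_vol)
  slices <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("xy", "xz", "xyz"), function(ax) {
    sub <- slices[slices$axis == ax, , drop = FALSE]
    data.frame(axis = ax,
               median_r = stats::median(sub$r),
               median_ssim = stats::median(sub$ssim),
               n = nrow(sub), n_skipped = skipped[[ax]])
  }))
  structure(list(slices = slices, summary = summ),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report:\n"); print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Otsu threshold of an image
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' data range.
#'
#' @param image Numeric array; must not be constant.
#' @param n_bins Histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: threshold undefined")
  br <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  w <- h / sum(h)
  centers <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * centers)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-n_bins])
  (centers[k] + centers[k + 1]) / 2
}

#' Rosin (unimodal) threshold of an image
#'
#' Draws a line from the histogram peak to the last non-empty bin and picks
#' the bin whose histogram point lies farthest below that line; suited to
#' histograms with one dominant background mode and a signal tail.
#'
#' @param image Numeric array; must not be constant.
#' @param n_bins Histogram bins (default 256).
#' @return Scalar threshold.
#' @export
rosin_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: threshold undefined")
  br <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  centers <- (br[-1] + br[-length(br)]) / 2
  pk <- which.max(h)
  last <- max(which(h > 0))
  if (last <= pk) return(centers[pk])
  ## perpendicular distance from (x_i, h_i) to the peak-to-end line
  x1 <- centers[pk]; y1 <- h[pk]; x2 <- centers[last]; y2 <- h[last]
  idx <- pk:last
  num <- abs((y2 - y1) * centers[idx] - (x2 - x1) * h[idx] +
               x2 * y1 - y2 * x1)
  centers[idx[which.max(num)]]
}

#' Foreground mask of a fluorescence image
#'
#' @param image Numeric array; must not be constant.
#' @param method "otsu" (bimodal, maximal between-class variance) or
#'   "rosin" (unimodal tail threshold).
#' @return Logical array, TRUE on foreground (above threshold).
#' @export
foreground_mask <- function(image, method = c("otsu", "rosin")) {
  method <- match.arg(method)
  th <- switch(method, otsu = otsu_threshold(image),
               rosin = rosin_threshold(image))
  image > th
}

#' Write a metrics report to CSV
#'
#' One row per slice/volume with columns id, axis, r, ssim.
#'
#' @param report A `metrics_report`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  utils::write.csv(report$slices, path, row.names = FALSE)
  invisible(path)
}
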