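#' Regularization configuration for phase deconvolution
#'
#' @param tau_phase Non-negative Tikhonov/TV weight for the phase channel.
#' @param tau_abs Non-negative weight for the absorption channel (2D joint
#'   solve only).
#' @param method "Tikhonov" (single-step frequency-domain solution) or "TV"
#'   (anisotropic total variation by alternating minimization).
#' @param tv_iterations Outer iterations of the TV solver (default 50).
#' @param tv_penalty Quadratic splitting penalty beta (default 1).
#' @param seed Recorded for provenance; the TV solver is deterministic
#'   (zero initialization) and does not consume randomness.
#' @return Object of class `reg_config`.
#' @export
reg_config <- function(tau_phase = 1e-3, tau_abs = 1e-3,
                       method = c("Tikhonov", "TV"), tv_iterations = 50L,
                       tv_penalty = 1.0, seed = NULL) {
  method <- match.arg(method)
  stopifnot(tau_phase >= 0, tau_abs >= 0, tv_iterations >= 1L,
            tv_penalty > 0)
  structure(list(tau_phase = tau_phase, tau_abs = tau_abs, method = method,
                 tv_iterations = as.integer(tv_iterations),
                 tv_penalty = tv_penalty, seed = seed),
            class = "reg_config")
}

#' Estimate the dc (background) level of a brightfield stack
#'
#' @param m0 Numeric array.
#' @param method "mean" (default) or "median"; ignored if `value` is given.
#' @param value Optional known constant.
#' @return Scalar dc estimate.
#' @export
estimate_dc <- function(m0, method = c("mean", "median"), value = NULL) {
  if (!is.null(value)) return(value)
  method <- match.arg(method)
  if (method == "mean") mean(m0) else stats::median(m0)
}

freq_floor <- function(x, rel = 1e-12) pmax(x, rel * max(x))

## circular forward-difference DFT symbols on the FFT grid:
## (D x)_j = x_{j+1} - x_j  <=>  (e^{+2 pi i k / N} - 1) * xhat
grad_symbols <- function(d) {
  lapply(seq_along(d), function(ax) {
    f <- exp(2i * pi * (seq_len(d[ax]) - 1) / d[ax]) - 1
    shape <- rep(1L, length(d)); shape[ax] <- d[ax]
    array(rep(f, each = prod(d[seq_len(ax - 1L)])), dim = d)
  })
}

fwd_diff <- function(x, ax) {
  idx <- lapply(dim(x), seq_len)
  idx[[ax]] <- c(2:dim(x)[ax], 1L)
  do.call(`[`, c(list(x), idx)) - x
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' 3D phase reconstruction from a brightfield stack
#'
#' Solves the volumetric weak-object deconvolution problem
#' \deqn{\min_\phi \sum_r |m_0'(r) - (\phi \otimes h_\phi)(r)|^2 +
#'   \tau_\phi\, \mathrm{Reg}(\phi)}
#' assuming negligible absorption. With Tikhonov regularization the solution
#' is the single-step frequency-domain Wiener-type filter
#' phi^ = conj(H) g^ / (|H|^2 + tau); with TV it runs
#' [tv_denoise_step()] for `tv_iterations` alternating-minimization
#' iterations from a zero initialization.
#'
#' @param m0 Brightfield (m0) stack, array (ny, nx, nz). Either raw m0 (the
#'   dc is estimated and removed) or the background-normalized BF ratio.
#' @param tf A 3D-mode `transfer_function_set` on the same grid.
#' @param reg A [reg_config()].
#' @param m0_dc Optional known dc level; default estimated by [estimate_dc()].
#' @return Phase volume (radians), array (ny, nx, nz). For TV the attribute
#'   `"objective"` carries the per-iteration objective values.
#' @export
reconstruct_phase_3d <- function(m0, tf, reg = reg_config(),
                                 m0_dc = NULL) {
  stopifnot(inherits(tf, "transfer_function_set"), tf$mode == "3D")
  stopifnot(all(dim(m0) == tf$shape))
  dc <- estimate_dc(m0, value = m0_dc)
  if (dc == 0) dc <- 1
  g <- m0 / dc - 1
  H <- tf$h_phase3
  G <- fft3(g)
  if (reg$method == "Tikhonov") {
    tau <- reg$tau_phase
    den <- Mod(H)^2 + tau
    if (tau == 0 && min(Mod(H)^2) < 1e-12 * max(Mod(H)^2))
      warning("tau_phase = 0 with transfer-function nulls; ",
              "applying a small frequency-domain floor")
    den <- freq_floor(den)
    phi <- Re(ifft3(Conj(H) * G / den))
    return(phi)
  }
  tv_solve(g, H, reg, dims = 3L)
}

tv_solve <- function(g, H, reg, dims) {
  d <- dim(g)
  G <- stats::fft(g)
  Dsym <- grad_symbols(d)
  if (dims == 2L && length(d) == 3L) Dsym <- Dsym[1:2]
  axes <- seq_along(Dsym)
  beta <- reg$tv_penalty; tau <- reg$tau_phase
  DtD <- Reduce(`+`, lapply(Dsym, function(s) Mod(s)^2))
  den <- freq_floor(Mod(H)^2 + beta * DtD)
  phi <- array(0, d)
  obj <- numeric(reg$tv_iterations)
  for (it in seq_len(reg$tv_iterations)) {
    st <- tv_denoise_step(phi, g, H, reg, Dsym = Dsym, den = den, G = G)
    phi <- st$phi
    obj[it] <- st$objective
  }
  attr(phi, "objective") <- obj
  phi
}

#' One alternating-minimization iteration of the TV solver
#'
#' Alternates an exact shrinkage solve of the anisotropic-TV subproblem
#' (d_i = soft-threshold of the forward differences) with the exact
#' frequency-domain quadratic subproblem for phi. Each step minimizes the
#' splitting objective
#' \deqn{J(\phi, d) = \|\,h_\phi \otimes \phi - g\|^2 +
#'   \beta \sum_i \|D_i\phi - d_i\|^2 + \tau \sum_i \|d_i\|_1}
#' exactly in one block, so J is non-increasing across iterations.
#'
#' @param current Current phase estimate (array).
#' @param data Contrast data g (array, same shape).
#' @param tf Transfer function: either a complex array H on the same grid or
#'   a `transfer_function_set` in 3D mode (its `h_phase3` is used).
#' @param reg A [reg_config()] (uses `tau_phase` and `tv_penalty`).
#' @param Dsym,den,G Precomputed internals (optional, for use in a loop).
#' @return List with `phi` (updated estimate) and `objective` (value of J
#'   after the update).
#' @export
tv_denoise_step <- function(current, data, tf, reg, Dsym = NULL, den = NULL,
                            G = NULL) {
  H <- if (inherits(tf, "transfer_function_set")) tf$h_phase3 else tf
  d <- dim(current)
  if (is.null(Dsym)) Dsym <- grad_symbols(d)
  beta <- reg$tv_penalty; tau <- reg$tau_phase
  if (is.null(den)) {
    DtD <- Reduce(`+`, lapply(Dsym, function(s) Mod(s)^2))
    den <- freq_floor(Mod(H)^2 + beta * DtD)
  }
  if (is.null(G)) G <- stats::fft(data)
  n <- length(current)
  ## d-step: exact minimizer of beta||Dphi - d||^2 + tau|d|
  dlist <- lapply(seq_along(Dsym), function(i) {
    soft_threshold(fwd_diff(current, i), tau / (2 * beta))
  })
  ## phi-step: exact quadratic solve in the frequency domain
  rhs <- Conj(H) * G
  for (i in seq_along(Dsym))
    rhs <- rhs + beta * Conj(Dsym[[i]]) * stats::fft(dlist[[i]])
  phi <- Re(stats::fft(rhs / den, inverse = TRUE)) / n
  ## objective after the update (re-solve d at new phi for the reported J)
  resid <- Re(stats::fft(H * stats::fft(phi), inverse = TRUE)) / n - data
  J <- sum(resid^2)
  for (i in seq_along(Dsym)) {
    di <- soft_threshold(fwd_diff(phi, i), tau / (2 * beta))
    J <- J + beta * sum((fwd_diff(phi, i) - di)^2) + tau * sum(abs(di))
  }
  list(phi = phi, objective = J)
}

#' 2D joint phase and absorption reconstruction from a defocus stack
#'
#' Treats the specimen as a single effective 2D layer observed at several
#' defocus planes and solves the joint least-squares problem over phase and
#' absorption. With Tikhonov regularization, each lateral frequency gives a
#' regularized 2x2 normal system accumulated over all z-planes, solved in
#' closed form; the TV variant alternates the closed-form quadratic solve
#' with anisotropic-TV shrinkage on both channels.
#'
#' @param m0 Brightfield stack, array (ny, nx, nz) with nz >= 2 (a single
#'   in-focus plane renders phase unobservable).
#' @param tf A 2D-mode `transfer_function_set` on the same grid.
#' @param reg A [reg_config()]; `tau_phase` and `tau_abs` regularize the two
#'   channels.
#' @param m0_dc Optional known dc level.
#' @return List with `phase` and `absorption` matrices (ny, nx).
#' @export
reconstruct_phase_2d <- function(m0, tf, reg = reg_config(),
                                 m0_dc = NULL) {
  stopifnot(inherits(tf, "transfer_function_set"), tf$mode == "2D")
  stopifnot(all(dim(m0) == tf$shape))
  nz <- dim(m0)[3]
  if (nz < 2L)
    stop("ill-posed: 2D phase reconstruction needs >= 2 defocus planes")
  dc <- estimate_dc(m0, value = m0_dc)
  if (dc == 0) dc <- 1
  g <- m0 / dc - 1
  ny <- dim(m0)[1]; nx <- dim(m0)[2]
  if (reg$method == "TV")
    return(tv_solve_2d(g, tf$h_phase, tf$h_abs, reg))
  Gz <- array(0i, dim(m0))
  for (k in seq_len(nz)) Gz[, , k] <- stats::fft(g[, , k])
  Hp <- tf$h_phase; Ha <- tf$h_abs
  a11 <- rowSums(Hp^2, dims = 2) + reg$tau_phase
  a22 <- rowSums(Ha^2, dims = 2) + reg$tau_abs
  a12 <- rowSums(Hp * Ha, dims = 2)
  b1 <- rowSums_cplx(Hp * Gz)
  b2 <- rowSums_cplx(Ha * Gz)
  det <- a11 * a22 - a12^2
  det <- freq_floor(det)
  if (min(a11 * a22 - a12^2) < 1e-12 * max(det) &&
      (reg$tau_phase == 0 || reg$tau_abs == 0))
    warning("singular normal matrix with zero regularization; ",
            "applying a small frequency-domain floor")
  Phi <- (a22 * b1 - a12 * b2) / det
  Mu <- (a11 * b2 - a12 * b1) / det
  phase <- Re(stats::fft(Phi, inverse = TRUE)) / (ny * nx)
  absorp <- Re(stats::fft(Mu, inverse = TRUE)) / (ny * nx)
  list(phase = phase, absorption = absorp)
}

rowSums_cplx <- function(x) {
  ## sum over the 3rd axis of a complex array
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  array(rowSums(m), d[1:2])
}

tv_solve_2d <- function(g, Hp, Ha, reg) {
  d2 <- dim(g)[1:2]; nz <- dim(g)[3]
  Gz <- array(0i, dim(g))
  for (k in seq_len(nz)) Gz[, , k] <- stats::fft(g[, , k])
  Dsym <- grad_symbols(d2)
  DtD <- Reduce(`+`, lapply(Dsym, function(s) Mod(s)^2))
  beta <- reg$tv_penalty
  a11 <- rowSums(Hp^2, dims = 2) + beta * DtD
  a22 <- rowSums(Ha^2, dims = 2) + beta * DtD
  a12 <- rowSums(Hp * Ha, dims = 2)
  det <- freq_floor(Re(a11 * a22 - a12^2))
  b1_0 <- rowSums_cplx(Hp * Gz)
  b2_0 <- rowSums_cplx(Ha * Gz)
  phi <- array(0, d2); mu <- array(0, d2)
  np <- prod(d2)
  obj <- numeric(reg$tv_iterations)
  for (it in seq_len(reg$tv_iterations)) {
    dp <- lapply(1:2, function(i)
      soft_threshold(fwd_diff(phi, i), reg$tau_phase / (2 * beta)))
    dm <- lapply(1:2, function(i)
      soft_threshold(fwd_diff(mu, i), reg$tau_abs / (2 * beta)))
    b1 <- b1_0; b2 <- b2_0
    for (i in 1:2) {
      b1 <- b1 + beta * Conj(Dsym[[i]]) * stats::fft(dp[[i]])
      b2 <- b2 + beta * Conj(Dsym[[i]]) * stats::fft(dm[[i]])
    }
    Phi <- (a22 * b1 - a12 * b2) / det
    Mu <- (a11 * b2 - a12 * b1) / det
    phi <- Re(stats::fft(Phi, inverse = TRUE)) / np
    mu <- Re(stats::fft(Mu, inverse = TRUE)) / np
    ## splitting objective at the new iterate
    J <- 0
    for (k in seq_len(nz)) {
      r <- Re(stats::fft(Hp[, , k] * stats::fft(phi) +
                         Ha[, , k] * stats::fft(mu), inverse = TRUE)) / np -
        g[, , k]
      J <- J + sum(r^2)
    }
    for (i in 1:2) {
      dpi <- soft_threshold(fwd_diff(phi, i), reg$tau_phase / (2 * beta))
      dmi <- soft_threshold(fwd_diff(mu, i), reg$tau_abs / (2 * beta))
      J <- J + beta * sum((fwd_diff(phi, i) - dpi)^2) +
        reg$tau_phase * sum(abs(dpi)) +
        beta * sum((fwd_diff(mu, i) - dmi)^2) + reg$tau_abs * sum(abs(dmi))
    }
    obj[it] <- J
  }
  structure(list(phase = phi, absorption = mu), objective = obj)
}
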