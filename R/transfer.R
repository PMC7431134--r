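## Weak-object transfer functions for partially coherent brightfield.
##
## The system is a circular incoherent source (radius NA_ill/lambda) imaged
## through a defocused circular pupil (radius NA_det/lambda). Linearizing
## image formation around a weak object o = exp(i*phi - mu) ~ 1 + i*phi - mu
## gives, per defocus z and lateral frequency u,
##   I(u, z) / I_dc = delta(u) + H_mu(u, z) mu^(u) + H_phi(u, z) phi^(u)
## with
##   H_phi = i [ Cbar(u) - conj(Cbar(-u)) ],  H_mu = -[ Cbar(u) + conj(Cbar(-u)) ]
## where Cbar is the source-pupil cross-correlation
##   C(u, z) = sum_{u'} S(u') conj(P_z(u')) P_z(u' + u)
## normalized by the source power C(0, 0). For a radially symmetric system
## both transfer functions are real, H_phi is antisymmetric and H_mu
## symmetric in z, and H_phi(0) = 0 (constant phase gives no contrast).

fft_freqs <- function(n, spacing) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * spacing)
}

neg_index <- function(n) c(1L, n:2L)

fft2 <- function(x) {
  if (length(dim(x)) == 2L) stats::fft(x)
  else apply(x, 3, stats::fft) |> array(dim = dim(x))
}

ifft2 <- function(x) {
  n <- prod(dim(x)[1:2])
  if (length(dim(x)) == 2L) stats::fft(x, inverse = TRUE) / n
  else array(apply(x, 3, stats::fft, inverse = TRUE), dim = dim(x)) / n
}

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Weak-object transfer functions for a stack geometry
#'
#' Numerically evaluates the phase and absorption transfer functions of a
#' partially coherent brightfield system on the FFT grid of the data, by
#' cross-correlating the circular source distribution with the defocused
#' pupil (see the package vignette for the construction). In `mode = "2D"`
#' the result is one pair of lateral transfer functions per defocus plane;
#' in `mode = "3D"` the per-defocus stack is Fourier-transformed along z
#' into a volumetric transfer function that multiplies the 3D FFT of the
#' specimen phase/absorption.
#'
#' @param optics An [optics_config()].
#' @param shape Integer vector (ny, nx, nz) of the intensity stack.
#' @param mode "2D" (thin specimen, per-defocus transfer) or "3D"
#'   (volumetric transfer).
#' @return Object of class `transfer_function_set`: list with `h_phase`,
#'   `h_abs` (real arrays (ny, nx, nz); in 3D mode complex arrays on the 3D
#'   frequency grid), `mode`, `optics`, `shape`, `z` (defocus values in
#'   FFT wrap order, micrometres), and `source_power`.
#' @export
transfer_functions <- function(optics, shape, mode = c("2D", "3D")) {
  mode <- match.arg(mode)
  stopifnot(inherits(optics, "optics_config"), length(shape) == 3L)
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  lam <- optics$wavelength
  fy <- fft_freqs(ny, optics$pixel_size)
  fx <- fft_freqs(nx, optics$pixel_size)
  fr2 <- outer(fy^2, fx^2, `+`)
  na_cut <- (optics$na_detection + optics$na_illumination) / lam
  nyq <- 1 / (2 * optics$pixel_size)
  if (na_cut > nyq)
    warning(sprintf(paste0("grid too coarse for the optics: intensity ",
                           "spectrum extends to %.3g cyc/um but the pixel ",
                           "size supports only %.3g cyc/um"), na_cut, nyq))
  P <- (fr2 <= (optics$na_detection / lam)^2) * 1.0
  S <- (fr2 <= (optics$na_illumination / lam)^2) * 1.0
  kz <- sqrt(pmax((optics$medium_index / lam)^2 - fr2, 0))
  kz0 <- optics$medium_index / lam
  kidx <- c(0:floor((nz - 1) / 2), -(ceiling((nz - 1) / 2):1))
  z <- kidx * optics$z_step
  c0 <- sum(S * P^2)
  hp <- array(0, c(ny, nx, nz))
  ha <- array(0, c(ny, nx, nz))
  ni <- neg_index(ny); nj <- neg_index(nx)
  for (k in seq_len(nz)) {
    Pz <- P * exp(2i * pi * z[k] * (kz - kz0))
    f <- S * Pz
    C <- stats::fft(Conj(stats::fft(f)) * stats::fft(Pz),
                    inverse = TRUE) / (ny * nx)
    C <- C / c0
    Cneg <- Conj(C[ni, nj, drop = FALSE])
    dim(Cneg) <- dim(C)
    hp[, , k] <- Re(1i * (C - Cneg))
    ha[, , k] <- Re(-(C + Cneg))
  }
  out <- list(h_phase = hp, h_abs = ha, mode = mode, optics = optics,
              shape = as.integer(shape), z = z, source_power = c0)
  if (mode == "3D") {
    out$h_phase3 <- array(apply_fft_z(hp), dim = dim(hp))
    out$h_abs3 <- array(apply_fft_z(ha), dim = dim(ha))
  }
  structure(out, class = "transfer_function_set")
}

apply_fft_z <- function(h) {
  ## DFT along the 3rd axis (z already in wrap order)
  d <- dim(h)
  m <- matrix(h, nrow = d[1] * d[2], ncol = d[3])
  t(stats::mvfft(t(m)))
}

#' Render weak-object brightfield contrast from phase and absorption maps
#'
#' Forward model of the brightfield (m0) channel: applies the transfer
#' functions of a `transfer_function_set` to specimen phase (radians) and
#' absorption maps and returns the intensity stack
#' `m0 = m0_dc * (1 + contrast)`. With a 2D-mode transfer set, `phi` and
#' `mu` are single 2D layers imaged at every defocus of the stack; with a
#' 3D-mode set they are volumes convolved with the 3D kernels.
#'
#' @param phi Phase map (2D matrix in 2D mode, 3D array in 3D mode), radians.
#' @param tf A `transfer_function_set`.
#' @param mu Optional absorption map, same shape as `phi` (default 0).
#' @param m0_dc Background (dc) intensity level, default 1.
#' @return Numeric intensity array (ny, nx, nz).
#' @export
forward_brightfield <- function(phi, tf, mu = NULL, m0_dc = 1) {
  stopifnot(inherits(tf, "transfer_function_set"))
  sh <- tf$shape
  if (tf$mode == "2D") {
    stopifnot(length(dim(phi) %||% 1) == 2L || is.matrix(phi))
    ph <- stats::fft(phi)
    mh <- if (is.null(mu)) 0 else stats::fft(mu)
    out <- array(0, sh)
    for (k in seq_len(sh[3])) {
      spec <- tf$h_phase[, , k] * ph
      if (!is.null(mu)) spec <- spec + tf$h_abs[, , k] * mh
      out[, , k] <- Re(stats::fft(spec, inverse = TRUE)) / (sh[1] * sh[2])
    }
  } else {
    stopifnot(identical(dim(phi), as.integer(sh)) || all(dim(phi) == sh))
    spec <- tf$h_phase3 * fft3(phi)
    if (!is.null(mu)) spec <- spec + tf$h_abs3 * fft3(mu)
    out <- Re(ifft3(spec))
  }
  m0_dc * (1 + out)
}
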