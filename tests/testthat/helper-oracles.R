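## Independent oracles and fixture builders shared across test files.
## These deliberately re-derive quantities by brute force (loops, dense
## solvers, direct enumeration) so they stay independent of the package's
## vectorized implementations.

## textbook Pearson correlation via explicit sums
brute_pearson <- function(t, p) {
  t <- as.numeric(t); p <- as.numeric(p)
  n <- length(t)
  mt <- sum(t) / n; mp <- sum(p) / n
  num <- sum((t - mt) * (p - mp))
  num / sqrt(sum((t - mt)^2) * sum((p - mp)^2))
}

## SSIM by direct per-window loops, straight from the local statistic
## definition (uniform N-window, c1 = (0.01 L)^2, c2 = (0.03 L)^2,
## unbiased variance/covariance, mean over fully contained windows)
brute_ssim <- function(t, p, N = 7L, L = max(t) - min(t)) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  d <- dim(t)
  stopifnot(length(d) %in% c(2L, 3L))
  scores <- c()
  npix <- N^length(d)
  if (length(d) == 2L) {
    for (i in seq_len(d[1] - N + 1L)) for (j in seq_len(d[2] - N + 1L)) {
      tw <- as.numeric(t[i:(i + N - 1L), j:(j + N - 1L)])
      pw <- as.numeric(p[i:(i + N - 1L), j:(j + N - 1L)])
      mt <- mean(tw); mp <- mean(pw)
      vt <- sum((tw - mt)^2) / (npix - 1)
      vp <- sum((pw - mp)^2) / (npix - 1)
      cv <- sum((tw - mt) * (pw - mp)) / (npix - 1)
      scores <- c(scores, (2 * mt * mp + c1) * (2 * cv + c2) /
                    ((mt^2 + mp^2 + c1) * (vt + vp + c2)))
    }
  } else {
    for (i in seq_len(d[1] - N + 1L)) for (j in seq_len(d[2] - N + 1L))
      for (k in seq_len(d[3] - N + 1L)) {
        tw <- as.numeric(t[i:(i + N - 1L), j:(j + N - 1L), k:(k + N - 1L)])
        pw <- as.numeric(p[i:(i + N - 1L), j:(j + N - 1L), k:(k + N - 1L)])
        mt <- mean(tw); mp <- mean(pw)
        vt <- sum((tw - mt)^2) / (npix - 1)
        vp <- sum((pw - mp)^2) / (npix - 1)
        cv <- sum((tw - mt) * (pw - mp)) / (npix - 1)
        scores <- c(scores, (2 * mt * mp + c1) * (2 * cv + c2) /
                      ((mt^2 + mp^2 + c1) * (vt + vp + c2)))
      }
  }
  mean(scores)
}

## dense normal-equations least squares, the stated oracle for the
## instrument-matrix inversion
normal_eq_solve <- function(A, I_mat) {
  ## I_mat: (n, 5); returns (n, 4)
  AtA <- t(A) %*% A
  t(solve(AtA, t(A) %*% t(I_mat)))
}

## brute-force partially coherent (Abbe) image of a weak object:
## sum over source points of |IFFT(FFT(o * ramp) * defocused pupil)|^2
abbe_image <- function(phi, mu, opt, z) {
  ny <- nrow(phi); nx <- ncol(phi)
  lam <- opt$wavelength
  fy <- qpli:::fft_freqs(ny, opt$pixel_size)
  fx <- qpli:::fft_freqs(nx, opt$pixel_size)
  fr2 <- outer(fy^2, fx^2, `+`)
  P <- (fr2 <= (opt$na_detection / lam)^2) * 1
  kz <- sqrt(pmax((1 / lam)^2 - fr2, 0)); kz0 <- 1 / lam
  Pz <- P * exp(2i * pi * z * (kz - kz0))
  S <- (fr2 <= (opt$na_illumination / lam)^2) * 1
  o <- exp(1i * phi - mu)
  I <- matrix(0, ny, nx)
  yy <- matrix(seq_len(ny) - 1, ny, nx)
  xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  src <- which(S > 0, arr.ind = TRUE)
  for (s in seq_len(nrow(src))) {
    usy <- fy[src[s, 1]]; usx <- fx[src[s, 2]]
    ramp <- exp(2i * pi * (usy * yy + usx * xx) * opt$pixel_size)
    field <- stats::fft(stats::fft(o * ramp) * Pz, inverse = TRUE) /
      (ny * nx)
    I <- I + Mod(field)^2
  }
  I / nrow(src)
}

test_optics <- function(z_step = 0.5)
  optics_config(wavelength = 0.532, na_detection = 0.55,
                na_illumination = 0.4, pixel_size = 0.2, z_step = z_step)

## paired tiles where the target depends on two independent factors:
## phase from one phantom, retardance from another. Multi-channel input
## sees both; single-channel input sees only the phase channel.
two_factor_tiles <- function(n, seed0, size = 16L) {
  x4 <- array(0, c(size, size, 3, 4, n))
  x1 <- array(0, c(size, size, 3, 1, n))
  y <- array(0, c(size, size, 1, n))
  for (i in seq_len(n)) {
    phA <- make_phantom("beads", c(size, size, 3),
                        params = list(n = 3, radius = 3, phi_amp = 0.3),
                        seed = seed0 + i)
    phB <- make_phantom("spokes", c(size, size, 3),
                        params = list(n_bars = 3, rho_amp = 0.3,
                                      r_inner = 2, r_outer = 7,
                                      bar_width = 2, phi_amp = 0),
                        seed = seed0 + 1000 + i)
    x4[, , , 1, i] <- phA$phi_map
    x4[, , , 2, i] <- phB$rho_map
    x4[, , , 3, i] <- phB$rho_map * cos(2 * phB$omega_map)
    x4[, , , 4, i] <- phB$rho_map * sin(2 * phB$omega_map)
    x1[, , , 1, i] <- phA$phi_map
    y[, , 1, i] <- phB$rho_map[, , 2] + phA$phi_map[, , 2]
  }
  list(x4 = x4, x1 = x1, y = y)
}

## retardance-target tiles for the learnability fixture
rho_target_tiles <- function(n, size = 16L, seed0 = 0L) {
  x <- array(0, c(size, size, 3, 4, n))
  y <- array(0, c(size, size, 1, n))
  for (i in seq_len(n)) {
    ph <- make_phantom("spokes", c(size, size, 3),
                       params = list(n_bars = 3, rho_amp = 0.3,
                                     r_inner = 2, r_outer = 7,
                                     bar_width = 2), seed = seed0 + i)
    ic <- phantom_input_channels(ph)
    x[, , , , i] <- ic[, , , 2:5]
    y[, , 1, i] <- ph$rho_map[, , 2]
  }
  list(x = x, y = y)
}

## finite-difference gradient check of a built model
nn_gradcheck <- function(spec, xdim, ydim, n_checks = 6L, seed = 3L) {
  m <- build_model(spec, seed = seed)
  set.seed(seed)
  x <- array(stats::rnorm(prod(xdim)), xdim)
  y <- array(stats::rnorm(prod(ydim)), ydim)
  fw <- qpli:::nn_forward(m, x, training = TRUE)
  l <- qpli:::l1_loss(fw$out, y)
  g <- qpli:::nn_backward(fw, l$grad)
  errs <- c()
  for (nm in sample(names(g), n_checks)) {
    p <- m$params[[nm]]; i <- sample(length(p), 1); h <- 1e-5
    m1 <- m; m1$params[[nm]][i] <- p[i] + h
    m2 <- m; m2$params[[nm]][i] <- p[i] - h
    f1 <- qpli:::l1_loss(qpli:::nn_forward(m1, x, TRUE)$out, y)$loss
    f2 <- qpli:::l1_loss(qpli:::nn_forward(m2, x, TRUE)$out, y)$loss
    num <- (f1 - f2) / (2 * h)
    errs <- c(errs, abs(num - g[[nm]][i]) /
                max(1e-8, abs(num) + abs(g[[nm]][i])))
  }
  max(errs)
}
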