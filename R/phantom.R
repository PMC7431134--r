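## Synthetic specimen phantoms and the renderer that turns them into
## five-channel polarization acquisitions through the package's own forward
## physics. The renderer is the single source of truth for forward
## simulation; the inversion modules never depend on it.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a ground-truth specimen phantom
#'
#' Produces voxel maps of transmission t in (0, 2], depolarization p in
#' (0, 1], retardance rho in radians, slow-axis orientation omega in
#' [0, pi), and phase phi in radians, on a (ny, nx, nz) grid. All kinds are
#' deterministic given `seed`.
#'
#' Kinds:
#' \describe{
#'   \item{beads}{`n` spherical inclusions with smooth phase profiles and
#'     optional uniform retardance with per-bead random slow axis; emulates
#'     cells/nucleoli in a clear mount.}
#'   \item{star}{an angular star target of alternating phase wedges;
#'     isotropic (rho = 0).}
#'   \item{spokes}{`n_bars` radial anisotropic bars; the slow axis on each
#'     bar is perpendicular to the bar direction (bar angle + pi/2, mod pi),
#'     as for myelinated axon tracts.}
#'   \item{layered_tissue}{horizontal strata with varying transmission,
#'     a depolarizing layer, slowly varying birefringence and smooth phase
#'     texture; emulates a tissue slice.}
#' }
#'
#' @param kind One of "beads", "star", "spokes", "layered_tissue".
#' @param shape Integer (ny, nx, nz); default c(64, 64, 1).
#' @param params Named list of kind-specific parameters (see Details above;
#'   common ones: `n`, `radius`, `phi_amp`, `rho_amp`, `n_bars`,
#'   `bar_width`).
#' @param seed Integer seed; same seed gives a bitwise-identical phantom.
#' @param pixel_size,z_step Grid spacings in micrometres.
#' @return Object of class `phantom`: list of the five maps plus spacings.
#' @export
make_phantom <- function(kind = c("beads", "star", "spokes",
                                  "layered_tissue"),
                         shape = c(64L, 64L, 1L), params = list(),
                         seed = 1L, pixel_size = 0.2, z_step = 0.5) {
  kind <- match.arg(kind)
  ny <- shape[1]; nx <- shape[2]; nz <- if (length(shape) >= 3) shape[3] else 1L
  d <- c(ny, nx, nz)
  p0 <- list(t = array(1, d), p = array(1, d), rho = array(0, d),
             omega = array(0, d), phi = array(0, d))
  yy <- matrix(seq_len(ny), ny, nx) - (ny + 1) / 2
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - (nx + 1) / 2
  pr <- function(name, default) params[[name]] %||% default
  ph <- with_seed(seed, switch(kind,
    beads = {
      n <- pr("n", 8L)
      rad <- pr("radius", max(3, round(min(ny, nx) / 12)))
      phi_amp <- pr("phi_amp", 0.1)
      rho_amp <- pr("rho_amp", 0)
      if (n > 0) {
        cy <- stats::runif(n, rad + 1, ny - rad)
        cx <- stats::runif(n, rad + 1, nx - rad)
        cz <- if (nz > 1) stats::runif(n, 1, nz) else rep(1, n)
        om <- stats::runif(n, 0, pi)
        for (b in seq_len(n)) {
          for (k in seq_len(nz)) {
            dz2 <- if (nz > 1) ((k - cz[b]) * z_step / pixel_size)^2 else 0
            r2 <- (yy - (cy[b] - (ny + 1) / 2))^2 +
              (xx - (cx[b] - (nx + 1) / 2))^2 + dz2
            prof <- pmax(1 - r2 / rad^2, 0)
            p0$phi[, , k] <- p0$phi[, , k] + phi_amp * prof
            sel <- prof > 0
            if (rho_amp > 0) {
              pl_r <- p0$rho[, , k]; pl_o <- p0$omega[, , k]
              pl_r[sel] <- pmax(pl_r[sel], rho_amp * prof[sel])
              pl_o[sel] <- om[b]
              p0$rho[, , k] <- pl_r; p0$omega[, , k] <- pl_o
            }
          }
        }
      }
      p0
    },
    star = {
      nw <- pr("n_wedges", 8L)
      phi_amp <- pr("phi_amp", 0.1)
      rmax <- pr("radius", min(ny, nx) / 2 - 2)
      th <- atan2(yy, xx)
      rr <- sqrt(yy^2 + xx^2)
      wedge <- (floor((th %% (2 * pi)) / (2 * pi / (2 * nw))) %% 2) == 0
      disk <- rr <= rmax & rr >= pr("r_inner", 2)
      for (k in seq_len(nz))
        p0$phi[, , k] <- phi_amp * (wedge & disk)
      p0
    },
    spokes = {
      nb <- pr("n_bars", 8L)
      w <- pr("bar_width", 3)
      r0 <- pr("r_inner", round(min(ny, nx) / 8))
      r1 <- pr("r_outer", round(min(ny, nx) / 2) - 2)
      rho_amp <- pr("rho_amp", 0.2)
      phi_amp <- pr("phi_amp", 0.05)
      angles <- pr("angles", (seq_len(nb) - 1) * pi / nb)
      rr <- sqrt(yy^2 + xx^2)
      for (b in seq_along(angles)) {
        a <- angles[b]
        ## distance to the line through origin at angle a
        dperp <- abs(-sin(a) * xx + cos(a) * yy)
        along <- cos(a) * xx + sin(a) * yy
        bar <- dperp <= w / 2 & along >= r0 & along <= r1
        for (k in seq_len(nz)) {
          pl_r <- p0$rho[, , k]; pl_o <- p0$omega[, , k]
          pl_f <- p0$phi[, , k]
          pl_r[bar] <- rho_amp
          pl_o[bar] <- (a + pi / 2) %% pi   # slow axis perpendicular to bar
          pl_f[bar] <- pl_f[bar] + phi_amp
          p0$rho[, , k] <- pl_r; p0$omega[, , k] <- pl_o
          p0$phi[, , k] <- pl_f
        }
      }
      p0
    },
    layered_tissue = {
      nl <- pr("n_layers", 4L)
      rho_amp <- pr("rho_amp", 0.15)
      phi_amp <- pr("phi_amp", 0.1)
      bounds <- round(seq(1, ny + 1, length.out = nl + 1))
      t_l <- stats::runif(nl, 0.7, 1.1)
      p_l <- stats::runif(nl, 0.6, 1.0)
      r_l <- stats::runif(nl, 0, rho_amp)
      o_l <- stats::runif(nl, 0, pi)
      tex <- matrix(stats::rnorm(ny * nx), ny, nx)
      tex <- Re(stats::fft(stats::fft(tex) *
        exp(-(outer(fft_freqs(ny, 1)^2, fft_freqs(nx, 1)^2, `+`)) *
              (2 * pi * pr("texture_scale", 4))^2 / 2),
        inverse = TRUE)) / (ny * nx)
      tex <- tex / max(abs(tex))
      for (l in seq_len(nl)) {
        rows <- bounds[l]:(bounds[l + 1] - 1)
        for (k in seq_len(nz)) {
          p0$t[rows, , k] <- t_l[l]
          p0$p[rows, , k] <- p_l[l]
          p0$rho[rows, , k] <- r_l[l]
          p0$omega[rows, , k] <- if (r_l[l] > 0) o_l[l] else 0
          p0$phi[rows, , k] <- phi_amp * (tex[rows, ] + 1) / 2
        }
      }
      p0
    }))
  structure(list(t_map = ph$t, p_map = ph$p, rho_map = ph$rho,
                 omega_map = ph$omega, phi_map = ph$phi,
                 shape = d, pixel_size = pixel_size, z_step = z_step),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom %s, dx=%.3g um, dz=%.3g um\n",
              paste(x$shape, collapse = "x"), x$pixel_size, x$z_step))
  cat(sprintf("  rho in [%.3g, %.3g] rad, phi in [%.3g, %.3g] rad\n",
              min(x$rho_map), max(x$rho_map), min(x$phi_map),
              max(x$phi_map)))
  invisible(x)
}

## transformed-coefficient representation of an anisotropy field:
## m1/m3 = tan(rho) sin(2 omega), m2/m3 = -tan(rho) cos(2 omega)
aniso_to_bar <- function(rho, omega)
  list(b1 = tan(rho) * sin(2 * omega), b2 = -tan(rho) * cos(2 * omega))

bar_to_aniso <- function(b1, b2) {
  rho <- atan(sqrt(b1^2 + b2^2))
  omega <- (0.5 * atan2(b1, -b2)) %% pi
  omega[b1 == 0 & b2 == 0] <- 0
  list(rho = rho, omega = omega)
}

norm_bgfield <- function(bgf, d2) {
  if (is.null(bgf)) return(NULL)
  as_map <- function(v, default) {
    if (is.null(v)) return(matrix(default, d2[1], d2[2]))
    if (length(v) == 1L) return(matrix(v, d2[1], d2[2]))
    stopifnot(all(dim(v) == d2)); v
  }
  list(rho = as_map(bgf$rho, 0), omega = as_map(bgf$omega, 0),
       t = as_map(bgf$t, 1), p = as_map(bgf$p, 1))
}

#' Render a phantom into a five-channel polarization acquisition
#'
#' Collapses the phantom's anisotropy to an effective thin layer (retardance
#' accumulates over z; transmission and depolarization multiply), composes
#' optional slowly varying instrument background fields in the transformed
#' coefficient space where the background-correction model is additive,
#' forms per-plane Mueller coefficients, applies defocus phase
#' contrast to the brightfield-bearing component through the weak-object
#' transfer functions when an optics configuration is supplied, maps to
#' intensities through the instrument matrix, and optionally adds shot
#' noise at a stated photon budget.
#'
#' @param ph A [make_phantom()] object.
#' @param optics An [optics_config()], or NULL for an idealized in-focus
#'   rendering with no defocus contrast (chi then defaults to 0.06*pi).
#' @param background Optional background anisotropy present in BOTH the
#'   specimen acquisition and the returned background acquisition: list with
#'   entries `rho`, `omega` (2D maps or scalars), optional `t`, `p`.
#' @param residual_background Optional additional background present in the
#'   specimen acquisition but NOT in the background acquisition (emulates
#'   background drift between the two measurements; exercised by the
#'   two-round correction).
#' @param photon_budget Expected photons per unit intensity per pixel;
#'   Poisson shot noise is applied at this budget (NULL = noiseless).
#' @param seed Seed for the shot noise.
#' @return List with `sample` and `background` (`polarization_stack`s of
#'   dim (ny, nx, nz, 5)) and `truth` (the effective thin-layer rho/omega
#'   maps after collapsing z, before background composition).
#' @export
render_polarization_stack <- function(ph, optics = NULL, background = NULL,
                                      residual_background = NULL,
                                      photon_budget = NULL, seed = NULL) {
  stopifnot(inherits(ph, "phantom"))
  d <- ph$shape; ny <- d[1]; nx <- d[2]; nz <- d[3]
  chi <- if (is.null(optics)) 0.06 * pi else optics$chi
  A <- instrument_matrix(chi)
  ## effective thin-layer anisotropy: accumulate retardance vectorially
  b1 <- matrix(0, ny, nx); b2 <- matrix(0, ny, nx)
  t_eff <- matrix(1, ny, nx); p_eff <- matrix(1, ny, nx)
  for (k in seq_len(nz)) {
    bb <- aniso_to_bar(ph$rho_map[, , k], ph$omega_map[, , k])
    b1 <- b1 + bb$b1; b2 <- b2 + bb$b2
    t_eff <- t_eff * ph$t_map[, , k]
    p_eff <- p_eff * ph$p_map[, , k]
  }
  truth <- bar_to_aniso(b1, b2)
  bg <- norm_bgfield(background, c(ny, nx))
  rbg <- norm_bgfield(residual_background, c(ny, nx))
  compose <- function(b1s, b2s, ts, ps, fields) {
    for (f in fields) {
      if (is.null(f)) next
      fb <- aniso_to_bar(f$rho, f$omega)
      b1s <- b1s + fb$b1; b2s <- b2s + fb$b2
      ts <- ts * f$t; ps <- ps * f$p
    }
    c(bar_to_aniso(b1s, b2s), list(t = ts, p = ps))
  }
  sm <- compose(b1, b2, t_eff, p_eff, list(bg, rbg))
  bgonly <- compose(matrix(0, ny, nx), matrix(0, ny, nx),
                    matrix(1, ny, nx), matrix(1, ny, nx), list(bg))
  ## defocus contrast on the brightfield-bearing intensity
  factor <- array(1, c(ny, nx, nz))
  if (!is.null(optics) && any(ph$phi_map != 0)) {
    if (nz > 1) {
      tf <- transfer_functions(optics, c(ny, nx, nz), mode = "3D")
      factor <- forward_brightfield(ph$phi_map, tf, m0_dc = 1)
    } else {
      tf <- transfer_functions(optics, c(ny, nx, 1L), mode = "2D")
      factor <- forward_brightfield(ph$phi_map[, , 1], tf, m0_dc = 1)
    }
    factor <- pmax(factor, 1e-6)
  }
  render <- function(maps, fac) {
    m <- mueller_coefficients(maps$t, maps$p, maps$rho, maps$omega)
    ii <- stack_mat(forward_intensities(m, A))   # (npix, 5)
    out <- array(0, c(ny, nx, nz, 5L))
    for (k in seq_len(nz)) {
      fk <- as.numeric(fac[, , k])
      for (ch in 1:5) out[, , k, ch] <- fk * ii[, ch]
    }
    out
  }
  i_sm <- render(sm, factor)
  i_bg <- render(bgonly, array(1, c(ny, nx, nz)))
  if (!is.null(photon_budget)) {
    i_sm <- with_seed(seed, {
      n <- array(stats::rpois(length(i_sm), i_sm * photon_budget),
                 dim(i_sm)) / photon_budget
      n
    })
  }
  list(sample = polarization_stack(i_sm),
       background = polarization_stack(i_bg),
       truth = list(rho = truth$rho, omega = truth$omega,
                    t = t_eff, p = p_eff))
}

#' Synthetic fluorescence target from a phantom
#'
#' Deterministic stand-in for a paired fluorescence acquisition: the target
#' is a named function of the ground-truth maps, optionally blurred and
#' corrupted with structured noise, always non-negative and reproducible
#' given a seed.
#'
#' @param ph A `phantom`.
#' @param generator_spec List: `name` one of "rho" (target = retardance),
#'   "phi" (positive part of phase), "rho_phi" (weighted sum, weights `a`,
#'   `b`, default 1 and 1), "beads" (alias for phi); optional `sigma`
#'   (Gaussian blur, px), `gaussian_sd` (additive noise), `poisson_scale`
#'   (shot-noise scale; 0 disables).
#' @param seed Seed for the noise.
#' @return Non-negative array (ny, nx, nz).
#' @export
make_fluorescence_target <- function(ph, generator_spec = list(name = "rho"),
                                     seed = 1L) {
  stopifnot(inherits(ph, "phantom"))
  name <- generator_spec$name %||% "rho"
  a <- generator_spec$a %||% 1; b <- generator_spec$b %||% 1
  base <- switch(name,
    rho = ph$rho_map,
    phi = pmax(ph$phi_map, 0),
    beads = pmax(ph$phi_map, 0),
    rho_phi = a * ph$rho_map + b * pmax(ph$phi_map, 0),
    stop("unknown generator_spec name: ", name))
  sig <- generator_spec$sigma %||% 0
  if (sig > 0) for (k in seq_len(dim(base)[3]))
    base[, , k] <- gauss_blur(base[, , k], sig)
  with_seed(seed, {
    gsd <- generator_spec$gaussian_sd %||% 0
    if (gsd > 0) base <- base + array(stats::rnorm(length(base), 0, gsd),
                                      dim(base))
    psc <- generator_spec$poisson_scale %||% 0
    if (psc > 0)
      base <- array(stats::rpois(length(base), pmax(base, 0) * psc),
                    dim(base)) / psc
    pmax(base, 0)
  })
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  ny <- nrow(img); nx <- ncol(img)
  fy <- fft_freqs(ny, 1); fx <- fft_freqs(nx, 1)
  H <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (ny * nx)
}

#' Build a paired label-free / fluorescence dataset from phantoms
#'
#' Renders each phantom into the five label-free input channels used for
#' virtual staining — brightfield, phase, retardance, and the orientation
#' pair (omega_x, omega_y) = rho*(cos 2 omega, sin 2 omega) which is
#' continuous where the raw angle is not — plus a synthetic fluorescence
#' target, and splits the volumes into train/validation/test groups.
#' Validation and test sizes are floored; the remainder goes to training.
#' Membership is a seeded permutation and volumes are never shared across
#' splits.
#'
#' @param phantoms List of >= 3 `phantom` objects.
#' @param generator_spec Passed to [make_fluorescence_target()].
#' @param split Fractions (train, val, test); must sum to 1.
#' @param seed Seed controlling the split and target noise.
#' @return List with `train`, `val`, `test` (each a list of entries with
#'   `input` array (ny, nx, nz, 5), `target` array (ny, nx, nz), `id`) and
#'   `manifest` data frame (id, split).
#' @export
make_paired_dataset <- function(phantoms,
                                generator_spec = list(name = "rho"),
                                split = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(phantoms) >= 3L)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  n <- length(phantoms)
  n_val <- floor(split[2] * n); n_test <- floor(split[3] * n)
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  labels <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  membership <- character(n)
  membership[perm] <- labels
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- phantoms[[i]]
    input <- phantom_input_channels(ph)
    target <- make_fluorescence_target(ph, generator_spec,
                                       seed = seed + i)
    entries[[i]] <- list(input = input, target = target, id = i)
  }
  out <- list(train = entries[membership == "train"],
              val = entries[membership == "val"],
              test = entries[membership == "test"],
              manifest = data.frame(id = seq_len(n), split = membership))
  out
}

#' Label-free input channels of a phantom
#'
#' Channel order: BF (transmission), phase, retardance, orientation-x,
#' orientation-y, where (ox, oy) = rho * (cos 2 omega, sin 2 omega).
#'
#' @param ph A `phantom`.
#' @return Array (ny, nx, nz, 5), dimnames on the channel axis.
#' @export
phantom_input_channels <- function(ph) {
  d <- ph$shape
  out <- array(0, c(d, 5L))
  out[, , , 1] <- ph$t_map
  out[, , , 2] <- ph$phi_map
  out[, , , 3] <- ph$rho_map
  out[, , , 4] <- ph$rho_map * cos(2 * ph$omega_map)
  out[, , , 5] <- ph$rho_map * sin(2 * ph$omega_map)
  dimnames(out) <- c(rep(list(NULL), 3),
                     list(c("BF", "phase", "retardance", "ox", "oy")))
  out
}
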