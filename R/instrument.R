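#' Instrument matrix of the five-state elliptical acquisition scheme
#'
#' The microscope illuminates the specimen sequentially with right-handed
#' circular light (RCP) and four elliptical states (0, 45, 90, 135 degrees)
#' whose ellipticity is set by the LC compensatory retardance chi, and
#' detects through a left-handed circular analyzer. The measured intensity
#' vector I relates to the retrievable Mueller coefficients m = (m0..m3) of
#' the specimen through I = A m, with the 5 x 4 instrument matrix
#' \deqn{A = \begin{pmatrix} 1 & 0 & 0 & -1 \\ 1 & \sin\chi & 0 & -\cos\chi \\
#'   1 & 0 & \sin\chi & -\cos\chi \\ 1 & -\sin\chi & 0 & -\cos\chi \\
#'   1 & 0 & -\sin\chi & -\cos\chi \end{pmatrix}.}
#' The matrix has full column rank for all chi in (0, pi); at sin(chi) = 0
#' all elliptical rows collapse onto the RCP row and inversion is impossible.
#'
#' @param chi LC compensatory retardance in radians.
#' @return An object of class `instrument_matrix` with elements `a` (5 x 4
#'   matrix, rows named RCP/0/45/90/135), `chi`, and `pinv` (the 4 x 5
#'   Moore-Penrose pseudo-inverse, precomputed once).
#' @examples
#' A <- instrument_matrix(pi / 2)
#' A$a
#' @export
instrument_matrix <- function(chi = 0.06 * pi) {
  stopifnot(is.numeric(chi), length(chi) == 1L, is.finite(chi))
  s <- sin(chi); c <- cos(chi)
  a <- rbind(RCP     = c(1,  0,  0, -1),
             `0`     = c(1,  s,  0, -c),
             `45`    = c(1,  0,  s, -c),
             `90`    = c(1, -s,  0, -c),
             `135`   = c(1,  0, -s, -c))
  colnames(a) <- c("m0", "m1", "m2", "m3")
  sv <- svd(a)
  tol <- max(dim(a)) * .Machine$double.eps * sv$d[1]
  if (sum(sv$d > tol) < 4L)
    stop("degenerate instrument: instrument matrix is rank-deficient ",
         "(sin(chi) = 0); choose chi in the open interval (0, pi)")
  pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
  structure(list(a = a, chi = chi, pinv = pinv), class = "instrument_matrix")
}

#' @export
print.instrument_matrix <- function(x, ...) {
  cat(sprintf("instrument_matrix (chi = %.4g rad):\n", x$chi))
  print(round(x$a, 6))
  invisible(x)
}

channel_names <- function() c("RCP", "0", "45", "90", "135")
component_names <- function() c("m0", "m1", "m2", "m3")

## Stacks are plain numeric arrays with the channel/component axis LAST:
## dim (y, x, 5) or (y, x, z, 5) for polarization stacks, and (..., 4) for
## Mueller coefficient stacks. Helpers below validate and tag them.

#' Construct a five-channel polarization intensity stack
#'
#' Wraps a numeric array whose last dimension indexes the five acquisition
#' channels in the fixed order RCP, 0, 45, 90, 135 degrees. Values are camera
#' counts: finite and non-negative.
#'
#' @param x Numeric array, last dimension of extent 5 (e.g. y, x, z, channel).
#' @param channels Channel names; must equal `c("RCP","0","45","90","135")`
#'   (the order is part of the acquisition contract and is validated, not
#'   permuted).
#' @return The array with class `polarization_stack` and channel names in
#'   `dimnames` on the last axis.
#' @export
polarization_stack <- function(x, channels = channel_names()) {
  x <- as_stack(x, 5L, "polarization stack")
  if (!identical(as.character(channels), channel_names()))
    stop("channel order must be exactly RCP, 0, 45, 90, 135")
  if (anyNA(x) || !all(is.finite(x)))
    stop("polarization stack must be finite")
  if (min(x) < 0)
    stop("polarization stack must be non-negative (camera counts)")
  class(x) <- c("polarization_stack", "array")
  x
}

#' Construct a Mueller coefficient stack
#'
#' Wraps a numeric array whose last dimension holds the four retrievable
#' Mueller coefficients (m0, m1, m2, m3) per voxel. m0 is the transmitted
#' intensity; for a physical specimen sqrt(m1^2+m2^2+m3^2) <= m0.
#'
#' @param x Numeric array, last dimension of extent 4.
#' @return The array with class `mueller_stack`.
#' @export
mueller_stack <- function(x) {
  x <- as_stack(x, 4L, "Mueller coefficient stack")
  class(x) <- c("mueller_stack", "array")
  x
}

as_stack <- function(x, nlast, what) {
  if (is.null(dim(x))) {
    if (length(x) == nlast) dim(x) <- c(1L, 1L, nlast)
    else stop(what, ": expected an array with last dimension ", nlast)
  }
  d <- dim(x)
  if (d[length(d)] != nlast)
    stop(what, ": last dimension must have extent ", nlast,
         ", got ", d[length(d)])
  storage.mode(x) <- "double"
  x
}

stack_mat <- function(x) {
  ## flatten all leading dims; one row per voxel, one column per channel
  d <- dim(x)
  nl <- d[length(d)]
  matrix(as.numeric(x), ncol = nl)
}

mat_stack <- function(m, template_dim, nlast) {
  dim(m) <- c(template_dim[-length(template_dim)], nlast)
  m
}

#' Mueller coefficients of a specimen from its physical properties
#'
#' Maps transmission t, depolarization p, retardance rho and slow-axis
#' orientation omega to the retrievable Mueller coefficient vector
#' \deqn{m = (t,\; t p \sin 2\omega \sin\rho,\; -t p \cos 2\omega \sin\rho,\;
#'   t p \cos\rho).}
#' All arguments are recycled to a common shape; array inputs produce a
#' `mueller_stack` with one extra trailing dimension of extent 4.
#'
#' @param t Transmission, in (0, 2].
#' @param p Depolarization factor, in (0, 1].
#' @param rho Retardance in radians.
#' @param omega Slow-axis orientation in radians (axis: omega and omega + pi
#'   are equivalent).
#' @return A `mueller_stack`.
#' @export
mueller_coefficients <- function(t, p, rho, omega) {
  d <- dim(t)
  n <- max(length(t), length(p), length(rho), length(omega))
  t <- rep_len(as.numeric(t), n); p <- rep_len(as.numeric(p), n)
  rho <- rep_len(as.numeric(rho), n); omega <- rep_len(as.numeric(omega), n)
  m <- cbind(t,
             t * p * sin(2 * omega) * sin(rho),
             -t * p * cos(2 * omega) * sin(rho),
             t * p * cos(rho))
  if (is.null(d)) d <- n
  mueller_stack(array(m, dim = c(d, 4L)))
}

#' Forward model: Mueller coefficients to five-channel intensities
#'
#' Per-voxel matrix-vector product I = A m; linear in m.
#'
#' @param m A `mueller_stack` (last dimension 4).
#' @param a An `instrument_matrix`.
#' @return A `polarization_stack` with the same leading dimensions.
#' @export
forward_intensities <- function(m, a) {
  stopifnot(inherits(a, "instrument_matrix"))
  m <- as_stack(m, 4L, "Mueller coefficient stack")
  im <- stack_mat(m) %*% t(a$a)
  polarization_stack(mat_stack(im, dim(m), 5L))
}

#' Inverse model: five-channel intensities to Mueller coefficients
#'
#' Per-voxel ordinary least squares via the precomputed Moore-Penrose
#' pseudo-inverse of the instrument matrix: m-hat = argmin ||A m - I||^2,
#' exact whenever I lies in the column space of A (5 equations, 4 unknowns).
#' Voxels whose recovered m0 is non-positive are physically invalid
#' (non-positive transmission) and are flagged in the `"valid"` attribute
#' rather than silently used.
#'
#' @param stack A `polarization_stack` (last dimension 5, order
#'   RCP/0/45/90/135).
#' @param a An `instrument_matrix`.
#' @return A `mueller_stack`; attribute `"valid"` is a logical array over
#'   voxels, FALSE where m0 <= 0.
#' @export
invert_intensities <- function(stack, a) {
  stopifnot(inherits(a, "instrument_matrix"))
  stack <- as_stack(stack, 5L, "polarization stack")
  mm <- stack_mat(stack) %*% t(a$pinv)
  out <- mueller_stack(mat_stack(mm, dim(stack), 4L))
  d <- dim(out)
  valid <- array(mm[, 1] > 0, dim = d[-length(d)])
  attr(out, "valid") <- valid
  out
}
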