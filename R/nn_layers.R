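## Minimal CPU tensor layers with hand-written backward passes.
##
## Internal layout is batch-first, channel-last: (B, spatial..., C). In
## column-major R this makes the (B*prod(spatial), C) matrix view of every
## activation a zero-copy reshape, so convolutions (offset-sum of small
## BLAS products), batch norm (column statistics), channel concatenation
## (cbind) and residual adds all run without array permutations. The
## public engine (nn_forward / nn_backward in nn_model.R) converts from
## the package-facing (spatial..., C, B) layout once per call. No external
## deep-learning framework exists in the supported environment, so
## everything the residual U-Nets need is implemented here from scratch.

pad_spatial <- function(x, pad) {
  ## zero-pad the spatial axes (2 .. 1+length(pad)) of (B, spatial..., C)
  if (all(pad == 0)) return(x)
  d <- dim(x)
  nd2 <- d
  nd2[1L + seq_along(pad)] <- d[1L + seq_along(pad)] + 2L * pad
  out <- array(0, nd2)
  idx <- lapply(seq_along(d), function(i) {
    if (i >= 2L && i <= 1L + length(pad)) seq_len(d[i]) + pad[i - 1L]
    else seq_len(d[i])
  })
  do.call(`[<-`, c(list(out), idx, list(x)))
}

crop_spatial <- function(x, pad) {
  if (all(pad == 0)) return(x)
  d <- dim(x)
  idx <- lapply(seq_along(d), function(i) {
    if (i >= 2L && i <= 1L + length(pad))
      (pad[i - 1L] + 1L):(d[i] - pad[i - 1L])
    else seq_len(d[i])
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

conv_geom <- function(sp_in, kernel, stride, B) {
  ## row indices into the (B*prod(sp_in), C) matrix view for each kernel
  ## offset: rows[, k] lists, batch-fastest, the input sample feeding each
  ## output position under offset k
  nd <- length(sp_in)
  n_out <- (sp_in - kernel) %/% stride + 1L
  stopifnot(all(n_out >= 1L))
  smul <- cumprod(c(1L, sp_in[-nd]))
  kgrid <- as.matrix(do.call(expand.grid,
                             lapply(kernel, function(k) 0:(k - 1L))))
  ogrid <- as.matrix(do.call(expand.grid,
                             lapply(seq_len(nd), function(i)
                               seq(0L, by = stride[i],
                                   length.out = n_out[i]))))
  base <- as.integer(ogrid %*% smul)
  koff <- as.integer(kgrid %*% smul)
  kvol <- nrow(kgrid); npos <- nrow(ogrid)
  rows <- matrix(0L, B * npos, kvol)
  bseq <- seq_len(B)
  for (k in seq_len(kvol))
    rows[, k] <- rep((base + koff[k]) * B, each = B) + bseq
  list(n_out = n_out, rows = rows, kvol = kvol, npos = npos)
}

.idx_cache <- new.env(parent = emptyenv())
conv_geom_cached <- function(sp_in, kernel, stride, B) {
  key <- paste(c(sp_in, kernel, stride, B), collapse = ",")
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- conv_geom(sp_in, kernel, stride, B)
    .idx_cache[[key]] <- v
  }
  v
}

conv_forward <- function(x, W, b, stride, pad) {
  ## x: (B, spatial..., Cin); W: (kernel..., Cin, Cout); b: (Cout)
  d <- dim(x); nd <- length(d) - 2L
  kd <- dim(W); kernel <- kd[seq_len(nd)]
  Cin <- kd[nd + 1L]; Cout <- kd[nd + 2L]
  B <- d[1L]
  stopifnot(d[nd + 2L] == Cin)
  xp <- pad_spatial(x, pad)
  spp <- dim(xp)[1L + seq_len(nd)]
  g <- conv_geom_cached(spp, kernel, stride, B)
  xm <- xp
  dim(xm) <- c(B * prod(spp), Cin)
  Wm <- matrix(W, ncol = Cout)
  out <- matrix(0, B * g$npos, Cout)
  for (k in seq_len(g$kvol)) {
    Wk <- Wm[k + g$kvol * (seq_len(Cin) - 1L), , drop = FALSE]
    out <- out + xm[g$rows[, k], , drop = FALSE] %*% Wk
  }
  out <- out + rep(as.vector(b), each = nrow(out))
  dim(out) <- c(B, g$n_out, Cout)
  list(out = out, cache = list(xm = xm, g = g, spp = spp, dims = d,
                               pad = pad))
}

conv_backward <- function(dout, W, cache) {
  d <- cache$dims; nd <- length(d) - 2L
  Cin <- d[nd + 2L]; B <- d[1L]
  Cout <- dim(W)[nd + 2L]
  g <- cache$g
  dm <- dout
  dim(dm) <- c(B * g$npos, Cout)
  Wm <- matrix(W, ncol = Cout)
  dW <- matrix(0, nrow(Wm), Cout)
  dxm <- matrix(0, B * prod(cache$spp), Cin)
  for (k in seq_len(g$kvol)) {
    crow <- k + g$kvol * (seq_len(Cin) - 1L)
    rows <- g$rows[, k]
    Xk <- cache$xm[rows, , drop = FALSE]
    dW[crow, ] <- crossprod(Xk, dm)
    dxm[rows, ] <- dxm[rows, ] + dm %*% t(Wm[crow, , drop = FALSE])
  }
  db <- colSums(dm)
  dim(dxm) <- c(B, cache$spp, Cin)
  dx <- crop_spatial(dxm, cache$pad)
  list(dx = dx, dW = array(dW, dim(W)), db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

bn_forward <- function(x, gamma, beta, running, training, momentum = 0.1,
                       eps = 1e-5) {
  ## channel axis is last; (B*S, C) view is zero-copy
  d <- dim(x); C <- d[length(d)]
  m <- x
  dim(m) <- c(prod(d) / C, C)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    va <- colMeans(xc^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean; va <- running$var
    xc <- sweep(m, 2, mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, as.vector(gamma), `*`), 2, as.vector(beta),
               `+`)
  dim(out) <- d
  list(out = out, running = running,
       cache = list(xhat = xhat, istd = istd, d = d,
                    training = training))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$d; C <- d[length(d)]
  dm <- dout
  dim(dm) <- c(prod(d) / C, C)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  if (cache$training) {
    dxhat <- sweep(dm, 2, colMeans(dm)) -
      sweep(cache$xhat, 2, colMeans(dm * cache$xhat), `*`)
  } else {
    dxhat <- dm
  }
  dx <- sweep(dxhat, 2, as.vector(gamma) * cache$istd, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

avgpool_forward <- function(x, kernel, stride, pad) {
  d <- dim(x); nd <- length(d) - 2L
  C <- d[nd + 2L]; B <- d[1L]
  xp <- pad_spatial(x, pad)
  spp <- dim(xp)[1L + seq_len(nd)]
  g <- conv_geom_cached(spp, kernel, stride, B)
  xm <- xp
  dim(xm) <- c(B * prod(spp), C)
  out <- matrix(0, B * g$npos, C)
  for (k in seq_len(g$kvol)) out <- out + xm[g$rows[, k], , drop = FALSE]
  out <- out / g$kvol
  dim(out) <- c(B, g$n_out, C)
  list(out = out, cache = list(g = g, spp = spp, dims = d, pad = pad))
}

avgpool_backward <- function(dout, cache) {
  d <- cache$dims; nd <- length(d) - 2L
  C <- d[nd + 2L]; B <- d[1L]
  g <- cache$g
  dm <- dout
  dim(dm) <- c(B * g$npos, C)
  dm <- dm / g$kvol
  dxm <- matrix(0, B * prod(cache$spp), C)
  for (k in seq_len(g$kvol)) {
    rows <- g$rows[, k]
    dxm[rows, ] <- dxm[rows, ] + dm
  }
  dim(dxm) <- c(B, cache$spp, C)
  crop_spatial(dxm, cache$pad)
}

upsample_matrix <- function(n, factor = 2L) {
  ## linear-interpolation matrix (factor*n x n), half-pixel convention
  m <- factor * n
  pos <- ((seq_len(m) - 0.5) / factor) - 0.5    # in 0-based input coords
  pos <- pmin(pmax(pos, 0), n - 1)
  lo <- floor(pos); hi <- pmin(lo + 1, n - 1); w <- pos - lo
  U <- matrix(0, m, n)
  U[cbind(seq_len(m), lo + 1)] <- U[cbind(seq_len(m), lo + 1)] + (1 - w)
  U[cbind(seq_len(m), hi + 1)] <- U[cbind(seq_len(m), hi + 1)] + w
  U
}

apply_axis_mat <- function(x, M, axis) {
  ## linear map along one axis of an array
  d <- dim(x)
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  m <- M %*% matrix(xp, nrow = d[axis])
  nd <- c(nrow(M), d[-axis])
  out <- array(m, nd)
  aperm(out, order(perm))
}

upsample_forward <- function(x, axes, factor = 2L) {
  ## axes are spatial axis numbers (1-based within the spatial block)
  d <- dim(x)
  mats <- lapply(axes, function(ax) upsample_matrix(d[ax + 1L], factor))
  out <- x
  for (i in seq_along(axes))
    out <- apply_axis_mat(out, mats[[i]], axes[i] + 1L)
  list(out = out, cache = list(mats = mats, axes = axes))
}

upsample_backward <- function(dout, cache) {
  out <- dout
  for (i in rev(seq_along(cache$axes)))
    out <- apply_axis_mat(out, t(cache$mats[[i]]), cache$axes[i] + 1L)
  out
}

he_init <- function(kdim) {
  nd <- length(kdim)
  fan_in <- prod(kdim[-nd])
  array(stats::rnorm(prod(kdim), 0, sqrt(2 / fan_in)), kdim)
}
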