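#' Specification of a residual U-Net translation model
#'
#' Declarative description of the 2D / 2.5D / 3D variants. The encoding
#' path uses blocks of two conv-ReLU-batchnorm repeats with a residual
#' connection from block input to block output (1x1 projection when the
#' channel count changes). Downsampling between encoder blocks is a 2x2
#' stride-2 convolution (2D), a 3x3x3 stride-2 convolution (3D), or an
#' N x 2 x 2 average pooling (2.5D). Decoding levels upsample by bilinear
#' interpolation and concatenate the matching encoder features; the 2.5D
#' variant first collapses the N z-slices of each encoder output to one
#' plane through an N x 1 x 1 valid convolution, so its output z-extent is
#' one per input window. The final block is a single convolution with no
#' activation (regression output). See the package vignette for how the
#' remaining unprinted details were pinned down by the published parameter
#' counts.
#'
#' @param variant "2D", "2.5D" or "3D".
#' @param in_channels Number of input channels (>= 1).
#' @param out_channels Number of output channels (default 1).
#' @param n_slices N, the odd number of input z-slices (2.5D only;
#'   typically 3, 5 or 7).
#' @param filters Encoder filter counts, strictly increasing; defaults
#'   c(16, 32, 64, 128, 256) for 2D/2.5D and c(16, 32, 64, 128) for 3D.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(variant = c("2D", "2.5D", "3D"), in_channels = 1L,
                       out_channels = 1L, n_slices = 5L, filters = NULL) {
  variant <- match.arg(variant)
  if (is.null(filters))
    filters <- if (variant == "3D") c(16L, 32L, 64L, 128L)
               else c(16L, 32L, 64L, 128L, 256L)
  stopifnot(in_channels >= 1L, out_channels >= 1L, length(filters) >= 2L)
  if (any(diff(filters) <= 0))
    stop("filters must be strictly increasing along the encoder")
  if (variant == "2.5D" && n_slices %% 2L == 0L)
    stop("2.5D variant requires an odd number of input slices")
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 n_slices = as.integer(n_slices),
                 filters = as.integer(filters)),
            class = "model_spec")
}

## ---- graph builder ---------------------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$ops <- list(); env$params <- list(); env$running <- list()
  env$node <- 1L
  env
}

b_node <- function(b) { b$node <- b$node + 1L; b$node }

b_op <- function(b, op, inputs, out, ...) {
  b$ops[[length(b$ops) + 1L]] <- c(list(op = op, inputs = inputs,
                                        out = out), list(...))
  out
}

b_conv <- function(b, in_node, name, kernel, cin, cout, stride, pad) {
  b$params[[paste0(name, ".W")]] <- he_init(c(kernel, cin, cout))
  b$params[[paste0(name, ".b")]] <- numeric(cout)
  b_op(b, "conv", in_node, b_node(b), param = name,
       stride = as.integer(stride), pad = as.integer(pad))
}

b_bn <- function(b, in_node, name, c) {
  b$params[[paste0(name, ".gamma")]] <- rep(1, c)
  b$params[[paste0(name, ".beta")]] <- rep(0, c)
  b$running[[name]] <- list(mean = rep(0, c), var = rep(1, c))
  b_op(b, "bn", in_node, b_node(b), param = name)
}

b_block <- function(b, in_node, prefix, cin, cout, kernel, nrep,
                    residual) {
  h <- in_node; c <- cin
  pad <- (kernel - 1L) %/% 2L
  for (r in seq_len(nrep)) {
    nm <- sprintf("%s.conv%d", prefix, r)
    h <- b_conv(b, h, nm, kernel, c, cout, rep(1L, length(kernel)), pad)
    h <- b_op(b, "relu", h, b_node(b))
    h <- b_bn(b, h, sprintf("%s.bn%d", prefix, r), cout)
    c <- cout
  }
  if (residual) {
    res <- in_node
    if (cin != cout)
      res <- b_conv(b, in_node, paste0(prefix, ".proj"),
                    rep(1L, length(kernel)), cin, cout,
                    rep(1L, length(kernel)), rep(0L, length(kernel)))
    h <- b_op(b, "add", c(h, res), b_node(b))
  }
  h
}

#' Build a residual U-Net from a model specification
#'
#' Allocates He-initialized weights and constructs the forward graph.
#' Deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Seed for weight initialization.
#' @return Object of class `unet_model`: list with `spec`, `ops`, `params`
#'   (named arrays), `running` (batch-norm running statistics), and node
#'   bookkeeping.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, build_model_impl(spec))
}

build_model_impl <- function(spec) {
  b <- new_builder()
  f <- spec$filters; L <- length(f)
  ci <- spec$in_channels
  input <- 1L
  if (spec$variant == "2D") {
    h <- input; c <- ci; skips <- list()
    for (i in seq_len(L)) {
      h <- b_block(b, h, sprintf("enc%d", i), c, f[i], c(3L, 3L), 2L, TRUE)
      c <- f[i]
      if (i < L) {
        skips[[i]] <- h
        h <- b_conv(b, h, sprintf("down%d", i), c(2L, 2L), c, c,
                    c(2L, 2L), c(0L, 0L))
      }
    }
    for (i in rev(seq_len(L - 1L))) {
      h <- b_op(b, "upsample", h, b_node(b), axes = c(1L, 2L))
      h <- b_op(b, "concat", c(skips[[i]], h), b_node(b))
      h <- b_block(b, h, sprintf("dec%d", i), f[i] + c, f[i], c(3L, 3L),
                   1L, TRUE)
      c <- f[i]
    }
    h <- b_conv(b, h, "out", c(3L, 3L), c, spec$out_channels, c(1L, 1L),
                c(1L, 1L))
  } else if (spec$variant == "3D") {
    h <- input; c <- ci; skips <- list()
    for (i in seq_len(L)) {
      h <- b_block(b, h, sprintf("enc%d", i), c, f[i], c(3L, 3L, 3L), 2L,
                   TRUE)
      c <- f[i]
      if (i < L) {
        skips[[i]] <- h
        h <- b_conv(b, h, sprintf("down%d", i), c(3L, 3L, 3L), c, c,
                    c(2L, 2L, 2L), c(1L, 1L, 1L))
      }
    }
    for (i in rev(seq_len(L - 1L))) {
      h <- b_op(b, "upsample", h, b_node(b), axes = c(1L, 2L, 3L))
      h <- b_op(b, "concat", c(skips[[i]], h), b_node(b))
      h <- b_block(b, h, sprintf("dec%d", i), f[i] + c, f[i],
                   c(3L, 3L, 3L), 1L, TRUE)
      c <- f[i]
    }
    h <- b_conv(b, h, "out", c(3L, 3L, 3L), c, spec$out_channels,
                c(1L, 1L, 1L), c(1L, 1L, 1L))
  } else {                                   # 2.5D
    N <- spec$n_slices
    h <- input; c <- ci; skips <- list()
    for (i in seq_len(L)) {
      h <- b_block(b, h, sprintf("enc%d", i), c, f[i], c(3L, 3L, 3L), 2L,
                   TRUE)
      c <- f[i]
      sk <- b_conv(b, h, sprintf("skip%d", i), c(1L, 1L, N), c, c,
                   c(1L, 1L, 1L), c(0L, 0L, 0L))
      skips[[i]] <- b_op(b, "squeeze", sk, b_node(b), axis = 3L)
      if (i < L)
        h <- b_op(b, "avgpool", h, b_node(b),
                  kernel = c(2L, 2L, N), stride = c(2L, 2L, 1L),
                  pad = c(0L, 0L, (N - 1L) %/% 2L))
    }
    d <- skips[[L]]
    for (i in rev(seq_len(L - 1L))) {
      d <- b_op(b, "upsample", d, b_node(b), axes = c(1L, 2L))
      d <- b_op(b, "concat", c(skips[[i]], d), b_node(b))
      d <- b_block(b, d, sprintf("dec%d", i), f[i] + c, f[i], c(3L, 3L),
                   2L, FALSE)
      c <- f[i]
    }
    h <- b_conv(b, d, "out", c(3L, 3L), c, spec$out_channels, c(1L, 1L),
                c(1L, 1L))
  }
  structure(list(spec = spec, ops = b$ops, params = b$params,
                 running = b$running, n_nodes = b$node, output = h),
            class = "unet_model")
}

#' Count trainable parameters of a built model
#'
#' Includes convolution weights and biases and the batch-norm scale/shift
#' parameters (running statistics are not trainable and are excluded).
#'
#' @param model A `unet_model`.
#' @return Integer total.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  np <- count_parameters(x)
  cat(sprintf("unet_model %s: %d channels in, filters [%s], %s parameters\n",
              x$spec$variant, x$spec$in_channels,
              paste(x$spec$filters, collapse = ","),
              format(np, big.mark = ",")))
  invisible(x)
}

check_input_shape <- function(model, x) {
  spec <- model$spec
  d <- dim(x)
  L <- length(spec$filters)
  div <- 2^(L - 1L)
  nd_needed <- switch(spec$variant, "2D" = 4L, 5L)
  if (length(d) != nd_needed)
    stop("input must have ", nd_needed, " dims (spatial..., channel, batch)")
  nch <- d[length(d) - 1L]
  if (nch != spec$in_channels)
    stop("input has ", nch, " channels, model expects ", spec$in_channels)
  sp <- switch(spec$variant, "2D" = d[1:2], "2.5D" = d[1:2], "3D" = d[1:3])
  if (any(sp %% div != 0) || any(sp < div * 2))
    stop("spatial extent (", paste(sp, collapse = "x"),
         ") must be a multiple of ", div, " and at least ", 2 * div,
         " (input smaller than the receptive field)")
  if (spec$variant == "2.5D" && d[3] != spec$n_slices)
    stop("2.5D input must have ", spec$n_slices, " z-slices, got ", d[3])
  invisible(TRUE)
}

## ---- forward / backward engine --------------------------------------
##
## Public tensors are (spatial..., C, B); internally everything runs
## batch-first channel-last (B, spatial..., C) so matrix views are
## zero-copy. The two aperm conversions happen once per call.

to_internal <- function(x) {
  nd <- length(dim(x))
  aperm(x, c(nd, seq_len(nd - 2L), nd - 1L))
}

to_external <- function(x) {
  nd <- length(dim(x))
  aperm(x, c(seq_len(nd - 2L) + 1L, nd, 1L))
}

nn_forward <- function(model, x, training = FALSE) {
  check_input_shape(model, x)
  x <- to_internal(x)
  vals <- vector("list", model$n_nodes)
  caches <- vector("list", length(model$ops))
  vals[[1L]] <- x
  for (k in seq_along(model$ops)) {
    op <- model$ops[[k]]
    inp <- vals[[op$inputs[1L]]]
    r <- switch(op$op,
      conv = {
        W <- model$params[[paste0(op$param, ".W")]]
        bb <- model$params[[paste0(op$param, ".b")]]
        conv_forward(inp, W, bb, op$stride, op$pad)
      },
      relu = relu_forward(inp),
      bn = {
        g <- model$params[[paste0(op$param, ".gamma")]]
        be <- model$params[[paste0(op$param, ".beta")]]
        rr <- bn_forward(inp, g, be, model$running[[op$param]], training)
        if (training) model$running[[op$param]] <- rr$running
        rr
      },
      add = {
        inp2 <- vals[[op$inputs[2L]]]
        list(out = inp + inp2, cache = NULL)
      },
      concat = {
        inp2 <- vals[[op$inputs[2L]]]
        nd <- length(dim(inp))
        list(out = cat_ch(inp, inp2),
             cache = c(dim(inp)[nd], dim(inp2)[nd]))
      },
      avgpool = avgpool_forward(inp, op$kernel, op$stride, op$pad),
      upsample = upsample_forward(inp, op$axes),
      squeeze = {
        d <- dim(inp)
        stopifnot(d[op$axis + 1L] == 1L)
        out <- inp; dim(out) <- d[-(op$axis + 1L)]
        list(out = out, cache = d)
      })
    vals[[op$out]] <- r$out
    caches[[k]] <- r$cache
  }
  list(out = to_external(vals[[model$output]]), caches = caches,
       model = model)
}

cat_ch <- function(a, b) {
  ## channel axis last in the internal layout
  nd <- length(dim(a))
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-nd] == db[-nd]))
  dim(a) <- c(prod(da[-nd]), da[nd])
  dim(b) <- c(prod(db[-nd]), db[nd])
  out <- cbind(a, b)
  dim(out) <- c(da[-nd], da[nd] + db[nd])
  out
}

split_ch <- function(g, c1, c2) {
  d <- dim(g); nd <- length(d)
  dim(g) <- c(prod(d[-nd]), c1 + c2)
  a <- g[, seq_len(c1), drop = FALSE]
  b <- g[, c1 + seq_len(c2), drop = FALSE]
  dim(a) <- c(d[-nd], c1)
  dim(b) <- c(d[-nd], c2)
  list(a, b)
}

nn_backward <- function(fw, dout) {
  model <- fw$model
  gnode <- vector("list", model$n_nodes)
  grads <- list()
  gnode[[model$output]] <- to_internal(dout)
  addg <- function(cur, g) if (is.null(cur)) g else cur + g
  for (k in rev(seq_along(model$ops))) {
    op <- model$ops[[k]]
    g <- gnode[[op$out]]
    if (is.null(g)) next
    switch(op$op,
      conv = {
        W <- model$params[[paste0(op$param, ".W")]]
        r <- conv_backward(g, W, fw$caches[[k]])
        grads[[paste0(op$param, ".W")]] <-
          addg(grads[[paste0(op$param, ".W")]], r$dW)
        grads[[paste0(op$param, ".b")]] <-
          addg(grads[[paste0(op$param, ".b")]], r$db)
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]], r$dx)
      },
      relu = {
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]],
                                       relu_backward(g, fw$caches[[k]]))
      },
      bn = {
        gamma <- model$params[[paste0(op$param, ".gamma")]]
        r <- bn_backward(g, gamma, fw$caches[[k]])
        grads[[paste0(op$param, ".gamma")]] <-
          addg(grads[[paste0(op$param, ".gamma")]], r$dgamma)
        grads[[paste0(op$param, ".beta")]] <-
          addg(grads[[paste0(op$param, ".beta")]], r$dbeta)
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]], r$dx)
      },
      add = {
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]], g)
        gnode[[op$inputs[2L]]] <- addg(gnode[[op$inputs[2L]]], g)
      },
      concat = {
        cc <- fw$caches[[k]]
        sp <- split_ch(g, cc[1L], cc[2L])
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]], sp[[1L]])
        gnode[[op$inputs[2L]]] <- addg(gnode[[op$inputs[2L]]], sp[[2L]])
      },
      avgpool = {
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]],
                                       avgpool_backward(g, fw$caches[[k]]))
      },
      upsample = {
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]],
                                       upsample_backward(g, fw$caches[[k]]))
      },
      squeeze = {
        gg <- g; dim(gg) <- fw$caches[[k]]
        gnode[[op$inputs[1L]]] <- addg(gnode[[op$inputs[1L]]], gg)
      })
    gnode[[op$out]] <- NULL
  }
  grads
}

#' Run a built model on a batch of inputs (inference mode)
#'
#' @param model A `unet_model`.
#' @param x Input batch: (H, W, C, B) for 2D, (H, W, N, C, B) for 2.5D,
#'   (H, W, D, C, B) for 3D.
#' @return Output array; 2.5D outputs have z-extent 1:
#'   (H, W, 1, out_channels, B).
#' @export
model_forward <- function(model, x) {
  out <- nn_forward(model, x, training = FALSE)$out
  if (model$spec$variant == "2.5D") {
    d <- dim(out)
    dim(out) <- c(d[1], d[2], 1L, d[3], d[4])
  }
  out
}
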