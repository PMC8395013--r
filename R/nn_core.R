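#' @useDynLib sctgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Tensor helpers. All activations/feature maps are 4D arrays dim (H, W, C, N).
# ---------------------------------------------------------------------------

as_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

# TensorFlow-style "same" padding: total pad = k - s when the input size is a
# multiple of the stride; the extra pixel (even totals) goes bottom/right.
same_pads <- function(size, k, stride) {
  if (stride == 1L) total <- k - 1L
  else total <- max(0L, (as.integer(ceiling(size / stride)) - 1L) * stride + k - size)
  a <- total %/% 2L
  c(a, total - a)
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# Layers. Each layer is an environment carrying parameters (W, b, gamma, beta),
# their gradients (dW, db, ...), and a forward cache. layer_forward() /
# layer_backward() dispatch on $type.
# ---------------------------------------------------------------------------

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  class(e) <- c(paste0("layer_", type), "sctgan_layer")
  e
}

# Counter handing out unique ids for conv layers (the FFT path keys its
# per-layer forward caches on them).
.layer_counter <- new.env(parent = emptyenv())
.layer_counter$n <- 0L

next_layer_id <- function() {
  .layer_counter$n <- .layer_counter$n + 1L
  .layer_counter$n
}

layer_conv <- function(in_channels, out_channels, kernel_size,
                       stride = 1L, use_bias = TRUE) {
  e <- new_layer("conv")
  e$id <- next_layer_id()
  e$k <- as.integer(kernel_size)
  e$stride <- as.integer(stride)
  e$cin <- as.integer(in_channels)
  e$cout <- as.integer(out_channels)
  # large stride-1 kernels run in the frequency domain (cost independent of
  # kernel size); small kernels through im2col + GEMM
  e$algo <- if (e$k >= 5L && e$stride == 1L) "fft" else "gemm"
  e$W <- array(0, dim = c(e$k, e$k, e$cin, e$cout))
  if (use_bias) e$b <- rep(0, e$cout)
  e
}

layer_instnorm <- function(channels, eps = 1e-5) {
  e <- new_layer("instnorm")
  e$c <- as.integer(channels)
  e$eps <- eps
  e$gamma <- rep(1, channels)
  e$beta <- rep(0, channels)
  e
}

layer_swish <- function() new_layer("swish")

# fused instance normalization + swish (C++ float kernel with its own cache)
layer_inswish <- function(channels, eps = 1e-5) {
  e <- new_layer("inswish")
  e$id <- next_layer_id()
  e$c <- as.integer(channels)
  e$eps <- eps
  e$gamma <- rep(1, channels)
  e$beta <- rep(0, channels)
  e
}
layer_sigmoid <- function() new_layer("sigmoid")
layer_maxpool2 <- function() new_layer("maxpool2")
layer_upnearest2 <- function() new_layer("upnearest2")

layer_forward <- function(e, x, train = TRUE) {
  switch(e$type,
    conv = {
      if (e$algo == "fft")
        return(.fftconv_forward(x, e$W, e$b, e$id, train))
      d <- dim(x)
      ph <- same_pads(d[1L], e$k, e$stride)
      pw <- same_pads(d[2L], e$k, e$stride)
      if (train) { e$x <- x; e$pads <- c(ph, pw) }
      .conv2d_forward(x, e$W, e$b, e$stride, ph[1L], ph[2L], pw[1L], pw[2L])
    },
    inswish = .inswish_forward(x, e$gamma, e$beta, e$eps, e$id, train),
    instnorm = {
      d <- dim(x)
      m <- d[1L] * d[2L]
      xm <- matrix(x, m, d[3L] * d[4L])
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = m)
      v <- colMeans(xc * xc)
      istd <- 1 / sqrt(v + e$eps)
      xhat <- xc * rep(istd, each = m)
      cidx <- rep(seq_len(d[3L]), d[4L])
      y <- xhat * rep(e$gamma[cidx], each = m) + rep(e$beta[cidx], each = m)
      if (train) { e$xhat <- xhat; e$istd <- istd; e$cidx <- cidx; e$d <- d }
      array(y, dim = d)
    },
    swish = {
      s <- sigmoid_(x)
      if (train) { e$x <- x; e$s <- s }
      x * s
    },
    sigmoid = {
      s <- sigmoid_(x)
      if (train) e$s <- s
      s
    },
    maxpool2 = {
      r <- .maxpool2_forward(x)
      if (train) { e$idx <- r$idx; e$in_dim <- dim(x) }
      r$y
    },
    upnearest2 = {
      d <- dim(x)
      if (train) e$in_dim <- d
      x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
        drop = FALSE]
    },
    stop("unknown layer type: ", e$type)
  )
}

layer_backward <- function(e, dy, need_dx = TRUE) {
  switch(e$type,
    conv = {
      r <- if (e$algo == "fft")
        .fftconv_backward(e$W, dy, e$id, need_dx, !is.null(e$b))
      else {
        p <- e$pads
        .conv2d_backward(e$x, e$W, dy, e$stride, p[1L], p[2L], p[3L], p[4L],
                         need_dx, TRUE, !is.null(e$b))
      }
      e$dW <- acc_grad(e$dW, r$dw)
      if (!is.null(e$b)) e$db <- acc_grad(e$db, r$db)
      r$dx
    },
    inswish = {
      r <- .inswish_backward(dy, e$gamma, e$id, need_dx)
      e$dgamma <- acc_grad(e$dgamma, r$dgamma)
      e$dbeta <- acc_grad(e$dbeta, r$dbeta)
      r$dx
    },
    instnorm = {
      d <- e$d
      m <- d[1L] * d[2L]
      dym <- matrix(dy, m, d[3L] * d[4L])
      gs <- colSums(dym * e$xhat)
      bs <- colSums(dym)
      e$dgamma <- acc_grad(e$dgamma, as.numeric(rowsum(gs, e$cidx)))
      e$dbeta <- acc_grad(e$dbeta, as.numeric(rowsum(bs, e$cidx)))
      if (!need_dx) return(NULL)
      dxhat <- dym * rep(e$gamma[e$cidx], each = m)
      t1 <- colMeans(dxhat)
      t2 <- colMeans(dxhat * e$xhat)
      dx <- (dxhat - rep(t1, each = m) - e$xhat * rep(t2, each = m)) *
        rep(e$istd, each = m)
      array(dx, dim = d)
    },
    swish = dy * (e$s * (1 + e$x * (1 - e$s))),
    sigmoid = dy * e$s * (1 - e$s),
    maxpool2 = .maxpool2_backward(dy, e$idx, as.integer(e$in_dim)),
    upnearest2 = {
      d <- dim(dy)
      ho <- seq(1L, d[1L], by = 2L); he <- seq(2L, d[1L], by = 2L)
      wo <- seq(1L, d[2L], by = 2L); we <- seq(2L, d[2L], by = 2L)
      dy[ho, wo, , , drop = FALSE] + dy[he, wo, , , drop = FALSE] +
        dy[ho, we, , , drop = FALSE] + dy[he, we, , , drop = FALSE]
    },
    stop("unknown layer type: ", e$type)
  )
}

acc_grad <- function(old, g) if (is.null(old)) g else old + g

# ---------------------------------------------------------------------------
# Parameter plumbing shared by blocks and whole networks.
# ---------------------------------------------------------------------------

PARAM_SLOTS <- c("W", "b", "gamma", "beta")
GRAD_SLOTS <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")

layer_param_names <- function(e) {
  PARAM_SLOTS[vapply(PARAM_SLOTS, function(p) !is.null(e[[p]]), logical(1))]
}

#' Count trainable parameters of a network, block, or layer
#'
#' Sums the element counts of every learnable tensor (convolution kernels,
#' biases, and instance-normalization scale/shift vectors).
#'
#' @param model A network built by [build_generator()] or
#'   [build_discriminator()], a block, a single layer, or a list of these.
#' @return Integer number of trainable parameters.
#' @export
count_trainable_parameters <- function(model) {
  sum(vapply(collect_layers(model), function(e) {
    sum(vapply(layer_param_names(e), function(p) length(e[[p]]), numeric(1)))
  }, numeric(1)))
}

# Flatten any nesting of layers / blocks / networks into a list of layer envs.
collect_layers <- function(x) {
  if (inherits(x, "sctgan_layer")) return(list(x))
  if (is.environment(x) && !is.null(x$layers)) return(collect_layers(x$layers))
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

zero_grads <- function(model) {
  for (e in collect_layers(model)) {
    for (p in layer_param_names(e)) e[[GRAD_SLOTS[[p]]]] <- NULL
  }
  invisible(model)
}

# Snapshot / restore parameter values (used for checkpointing on best
# validation SSIM and for lr = 0 invariance tests).
get_weights <- function(model) {
  lapply(collect_layers(model), function(e) {
    stats::setNames(lapply(layer_param_names(e), function(p) e[[p]]),
                    layer_param_names(e))
  })
}

set_weights <- function(model, weights) {
  layers <- collect_layers(model)
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) {
    for (p in names(weights[[i]])) layers[[i]][[p]] <- weights[[i]][[p]]
  }
  invisible(model)
}

# GAN-conventional initialization: kernels ~ N(0, 0.02), biases/shift 0,
# scale 1. Consumes the current RNG stream so builds are seedable.
init_weights <- function(model, sd = 0.02) {
  for (e in collect_layers(model)) {
    if (!is.null(e$W)) e$W <- array(stats::rnorm(length(e$W), 0, sd), dim = dim(e$W))
    if (!is.null(e$b)) e$b <- rep(0, length(e$b))
    if (!is.null(e$gamma)) e$gamma <- rep(1, length(e$gamma))
    if (!is.null(e$beta)) e$beta <- rep(0, length(e$beta))
  }
  invisible(model)
}

# ---------------------------------------------------------------------------
# ADAM optimizer (Kingma & Ba) over one or more networks.
# ---------------------------------------------------------------------------

adam_new <- function(model, lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  layers <- collect_layers(model)
  state <- lapply(layers, function(e) {
    stats::setNames(lapply(layer_param_names(e), function(p) {
      list(m = 0 * e[[p]], v = 0 * e[[p]])
    }), layer_param_names(e))
  })
  list(layers = layers, state = state, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$layers)) {
    e <- opt$layers[[i]]
    for (p in names(opt$state[[i]])) {
      g <- e[[GRAD_SLOTS[[p]]]]
      if (is.null(g)) next
      s <- opt$state[[i]][[p]]
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g * g
      opt$state[[i]][[p]] <- s
      e[[p]] <- e[[p]] - opt$lr * (s$m / bc1) / (sqrt(s$v / bc2) + opt$eps)
    }
  }
  opt
}
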