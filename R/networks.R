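# Generator (Inception-augmented U-Net) and PatchGAN discriminator.
#
# ConvBlock = 2D convolution + instance normalization + swish. Convolutions
# inside normalized blocks carry no bias (the normalization's learned shift
# subsumes it); the printed trainable-parameter totals of the reference
# architecture are reproduced exactly under this convention and are asserted
# in the test suite.

#' ConvBlock: convolution + instance normalization + swish
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel_size Kernel side (1, 3, 4, 5, 7 or 11).
#' @param stride 1 or 2.
#' @param normalization Include the instance-normalization layer.
#' @param use_bias Convolution bias. Defaults to the opposite of
#'   `normalization`: a learned shift follows anyway when normalizing.
#' @param activation `"swish"`, `"sigmoid"`, or `"none"`.
#' @return A block (list of layers applied in sequence).
#' @export
conv_block <- function(in_channels, out_channels, kernel_size = 3L,
                       stride = 1L, normalization = TRUE,
                       use_bias = !normalization,
                       activation = c("swish", "sigmoid", "none")) {
  if (!kernel_size %in% c(1L, 3L, 4L, 5L, 7L, 11L))
    stop("unsupported kernel size: ", kernel_size)
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  activation <- match.arg(activation)
  layers <- list(layer_conv(in_channels, out_channels, kernel_size,
                            stride, use_bias))
  if (normalization && activation == "swish") {
    layers <- c(layers, list(layer_inswish(out_channels)))
  } else {
    if (normalization) layers <- c(layers, list(layer_instnorm(out_channels)))
    layers <- c(layers, switch(activation,
                               swish = list(layer_swish()),
                               sigmoid = list(layer_sigmoid()),
                               none = list()))
  }
  structure(list(layers = layers, type = "conv_block"), class = "sctgan_block")
}

#' InceptionBlock: parallel multi-scale ConvBlocks
#'
#' Four parallel ConvBlocks with kernel sizes 1, 5, 7 and 11 and equal output
#' width, concatenated on the channel axis (output channels =
#' `4 * branch_channels`).
#'
#' @param in_channels Input channels.
#' @param branch_channels Output channels of each branch.
#' @param use_bias Convolution bias inside the branches (off by default, as
#'   every branch is instance-normalized).
#' @return An inception block.
#' @export
inception_block <- function(in_channels, branch_channels, use_bias = FALSE) {
  if (branch_channels < 1L) stop("branch_channels must be >= 1")
  branches <- lapply(c(1L, 5L, 7L, 11L), function(k)
    conv_block(in_channels, branch_channels, kernel_size = k,
               use_bias = use_bias))
  structure(list(layers = branches, type = "inception_block"),
            class = "sctgan_block")
}

block_forward <- function(block, x, train = TRUE) {
  if (block$type == "inception_block") {
    outs <- lapply(block$layers, function(br) block_forward(br, x, train))
    return(abind4(outs))
  }
  for (l in block$layers) x <- layer_forward(l, x, train)
  x
}

block_backward <- function(block, dy, need_dx = TRUE) {
  if (block$type == "inception_block") {
    # every branch has the same width; split dy accordingly
    b <- dim(dy)[3L] %/% length(block$layers)
    dx <- NULL
    for (i in seq_along(block$layers)) {
      dyi <- dy[, , ((i - 1L) * b + 1L):(i * b), , drop = FALSE]
      dxi <- block_backward(block$layers[[i]], dyi, need_dx)
      if (need_dx) dx <- if (is.null(dx)) dxi else dx + dxi
    }
    return(dx)
  }
  for (l in rev(block$layers)) {
    dy <- layer_backward(l, dy, need_dx = need_dx ||
                           !identical(l, block$layers[[1L]]))
  }
  dy
}

abind4 <- function(tensors) {
  d <- dim(tensors[[1L]])
  cs <- vapply(tensors, function(t) dim(t)[3L], numeric(1))
  out <- array(0, dim = c(d[1L], d[2L], sum(cs), d[4L]))
  at <- 0L
  for (t in tensors) {
    out[, , (at + 1L):(at + dim(t)[3L]), ] <- t
    at <- at + dim(t)[3L]
  }
  out
}

#' Generator configuration
#'
#' Five resolution levels: the two full/half-resolution stages use
#' InceptionBlocks (multi-scale context), the three deeper stages plain 3x3
#' ConvBlocks. Contraction by 2x2 max pooling; expansion by nearest-neighbour
#' upsampling, skip concatenation, and the mirrored stage block; a final 1x1
#' convolution with sigmoid maps to one output channel in `[0, 1]`.
#'
#' The per-level channel widths are not printed in the reference text; the
#' default layout is resolved so the generator's trainable-parameter total is
#' exactly 2,554,977.
#'
#' @param channels Integer vector of 5 output widths per level (levels 1-2
#'   divisible by 4: inception branches get `channels/4` each).
#' @param final_kernel Kernel size of the output convolution.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(channels = c(16L, 28L, 92L, 208L, 400L),
                             final_kernel = 3L) {
  stopifnot(length(channels) == 5L, all(channels >= 4L),
            channels[1L] %% 4L == 0L, channels[2L] %% 4L == 0L)
  structure(list(channels = as.integer(channels),
                 levels = 5L,
                 level_types = c("inception", "inception", "conv", "conv",
                                 "conv"),
                 final_kernel = as.integer(final_kernel)),
            class = "generator_config")
}

#' Build the Inception-augmented U-Net generator
#'
#' Maps a 1-channel normalized image to a 1-channel normalized image of the
#' same shape, with outputs in `[0, 1]` (final sigmoid). Input sides must be
#' divisible by `2^4 = 16`.
#'
#' @param config A [generator_config()].
#' @param seed Seed for the N(0, 0.02) weight initialization.
#' @return A generator object; run it with [generator_forward()] or wrap with
#'   [make_translator()].
#' @export
build_generator <- function(config = generator_config(), seed = 1L) {
  ch <- config$channels
  stage <- function(cin, cout, type) {
    if (type == "inception") inception_block(cin, cout %/% 4L)
    else conv_block(cin, cout, 3L)
  }
  g <- new.env(parent = emptyenv())
  g$config <- config
  lt <- config$level_types
  g$enc <- list(stage(1L, ch[1], lt[1]), stage(ch[1], ch[2], lt[2]),
                stage(ch[2], ch[3], lt[3]), stage(ch[3], ch[4], lt[4]),
                stage(ch[4], ch[5], lt[5]))
  g$pool <- lapply(1:4, function(i) layer_maxpool2())
  g$up <- lapply(1:4, function(i) layer_upnearest2())
  g$dec <- list(stage(ch[5] + ch[4], ch[4], lt[4]),
                stage(ch[4] + ch[3], ch[3], lt[3]),
                stage(ch[3] + ch[2], ch[2], lt[2]),
                stage(ch[2] + ch[1], ch[1], lt[1]))
  g$final <- conv_block(ch[1], 1L, config$final_kernel,
                        normalization = FALSE, use_bias = TRUE,
                        activation = "sigmoid")
  g$layers <- c(g$enc, g$pool, g$up, g$dec, list(g$final))
  with_seed(seed, init_weights(g))
  g$initialized <- TRUE
  class(g) <- c("sct_generator", "sctgan_network")
  g
}

#' Run the generator
#'
#' @param g A generator from [build_generator()].
#' @param x Input tensor `(H, W, 1, N)` with sides divisible by 16.
#' @param train Keep caches for a subsequent backward pass.
#' @return Output tensor of identical shape, values in `[0, 1]`.
#' @export
generator_forward <- function(g, x, train = TRUE) {
  x <- as_tensor(x)
  d <- dim(x)
  if (d[1L] %% 16L != 0L || d[2L] %% 16L != 0L)
    stop("input sides must be divisible by 16 (2^(levels-1))")
  e1 <- block_forward(g$enc[[1]], x, train)
  e2 <- block_forward(g$enc[[2]], layer_forward(g$pool[[1]], e1, train), train)
  e3 <- block_forward(g$enc[[3]], layer_forward(g$pool[[2]], e2, train), train)
  e4 <- block_forward(g$enc[[4]], layer_forward(g$pool[[3]], e3, train), train)
  e5 <- block_forward(g$enc[[5]], layer_forward(g$pool[[4]], e4, train), train)
  if (train) g$skip_channels <- c(dim(e1)[3], dim(e2)[3], dim(e3)[3],
                                  dim(e4)[3])
  d4 <- block_forward(g$dec[[1]],
                      abind4(list(layer_forward(g$up[[1]], e5, train), e4)),
                      train)
  d3 <- block_forward(g$dec[[2]],
                      abind4(list(layer_forward(g$up[[2]], d4, train), e3)),
                      train)
  d2 <- block_forward(g$dec[[3]],
                      abind4(list(layer_forward(g$up[[3]], d3, train), e2)),
                      train)
  d1 <- block_forward(g$dec[[4]],
                      abind4(list(layer_forward(g$up[[4]], d2, train), e1)),
                      train)
  block_forward(g$final, d1, train)
}

#' Backpropagate through the generator
#'
#' Accumulates parameter gradients for the cached forward pass.
#'
#' @param g The generator (after a `train = TRUE` forward).
#' @param dy Gradient of the loss w.r.t. the generator output.
#' @param need_dx Also return the gradient w.r.t. the input.
#' @return Input gradient (invisibly `NULL` when `need_dx = FALSE`).
#' @export
generator_backward <- function(g, dy, need_dx = FALSE) {
  split_up <- function(dcat, up_channels) {
    list(dup = dcat[, , seq_len(up_channels), , drop = FALSE],
         dskip = dcat[, , -seq_len(up_channels), , drop = FALSE])
  }
  ch <- g$config$channels
  dd1 <- block_backward(g$final, dy, need_dx = TRUE)
  s <- split_up(block_backward(g$dec[[4]], dd1, TRUE), ch[2])
  de1 <- s$dskip
  dd2 <- layer_backward(g$up[[4]], s$dup)
  s <- split_up(block_backward(g$dec[[3]], dd2, TRUE), ch[3])
  de2 <- s$dskip
  dd3 <- layer_backward(g$up[[3]], s$dup)
  s <- split_up(block_backward(g$dec[[2]], dd3, TRUE), ch[4])
  de3 <- s$dskip
  dd4 <- layer_backward(g$up[[2]], s$dup)
  s <- split_up(block_backward(g$dec[[1]], dd4, TRUE), ch[5])
  de4 <- s$dskip
  de5 <- layer_backward(g$up[[1]], s$dup)
  de4 <- de4 + layer_backward(g$pool[[4]],
                              block_backward(g$enc[[5]], de5, TRUE))
  de3 <- de3 + layer_backward(g$pool[[3]],
                              block_backward(g$enc[[4]], de4, TRUE))
  de2 <- de2 + layer_backward(g$pool[[2]],
                              block_backward(g$enc[[3]], de3, TRUE))
  de1 <- de1 + layer_backward(g$pool[[1]],
                              block_backward(g$enc[[2]], de2, TRUE))
  dx <- block_backward(g$enc[[1]], de1, need_dx = need_dx)
  if (need_dx) dx else invisible(NULL)
}

#' Discriminator configuration
#'
#' Four 4x4 ConvBlocks with strides (2, 2, 2, 1): the first three halve the
#' spatial size and double the feature maps, the fourth preserves both; a
#' final 4x4 convolution + sigmoid produces a one-channel patch map (32x32
#' for 256x256 input). PatchGAN convention: no normalization on the first
#' block. The default base width reproduces the printed 429,185-parameter
#' total exactly.
#'
#' @param base_channels Feature maps of the first block.
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(base_channels = 32L) {
  structure(list(base_channels = as.integer(base_channels),
                 kernel = 4L, strides = c(2L, 2L, 2L, 1L)),
            class = "discriminator_config")
}

#' Build the PatchGAN discriminator
#'
#' @param config A [discriminator_config()].
#' @param seed Weight-initialization seed.
#' @return A discriminator object mapping `(H, W, 1, N)` inputs (sides
#'   divisible by 8) to `(H/8, W/8, 1, N)` patch maps in `[0, 1]`.
#' @export
build_discriminator <- function(config = discriminator_config(), seed = 1L) {
  cb <- config$base_channels
  d <- new.env(parent = emptyenv())
  d$config <- config
  d$blocks <- list(
    conv_block(1L, cb, 4L, stride = 2L, normalization = FALSE,
               use_bias = FALSE),
    conv_block(cb, 2L * cb, 4L, stride = 2L),
    conv_block(2L * cb, 4L * cb, 4L, stride = 2L),
    conv_block(4L * cb, 4L * cb, 4L, stride = 1L))
  d$head <- conv_block(4L * cb, 1L, 4L, normalization = FALSE,
                       use_bias = TRUE, activation = "sigmoid")
  d$layers <- c(d$blocks, list(d$head))
  with_seed(seed, init_weights(d))
  d$initialized <- TRUE
  class(d) <- c("sct_discriminator", "sctgan_network")
  d
}

#' Run the discriminator
#'
#' @param d A discriminator from [build_discriminator()].
#' @param x Input tensor with sides divisible by 8.
#' @param train Keep caches for a backward pass.
#' @return Patch map in `[0, 1]`, spatial size input/8.
#' @export
discriminator_forward <- function(d, x, train = TRUE) {
  x <- as_tensor(x)
  dd <- dim(x)
  if (dd[1L] %% 8L != 0L || dd[2L] %% 8L != 0L)
    stop("input sides must be divisible by 8")
  for (b in d$layers) x <- block_forward(b, x, train)
  x
}

#' Backpropagate through the discriminator, accumulating parameter gradients
#'
#' @param d The discriminator (after a `train = TRUE` forward).
#' @param dy Gradient w.r.t. the patch map.
#' @return Invisibly `NULL`.
#' @export
discriminator_backward <- function(d, dy) {
  for (b in rev(d$layers)) dy <- block_backward(b, dy, need_dx = TRUE)
  invisible(NULL)
}

# Input gradient only (discriminator frozen): used for the generators'
# adversarial term without touching discriminator weights.
discriminator_backward_input <- function(d, dy) {
  grads <- get_grads_snapshot(d)
  for (b in rev(d$layers)) dy <- block_backward(b, dy, need_dx = TRUE)
  restore_grads_snapshot(d, grads)
  dy
}

get_grads_snapshot <- function(model) {
  lapply(collect_layers(model), function(e)
    lapply(GRAD_SLOTS, function(gn) e[[gn]]))
}

restore_grads_snapshot <- function(model, snap) {
  layers <- collect_layers(model)
  for (i in seq_along(layers)) {
    for (j in seq_along(GRAD_SLOTS))
      layers[[i]][[GRAD_SLOTS[[j]]]] <- snap[[i]][[j]]
  }
  invisible(model)
}
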