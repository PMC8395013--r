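# Network blocks and architectures: hand-counted parameters, shape/range
# contracts, printed parameter totals, determinism, equivariance.

test_that("ConvBlock parameter counts match hand counts", {
  # 3x3, 1 -> 8, conv bias + affine instance norm: 72 + 8 + 16
  cb <- conv_block(1, 8, 3, use_bias = TRUE)
  expect_equal(count_trainable_parameters(cb), 96)
  # normalized blocks default to bias-free convolutions: 72 + 16
  expect_equal(count_trainable_parameters(conv_block(1, 8, 3)), 88)
  expect_error(conv_block(1, 8, kernel_size = 2), "kernel")
  expect_error(conv_block(1, 8, stride = 3), "stride")
})

test_that("ConvBlock geometry and null-input behaviour", {
  blk <- conv_block(1, 8, 3)
  with_seed(1, init_weights(blk))
  x0 <- array(0, dim = c(16, 16, 1, 2))
  y0 <- block_forward(blk, x0, train = FALSE)
  expect_equal(max(abs(y0)), 0)  # swish(IN shift 0) = 0 on zero input
  s2 <- conv_block(1, 8, 3, stride = 2)
  with_seed(1, init_weights(s2))
  y <- block_forward(s2, array(rnorm(64 * 64), dim = c(64, 64, 1, 1)),
                     train = FALSE)
  expect_equal(dim(y)[1:2], c(32L, 32L))
})

test_that("InceptionBlock concatenates four branches with per-branch hand counts", {
  ib <- inception_block(1, 16, use_bias = TRUE)
  x <- array(rnorm(32 * 32), dim = c(32, 32, 1, 1))
  with_seed(2, init_weights(ib))
  y <- block_forward(ib, x, train = FALSE)
  expect_equal(dim(y), c(32L, 32L, 64L, 1L))
  counts <- vapply(ib$layers, count_trainable_parameters, numeric(1))
  expect_equal(counts, c(16 + 16 + 32, 400 + 16 + 32, 784 + 16 + 32,
                         1936 + 16 + 32))
  expect_error(inception_block(1, 0), "branch_channels")
})

test_that("generator satisfies shape, range, and printed parameter count", {
  g <- build_generator(seed = 1)
  expect_equal(count_trainable_parameters(g), 2554977)
  x <- array(runif(64 * 64 * 2), dim = c(64, 64, 1, 2))
  y <- generator_forward(g, x, train = FALSE)
  expect_equal(dim(y), dim(x))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(generator_forward(g, array(0, dim = c(60, 60, 1, 1))),
               "divisible")
  # same config and seed build identical networks
  g2 <- build_generator(seed = 1)
  expect_identical(get_weights(g), get_weights(g2))
  expect_identical(generator_forward(g2, x, train = FALSE), y)
})

test_that("discriminator produces an input/8 patch map in [0,1] with the printed count", {
  d <- build_discriminator(seed = 1)
  expect_equal(count_trainable_parameters(d), 429185)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 1, 3))
  p <- discriminator_forward(d, x, train = FALSE)
  expect_equal(dim(p), c(8L, 8L, 1L, 3L))  # 256x256 input gives 32x32
  expect_true(all(p >= 0 & p <= 1))
  expect_error(discriminator_forward(d, array(0, dim = c(60, 60, 1, 1))),
               "divisible")
  # stride-2 blocks halve size and double channels along the trunk
  h <- block_forward(d$blocks[[1]], x, train = FALSE)
  expect_equal(dim(h), c(32L, 32L, 32L, 3L))
  h <- block_forward(d$blocks[[2]], h, train = FALSE)
  expect_equal(dim(h), c(16L, 16L, 64L, 3L))
})

test_that("parameter bookkeeping: trivial models and the ensemble total", {
  expect_equal(count_trainable_parameters(list()), 0)
  single <- conv_block(1, 1, 1, normalization = FALSE, use_bias = TRUE,
                       activation = "none")
  expect_equal(count_trainable_parameters(single), 2)
  total <- 2 * count_trainable_parameters(build_generator(seed = 1)) +
    2 * count_trainable_parameters(build_discriminator(seed = 1))
  expect_equal(total, 5968324)
})

test_that("stride-1 convolution is translation equivariant away from borders", {
  # equivariance is a property of the convolution itself; the normalization
  # that follows is a global per-channel statistic and is exempt
  blk <- conv_block(1, 4, 3)
  with_seed(5, init_weights(blk))
  conv <- blk$layers[[1]]
  x <- array(rnorm(32 * 32), dim = c(32, 32, 1, 1))
  xs <- array(0, dim = dim(x))
  xs[6:32, , 1, 1] <- x[1:27, , 1, 1]  # shift down by 5
  y <- layer_forward(conv, x, train = FALSE)
  ys <- layer_forward(conv, xs, train = FALSE)
  expect_equal(ys[12:28, 10:20, , , drop = FALSE],
               y[7:23, 10:20, , , drop = FALSE], tolerance = 1e-5)
})

test_that("conv layer gradients agree with finite differences (dense and fft paths)", {
  for (k in c(3L, 7L)) {
    set.seed(10 + k)
    blk <- conv_block(2, 3, k)
    init_weights(blk)
    conv <- blk$layers[[1]]
    x <- array(rnorm(16 * 16 * 2 * 2), dim = c(16, 16, 2, 2))
    y <- layer_forward(conv, x, train = TRUE)
    dy <- array(rnorm(length(y)), dim = dim(y))
    dx <- layer_backward(conv, dy, need_dx = TRUE)
    eps <- 1e-4
    idx <- c(5, 7, 1, 2)
    xp <- x; xp[5, 7, 1, 2] <- xp[5, 7, 1, 2] + eps
    num <- sum((layer_forward(conv, xp, train = FALSE) - y) * dy) / eps
    expect_equal(num, dx[5, 7, 1, 2], tolerance = 5e-2)
    wsave <- conv$W
    conv$W[2, 2, 1, 1] <- conv$W[2, 2, 1, 1] + eps
    numw <- sum((layer_forward(conv, x, train = FALSE) - y) * dy) / eps
    conv$W <- wsave
    expect_equal(numw, conv$dW[2, 2, 1, 1], tolerance = 5e-2)
  }
})

test_that("instance norm normalizes per sample and channel and backprops", {
  ln <- layer_instnorm(3)
  x <- array(rnorm(8 * 8 * 3 * 2, mean = 5, sd = 3), dim = c(8, 8, 3, 2))
  y <- layer_forward(ln, x, train = TRUE)
  for (n in 1:2) for (c in 1:3) {
    expect_equal(mean(y[, , c, n]), 0, tolerance = 1e-8)
    expect_equal(stats::sd(as.numeric(y[, , c, n])) * sqrt(63 / 64), 1,
                 tolerance = 1e-3)
  }
  dy <- array(rnorm(length(y)), dim = dim(y))
  dx <- layer_backward(ln, dy, need_dx = TRUE)
  eps <- 1e-5
  xp <- x; xp[3, 4, 2, 1] <- xp[3, 4, 2, 1] + eps
  num <- sum((layer_forward(ln, xp, train = FALSE) - y) * dy) / eps
  expect_equal(num, dx[3, 4, 2, 1], tolerance = 1e-3)
})
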