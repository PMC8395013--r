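# Shared fixtures: tiny deterministic phantoms and datasets built in code.

simple_spec <- function(size = 64L, axes = c(22, 16), ...) {
  phantom_spec(image_size = size, body_axes = axes, ...)
}

# A deterministic disk image: `value` HU on air background.
disk_image <- function(size = 64L, radius = 20, value = 0,
                       center = c((size + 1) / 2, (size + 1) / 2)) {
  px <- matrix(-1000, size, size)
  r <- matrix(seq_len(size), size, size) - center[1]
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - center[2]
  px[r^2 + cc^2 <= radius^2] <- value
  px
}

linear_dataset <- function(n_subjects = 6L, slices = 4L, size = 32L,
                           gain = 1.1, offset = 40, seed = 5L) {
  generate_dataset(n_subjects, slices,
                   model_ranges = list(gain = gain, offset = offset),
                   image_size = size, seed = seed)
}

# Independent windowed-SSIM oracle: direct per-window loops.
brute_ssim <- function(a, b, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  half <- (win - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- K1^2; C2 <- K2^2
  n <- nrow(a)
  vals <- c()
  for (i in seq_len(n - win + 1)) {
    for (j in seq_len(n - win + 1)) {
      pa <- a[i:(i + win - 1), j:(j + win - 1)]
      pb <- b[i:(i + win - 1), j:(j + win - 1)]
      mu1 <- sum(w * pa); mu2 <- sum(w * pb)
      s1 <- sum(w * pa^2) - mu1^2; s2 <- sum(w * pb^2) - mu2^2
      s12 <- sum(w * pa * pb) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                        ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
    }
  }
  mean(vals)
}
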