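# Training routines: loss formulas, optimizer null cases, gradient isolation,
# reproducibility, checkpointing, and a scaled-down supervised recovery run.

test_that("supervised L1 loss matches hand computations", {
  a <- array(1, dim = c(2, 2, 1, 1))
  expect_equal(supervised_loss(a, a), 0)
  expect_equal(supervised_loss(a, a * 0.75), 0.25)
  expect_equal(supervised_loss(c(0, 0.5, 1), c(0.1, 0.4, 1)), 0.2 / 3)
  expect_error(supervised_loss(a, array(1, dim = c(2, 2, 1, 2))),
               "shape mismatch")
})

test_that("cycle-consistent loss terms satisfy their closed forms", {
  img <- array(runif(16 * 16), dim = c(16, 16, 1, 1))
  bundle <- list(ct = img, cbct = img, sct = img, scbct = img,
                 cycle_ct = img, cycle_cbct = img, id_ct = img,
                 id_cbct = img)
  half <- array(0.5, dim = c(4, 4, 1, 1))
  d_out <- list(d_ct_real = half, d_ct_fake = half,
                d_cbct_real = half, d_cbct_fake = half)
  rep_ <- cyclegan_losses(bundle, d_out)
  # identity generators with ct == cbct: cycle and identity terms vanish
  expect_equal(rep_$cycle, 0)
  expect_equal(rep_$identity, 0)
  # a 0.5 patch map scores -ln(0.5) per adversarial term
  expect_equal(rep_$gen_adv_ct, -log(0.5), tolerance = 1e-12)
  expect_equal(rep_$d_ct, 2 * -log(0.5), tolerance = 1e-12)
  # zero weights reduce the generator loss to the adversarial terms
  rep0 <- cyclegan_losses(bundle, d_out,
                          weights = list(lambda_cycle = 0,
                                         lambda_identity = 0))
  expect_equal(rep0$generator_total, rep0$gen_adv_ct + rep0$gen_adv_cbct)
  expect_error(cyclegan_losses(bundle[-3], d_out), "missing bundle member")
  # loss terms stay finite even for saturated patch maps
  sat <- list(d_ct_real = half * 0, d_ct_fake = half * 0 + 1,
              d_cbct_real = half * 0, d_cbct_fake = half * 0 + 1)
  repsat <- cyclegan_losses(bundle, sat)
  expect_true(all(is.finite(unlist(repsat))))
})

test_that("zero learning rate leaves all networks untouched", {
  ds <- linear_dataset(4, 3, size = 32L)
  cfg <- train_config(epochs = 1, batch_size = 5, learning_rate = 0,
                      seed = 11)
  g0 <- build_generator(seed = 11)
  w_before <- get_weights(g0)
  fit <- train_supervised(ds, cfg, generator = g0)
  expect_identical(get_weights(fit$generator), w_before)
  fitc <- train_cyclegan(unpair_dataset(ds), cfg)
  expect_identical(get_weights(fitc$g_ct),
                   get_weights(build_generator(seed = cfg$seed)))
  expect_identical(get_weights(fitc$d_cbct),
                   get_weights(build_discriminator(seed = cfg$seed + 3L)))
})

test_that("history bookkeeping and checkpoint rule", {
  ds <- linear_dataset(5, 2, size = 32L)
  cfg <- train_config(epochs = 3, batch_size = 5, seed = 2)
  fit <- train_supervised(ds, cfg)
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(unlist(fit$history))))
  # returned checkpoint is the epoch with maximal validation SSIM
  expect_equal(fit$best_epoch, which.max(fit$history$val_ssim))
  expect_error(train_supervised(list(), cfg), "empty")
})

test_that("discriminator updates never touch generator weights and vice versa", {
  ds <- linear_dataset(4, 2, size = 32L)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 6)
  pools <- unpair_dataset(ds)
  g_ct <- build_generator(seed = 6)
  d_ct <- build_discriminator(seed = 8)
  d_cbct <- build_discriminator(seed = 9)
  g_cbct <- build_generator(seed = 7)
  tens <- sctgan:::stack_pairs(ds)
  w_d_before <- get_weights(d_ct)
  step <- sctgan:::cyclegan_step(g_ct, g_cbct, d_ct, d_cbct,
                                 tens$ct, tens$cbct,
                                 list(lambda_cycle = 10, lambda_identity = 5),
                                 "bce")
  # generator-side backward leaves discriminator weights AND grads untouched
  expect_identical(get_weights(d_ct), w_d_before)
  expect_true(all(vapply(sctgan:::collect_layers(d_ct), function(e)
    is.null(e$dW), logical(1))))
  # discriminator update leaves generator weights untouched
  w_g <- get_weights(g_ct)
  sctgan:::disc_step(d_ct, step$real_ct, step$sct, "bce")
  expect_identical(get_weights(g_ct), w_g)
})

test_that("identical seeds give identical loss histories", {
  ds <- linear_dataset(4, 2, size = 32L)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 17)
  f1 <- train_supervised(ds, cfg)
  f2 <- train_supervised(ds, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
})

test_that("a toy supervised run recovers a linear HU corruption", {
  ds <- generate_dataset(10, 10, model_ranges = list(gain = 1.1, offset = 40),
                         image_size = 32L, seed = 23)
  cfg <- train_config(epochs = 20, batch_size = 10, seed = 3,
                      augment = FALSE)
  g0 <- build_generator(seed = cfg$seed)
  sp <- sctgan:::split_train_val(ds, cfg$val_fraction, cfg$seed)
  untrained <- sctgan:::validation_mae_hu(g0, sp$val)
  fit <- train_supervised(ds, cfg, generator = g0)
  final <- min(fit$history$val_mae_hu)
  # training must close at least 80% of the gap from the untrained network
  expect_lt(final, 0.2 * untrained)
  # and the loss trajectory must be broadly decreasing
  expect_lt(mean(tail(fit$history$train_l1, 3)),
            mean(head(fit$history$train_l1, 3)))
})

test_that("translate_volume preserves geometry, range, and slice count", {
  g <- build_generator(seed = 1)
  vol <- lapply(1:3, function(i)
    generate_phantom(simple_spec(size = 32L, axes = c(12, 9)), seed = i))
  out <- translate_volume(g, vol)
  expect_length(out, 3L)
  expect_equal(dim(out[[1]]$pixels), dim(vol[[1]]$pixels))
  for (s in out)
    expect_true(all(s$pixels >= -1024 & s$pixels <= 3200))
  g$initialized <- FALSE
  expect_error(translate_volume(g, vol), "uninitialized")
})
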