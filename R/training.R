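# Supervised (pixel-wise L1) and unsupervised (cycle-consistent adversarial)
# training routines with the ADAM protocol: lr 2e-4, beta1 0.5, beta2 0.999,
# batch size 10, run-time coherent augmentation, checkpoint on best
# validation SSIM.

#' Training configuration
#'
#' @param epochs Number of epochs (25 in the reference protocol; scale down
#'   for desk-scale runs).
#' @param batch_size Images per batch.
#' @param learning_rate,beta1,beta2 ADAM hyper-parameters.
#' @param lambda_cycle,lambda_identity Cycle-consistency and identity loss
#'   weights for the unsupervised routine (adversarial weight fixed at 1).
#' @param adversarial One of `"bce"` (binary cross-entropy on the sigmoid
#'   patch map, default) or `"lsgan"` (least-squares).
#' @param val_fraction Fraction of subjects held out for validation.
#' @param augment Apply coherent 90-degree-rotation/flip augmentation each
#'   epoch.
#' @param seed Seed controlling weight init, shuffling and augmentation.
#' @param verbose Print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 25L, batch_size = 10L,
                         learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         lambda_cycle = 10, lambda_identity = 5,
                         adversarial = c("bce", "lsgan"),
                         val_fraction = 0.2, augment = TRUE, seed = 1L,
                         verbose = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lambda_cycle >= 0,
            lambda_identity >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 lambda_cycle = lambda_cycle,
                 lambda_identity = lambda_identity,
                 adversarial = match.arg(adversarial),
                 val_fraction = val_fraction, augment = isTRUE(augment),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Supervised L1 loss between ground-truth CT and synthetic CT
#'
#' Mean absolute pixel difference over normalized images.
#'
#' @param ct,sct Numeric arrays of identical shape.
#' @return Scalar loss.
#' @export
supervised_loss <- function(ct, sct) {
  if (!all(dim(as.array(ct)) == dim(as.array(sct)))) stop("shape mismatch")
  mean(abs(ct - sct))
}

bce_eps <- 1e-7

# Binary cross-entropy of a sigmoid patch map against a constant label,
# averaged over patches; inputs clamped away from {0, 1}.
bce_loss <- function(p, target) {
  p <- pmin(pmax(p, bce_eps), 1 - bce_eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

adv_loss <- function(p, target, kind) {
  if (kind == "lsgan") mean((p - target)^2) else bce_loss(p, target)
}

# d(adv)/d(p) for a patch map with M patches.
adv_grad <- function(p, target, kind) {
  m <- length(p)
  if (kind == "lsgan") return(2 * (p - target) / m)
  pc <- pmin(pmax(p, bce_eps), 1 - bce_eps)
  (pc - target) / (pc * (1 - pc)) / m
}

#' Loss terms of the cycle-consistent adversarial objective
#'
#' Given a complete translation bundle, computes the generator objective
#' `adv(D_CT(sCT), 1) + adv(D_CBCT(sCBCT), 1)
#'  + lambda_cycle * (L1(cycleCBCT, CBCT) + L1(cycleCT, CT))
#'  + lambda_identity * (L1(idCT, CT) + L1(idCBCT, CBCT))`
#' and the two discriminator objectives `adv(D(real), 1) + adv(D(fake), 0)`
#' (fakes treated as detached from the generators).
#'
#' @param bundle Named list with members `ct`, `cbct`, `sct`, `scbct`,
#'   `cycle_ct`, `cycle_cbct`, `id_ct`, `id_cbct` (arrays in `[0, 1]`).
#' @param d_outputs Named list with discriminator patch maps `d_ct_real`,
#'   `d_ct_fake`, `d_cbct_real`, `d_cbct_fake` (values in `[0, 1]`).
#' @param weights List with `lambda_cycle` and `lambda_identity`.
#' @param adversarial `"bce"` or `"lsgan"`.
#' @return Named list of scalar loss terms plus the combined
#'   `generator_total`.
#' @export
cyclegan_losses <- function(bundle, d_outputs,
                            weights = list(lambda_cycle = 10,
                                           lambda_identity = 5),
                            adversarial = "bce") {
  need <- c("ct", "cbct", "sct", "scbct", "cycle_ct", "cycle_cbct",
            "id_ct", "id_cbct")
  missing <- setdiff(need, names(bundle))
  if (length(missing)) stop("missing bundle member(s): ",
                            paste(missing, collapse = ", "))
  adv_ct <- adv_loss(d_outputs$d_ct_fake, 1, adversarial)
  adv_cbct <- adv_loss(d_outputs$d_cbct_fake, 1, adversarial)
  cyc <- supervised_loss(bundle$cbct, bundle$cycle_cbct) +
    supervised_loss(bundle$ct, bundle$cycle_ct)
  idl <- supervised_loss(bundle$ct, bundle$id_ct) +
    supervised_loss(bundle$cbct, bundle$id_cbct)
  gen_total <- adv_ct + adv_cbct + weights$lambda_cycle * cyc +
    weights$lambda_identity * idl
  list(gen_adv_ct = adv_ct, gen_adv_cbct = adv_cbct,
       cycle = cyc, identity = idl, generator_total = gen_total,
       d_ct = adv_loss(d_outputs$d_ct_real, 1, adversarial) +
         adv_loss(d_outputs$d_ct_fake, 0, adversarial),
       d_cbct = adv_loss(d_outputs$d_cbct_real, 1, adversarial) +
         adv_loss(d_outputs$d_cbct_fake, 0, adversarial))
}

# --- dataset plumbing ------------------------------------------------------

# Stack normalized CT/CBCT matrices of a list of paired slices into tensors.
stack_pairs <- function(pairs) {
  n <- length(pairs)
  d <- dim(pairs[[1]]$ct$pixels)
  ct <- array(0, dim = c(d[1], d[2], 1L, n))
  cbct <- array(0, dim = c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    ct[, , 1L, i] <- normalize_hu(pairs[[i]]$ct)
    cbct[, , 1L, i] <- normalize_hu(pairs[[i]]$cbct)
  }
  list(ct = ct, cbct = cbct)
}

# Subject-level train/validation split (no subject straddles the split).
split_train_val <- function(dataset, val_fraction, seed) {
  ids <- vapply(dataset, function(p) p$subject_id, character(1))
  subjects <- unique(ids)
  n_val <- max(1L, round(val_fraction * length(subjects)))
  if (n_val >= length(subjects)) n_val <- length(subjects) - 1L
  val_subj <- with_seed(seed + 131L, sample(subjects, n_val))
  list(train = dataset[!ids %in% val_subj],
       val = dataset[ids %in% val_subj])
}

#' Break the pairing of a dataset
#'
#' Returns independent CT and CBCT pools (the CBCT pool shuffled), as consumed
#' by [train_cyclegan()].
#'
#' @param dataset List of `paired_slice` objects.
#' @param seed Shuffle seed.
#' @return List with `ct_pool` and `cbct_pool` (lists of `paired_slice`,
#'   where only the respective modality is meaningful).
#' @export
unpair_dataset <- function(dataset, seed = 7L) {
  perm <- with_seed(seed, sample(seq_along(dataset)))
  list(ct_pool = dataset, cbct_pool = dataset[perm])
}

# Per-epoch coherent augmentation of a list of pairs.
augment_epoch <- function(pairs, enabled) {
  if (!enabled) return(pairs)
  ks <- sample(0:3, length(pairs), replace = TRUE)
  fl <- sample(c(TRUE, FALSE), length(pairs), replace = TRUE)
  lapply(seq_along(pairs), function(i) augment_pair(pairs[[i]], ks[i], fl[i]))
}

# Batched validation translation: run the generator over the validation pool
# in chunks and hand each slice to a per-image metric.
validate_generator <- function(gen, val_pairs, metric, chunk = 10L) {
  vals <- numeric(length(val_pairs))
  for (b in batch_indices(seq_along(val_pairs), chunk)) {
    x <- stack_pairs(val_pairs[b])$cbct
    y <- generator_forward(gen, x, train = FALSE)
    for (j in seq_along(b))
      vals[b[j]] <- metric(val_pairs[[b[j]]], y[, , 1L, j])
  }
  mean(vals)
}

# mean SSIM between generated and ground-truth CT on the normalized scale
validation_ssim <- function(gen, val_pairs) {
  validate_generator(gen, val_pairs, function(p, sct_n)
    compute_ssim(normalize_hu(p$ct), sct_n))
}

# mean body-region MAE in HU between generated sCT and ground-truth CT
validation_mae_hu <- function(gen, val_pairs) {
  validate_generator(gen, val_pairs, function(p, sct_n)
    compute_mae_hu(p$ct$pixels, denormalize_hu(sct_n),
                   region = attr(p, "body_mask")))
}

#' Train the generator with supervised L1 loss
#'
#' Minimizes the mean absolute difference between generated sCT and
#' ground-truth CT with ADAM, applying coherent augmentation each epoch, and
#' returns the weights of the epoch with maximal validation SSIM.
#'
#' @param dataset List of `paired_slice` objects (split internally into
#'   train/validation by subject).
#' @param config A [train_config()].
#' @param generator Optional pre-built generator (e.g. for continued
#'   training); by default one is built from [generator_config()] sized to
#'   the data.
#' @return List with `generator` (best checkpoint restored), `history`
#'   (per-epoch data frame: train loss, validation SSIM and MAE), and
#'   `best_epoch`.
#' @export
train_supervised <- function(dataset, config = train_config(),
                             generator = NULL) {
  if (length(dataset) == 0L) stop("empty dataset")
  if (!all(vapply(dataset, inherits, logical(1), "paired_slice")))
    stop("dataset must consist of paired slices")
  sp <- split_train_val(dataset, config$val_fraction, config$seed)
  if (is.null(generator))
    generator <- build_generator(seed = config$seed)
  opt <- adam_new(generator, lr = config$learning_rate,
                  beta1 = config$beta1, beta2 = config$beta2)
  best <- list(ssim = -Inf, weights = get_weights(generator), epoch = 0L)
  hist <- data.frame()
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    pairs <- augment_epoch(sp$train, config$augment)
    order_idx <- sample(seq_along(pairs))
    losses <- c()
    for (b in batch_indices(order_idx, config$batch_size)) {
      tens <- stack_pairs(pairs[b])
      zero_grads(generator)
      sct <- generator_forward(generator, tens$cbct, train = TRUE)
      losses <- c(losses, supervised_loss(tens$ct, sct))
      dsct <- sign(sct - tens$ct) / length(sct)
      generator_backward(generator, dsct, need_dx = FALSE)
      opt <- adam_step(opt)
    }
    vs <- validation_ssim(generator, sp$val)
    vm <- validation_mae_hu(generator, sp$val)
    hist <- rbind(hist, data.frame(epoch = ep, train_l1 = mean(losses),
                                   val_ssim = vs, val_mae_hu = vm))
    if (config$verbose)
      message(sprintf("epoch %d: L1 %.4f, val SSIM %.4f, val MAE %.1f HU",
                      ep, mean(losses), vs, vm))
    if (vs > best$ssim)
      best <- list(ssim = vs, weights = get_weights(generator), epoch = ep)
  }
  set_weights(generator, best$weights)
  list(generator = generator, history = hist, best_epoch = best$epoch,
       validation = sp$val)
}

batch_indices <- function(order_idx, batch_size) {
  split(order_idx, ceiling(seq_along(order_idx) / batch_size))
}

#' Train the cycle-consistent adversarial model on unpaired pools
#'
#' Alternates generator and discriminator ADAM updates per batch: the two
#' generators are optimized jointly on adversarial + cycle + identity terms;
#' each discriminator is then updated on real versus (detached) fake patch
#' maps. Pairing between the CT and CBCT pools is never used. Checkpoints on
#' maximal validation SSIM of the CBCT-to-CT generator.
#'
#' @param pools List with `ct_pool` and `cbct_pool` (see [unpair_dataset()]),
#'   or a paired dataset which will be unpaired internally.
#' @param config A [train_config()].
#' @return List with the four trained networks (`g_ct`, `g_cbct`, `d_ct`,
#'   `d_cbct`), the per-epoch `history`, and `best_epoch`.
#' @export
train_cyclegan <- function(pools, config = train_config()) {
  if (!is.list(pools)) stop("empty pool")
  if (is.null(pools$ct_pool)) pools <- unpair_dataset(pools)
  if (length(pools$ct_pool) == 0L || length(pools$cbct_pool) == 0L)
    stop("empty pool")
  sp_ct <- split_train_val(pools$ct_pool, config$val_fraction, config$seed)
  sp_cbct <- split_train_val(pools$cbct_pool, config$val_fraction,
                             config$seed)
  g_ct <- build_generator(seed = config$seed)
  g_cbct <- build_generator(seed = config$seed + 1L)
  d_ct <- build_discriminator(seed = config$seed + 2L)
  d_cbct <- build_discriminator(seed = config$seed + 3L)
  opt_g <- adam_new(list(g_ct, g_cbct), lr = config$learning_rate,
                    beta1 = config$beta1, beta2 = config$beta2)
  opt_d <- adam_new(list(d_ct, d_cbct), lr = config$learning_rate,
                    beta1 = config$beta1, beta2 = config$beta2)
  weights <- list(lambda_cycle = config$lambda_cycle,
                  lambda_identity = config$lambda_identity)
  kind <- config$adversarial
  best <- list(ssim = -Inf, weights = get_weights(g_ct), epoch = 0L)
  hist <- data.frame()
  set.seed(config$seed + 2L)
  n_batches <- max(1L, min(length(sp_ct$train), length(sp_cbct$train)) %/%
                     config$batch_size)
  for (ep in seq_len(config$epochs)) {
    ct_pairs <- augment_epoch(sp_ct$train, config$augment)
    cbct_pairs <- augment_epoch(sp_cbct$train, config$augment)
    ct_order <- sample(seq_along(ct_pairs))
    cbct_order <- sample(seq_along(cbct_pairs))
    terms <- NULL
    for (bi in seq_len(n_batches)) {
      sel <- function(ord) ord[((bi - 1L) * config$batch_size + 1L):
                                 min(bi * config$batch_size, length(ord))]
      ct <- stack_pairs(ct_pairs[sel(ct_order)])$ct
      cbct <- stack_pairs(cbct_pairs[sel(cbct_order)])$cbct
      step <- cyclegan_step(g_ct, g_cbct, d_ct, d_cbct, ct, cbct,
                            weights, kind)
      opt_g <- adam_step(opt_g)
      l_d_ct <- disc_step(d_ct, step$real_ct, step$sct, kind)
      l_d_cbct <- disc_step(d_cbct, step$real_cbct, step$scbct, kind)
      opt_d <- adam_step(opt_d)
      terms <- rbind(terms, cbind(as.data.frame(step$losses),
                                  data.frame(d_ct = l_d_ct,
                                             d_cbct = l_d_cbct)))
    }
    vs <- validation_ssim(g_ct, sp_cbct$val)
    vm <- validation_mae_hu(g_ct, sp_cbct$val)
    hist <- rbind(hist, cbind(data.frame(epoch = ep), t(colMeans(terms)),
                              data.frame(val_ssim = vs, val_mae_hu = vm)))
    if (config$verbose)
      message(sprintf("epoch %d: G %.3f, D %.3f/%.3f, val SSIM %.4f, MAE %.1f",
                      ep, mean(terms$generator_total), mean(terms$d_ct),
                      mean(terms$d_cbct), vs, vm))
    if (vs > best$ssim)
      best <- list(ssim = vs, weights = get_weights(g_ct), epoch = ep)
  }
  set_weights(g_ct, best$weights)
  list(g_ct = g_ct, g_cbct = g_cbct, d_ct = d_ct, d_cbct = d_cbct,
       history = hist, best_epoch = best$epoch,
       validation = sp_cbct$val)
}

# One joint generator update. Pass order is arranged so each network's
# forward cache is consumed by its backward before being overwritten:
# translate -> cycle -> (cycle bwd) -> (adversarial bwd) -> primary bwd,
# then the identity passes. Returns detached fakes for the discriminator
# step plus the evaluated generator loss terms.
cyclegan_step <- function(g_ct, g_cbct, d_ct, d_cbct, ct, cbct,
                          weights, kind) {
  zero_grads(list(g_ct, g_cbct))

  # CBCT -> sCT -> cycleCBCT
  sct <- generator_forward(g_ct, cbct, train = TRUE)
  np <- length(sct)
  cyc_cbct <- generator_forward(g_cbct, sct, train = TRUE)
  l_cyc_cbct <- supervised_loss(cbct, cyc_cbct)
  dsct_cyc <- generator_backward(
    g_cbct, weights$lambda_cycle * sign(cyc_cbct - cbct) / np, need_dx = TRUE)
  p_ct <- discriminator_forward(d_ct, sct, train = TRUE)
  g_adv_ct <- adv_loss(p_ct, 1, kind)
  dsct_adv <- discriminator_backward_input(d_ct, adv_grad(p_ct, 1, kind))
  generator_backward(g_ct, dsct_adv + dsct_cyc, need_dx = FALSE)

  # CT -> sCBCT -> cycleCT
  scbct <- generator_forward(g_cbct, ct, train = TRUE)
  cyc_ct <- generator_forward(g_ct, scbct, train = TRUE)
  l_cyc_ct <- supervised_loss(ct, cyc_ct)
  dscbct_cyc <- generator_backward(
    g_ct, weights$lambda_cycle * sign(cyc_ct - ct) / np, need_dx = TRUE)
  p_cbct <- discriminator_forward(d_cbct, scbct, train = TRUE)
  g_adv_cbct <- adv_loss(p_cbct, 1, kind)
  dscbct_adv <- discriminator_backward_input(d_cbct,
                                             adv_grad(p_cbct, 1, kind))
  generator_backward(g_cbct, dscbct_adv + dscbct_cyc, need_dx = FALSE)

  # identity terms
  id_ct <- generator_forward(g_ct, ct, train = TRUE)
  l_id_ct <- supervised_loss(ct, id_ct)
  generator_backward(g_ct, weights$lambda_identity * sign(id_ct - ct) / np,
                     need_dx = FALSE)
  id_cbct <- generator_forward(g_cbct, cbct, train = TRUE)
  l_id_cbct <- supervised_loss(cbct, id_cbct)
  generator_backward(g_cbct,
                     weights$lambda_identity * sign(id_cbct - cbct) / np,
                     need_dx = FALSE)

  losses <- list(gen_adv_ct = g_adv_ct, gen_adv_cbct = g_adv_cbct,
                 cycle = l_cyc_cbct + l_cyc_ct,
                 identity = l_id_ct + l_id_cbct,
                 generator_total = g_adv_ct + g_adv_cbct +
                   weights$lambda_cycle * (l_cyc_cbct + l_cyc_ct) +
                   weights$lambda_identity * (l_id_ct + l_id_cbct))
  list(losses = losses, sct = sct, scbct = scbct,
       real_ct = ct, real_cbct = cbct)
}

# Discriminator update on real (label 1) vs detached fake (label 0);
# returns the discriminator loss for reporting.
disc_step <- function(d, real, fake, kind) {
  zero_grads(d)
  p_real <- discriminator_forward(d, real, train = TRUE)
  discriminator_backward(d, adv_grad(p_real, 1, kind))
  p_fake <- discriminator_forward(d, fake, train = TRUE)
  discriminator_backward(d, adv_grad(p_fake, 0, kind))
  adv_loss(p_real, 1, kind) + adv_loss(p_fake, 0, kind)
}

#' Wrap a trained generator as a slice translator
#'
#' @param generator A trained generator.
#' @return Function mapping a normalized CBCT matrix to a normalized sCT
#'   matrix.
#' @export
make_translator <- function(generator) {
  force(generator)
  function(cbct_norm) {
    x <- array(cbct_norm, dim = c(dim(cbct_norm), 1L, 1L))
    y <- generator_forward(generator, x, train = FALSE)
    matrix(y, dim(y)[1L], dim(y)[2L])
  }
}

#' Translate a CBCT volume slice-wise into synthetic CT
#'
#' Each slice is normalized, passed through the generator, and denormalized
#' back to HU; geometry is preserved.
#'
#' @param generator A trained generator (flagged by [train_supervised()] /
#'   [train_cyclegan()] or built and initialized explicitly).
#' @param cbct_volume List of [hu_image()] slices (or matrices).
#' @return List of [hu_image()] slices in HU.
#' @export
translate_volume <- function(generator, cbct_volume) {
  if (is.null(generator$initialized) || !generator$initialized)
    stop("generator is uninitialized; train or initialize it first")
  slices <- volume_slices(cbct_volume)
  tr <- make_translator(generator)
  lapply(seq_along(slices), function(i) {
    ref <- if (inherits(cbct_volume[[i]], "hu_image")) cbct_volume[[i]]
           else hu_image(slices[[i]])
    hu_image(clip_hu(denormalize_hu(tr(normalize_hu(slices[[i]])))),
             ref$pixel_spacing, ref$slice_thickness)
  })
}
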