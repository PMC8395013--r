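# HU-accuracy evaluation: MAE / PSNR / SSIM, patient-wise k-fold
# cross-validation, and non-parametric model comparison
# (Kruskal-Wallis + Tukey-Kramer-type post-hoc on rank sums).

#' Mean absolute error in Hounsfield units
#'
#' @param a,b [hu_image()] objects or matrices in HU.
#' @param region Optional logical matrix restricting the average (typically
#'   the body mask). `NULL` averages over the whole frame.
#' @return MAE in HU.
#' @export
compute_mae_hu <- function(a, b, region = NULL) {
  a <- if (inherits(a, "hu_image")) a$pixels else a
  b <- if (inherits(b, "hu_image")) b$pixels else b
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  d <- abs(a - b)
  if (!is.null(region)) {
    if (!any(region)) stop("empty evaluation region")
    d <- d[region]
  }
  mean(d)
}

#' Peak signal-to-noise ratio on normalized images
#'
#' `10 * log10(data_range^2 / MSE)`; returns `Inf` for identical images.
#'
#' @param a,b Numeric matrices on the normalized `[0, 1]` scale.
#' @param data_range Dynamic range of the data (1 for normalized images).
#' @return PSNR in dB.
#' @export
compute_psnr <- function(a, b, data_range = 1) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# Valid-mode 2D correlation with a small window, via the package conv engine.
filter_valid <- function(x, w) {
  k <- nrow(w)
  xt <- array(x, dim = c(dim(x), 1L, 1L))
  wt <- array(w, dim = c(k, k, 1L, 1L))
  y <- .conv2d_forward(xt, wt, NULL, 1L, 0L, 0L, 0L, 0L)
  matrix(y, dim(y)[1L], dim(y)[2L])
}

#' Structural similarity index (mean SSIM)
#'
#' Classic Wang et al. formulation: local statistics under an 11x11 Gaussian
#' window (sigma 1.5), stability constants `K1 = 0.01`, `K2 = 0.03`, computed
#' in valid mode and averaged over the map.
#'
#' @param a,b Numeric matrices on the normalized scale.
#' @param data_range Dynamic range (1 for normalized images).
#' @param window_size,sigma Gaussian window geometry.
#' @param K1,K2 Stability constants.
#' @return Mean SSIM.
#' @export
compute_ssim <- function(a, b, data_range = 1, window_size = 11L, sigma = 1.5,
                         K1 = 0.01, K2 = 0.03) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (any(dim(a) < window_size)) stop("image smaller than the SSIM window")
  w <- gaussian_window(window_size, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu1 <- filter_valid(a, w); mu2 <- filter_valid(b, w)
  s11 <- filter_valid(a * a, w) - mu1^2
  s22 <- filter_valid(b * b, w) - mu2^2
  s12 <- filter_valid(a * b, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Subject-level fold assignment for cross-validation
#'
#' Subjects (never individual slices) are shuffled under `seed` and dealt
#' round-robin into `k` near-equal folds.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `fold_split`: a named integer vector mapping
#'   subject to fold.
#' @export
make_folds <- function(subject_ids, k = 4L, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (k > length(subject_ids)) stop("k exceeds the number of subjects")
  perm <- with_seed(seed, sample(subject_ids))
  assignment <- stats::setNames(rep(seq_len(k), length.out = length(perm)),
                                perm)
  structure(assignment[subject_ids], class = "fold_split", k = k)
}

metrics_record <- function(pair_id, model_label, ct, img, mask = NULL) {
  ct_n <- normalize_hu(ct)
  img_n <- normalize_hu(img)
  data.frame(image_id = pair_id, model = model_label,
             ssim = compute_ssim(ct_n, img_n),
             psnr = compute_psnr(ct_n, img_n),
             mae = compute_mae_hu(denormalize_hu(ct_n), denormalize_hu(img_n),
                                  region = mask),
             stringsAsFactors = FALSE)
}

#' Evaluate translated slices against ground-truth CT
#'
#' @param dataset List of `paired_slice` objects.
#' @param translator Function mapping a normalized CBCT matrix to a normalized
#'   sCT matrix (e.g. [make_translator()] around a trained generator), or
#'   `NULL` to evaluate the CBCT baseline only.
#' @param use_mask Evaluate MAE over the body mask (`TRUE`, default) or the
#'   whole frame.
#' @return A data frame of per-image `MetricsRecord` rows (model labels
#'   `"CBCT"` and `"sCT"`).
#' @export
evaluate_dataset <- function(dataset, translator = NULL, use_mask = TRUE) {
  rows <- lapply(seq_along(dataset), function(i) {
    p <- dataset[[i]]
    mask <- if (use_mask) attr(p, "body_mask") else NULL
    out <- metrics_record(i, "CBCT", p$ct, p$cbct, mask)
    if (!is.null(translator)) {
      sct_n <- translator(normalize_hu(p$cbct))
      sct <- hu_image(denormalize_hu(sct_n), p$ct$pixel_spacing,
                      p$ct$slice_thickness)
      out <- rbind(out, metrics_record(i, "sCT", p$ct, sct, mask))
    }
    out$subject_id <- p$subject_id
    out
  })
  do.call(rbind, rows)
}

#' Patient-wise k-fold cross-validation
#'
#' For each fold, trains on the remaining folds (supervised or unsupervised
#' mode) and evaluates SSIM/PSNR/MAE on the held-out fold for both the CBCT
#' baseline and the generated sCT. A custom `trainer` can replace the built-in
#' routines (e.g. an identity plug-in for oracle checks); it receives the
#' training subset and must return a translator function.
#'
#' @param dataset List of `paired_slice` objects.
#' @param config A [train_config()].
#' @param mode `"supervised"` or `"unsupervised"`.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param trainer Optional `function(train_set, config)` returning a
#'   translator `function(cbct_norm) -> sct_norm`.
#' @param use_mask Evaluate MAE over the body mask.
#' @return List with `records` (per-image data frame with fold column) and
#'   `summary` (median and IQR per fold, model, metric).
#' @export
cross_validate <- function(dataset, config = train_config(),
                           mode = c("supervised", "unsupervised"),
                           k = 4L, seed = 1L, trainer = NULL,
                           use_mask = TRUE) {
  mode <- match.arg(mode)
  ids <- vapply(dataset, function(p) p$subject_id, character(1))
  folds <- make_folds(unique(ids), k = k, seed = seed)
  if (is.null(trainer)) {
    trainer <- function(train_set, config) {
      if (mode == "supervised") {
        fit <- train_supervised(train_set, config)
        make_translator(fit$generator)
      } else {
        fit <- train_cyclegan(unpair_dataset(train_set), config)
        make_translator(fit$g_ct)
      }
    }
  }
  all_records <- NULL
  for (f in seq_len(k)) {
    test_idx <- which(folds[ids] == f)
    if (length(test_idx) == 0L) stop("fold ", f, " has no images")
    train_set <- dataset[-test_idx]
    translator <- trainer(train_set, config)
    rec <- evaluate_dataset(dataset[test_idx], translator, use_mask = use_mask)
    rec$fold <- f
    # leakage guard: no training subject may appear in the held-out fold
    stopifnot(!any(vapply(train_set, function(p) p$subject_id, character(1))
                   %in% rec$subject_id))
    all_records <- rbind(all_records, rec)
  }
  summary <- stats::aggregate(
    cbind(ssim, psnr, mae) ~ fold + model, data = all_records,
    FUN = function(v) c(median = stats::median(v), iqr = stats::IQR(v)))
  list(records = all_records, summary = summary)
}

#' Compare models with Kruskal-Wallis and Tukey-Kramer-type post-hoc tests
#'
#' For each metric, performs a tie-corrected Kruskal-Wallis test across model
#' groups; when its p-value falls below `alpha`, pairwise mean-rank
#' differences are tested against Tukey-type critical values (studentized
#' range on rank sums, the Kramer form for unequal group sizes). Group
#' summaries are reported as median (interquartile range).
#'
#' @param records Data frame with a `model` column and one column per metric.
#' @param metrics Character vector of metric column names.
#' @param alpha Significance level (default 0.01).
#' @return Object of class `stats_report`: per-metric Kruskal-Wallis p-values,
#'   post-hoc decisions, and group medians/IQRs.
#' @export
compare_models <- function(records, metrics = c("ssim", "psnr", "mae"),
                           alpha = 0.01) {
  stopifnot("model" %in% names(records))
  groups <- split(records, records$model)
  if (length(groups) < 2L) stop("need at least 2 model groups")
  if (any(vapply(groups, nrow, integer(1)) < 5L))
    stop("each group needs >= 5 records")
  out <- list()
  for (m in metrics) {
    v <- records[[m]]
    if (length(unique(v)) == 1L) stop("degenerate all-tied data for ", m)
    g <- factor(records$model)
    kw <- stats::kruskal.test(v, g)
    med <- tapply(v, g, stats::median)
    iqr <- tapply(v, g, stats::IQR)
    posthoc <- NULL
    if (is.finite(kw$p.value) && kw$p.value < alpha)
      posthoc <- tukey_kramer_ranks(v, g, alpha)
    out[[m]] <- list(kruskal_wallis_p = kw$p.value,
                     kruskal_wallis_H = unname(kw$statistic),
                     medians = med, iqrs = iqr, posthoc = posthoc,
                     formatted = sprintf("%.3f (%.3f)", med, iqr))
  }
  structure(out, class = "stats_report", alpha = alpha)
}

# Pairwise mean-rank comparisons with studentized-range critical values
# (Nemenyi / Tukey-Kramer on rank sums; Kramer correction for unequal n).
tukey_kramer_ranks <- function(v, g, alpha = 0.01) {
  r <- rank(v)
  n <- length(v)
  levs <- levels(g)
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  k <- length(levs)
  pairs <- utils::combn(levs, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, critical = NA_real_, reject = NA)
  qcrit <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(n * (n + 1) / 12 * (1 / ns[[a]] + 1 / ns[[b]]))
    res$diff[i] <- abs(mean_ranks[[a]] - mean_ranks[[b]])
    res$critical[i] <- qcrit * se
    res$reject[i] <- res$diff[i] > res$critical[i]
  }
  res
}

#' @export
print.stats_report <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("%s: Kruskal-Wallis H = %.3f, p = %.3g\n", m,
                x[[m]]$kruskal_wallis_H, x[[m]]$kruskal_wallis_p))
    lab <- names(x[[m]]$medians)
    for (i in seq_along(lab))
      cat(sprintf("  %-16s %s\n", lab[i], x[[m]]$formatted[i]))
  }
  invisible(x)
}
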