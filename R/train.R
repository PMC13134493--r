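# Fine-tuning recipe: inverse-frequency weighted cross-entropy, linearly
# decaying learning rate, fixed batch sizes and epoch counts, flip-only
# augmentation, one independent model per imaging modality.

#' Training configuration
#'
#' Two named presets mirror the two fine-tuning regimes used throughout:
#' `"foundation"` (batch 32, 2 epochs) for the initial large-scale style of
#' training and `"finetune"` (batch 16, 1 epoch) for subsequent local
#' adaptations. The learning rate always starts at 0.0005 and decays
#' linearly to zero over the run.
#'
#' @param lr0 Initial learning rate.
#' @param batch_size Images per optimization step.
#' @param epochs Passes over the training manifest.
#' @param modality Which modality's rows to train on: `"visible"`, `"uv"`,
#'   or `"all"` for a foundation-style fit over every image regardless of
#'   modality.
#' @param seed Integer seed controlling shuffling and augmentation.
#' @param preset Optional preset: `"foundation"` or `"finetune"`.
#' @param threshold Decision threshold on the crystal probability used by
#'   downstream binary calls; one constant shared with fusion and the
#'   curation loop.
#' @param beta1,beta2,adam_eps Adaptive-moment optimizer constants.
#' @param weight_decay Decoupled weight decay (default 0).
#' @param clip_norm Global gradient-norm clip; `NULL` (default) disables
#'   clipping.
#' @param warmup_frac Fraction of total steps spent ramping the learning
#'   rate linearly from zero to `lr0` before the linear decay begins
#'   (default 0: pure linear decay from `lr0`).
#' @param avg_tail_frac When positive, the returned model's trainable
#'   arrays are the average of their values over the final fraction of
#'   optimization steps (tail weight averaging), which damps the
#'   step-to-step noise of small-batch training. Default 0 (off).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 5e-4, batch_size = 16L, epochs = 1L,
                         modality = c("visible", "uv", "all"), seed = 1L,
                         preset = NULL, threshold = 0.5,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         weight_decay = 0, clip_norm = NULL,
                         warmup_frac = 0, avg_tail_frac = 0) {
  modality <- match.arg(modality)
  if (!is.null(preset)) {
    if (preset == "foundation") { batch_size <- 32L; epochs <- 2L }
    else if (preset == "finetune") { batch_size <- 16L; epochs <- 1L }
    else rlang::abort(paste0("unknown train preset: ", preset),
                      class = "dropvision_error_config")
  }
  if (lr0 <= 0 || batch_size < 1L || epochs < 1L) {
    rlang::abort("lr0 must be positive; batch_size and epochs at least 1",
                 class = "dropvision_error_config")
  }
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), modality = modality,
                 seed = as.integer(seed), threshold = threshold,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 warmup_frac = warmup_frac, avg_tail_frac = avg_tail_frac),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' Weights are proportional to the inverse class frequency and normalized so
#' the mean weight is one: `w_c = N / (2 n_c)` with `N = n_crystal + n_other`.
#' Balanced classes give unit weights; rare classes are up-weighted.
#'
#' @param n_crystal,n_other Per-class training counts (both must be >= 1).
#' @return Named numeric vector with elements `crystal` and `other`.
#' @export
class_weights <- function(n_crystal, n_other) {
  if (n_crystal < 1 || n_other < 1) {
    rlang::abort("both classes must be represented in the training manifest",
                 class = "dropvision_error_degenerate")
  }
  N <- n_crystal + n_other
  c(crystal = N / (2 * n_crystal), other = N / (2 * n_other))
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `-w[y_i] * log p_i(y_i)`. Probabilities at the
#' true label are clamped below at `eps` before the logarithm.
#'
#' @param probs Matrix of predicted class probabilities with columns named
#'   `other` and `crystal` (rows sum to one).
#' @param labels Character vector of true labels (`"crystal"`/`"other"`).
#' @param weights Named class weights as from [class_weights()]; equal
#'   weights reduce the loss to the unweighted cross-entropy exactly.
#' @param eps Clamp for zero probabilities.
#' @return Scalar loss.
#' @export
weighted_loss <- function(probs, labels, weights = c(crystal = 1, other = 1),
                          eps = 1e-12) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(labels)) {
    rlang::abort("probs and labels lengths differ", class = "dropvision_error_shape")
  }
  p_true <- probs[cbind(seq_along(labels), match(labels, colnames(probs)))]
  mean(weights[labels] * -log(pmax(p_true, eps)))
}

#' Linearly decaying learning rate
#'
#' `lr0 * (1 - step / total_steps)`: the configured rate at step 0, zero at
#' the final step.
#'
#' @param step Current step, `0 <= step <= total_steps`.
#' @param total_steps Total optimization steps in the run (> 0).
#' @param lr0 Initial learning rate.
#' @return The learning rate at `step`.
#' @export
lr_at <- function(step, total_steps, lr0 = 5e-4) {
  if (total_steps <= 0) {
    rlang::abort("total_steps must be positive", class = "dropvision_error_config")
  }
  if (any(step < 0) || any(step > total_steps)) {
    rlang::abort("step must lie in [0, total_steps]", class = "dropvision_error_config")
  }
  lr0 * (1 - step / total_steps)
}

#' Fine-tune a classifier on one modality of a manifest
#'
#' Trains only the trainable arrays of the model (the active adapter stage
#' and, if configured, the classification head; for an un-adapted model,
#' everything) with an adaptive-moment optimizer under the weighted
#' cross-entropy loss. Images are standardized once up front; normalization
#' constants default to the training-set mean and standard deviation and are
#' stored on the returned model. Augmentation is flip-only. Training is
#' deterministic under a fixed seed.
#'
#' The manifest must contain only training rows: any `split == "test"` row
#' is a hard error (train/test hygiene), and rows are filtered to
#' `cfg$modality` with a present binary label.
#'
#' @param model A `vit_classifier` (typically adapter-injected).
#' @param manifest A manifest with `image_path`, `modality`, `binary_label`
#'   and `split` columns.
#' @param images Named list of image matrices keyed by `image_path`.
#' @param cfg A [train_config()].
#' @param pcfg A [preprocess_config()]; `NULL` normalization constants are
#'   computed from the training images.
#' @param weights Named class weights (`crystal`, `other`); the default
#'   `NULL` computes inverse-frequency weights from the training rows.
#' @return A list with elements `model` (trained) and `history` (a tibble of
#'   per-step `epoch`, `step`, `lr`, `loss`).
#' @export
fit <- function(model, manifest, images, cfg = train_config(),
                pcfg = preprocess_config(target_size = model$cfg$image_size),
                weights = NULL) {
  stopifnot(inherits(model, "vit_classifier"))
  if (any(manifest$split == "test", na.rm = TRUE)) {
    rlang::abort("manifest contains test-split rows; training refused",
                 class = "dropvision_error_split")
  }
  rows <- manifest[(cfg$modality == "all" | manifest$modality == cfg$modality) &
                     !is.na(manifest$binary_label), , drop = FALSE]
  if (nrow(rows) == 0L) {
    rlang::abort("no labelled training rows for the requested modality",
                 class = "dropvision_error_degenerate")
  }
  if (pcfg$target_size != model$cfg$image_size) {
    rlang::abort("preprocess target_size must match the model image size",
                 class = "dropvision_error_config")
  }
  missing <- setdiff(rows$image_path, names(images))
  if (length(missing)) {
    rlang::abort(paste0("images missing for ", length(missing), " manifest rows"),
                 class = "dropvision_error_io")
  }
  labels <- rows$binary_label
  wts <- weights %||%
    class_weights(sum(labels == "crystal"), sum(labels == "other"))

  raw <- lapply(images[rows$image_path], standardize,
                cfg = preprocess_config(target_size = pcfg$target_size))
  if (is.null(pcfg$norm_mean) || is.null(pcfg$norm_sd)) {
    nrm <- compute_normalization(raw)
    pcfg$norm_mean <- nrm$mean; pcfg$norm_sd <- nrm$sd
  }
  xs <- lapply(raw, function(x) (x - pcfg$norm_mean) / pcfg$norm_sd)

  n <- length(xs)
  n_batches <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$epochs * n_batches
  opt <- new.env(parent = emptyenv())
  opt$m <- list(); opt$v <- list()
  trainable_head <- !model$base_frozen || model$head_trainable
  active <- model$active_stage

  adam <- function(key, theta, g, lr) {
    m <- opt$m[[key]] %||% (theta * 0)
    v <- opt$v[[key]] %||% (theta * 0)
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
    opt$m[[key]] <- m; opt$v[[key]] <- v
    t <- opt$t
    mh <- m / (1 - cfg$beta1^t)
    vh <- v / (1 - cfg$beta2^t)
    theta - lr * (mh / (sqrt(vh) + cfg$adam_eps) + cfg$weight_decay * theta)
  }

  set.seed(cfg$seed)
  hist <- vector("list", total_steps)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (bi in seq_len(n_batches)) {
      sel <- ord[(((bi - 1L) * cfg$batch_size) + 1L):min(bi * cfg$batch_size, n)]
      xb <- lapply(xs[sel], function(x) {
        r <- stats::runif(2)
        if (pcfg$augment_flips) {
          if (r[1] < 0.5) x <- x[, rev(seq_len(ncol(x)))]
          if (r[2] < 0.5) x <- x[rev(seq_len(nrow(x))), ]
        }
        x
      })
      yb <- labels[sel]
      fw <- .vit_fwd(model, xb, keep_cache = TRUE)
      p <- fw$probs
      yi <- ifelse(yb == "crystal", 2L, 1L)
      wb <- unname(wts[yb])
      loss <- mean(wb * -log(pmax(p[cbind(seq_along(yi), yi)], 1e-12)))
      dlogits <- p
      dlogits[cbind(seq_along(yi), yi)] <- dlogits[cbind(seq_along(yi), yi)] - 1
      dlogits <- dlogits * (wb / length(yi))
      gr <- .vit_bwd(model, fw$cache, dlogits)
      if (!is.null(cfg$clip_norm)) {
        sq <- sum(gr$head_w^2) + sum(gr$head_b^2) +
          sum(vapply(gr$adapters, function(g) sum(g$A^2) + sum(g$B^2), numeric(1)))
        gn <- sqrt(sq)
        if (gn > cfg$clip_norm) {
          sc <- cfg$clip_norm / gn
          gr$head_w <- gr$head_w * sc; gr$head_b <- gr$head_b * sc
          gr$adapters <- lapply(gr$adapters, function(g)
            list(A = g$A * sc, B = g$B * sc))
        }
      }
      wsteps <- floor(cfg$warmup_frac * total_steps)
      lr <- if (step < wsteps) {
        cfg$lr0 * (step + 1) / wsteps
      } else {
        lr_at(step - wsteps, total_steps - wsteps, cfg$lr0)
      }
      opt$t <- step + 1L
      if (trainable_head) {
        model$params$head_w <- adam("head_w", model$params$head_w, gr$head_w, lr)
        model$params$head_b <- adam("head_b", model$params$head_b, gr$head_b, lr)
      }
      if (active > 0L && isTRUE(model$adapters[[active]]$trainable)) {
        for (nm in names(gr$adapters)) {
          ad <- model$adapters[[active]]$layers[[nm]]
          ad$A <- adam(paste0("A.", nm), ad$A, gr$adapters[[nm]]$A, lr)
          ad$B <- adam(paste0("B.", nm), ad$B, gr$adapters[[nm]]$B, lr)
          model$adapters[[active]]$layers[[nm]] <- ad
        }
      }
      step <- step + 1L
      hist[[step]] <- tibble::tibble(epoch = ep, step = step, lr = lr, loss = loss)
      if (cfg$avg_tail_frac > 0 && step > (1 - cfg$avg_tail_frac) * total_steps) {
        opt$avg_n <- (opt$avg_n %||% 0) + 1
        acc <- function(key, theta) {
          opt$avg[[key]] <- (opt$avg[[key]] %||% (theta * 0)) + theta
        }
        if (is.null(opt$avg)) opt$avg <- list()
        if (trainable_head) { acc("head_w", model$params$head_w); acc("head_b", model$params$head_b) }
        if (active > 0L) for (nm in names(model$adapters[[active]]$layers)) {
          acc(paste0("A.", nm), model$adapters[[active]]$layers[[nm]]$A)
          acc(paste0("B.", nm), model$adapters[[active]]$layers[[nm]]$B)
        }
      }
    }
  }
  if (cfg$avg_tail_frac > 0 && !is.null(opt$avg)) {
    if (trainable_head) {
      model$params$head_w <- opt$avg[["head_w"]] / opt$avg_n
      model$params$head_b <- opt$avg[["head_b"]] / opt$avg_n
    }
    if (active > 0L) for (nm in names(model$adapters[[active]]$layers)) {
      model$adapters[[active]]$layers[[nm]]$A <- opt$avg[[paste0("A.", nm)]] / opt$avg_n
      model$adapters[[active]]$layers[[nm]]$B <- opt$avg[[paste0("B.", nm)]] / opt$avg_n
    }
  }
  model$preprocess <- pcfg
  list(model = model, history = dplyr::bind_rows(hist))
}

#' Score images with a trained model
#'
#' Standardizes images with the normalization constants stored on the model
#' at training time and returns the per-image crystal probability.
#'
#' @param model A trained `vit_classifier` (with `model$preprocess` set; a
#'   plain [preprocess_config()] is used otherwise).
#' @param images Named list of image matrices.
#' @return Numeric vector of crystal probabilities, named by image.
#' @export
score_images <- function(model, images) {
  pcfg <- model$preprocess %||% preprocess_config(target_size = model$cfg$image_size)
  xs <- lapply(images, standardize, cfg = pcfg)
  p <- vit_predict(model, xs)
  names(p) <- names(images)
  p
}

#' Image-inference accounting for a training run
#'
#' Number of training-image inferences a run performs: every image is
#' inferred once per epoch per model trained, so a paired-modality
#' fine-tuning (one visible and one UV model) doubles the per-model count.
#'
#' @param n_images Images seen by each model per epoch.
#' @param epochs Epochs per model.
#' @param models Number of independent models trained (default 1).
#' @return Total image inferences (numeric scalar).
#' @export
training_inferences <- function(n_images, epochs, models = 1L) {
  as.numeric(n_images) * as.numeric(epochs) * as.numeric(models)
}
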