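# Minimal vision-transformer classifier with a 2-class head.
#
# The backbone follows the standard pre-norm ViT contract: patch-embedding
# projection, learned class token and position embeddings, L encoder blocks
# (LayerNorm -> multi-head self-attention -> residual, LayerNorm -> 2-layer
# GELU MLP -> residual), final LayerNorm and a linear head on the class token.
# Forward and backward passes are implemented directly on dense matrices so
# that low-rank adapters (see lora.R) can be injected into every dense layer
# and trained while the base weights stay frozen bit-for-bit.

#' Vision transformer configuration
#'
#' Two presets are provided. `"base-accounting"` mirrors the geometry of a
#' ViT-B/14 backbone (518x518 input, 12 blocks, hidden 768, 12 heads, MLP
#' 3072, 3 input channels); it exists to verify parameter arithmetic and is
#' never trained here. `"tiny-desk"` (64x64 input, 4 blocks, hidden 64,
#' 4 heads, MLP 256, grayscale) is small enough to train on a CPU in minutes
#' and is the default for all experiments in this package.
#'
#' @param preset Optional preset name, `"base-accounting"` or `"tiny-desk"`.
#'   When given, the remaining geometry arguments are ignored.
#' @param image_size,patch_size Input side length and square patch side, in
#'   pixels. `image_size` must be divisible by `patch_size`.
#' @param depth Number of encoder blocks.
#' @param hidden Token channel dimension; must be divisible by `heads`.
#' @param heads Number of attention heads.
#' @param mlp_dim Hidden width of the per-block MLP.
#' @param in_channels Input channels (1 for grayscale).
#' @param num_classes Number of output classes; fixed to 2 (crystal / other).
#' @param qkv_fused If `TRUE`, query/key/value are computed by a single fused
#'   dense layer per block instead of three separate ones. Both conventions
#'   are supported because adapter targeting and parameter accounting depend
#'   on how the dense-layer inventory is laid out.
#' @param pool Head pooling: `"mean"` (average of the patch tokens, the
#'   default) or `"cls"` (class token). Mean pooling gives every patch a
#'   direct gradient path to the head, which matters when the backbone is
#'   trained from scratch rather than adapted from a pretrained checkpoint;
#'   the class token is kept in the token stream under either setting.
#' @return An object of class `vit_config`.
#' @export
vit_config <- function(preset = NULL, image_size = 64L, patch_size = 8L,
                       depth = 4L, hidden = 64L, heads = 4L, mlp_dim = 256L,
                       in_channels = 1L, num_classes = 2L, qkv_fused = FALSE,
                       pool = c("mean", "cls")) {
  pool <- match.arg(pool)
  presets <- list(
    "base-accounting" = list(image_size = 518L, patch_size = 14L, depth = 12L,
                             hidden = 768L, heads = 12L, mlp_dim = 3072L,
                             in_channels = 3L),
    "tiny-desk" = list(image_size = 64L, patch_size = 8L, depth = 4L,
                       hidden = 64L, heads = 4L, mlp_dim = 256L,
                       in_channels = 1L)
  )
  if (!is.null(preset)) {
    if (!preset %in% names(presets)) {
      rlang::abort(paste0("unknown vit preset: ", preset),
                   class = "dropvision_error_config")
    }
    p <- presets[[preset]]
    image_size <- p$image_size; patch_size <- p$patch_size
    depth <- p$depth; hidden <- p$hidden; heads <- p$heads
    mlp_dim <- p$mlp_dim; in_channels <- p$in_channels
  }
  cfg <- list(preset = preset %||% "custom",
              image_size = as.integer(image_size),
              patch_size = as.integer(patch_size),
              depth = as.integer(depth), hidden = as.integer(hidden),
              heads = as.integer(heads), mlp_dim = as.integer(mlp_dim),
              in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              qkv_fused = isTRUE(qkv_fused), pool = pool)
  if (cfg$image_size %% cfg$patch_size != 0L) {
    rlang::abort("image_size must be divisible by patch_size",
                 class = "dropvision_error_config")
  }
  if (cfg$hidden %% cfg$heads != 0L) {
    rlang::abort("hidden must be divisible by heads",
                 class = "dropvision_error_config")
  }
  if (cfg$num_classes != 2L) {
    rlang::abort("this classifier is binary: num_classes must be 2",
                 class = "dropvision_error_config")
  }
  structure(cfg, class = "vit_config")
}

#' Build a classifier with deterministic initialization
#'
#' Dense kernels use Glorot-scaled normal initialization; class token and
#' position embeddings use a small-variance normal; LayerNorm gains start at
#' one. The same `cfg` and `seed` always produce identical weights.
#'
#' @param cfg A [vit_config()].
#' @param seed Integer seed controlling initialization.
#' @return An object of class `vit_classifier`.
#' @export
vit_build <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "vit_config"))
  set.seed(seed)
  d <- cfg$hidden; m <- cfg$mlp_dim
  pd <- cfg$patch_size^2 * cfg$in_channels
  n_tok <- (cfg$image_size %/% cfg$patch_size)^2 + 1L
  init <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(2 / (fi + fo))), fi, fo)
  blocks <- lapply(seq_len(cfg$depth), function(i) {
    bl <- list(ln1_g = rep(1, d), ln1_b = numeric(d))
    if (cfg$qkv_fused) {
      bl$wqkv <- init(d, 3L * d); bl$bqkv <- numeric(3L * d)
    } else {
      bl$wq <- init(d, d); bl$bq <- numeric(d)
      bl$wk <- init(d, d); bl$bk <- numeric(d)
      bl$wv <- init(d, d); bl$bv <- numeric(d)
    }
    bl$wo <- init(d, d); bl$bo <- numeric(d)
    bl$ln2_g <- rep(1, d); bl$ln2_b <- numeric(d)
    bl$w1 <- init(d, m); bl$b1 <- numeric(m)
    bl$w2 <- init(m, d); bl$b2 <- numeric(d)
    bl
  })
  params <- list(
    patch_w = init(pd, d), patch_b = numeric(d),
    cls = matrix(stats::rnorm(d, 0, 0.02), 1, d),
    pos = matrix(stats::rnorm(n_tok * d, 0, 0.02), n_tok, d),
    blocks = blocks,
    lnf_g = rep(1, d), lnf_b = numeric(d),
    head_w = init(d, cfg$num_classes), head_b = numeric(cfg$num_classes)
  )
  structure(list(cfg = cfg, params = params, adapters = list(),
                 active_stage = 0L, base_frozen = FALSE,
                 head_trainable = TRUE, seed = as.integer(seed),
                 preprocess = NULL),
            class = "vit_classifier")
}

#' Dense-layer inventory of a classifier
#'
#' Lists every dense (fully connected) layer of the backbone with its fan-in
#' and fan-out: per block the query/key/value maps (or the fused qkv map),
#' the attention output map and both MLP layers, plus the patch-embedding
#' projection and the classification head. With separate q/k/v layers the
#' inventory holds `6 * depth + 2` rows. This inventory is the surface the
#' LoRA machinery targets.
#'
#' @param model A `vit_classifier` (or a `vit_config`).
#' @return A tibble with columns `name`, `fan_in`, `fan_out`.
#' @export
dense_inventory <- function(model) {
  cfg <- if (inherits(model, "vit_config")) model else model$cfg
  d <- cfg$hidden; m <- cfg$mlp_dim
  pd <- cfg$patch_size^2 * cfg$in_channels
  rows <- list(tibble::tibble(name = "patch_embed", fan_in = pd, fan_out = d))
  for (i in seq_len(cfg$depth)) {
    pre <- paste0("block", i, ".")
    if (cfg$qkv_fused) {
      attn <- tibble::tibble(name = paste0(pre, "attn.qkv"), fan_in = d, fan_out = 3 * d)
    } else {
      attn <- tibble::tibble(name = paste0(pre, "attn.", c("q", "k", "v")),
                             fan_in = d, fan_out = d)
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      attn,
      tibble::tibble(name = paste0(pre, "attn.out"), fan_in = d, fan_out = d),
      tibble::tibble(name = paste0(pre, "mlp.fc1"), fan_in = d, fan_out = m),
      tibble::tibble(name = paste0(pre, "mlp.fc2"), fan_in = m, fan_out = d)
    )
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(name = "head", fan_in = d,
                                              fan_out = cfg$num_classes)
  dplyr::bind_rows(rows)
}

# Map an inventory layer name to its weight matrix within params.
.layer_W <- function(params, name) {
  if (name == "patch_embed") return(params$patch_w)
  if (name == "head") return(params$head_w)
  mt <- regmatches(name, regexec("^block([0-9]+)\\.(attn|mlp)\\.(.+)$", name))[[1]]
  bl <- params$blocks[[as.integer(mt[2])]]
  switch(paste(mt[3], mt[4]),
         "attn q" = bl$wq, "attn k" = bl$wk, "attn v" = bl$wv,
         "attn qkv" = bl$wqkv, "attn out" = bl$wo,
         "mlp fc1" = bl$w1, "mlp fc2" = bl$w2,
         rlang::abort(paste0("unknown dense layer: ", name)))
}

.layer_W_set <- function(params, name, W) {
  if (name == "patch_embed") { params$patch_w <- W; return(params) }
  if (name == "head") { params$head_w <- W; return(params) }
  mt <- regmatches(name, regexec("^block([0-9]+)\\.(attn|mlp)\\.(.+)$", name))[[1]]
  i <- as.integer(mt[2])
  fld <- switch(paste(mt[3], mt[4]),
                "attn q" = "wq", "attn k" = "wk", "attn v" = "wv",
                "attn qkv" = "wqkv", "attn out" = "wo",
                "mlp fc1" = "w1", "mlp fc2" = "w2")
  params$blocks[[i]][[fld]] <- W
  params
}

#' Count total and trainable parameters
#'
#' Walks every weight array of the model (base weights and any adapter
#' stages) and sums element counts, split by the frozen/trainable state:
#' base weights count as trainable unless the base has been frozen by
#' adapter injection (or [freeze_base()]), adapter factors count as
#' trainable only in the active stage, and the classification head follows
#' the model's `head_trainable` flag once the base is frozen.
#'
#' @param model A `vit_classifier`.
#' @return A list with elements `total` and `trainable`.
#' @export
param_count <- function(model) {
  stopifnot(inherits(model, "vit_classifier"))
  n_of <- function(x) if (is.null(x)) 0 else length(x)
  flat <- function(x) {
    if (is.list(x)) sum(vapply(x, flat, numeric(1))) else n_of(x)
  }
  base_total <- flat(model$params)
  head_n <- length(model$params$head_w) + length(model$params$head_b)
  ad_total <- 0; ad_trainable <- 0
  for (si in seq_along(model$adapters)) {
    st <- model$adapters[[si]]
    n <- sum(vapply(st$layers, function(l) length(l$A) + length(l$B), numeric(1)))
    ad_total <- ad_total + n
    if (isTRUE(st$trainable)) ad_trainable <- ad_trainable + n
  }
  if (!model$base_frozen) {
    trainable <- base_total + ad_trainable
  } else {
    trainable <- ad_trainable + if (isTRUE(model$head_trainable)) head_n else 0
  }
  list(total = base_total + ad_total, trainable = trainable)
}

#' Freeze all base weights
#'
#' @param model A `vit_classifier`.
#' @param head_trainable Keep the classification head trainable?
#' @return The model with its base marked frozen.
#' @export
freeze_base <- function(model, head_trainable = FALSE) {
  model$base_frozen <- TRUE
  model$head_trainable <- isTRUE(head_trainable)
  model
}

# patch extraction indices: (patch_size^2) x n_patches matrix of linear
# indices into an image matrix, patches ordered left-to-right, top-to-bottom,
# pixels within a patch column-major.
.patch_index <- function(S, P) {
  np <- S %/% P
  idx <- matrix(0L, P * P, np * np)
  n <- 0L
  for (pr in seq_len(np)) {
    rows <- ((pr - 1L) * P + 1L):(pr * P)
    for (pc in seq_len(np)) {
      n <- n + 1L
      cols <- ((pc - 1L) * P + 1L):(pc * P)
      idx[, n] <- as.integer(outer(rows, (cols - 1L) * S, `+`))
    }
  }
  idx
}

.ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  y <- sweep(xh, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, xh = xh, inv = inv)
}

# backward of layer norm w.r.t. its input only (gain/bias are frozen here)
.ln_bwd <- function(dY, ln, g) {
  dxh <- sweep(dY, 2, g, `*`)
  (dxh - rowMeans(dxh) - ln$xh * rowMeans(dxh * ln$xh)) * ln$inv
}

.lora_scaling <- function(lcfg) {
  if (lcfg$convention == "alpha_over_r") lcfg$alpha / lcfg$rank else lcfg$alpha
}

# dense layer forward with adapter contributions from every stage; caches
# the input (and the active stage's low-rank intermediate) when training.
.dense_fwd <- function(model, name, X, W, bvec, CC = NULL) {
  Y <- X %*% W
  Y <- sweep(Y, 2, bvec, `+`)
  for (si in seq_along(model$adapters)) {
    st <- model$adapters[[si]]
    ad <- st$layers[[name]]
    if (is.null(ad)) next
    s <- .lora_scaling(st$cfg)
    Z <- X %*% t(ad$A)
    Y <- Y + s * (Z %*% t(ad$B))
    if (!is.null(CC) && si == model$active_stage) CC$Z[[name]] <- Z
  }
  if (!is.null(CC)) CC$X[[name]] <- X
  Y
}

# dense layer backward: returns dX; accumulates adapter (and head) gradients
# into the environment GR when the layer is trainable.
.dense_bwd <- function(model, name, dY, W, CC, GR) {
  dX <- dY %*% t(W)
  for (si in seq_along(model$adapters)) {
    st <- model$adapters[[si]]
    ad <- st$layers[[name]]
    if (is.null(ad)) next
    s <- .lora_scaling(st$cfg)
    dZ <- s * (dY %*% ad$B)
    dX <- dX + dZ %*% ad$A
    if (si == model$active_stage && isTRUE(st$trainable)) {
      g <- GR$adapters[[name]]
      g$A <- g$A + crossprod(dZ, CC$X[[name]])
      g$B <- g$B + s * crossprod(dY, CC$Z[[name]])
      GR$adapters[[name]] <- g
    }
  }
  if (name == "head" && model$head_trainable) {
    GR$head_w <- GR$head_w + crossprod(CC$X[[name]], dY)
    GR$head_b <- GR$head_b + colSums(dY)
  }
  dX
}

# Full forward pass over a batch. `xb` is a list of standardized image
# matrices. Returns probabilities (and a cache when keep_cache = TRUE).
.vit_fwd <- function(model, xb, keep_cache = FALSE) {
  cfg <- model$cfg; prm <- model$params
  d <- cfg$hidden; h <- cfg$heads; dh <- d %/% h
  P <- cfg$patch_size; S <- cfg$image_size
  N <- (S %/% P)^2; Tt <- N + 1L
  B <- length(xb); BT <- B * Tt
  if (cfg$in_channels != 1L) {
    rlang::abort("forward pass supports single-channel input",
                 class = "dropvision_error_shape")
  }
  for (x in xb) {
    if (!is.matrix(x) || nrow(x) != S || ncol(x) != S) {
      rlang::abort(sprintf("input images must be %dx%d matrices", S, S),
                   class = "dropvision_error_shape")
    }
  }
  idx <- .patch_index(S, P)
  CC <- if (keep_cache) new.env(parent = emptyenv())
  if (keep_cache) { CC$X <- list(); CC$Z <- list(); CC$blocks <- vector("list", cfg$depth) }
  cls_rows <- (seq_len(B) - 1L) * Tt + 1L
  tok_rows <- setdiff(seq_len(BT), cls_rows)
  Xp <- matrix(0, B * N, P * P)
  for (b in seq_len(B)) {
    Xp[((b - 1L) * N + 1L):(b * N), ] <- t(matrix(xb[[b]][idx], nrow = P * P))
  }
  tok <- .dense_fwd(model, "patch_embed", Xp, prm$patch_w, prm$patch_b, CC)
  H <- matrix(0, BT, d)
  H[tok_rows, ] <- tok
  H[cls_rows, ] <- matrix(prm$cls, B, d, byrow = TRUE)
  H <- H + prm$pos[rep(seq_len(Tt), B), ]
  isd <- 1 / sqrt(dh)
  for (i in seq_len(cfg$depth)) {
    bl <- prm$blocks[[i]]
    ln1 <- .ln_fwd(H, bl$ln1_g, bl$ln1_b)
    if (cfg$qkv_fused) {
      QKV <- .dense_fwd(model, paste0("block", i, ".attn.qkv"), ln1$y, bl$wqkv, bl$bqkv, CC)
      Q <- QKV[, 1:d]; K <- QKV[, (d + 1):(2 * d)]; V <- QKV[, (2 * d + 1):(3 * d)]
    } else {
      Q <- .dense_fwd(model, paste0("block", i, ".attn.q"), ln1$y, bl$wq, bl$bq, CC)
      K <- .dense_fwd(model, paste0("block", i, ".attn.k"), ln1$y, bl$wk, bl$bk, CC)
      V <- .dense_fwd(model, paste0("block", i, ".attn.v"), ln1$y, bl$wv, bl$bv, CC)
    }
    O <- matrix(0, BT, d)
    att <- if (keep_cache) array(0, c(Tt, Tt, B * h))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tt + 1L):(b * Tt)
      for (hh in seq_len(h)) {
        cc <- ((hh - 1L) * dh + 1L):(hh * dh)
        Qh <- Q[rows, cc]; Kh <- K[rows, cc]
        Sc <- tcrossprod(Qh, Kh) * isd
        mx <- Sc[cbind(seq_len(Tt), max.col(Sc))]
        A <- exp(Sc - mx)
        A <- A / rowSums(A)
        O[rows, cc] <- A %*% V[rows, cc]
        if (keep_cache) att[, , (b - 1L) * h + hh] <- A
      }
    }
    AO <- .dense_fwd(model, paste0("block", i, ".attn.out"), O, bl$wo, bl$bo, CC)
    H2 <- H + AO
    ln2 <- .ln_fwd(H2, bl$ln2_g, bl$ln2_b)
    U <- .dense_fwd(model, paste0("block", i, ".mlp.fc1"), ln2$y, bl$w1, bl$b1, CC)
    G <- U * stats::pnorm(U)
    M2 <- .dense_fwd(model, paste0("block", i, ".mlp.fc2"), G, bl$w2, bl$b2, CC)
    Hn <- H2 + M2
    if (keep_cache) {
      CC$blocks[[i]] <- list(ln1 = ln1[c("xh", "inv")], ln2 = ln2[c("xh", "inv")],
                             Q = Q, K = K, V = V, att = att, U = U)
    }
    H <- Hn
  }
  lnf <- .ln_fwd(H, prm$lnf_g, prm$lnf_b)
  Xcls <- if (identical(cfg$pool, "cls")) {
    lnf$y[cls_rows, , drop = FALSE]
  } else {
    (rowsum(lnf$y, rep(seq_len(B), each = Tt)) -
       lnf$y[cls_rows, , drop = FALSE]) / N
  }
  logits <- .dense_fwd(model, "head", Xcls, prm$head_w, prm$head_b, CC)
  mx <- logits[cbind(seq_len(B), max.col(logits))]
  E <- exp(logits - mx)
  probs <- E / rowSums(E)
  colnames(probs) <- c("other", "crystal")
  if (keep_cache) {
    CC$lnf <- lnf[c("xh", "inv")]
    CC$cls_rows <- cls_rows; CC$tok_rows <- tok_rows
    CC$B <- B; CC$Tt <- Tt
  }
  list(probs = probs, logits = logits, cache = CC)
}

# Backward pass from dlogits; returns gradients for the trainable arrays.
.vit_bwd <- function(model, CC, dlogits) {
  cfg <- model$cfg; prm <- model$params
  d <- cfg$hidden; h <- cfg$heads; dh <- d %/% h
  B <- CC$B; Tt <- CC$Tt; BT <- B * Tt
  isd <- 1 / sqrt(dh)
  GR <- new.env(parent = emptyenv())
  GR$adapters <- list()
  if (model$active_stage > 0L) {
    st <- model$adapters[[model$active_stage]]
    if (isTRUE(st$trainable)) {
      GR$adapters <- lapply(st$layers, function(ad) {
        list(A = ad$A * 0, B = ad$B * 0)
      })
    }
  }
  GR$head_w <- prm$head_w * 0
  GR$head_b <- prm$head_b * 0
  dXcls <- .dense_bwd(model, "head", dlogits, prm$head_w, CC, GR)
  dY <- matrix(0, BT, d)
  if (identical(cfg$pool, "cls")) {
    dY[CC$cls_rows, ] <- dXcls
  } else {
    N <- Tt - 1L
    dY[CC$tok_rows, ] <- dXcls[rep(seq_len(B), each = N), , drop = FALSE] / N
  }
  dH <- .ln_bwd(dY, CC$lnf, prm$lnf_g)
  for (i in rev(seq_len(cfg$depth))) {
    bl <- prm$blocks[[i]]
    bc <- CC$blocks[[i]]
    dG <- .dense_bwd(model, paste0("block", i, ".mlp.fc2"), dH, bl$w2, CC, GR)
    U <- bc$U
    dU <- dG * (stats::pnorm(U) + U * stats::dnorm(U))
    dXn2 <- .dense_bwd(model, paste0("block", i, ".mlp.fc1"), dU, bl$w1, CC, GR)
    dH2 <- dH + .ln_bwd(dXn2, bc$ln2, bl$ln2_g)
    dO <- .dense_bwd(model, paste0("block", i, ".attn.out"), dH2, bl$wo, CC, GR)
    dQ <- matrix(0, BT, d); dK <- matrix(0, BT, d); dV <- matrix(0, BT, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tt + 1L):(b * Tt)
      for (hh in seq_len(h)) {
        cc <- ((hh - 1L) * dh + 1L):(hh * dh)
        A <- bc$att[, , (b - 1L) * h + hh]
        dOh <- dO[rows, cc]
        Vh <- bc$V[rows, cc]
        dA <- tcrossprod(dOh, Vh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cc] <- (dS %*% bc$K[rows, cc]) * isd
        dK[rows, cc] <- crossprod(dS, bc$Q[rows, cc]) * isd
        dV[rows, cc] <- crossprod(A, dOh)
      }
    }
    if (cfg$qkv_fused) {
      dXn1 <- .dense_bwd(model, paste0("block", i, ".attn.qkv"),
                         cbind(dQ, dK, dV), bl$wqkv, CC, GR)
    } else {
      dXn1 <- .dense_bwd(model, paste0("block", i, ".attn.q"), dQ, bl$wq, CC, GR) +
        .dense_bwd(model, paste0("block", i, ".attn.k"), dK, bl$wk, CC, GR) +
        .dense_bwd(model, paste0("block", i, ".attn.v"), dV, bl$wv, CC, GR)
    }
    dH <- dH2 + .ln_bwd(dXn1, bc$ln1, bl$ln1_g)
  }
  # patch embedding adapter gradients, when such an adapter is configured
  if (!is.null(CC$X[["patch_embed"]])) {
    dtok <- dH[CC$tok_rows, , drop = FALSE]
    invisible(.dense_bwd(model, "patch_embed", dtok, prm$patch_w, CC, GR))
  }
  list(head_w = GR$head_w, head_b = GR$head_b, adapters = GR$adapters)
}

#' Forward pass: class probabilities for a batch of images
#'
#' @param model A `vit_classifier`.
#' @param x A list of standardized image matrices, a single matrix, or a
#'   3-d array with the batch on the first dimension.
#' @return A numeric matrix with one row per image and columns
#'   `other` and `crystal`; rows sum to one.
#' @export
vit_forward <- function(model, x) {
  xb <- .as_image_list(x)
  .vit_fwd(model, xb, keep_cache = FALSE)$probs
}

#' Crystal probability for a batch of images
#'
#' Convenience wrapper around [vit_forward()] returning only the crystal
#' column, processed in batches to bound memory.
#'
#' @inheritParams vit_forward
#' @param batch_size Number of images per forward batch.
#' @return Numeric vector of crystal probabilities in `[0, 1]`.
#' @export
vit_predict <- function(model, x, batch_size = 64L) {
  xb <- .as_image_list(x)
  out <- numeric(length(xb))
  i <- 1L
  while (i <= length(xb)) {
    j <- min(i + batch_size - 1L, length(xb))
    out[i:j] <- vit_forward(model, xb[i:j])[, "crystal"]
    i <- j + 1L
  }
  out
}

.as_image_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[1]), function(b) x[b, , ]))
  }
  rlang::abort("x must be a matrix, a list of matrices, or a 3-d array",
               class = "dropvision_error_shape")
}
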