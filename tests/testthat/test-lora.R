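test_that("a freshly injected model is exactly the base model", {
  xs <- random_images(4)
  for (fused in c(FALSE, TRUE)) for (pool in c("mean", "cls")) {
    base <- tiny_model(seed = 2, qkv_fused = fused, pool = pool)
    adapted <- lora_inject(base, lora_config(rank = 3), seed = 5)
    expect_identical(vit_forward(base, xs), vit_forward(adapted, xs))
  }
})

test_that("the adapted dense map matches hand computation in 1-d", {
  X <- matrix(3); W <- matrix(2); A <- matrix(1); B <- matrix(0.5)
  out <- adapted_dense(X, W, A = A, B = B, alpha = 20, rank = 25,
                       convention = "alpha_over_r")
  expect_equal(out[1, 1], 2 * 3 + 0.8 * 0.5 * 1 * 3)   # 7.2
  out2 <- adapted_dense(X, W, A = A, B = B, alpha = 20,
                        convention = "alpha_direct")
  expect_equal(out2[1, 1], 2 * 3 + 20 * 0.5 * 1 * 3)   # 36
  expect_error(adapted_dense(X, W, A = matrix(1, 1, 2), B = B),
               class = "dropvision_error_shape")
})

test_that("a rank-1 adapter on a 3->5 layer adds 8 trainable entries", {
  inv <- tibble::tibble(name = "x", fan_in = 3, fan_out = 5)
  cfg <- lora_config(rank = 1, target_layers = "x", train_head = FALSE)
  expect_equal(count_trainable(inv, cfg), 8)
  expect_equal(count_trainable(inv[0, ], cfg), 0)
})

test_that("count_trainable equals enumeration of injected adapter entries", {
  for (fused in c(FALSE, TRUE)) for (r in c(1, 3, 25)) {
    m <- tiny_model(seed = 1, qkv_fused = fused)
    cfg <- lora_config(rank = r)
    adapted <- lora_inject(m, cfg, seed = 2)
    st <- adapted$adapters[[1]]
    enum <- sum(vapply(st$layers, function(l) length(l$A) + length(l$B),
                       numeric(1))) +
      length(m$params$head_w) + length(m$params$head_b)
    expect_equal(count_trainable(dense_inventory(m), cfg), enum)
    expect_equal(param_count(adapted)$trainable, enum)
  }
})

test_that("merging folds adapters into the base weights exactly", {
  base <- tiny_model(seed = 7)
  fresh <- lora_inject(base, lora_config(rank = 4), seed = 8)
  merged0 <- lora_merge(fresh)
  expect_identical(merged0$params, base$params)  # B = 0: bit-identical
  # non-trivial adapters: outputs agree to 1e-5 sup-norm on 100 inputs
  pert <- perturb_adapters(fresh)
  merged <- lora_merge(pert)
  expect_length(merged$adapters, 0)
  xs <- random_images(100, seed = 31)
  expect_lt(max(abs(vit_forward(pert, xs) - vit_forward(merged, xs))), 1e-5)
  # merge then inject fresh adapters: still the merged model
  reinjected <- lora_inject(merged, lora_config(rank = 4), seed = 9)
  expect_equal(vit_forward(reinjected, xs), vit_forward(merged, xs))
})

test_that("successive injections stack stages and freeze earlier ones", {
  m <- lora_inject(tiny_model(), lora_config(rank = 2), seed = 1)
  m <- perturb_adapters(m)
  p1 <- vit_forward(m, random_images(3))
  m2 <- lora_inject(m, lora_config(rank = 2), seed = 2)
  expect_length(m2$adapters, 2)
  expect_false(m2$adapters[[1]]$trainable)
  expect_true(m2$adapters[[2]]$trainable)
  expect_equal(m2$active_stage, 2L)
  # the fresh stage starts at identity: stage-1 behaviour is preserved
  expect_identical(vit_forward(m2, random_images(3)), p1)
  expect_error(lora_inject(tiny_model(), lora_config(target_layers = character(0))),
               class = "dropvision_error_config")
})

test_that("adapter targeting can include the patch embedding and head", {
  m <- tiny_model()
  cfg <- lora_config(rank = 2, include_patch_embed = TRUE, include_head = TRUE)
  adapted <- lora_inject(m, cfg, seed = 3)
  expect_true(all(c("patch_embed", "head") %in%
                    names(adapted$adapters[[1]]$layers)))
  expect_false(adapted$head_trainable)  # an adapted head is not fully trained
  expect_identical(vit_forward(adapted, random_images(2)),
                   vit_forward(m, random_images(2)))
})

test_that("checkpoints round-trip bit-exactly with a JSON header", {
  m <- perturb_adapters(lora_inject(tiny_model(seed = 3), lora_config(rank = 2),
                                    seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_identical(load_checkpoint(path), m)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(hdr$format, "dropvision-checkpoint-1")
  expect_equal(hdr$stages[[1]]$rank, 2)
  expect_equal(hdr$stages[[1]]$convention, "alpha_over_r")
})

test_that("training moves only adapter and head arrays; base is bit-frozen", {
  gs <- separable_set(6, 12, size = 16, seed = 5)
  man <- gs$manifest; man$split <- "train"
  m <- lora_inject(tiny_model(seed = 6), lora_config(rank = 2), seed = 7)
  before <- m$params
  fr <- fit(m, man, gs$images,
            train_config(lr0 = 1e-3, batch_size = 4, epochs = 1,
                         modality = "visible", seed = 8))
  after <- fr$model$params
  expect_false(identical(fr$model$adapters, m$adapters))
  expect_false(identical(after$head_w, before$head_w))
  # every non-head base array is unchanged bit for bit
  before$head_w <- NULL; before$head_b <- NULL
  after$head_w <- NULL; after$head_b <- NULL
  expect_identical(after, before)
})
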