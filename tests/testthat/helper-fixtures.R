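# Shared fixtures: everything is generated in code at test time.

# a backbone small enough that forward/backward run in milliseconds
tiny_cfg <- function(qkv_fused = FALSE, pool = "mean") {
  vit_config(image_size = 16, patch_size = 8, depth = 2, hidden = 8,
             heads = 2, mlp_dim = 16, qkv_fused = qkv_fused, pool = pool)
}

tiny_model <- function(seed = 1, ...) vit_build(tiny_cfg(...), seed = seed)

random_images <- function(n, size = 16, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(stats::rnorm(size^2), size, size))
}

# give adapters non-zero B so both factors influence the forward pass
perturb_adapters <- function(model, sd = 0.05, seed = 9) {
  set.seed(seed)
  st <- model$active_stage
  for (nm in names(model$adapters[[st]]$layers)) {
    B <- model$adapters[[st]]$layers[[nm]]$B
    model$adapters[[st]]$layers[[nm]]$B <- matrix(stats::rnorm(length(B), 0, sd),
                                                  nrow(B), ncol(B))
  }
  model
}

# minimal manifest rows; n experiments, paired modalities optional
make_manifest <- function(n, modalities = c("visible", "uv"), raw_label = "clear",
                          plate = "P1", purpose = "screening", inspection = 1L) {
  rows <- expand.grid(e = seq_len(n), modality = modalities,
                      stringsAsFactors = FALSE)
  manifest(tibble::tibble(
    image_path = sprintf("%s_w%d_%s_i%d.png", plate, rows$e, rows$modality, inspection),
    modality = rows$modality,
    plate_id = plate,
    well = paste0("A", rows$e),
    drop = 1L,
    inspection_id = inspection,
    plate_purpose = purpose,
    raw_label = raw_label
  ))
}

# a small separable training set: clear drops vs single crystals
separable_set <- function(n_crystal = 20, n_other = 40, size = 16, seed = 3) {
  generate_plate(c(single_crystal = n_crystal, clear = n_other),
                 uv_only = 0, visible_only = 0, seed = seed, size = size)
}
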