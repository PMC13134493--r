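test_that("phenotype to binary mapping is total and correct", {
  expect_equal(phenotype_binary(c("microcrystals", "needles_clusters",
                                  "single_crystal")),
               rep("crystal", 3))
  expect_equal(phenotype_binary(c("clear", "precipitate", "phase_separation")),
               rep("other", 3))
  expect_error(phenotype_binary("sea_urchin"),
               class = "dropvision_error_phenotype")
})

test_that("a clear drop contains no foreground objects", {
  for (mod in c("visible", "uv")) {
    img <- render_drop(scene_spec("clear", seed = 4), mod)
    expect_equal(sum(attr(img, "object_mask") & attr(img, "drop_mask")), 0)
  }
})

test_that("rendering is byte-identical under a fixed seed and scene", {
  spec <- scene_spec("needles_clusters", occlusion_level = 0.3, seed = 77)
  expect_identical(render_drop(spec, "visible"), render_drop(spec, "visible"))
  expect_identical(render_drop(spec, "uv"), render_drop(spec, "uv"))
  # both modalities of one scene share the same geometry
  expect_identical(attr(render_drop(spec, "visible"), "crystal_mask"),
                   attr(render_drop(spec, "uv"), "crystal_mask"))
})

test_that("unknown phenotype or modality is rejected by name", {
  expect_error(scene_spec("blob"))
  expect_error(render_drop(scene_spec("clear"), "infrared"),
               class = "dropvision_error_modality")
  expect_error(scene_spec("clear", occlusion_level = 1.2),
               class = "dropvision_error_config")
})

test_that("a heavily occluded fluorescent crystal is UV-only detectable", {
  spec <- scene_spec("single_crystal", uv_fluorescent = TRUE,
                     occlusion_level = 0.9, contrast = 1, seed = 12)
  vis <- scene_contrast(render_drop(spec, "visible"))
  uv <- scene_contrast(render_drop(spec, "uv"))
  expect_lt(vis$delta, dropvision:::VISIBLE_DETECTABILITY_FLOOR)
  expect_gt(uv$snr, dropvision:::UV_SNR_CEILING)
})

test_that("generate_plate echoes requested counts and pairs every experiment", {
  gs <- generate_plate(c(single_crystal = 3, clear = 5), seed = 7)
  m <- gs$manifest
  expect_equal(length(unique(m$experiment_key)), 8)
  expect_equal(nrow(m), 16)
  expect_equal(length(gs$images), 16)
  expect_equal(sum(m$binary_label == "crystal" & m$modality == "visible"), 3)
  paired <- pair_modalities(m)
  expect_true(all(paired$pair_complete))
  # empty request is an empty set, not an error
  e <- generate_plate(c(clear = 0), seed = 1)
  expect_equal(nrow(e$manifest), 0)
  expect_error(generate_plate(c(clear = -1)), class = "dropvision_error_config")
})

test_that("seeds change pixel content but not the manifest", {
  g7 <- generate_plate(c(single_crystal = 2, precipitate = 2), seed = 7, size = 32)
  g8 <- generate_plate(c(single_crystal = 2, precipitate = 2), seed = 8, size = 32)
  expect_identical(as.data.frame(g7$manifest), as.data.frame(g8$manifest))
  expect_false(identical(g7$images, g8$images))
  expect_identical(generate_plate(c(single_crystal = 2, precipitate = 2),
                                  seed = 7, size = 32)$images,
                   g7$images)
})

test_that("complementarity fractions are realized exactly in the manifest", {
  gs <- generate_plate(c(single_crystal = 4, microcrystals = 3,
                         needles_clusters = 3, clear = 5),
                       uv_only = 0.5, visible_only = 0.2, seed = 1, size = 32)
  per_exp <- gs$manifest[gs$manifest$modality == "visible", ]
  expect_equal(sum(per_exp$detectability == "uv_only", na.rm = TRUE), 5)
  expect_equal(sum(per_exp$detectability == "visible_only", na.rm = TRUE), 2)
  expect_true(all(is.na(per_exp$detectability[per_exp$binary_label == "other"])))
  expect_error(generate_plate(c(single_crystal = 2), uv_only = 0.9,
                              visible_only = 0.9),
               class = "dropvision_error_config")
})

test_that("generated labels always equal the phenotype mapping", {
  gs <- generate_plate(c(clear = 3, precipitate = 3, phase_separation = 3,
                         microcrystals = 3, needles_clusters = 3,
                         single_crystal = 3), seed = 5, size = 32)
  expect_equal(gs$manifest$binary_label,
               phenotype_binary(gs$manifest$phenotype))
})

test_that("UV-only scenes have weaker visible than UV contrast (measured)", {
  n <- 100
  worse <- logical(n)
  set.seed(42)
  seeds <- sample.int(1e6, n)
  phens <- rep(c("single_crystal", "needles_clusters", "microcrystals"),
               length.out = n)
  for (i in seq_len(n)) {
    spec <- scene_spec(phens[i], uv_fluorescent = TRUE,
                       occlusion_level = runif(1, 0.88, 0.97),
                       contrast = runif(1, 0.8, 1), seed = seeds[i])
    vis <- scene_contrast(render_drop(spec, "visible"))
    uv <- scene_contrast(render_drop(spec, "uv"))
    worse[i] <- vis$delta < uv$delta
  }
  expect_gte(mean(worse), 0.95)
})
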