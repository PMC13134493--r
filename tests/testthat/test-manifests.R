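test_that("4-class consolidation applies the mapping and conserves rows", {
  m <- make_manifest(4, modalities = "visible")
  m$raw_label <- c("crystal", "clear", "precipitate", "other")
  out <- consolidate_four_to_two(m)
  expect_equal(out$binary_label, c("crystal", "other", "other", "other"))
  expect_equal(nrow(out), nrow(m))
  empty <- manifest(NULL)
  expect_equal(nrow(consolidate_four_to_two(empty)), 0)
})

test_that("unknown raw labels are rejected with the rows attached", {
  m <- make_manifest(3, modalities = "visible")
  m$raw_label <- c("crystal", "granular", "clear")
  err <- expect_error(consolidate_four_to_two(m),
                      class = "dropvision_error_unknown_label")
  expect_equal(nrow(err$rejected), 1)
  expect_equal(err$rejected$raw_label, "granular")
})

test_that("7-class user scores map to binary; unscored rows are reported", {
  m <- make_manifest(7, modalities = "visible")
  m$user_score <- c("clear", "denatured", "precipitate", "phase_separation",
                    "interesting", "microcrystals_clusters", "single_crystals")
  out <- map_user_scores(m)
  expect_equal(sum(out$binary_label == "crystal"), 2)
  expect_equal(sum(out$binary_label == "other"), 5)
  expect_equal(nrow(out), 7)
  m2 <- make_manifest(3, modalities = "visible")
  m2$user_score <- c("single_crystals", NA, "interesting")
  expect_warning(out2 <- map_user_scores(m2),
                 class = "dropvision_warning_unmapped")
  expect_equal(nrow(attr(out2, "unmapped")), 1)
  expect_true(is.na(out2$binary_label[2]))
})

test_that("modality pairing flags complete pairs and keeps singletons", {
  m <- make_manifest(3)
  solo <- make_manifest(1, modalities = "visible", plate = "P2")
  paired <- pair_modalities(dplyr::bind_rows(m, solo))
  expect_equal(count_pairs(paired), 3)
  expect_equal(paired$missing_modality[paired$plate_id == "P2"], "missing_uv")
  expect_false(any(paired$pair_complete[paired$plate_id == "P2"]))
  expect_equal(nrow(pair_modalities(manifest(NULL))), 0)
  # un-pairing then re-pairing reproduces the same groups
  again <- pair_modalities(paired[, setdiff(names(paired),
                                            c("pair_complete", "missing_modality"))])
  expect_equal(again$pair_complete, paired$pair_complete)
})

test_that("duplicate modality rows for one experiment are an error", {
  m <- make_manifest(2, modalities = "visible")
  dup <- m
  dup$image_path <- paste0("b_", dup$image_path)
  expect_error(pair_modalities(dplyr::bind_rows(m, dup)),
               class = "dropvision_error_duplicate_modality")
})

test_that("screening sampling drops optimization plates and keeps one inspection", {
  plates <- dplyr::bind_rows(
    make_manifest(2, plate = "S1", inspection = 1L),
    make_manifest(2, plate = "S1", inspection = 2L),
    make_manifest(2, plate = "S1", inspection = 3L),
    make_manifest(2, plate = "S2", inspection = 1L),
    make_manifest(2, plate = "S2", inspection = 2L),
    make_manifest(2, plate = "OPT", purpose = "optimization")
  )
  out <- sample_screening_inspections(plates, seed = 1)
  expect_false("OPT" %in% out$plate_id)
  per_plate <- tapply(out$inspection_id, out$plate_id,
                      function(x) length(unique(x)))
  expect_true(all(per_plate == 1))
  expect_identical(out, sample_screening_inspections(plates, seed = 1))
})

test_that("a plate whose only dual-modality inspection is second gets it", {
  dual2 <- dplyr::bind_rows(
    make_manifest(2, plate = "S1", inspection = 1L, modalities = "visible"),
    make_manifest(2, plate = "S1", inspection = 2L),
    make_manifest(2, plate = "S1", inspection = 3L, modalities = "visible")
  )
  out <- sample_screening_inspections(dual2, seed = 1)
  expect_equal(unique(out$inspection_id), 2L)
  # several dual sessions: the earliest wins deterministically
  dual23 <- dplyr::bind_rows(
    make_manifest(2, plate = "S1", inspection = 1L, modalities = "visible"),
    make_manifest(2, plate = "S1", inspection = 2L),
    make_manifest(2, plate = "S1", inspection = 3L)
  )
  expect_equal(unique(sample_screening_inspections(dual23, seed = 9)$inspection_id), 2L)
})

test_that("train and test splits may never share experiments", {
  m <- make_manifest(2)
  ok <- m
  ok$split <- ifelse(ok$well == "A1", "train", "test")  # split by experiment
  expect_silent(validate_manifest(manifest(ok[, setdiff(names(ok), "experiment_key")])))
  bad <- m
  bad$split <- ifelse(bad$modality == "visible", "train", "test")
  expect_error(manifest(bad[, setdiff(names(bad), "experiment_key")]),
               class = "dropvision_error_split")
})

test_that("dataset versions store recomputable class counts", {
  m <- make_manifest(6)
  m$binary_label <- rep(c("crystal", "other", "other"), 4)
  dv <- dataset_version(m, "v1")
  expect_equal(dv$n_images, 12)
  expect_silent(validate_dataset_version(dv))
  dv$class_counts$n[1] <- dv$class_counts$n[1] + 1
  expect_error(validate_dataset_version(dv), class = "dropvision_error_version")
})

test_that("manifests round-trip through CSV", {
  gs <- generate_plate(c(single_crystal = 2, clear = 2), seed = 3, size = 32)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(gs$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$experiment_key, gs$manifest$experiment_key)
  expect_equal(back$binary_label, gs$manifest$binary_label)
})
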