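# Tabular data model for image manifests: class consolidation, user-score
# mapping, modality pairing, screening-plate sampling and dataset
# versioning. A manifest is a tibble with a fixed column set; every image is
# one row, keyed by experiment (plate:well:drop:inspection) and modality.

MANIFEST_COLUMNS <- c("image_path", "modality", "plate_id", "well", "drop",
                      "inspection_id", "plate_purpose", "raw_label",
                      "binary_label", "crystal_type", "split",
                      "curator_label", "user_score", "model_prob",
                      "version_tag")

FOUR_TO_TWO <- c(crystal = "crystal", clear = "other",
                 precipitate = "other", other = "other")

USER_SCORES <- c("clear", "denatured", "precipitate", "phase_separation",
                 "interesting", "microcrystals_clusters", "single_crystals")

USER_TO_BINARY <- c(clear = "other", denatured = "other",
                    precipitate = "other", phase_separation = "other",
                    interesting = "other",
                    microcrystals_clusters = "crystal",
                    single_crystals = "crystal")

#' Construct and validate a manifest
#'
#' Fills missing optional columns with `NA`, derives the
#' `experiment_key` as `"plate:well:drop:inspection"`, and enforces the
#' manifest invariants: known modalities, no duplicate
#' (experiment_key, modality, image_path) triples, `model_prob` in `[0, 1]`
#' when present, and disjoint train/test splits by experiment.
#'
#' @param df A data frame with at least `image_path`, `modality`,
#'   `plate_id`, `well`, `drop`, `inspection_id`; or `NULL` for an empty
#'   manifest.
#' @return A tibble with the standard manifest columns plus
#'   `experiment_key` (and any extra truth columns carried through).
#' @export
manifest <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    out <- tibble::as_tibble(sapply(MANIFEST_COLUMNS, function(x) character(0),
                                    simplify = FALSE))
    out$drop <- integer(0); out$inspection_id <- integer(0)
    out$model_prob <- numeric(0)
    out$experiment_key <- character(0)
    return(out)
  }
  df <- tibble::as_tibble(df)
  need <- c("image_path", "modality", "plate_id", "well", "drop", "inspection_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("manifest is missing columns: ", paste(miss, collapse = ", ")),
                 class = "dropvision_error_manifest")
  }
  defaults <- list(plate_purpose = "screening", raw_label = NA_character_,
                   binary_label = NA_character_, crystal_type = NA_character_,
                   split = "unassigned", curator_label = NA_character_,
                   user_score = NA_character_, model_prob = NA_real_,
                   version_tag = NA_character_)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df$experiment_key <- paste(df$plate_id, df$well, df$drop, df$inspection_id,
                             sep = ":")
  validate_manifest(df)
  df
}

#' @rdname manifest
#' @param m A manifest tibble.
#' @export
validate_manifest <- function(m) {
  if (nrow(m) == 0L) return(invisible(m))
  if (!all(m$modality %in% c("visible", "uv"))) {
    rlang::abort("modality must be 'visible' or 'uv'",
                 class = "dropvision_error_manifest")
  }
  if (any(m$experiment_key == "" | is.na(m$experiment_key))) {
    rlang::abort("experiment_key must be non-empty",
                 class = "dropvision_error_manifest")
  }
  key3 <- paste(m$experiment_key, m$modality, m$image_path)
  if (anyDuplicated(key3)) {
    rlang::abort("duplicate (experiment_key, modality, image_path) rows",
                 class = "dropvision_error_manifest")
  }
  pr <- m$model_prob
  if (any(!is.na(pr) & (pr < 0 | pr > 1))) {
    rlang::abort("model_prob must lie in [0, 1]",
                 class = "dropvision_error_manifest")
  }
  tr <- unique(m$experiment_key[m$split == "train"])
  te <- unique(m$experiment_key[m$split == "test"])
  if (length(intersect(tr, te))) {
    rlang::abort("train and test splits share experiment keys",
                 class = "dropvision_error_split")
  }
  invisible(m)
}

#' Read / write manifests as CSV
#'
#' CSV with a one-line header and the documented column order, UTF-8.
#'
#' @param m A manifest tibble.
#' @param path File path.
#' @return `read_manifest` returns a validated manifest;
#'   `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(m, path) {
  ord <- c(intersect(MANIFEST_COLUMNS, names(m)),
           setdiff(names(m), c(MANIFEST_COLUMNS, "experiment_key")))
  readr::write_csv(m[, ord], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  manifest(df)
}

#' Consolidate 4-class labels to the binary scheme
#'
#' The four-way raw labels collapse to two: `crystal -> crystal`;
#' `clear`, `precipitate`, `other -> other`. The row count is unchanged.
#' Rows with a raw label outside the 4-class set are rejected: the error
#' condition carries them in its `rejected` field.
#'
#' @param m A manifest whose rows carry 4-class `raw_label`s.
#' @return The manifest with `binary_label` set on every row.
#' @export
consolidate_four_to_two <- function(m) {
  if (nrow(m) == 0L) return(m)
  known <- m$raw_label %in% names(FOUR_TO_TWO)
  if (!all(known)) {
    rlang::abort("rows with unknown 4-class raw_label rejected",
                 class = "dropvision_error_unknown_label",
                 rejected = m[!known, , drop = FALSE])
  }
  m$binary_label <- unname(FOUR_TO_TWO[m$raw_label])
  m
}

#' Map 7-class user scores to the binary scheme
#'
#' The two user scores denoting crystalline material
#' (`microcrystals_clusters`, `single_crystals`) map to `"crystal"`; the
#' remaining five (`clear`, `denatured`, `precipitate`, `phase_separation`,
#' `interesting`) map to `"other"`. Unscored rows are left unmapped and
#' reported via a warning and the `unmapped` attribute.
#'
#' @param m A manifest whose rows carry `user_score`s.
#' @return The manifest with `binary_label` filled from `user_score`.
#' @export
map_user_scores <- function(m) {
  if (nrow(m) == 0L) return(m)
  bad <- !is.na(m$user_score) & !m$user_score %in% USER_SCORES
  if (any(bad)) {
    rlang::abort("rows with unknown user scores rejected",
                 class = "dropvision_error_unknown_label",
                 rejected = m[bad, , drop = FALSE])
  }
  mapped <- !is.na(m$user_score)
  m$binary_label[mapped] <- unname(USER_TO_BINARY[m$user_score[mapped]])
  if (any(!mapped)) {
    attr(m, "unmapped") <- m[!mapped, , drop = FALSE]
    rlang::warn(paste0(sum(!mapped), " unscored rows left unmapped"),
                class = "dropvision_warning_unmapped")
  }
  m
}

#' Pair visible and UV images by experiment
#'
#' Groups rows by `experiment_key` and flags complete visible/UV pairs.
#' Singletons are retained with a `missing_modality` flag rather than
#' dropped, so downstream fusion can fall back to a single modality. Two
#' images of the same modality for one experiment are an error.
#'
#' @param m A manifest.
#' @return The manifest with logical `pair_complete` and character
#'   `missing_modality` columns; the number of complete pairs is in the
#'   `n_pairs` attribute (also via [count_pairs()]).
#' @export
pair_modalities <- function(m) {
  if (nrow(m) == 0L) {
    m$pair_complete <- logical(0); m$missing_modality <- character(0)
    attr(m, "n_pairs") <- 0L
    return(m)
  }
  km <- paste(m$experiment_key, m$modality)
  if (anyDuplicated(km)) {
    rlang::abort("duplicate modality for an experiment",
                 class = "dropvision_error_duplicate_modality",
                 keys = unique(m$experiment_key[duplicated(km)]))
  }
  has <- m %>%
    dplyr::distinct(.data$experiment_key, .data$modality) %>%
    dplyr::group_by(.data$experiment_key) %>%
    dplyr::summarise(has_vis = "visible" %in% .data$modality,
                     has_uv = "uv" %in% .data$modality, .groups = "drop")
  m <- dplyr::left_join(m, has, by = "experiment_key")
  m$pair_complete <- m$has_vis & m$has_uv
  m$missing_modality <- dplyr::case_when(
    m$pair_complete ~ NA_character_,
    !m$has_uv ~ "missing_uv",
    TRUE ~ "missing_visible"
  )
  m$has_vis <- NULL; m$has_uv <- NULL
  attr(m, "n_pairs") <- length(unique(m$experiment_key[m$pair_complete]))
  m
}

#' @rdname pair_modalities
#' @param paired A manifest processed by [pair_modalities()].
#' @return `count_pairs` returns the number of complete pairs.
#' @export
count_pairs <- function(paired) {
  length(unique(paired$experiment_key[paired$pair_complete]))
}

#' Sample one inspection per screening plate
#'
#' Applies the screening-set sampling rules: optimization plates are
#' excluded (to avoid over-representing particular crystal forms), and
#' exactly one imaging session is kept per retained plate so no experiment
#' appears at two time points. Sessions with both visible and UV images are
#' preferred; among several dual-modality sessions the earliest
#' `inspection_id` wins (deterministic tie-break), and plates without any
#' dual session fall back to a seeded random choice.
#'
#' @param plates A manifest covering one or more plates and inspections.
#' @param seed Integer seed for the random fallback choice.
#' @return The manifest restricted to the selected inspections.
#' @export
sample_screening_inspections <- function(plates, seed = 1L) {
  if (nrow(plates) == 0L) return(plates)
  scr <- plates[plates$plate_purpose == "screening", , drop = FALSE]
  if (nrow(scr) == 0L) return(scr)
  insp <- scr %>%
    dplyr::distinct(.data$plate_id, .data$inspection_id, .data$modality) %>%
    dplyr::group_by(.data$plate_id, .data$inspection_id) %>%
    dplyr::summarise(dual = all(c("visible", "uv") %in% .data$modality),
                     .groups = "drop")
  set.seed(seed)
  pick <- insp %>%
    dplyr::arrange(.data$plate_id, .data$inspection_id) %>%
    dplyr::group_by(.data$plate_id) %>%
    dplyr::summarise(inspection_id = if (any(.data$dual)) {
      min(.data$inspection_id[.data$dual])
    } else {
      .data$inspection_id[sample.int(dplyr::n(), 1L)]
    }, .groups = "drop")
  dplyr::semi_join(scr, pick, by = c("plate_id", "inspection_id"))
}

#' Freeze a manifest as a versioned dataset
#'
#' A dataset version records the manifest, per-modality class counts, the
#' parent version tag and (optionally) the curation accounting report. The
#' stored class counts must always be recomputable from the rows;
#' `validate_dataset_version()` asserts that.
#'
#' @param m A manifest with binary labels.
#' @param version_tag Version identifier string.
#' @param parent Parent version tag, or `NULL` for a root version.
#' @param accounting Optional accounting report (see
#'   [assemble_version()]).
#' @return An object of class `dataset_version`.
#' @export
dataset_version <- function(m, version_tag, parent = NULL, accounting = NULL) {
  validate_manifest(m)
  counts <- m %>%
    dplyr::count(.data$modality, .data$binary_label, name = "n") %>%
    dplyr::arrange(.data$modality, .data$binary_label)
  dv <- structure(list(manifest = m, class_counts = counts,
                       n_images = nrow(m), version_tag = version_tag,
                       parent_version = parent, accounting = accounting),
                  class = "dataset_version")
  validate_dataset_version(dv)
}

#' @rdname dataset_version
#' @param dv A `dataset_version`.
#' @export
validate_dataset_version <- function(dv) {
  recount <- dv$manifest %>%
    dplyr::count(.data$modality, .data$binary_label, name = "n") %>%
    dplyr::arrange(.data$modality, .data$binary_label)
  if (!identical(as.data.frame(recount), as.data.frame(dv$class_counts)) ||
      dv$n_images != nrow(dv$manifest)) {
    rlang::abort("stored class counts do not match the manifest rows",
                 class = "dropvision_error_version")
  }
  invisible(dv)
}

#' @export
print.dataset_version <- function(x, ...) {
  cat("<dataset_version ", x$version_tag, "> ", x$n_images, " images\n", sep = "")
  print(x$class_counts)
  invisible(x)
}
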