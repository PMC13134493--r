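# Procedural generator for paired visible/UV crystallization-drop
# micrographs with ground-truth manifests.
#
# A scene is realized once (seeded geometry: drop, crystals, textures) and
# rendered twice, under visible and UV illumination. Crystalline objects are
# convex polygons, thin elongated needles radiating in clusters, or fields
# of tiny microcrystal diamonds; amorphous precipitate is a band-limited
# blob field; phase separation is a set of circular droplets. Under UV,
# only fluorescent (protein) objects emit; amorphous precipitate fluoresces
# at a configurable nuisance intensity, reproducing the classic UV
# false-positive failure mode. Occlusion buries crystals under a drop-wide
# precipitate veil that suppresses their visible contrast but not their
# fluorescence, which is how UV-only-detectable scenes arise; salt-like
# (non-fluorescent) crystals are visible-only-detectable.
#
# The rendering is a morphological stand-in, not a reproduction of any
# particular imaging system: no published description of the source imagery
# (resolution, bit depth, illumination) exists to reproduce.

PHENOTYPES <- c("clear", "precipitate", "phase_separation",
                "microcrystals", "needles_clusters", "single_crystal")
CRYSTAL_PHENOTYPES <- c("microcrystals", "needles_clusters", "single_crystal")

# Stated detectability limits of the generator, used by its own acceptance
# checks: a crystal whose visible foreground-background intensity difference
# (on the [0,1] scale) falls below the floor counts as undetectable under
# visible light; a UV signal-to-background ratio above the ceiling counts as
# unambiguous under UV.
VISIBLE_DETECTABILITY_FLOOR <- 0.08
UV_SNR_CEILING <- 5

#' Phenotype to binary label mapping
#'
#' Microcrystals, needles/clusters and single crystals map to `"crystal"`;
#' clear, precipitate and phase separation map to `"other"`. The mapping is
#' total over the six phenotypes.
#'
#' @param name Character vector of phenotype names.
#' @return Character vector of `"crystal"`/`"other"`.
#' @export
phenotype_binary <- function(name) {
  name <- as.character(name)
  bad <- setdiff(unique(name), PHENOTYPES)
  if (length(bad)) {
    rlang::abort(paste0("unknown phenotype: ", paste(bad, collapse = ", ")),
                 class = "dropvision_error_phenotype")
  }
  ifelse(name %in% CRYSTAL_PHENOTYPES, "crystal", "other")
}

#' Scene specification
#'
#' @param phenotype One of `"clear"`, `"precipitate"`, `"phase_separation"`,
#'   `"microcrystals"`, `"needles_clusters"`, `"single_crystal"`.
#' @param uv_fluorescent Does the crystalline object fluoresce under UV
#'   (protein crystal) or not (salt-like object)?
#' @param occlusion_level Fraction in `[0, 1]`: how strongly a precipitate
#'   veil buries the crystals in the visible rendering. Fluorescence is not
#'   blocked by the veil.
#' @param contrast Fraction in `[0, 1]` scaling object intensity.
#' @param drop_radius_px Drop radius in pixels (default 0.42 x size).
#' @param size Image side length in pixels (default 64; configurable up to
#'   518).
#' @param seed Integer seed; a fixed seed yields byte-identical renderings.
#' @param uv_nuisance Fluorescence intensity of amorphous precipitate
#'   relative to a protein crystal (default 0.5).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(phenotype, uv_fluorescent = TRUE, occlusion_level = 0,
                       contrast = 1, drop_radius_px = NULL, size = 64L,
                       seed = 1L, uv_nuisance = 0.5) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  if (occlusion_level < 0 || occlusion_level > 1 || contrast < 0 || contrast > 1) {
    rlang::abort("occlusion_level and contrast must lie in [0, 1]",
                 class = "dropvision_error_config")
  }
  size <- as.integer(size)
  structure(list(phenotype = phenotype, uv_fluorescent = isTRUE(uv_fluorescent),
                 occlusion_level = occlusion_level, contrast = contrast,
                 drop_radius_px = drop_radius_px %||% round(0.42 * size),
                 size = size, seed = as.integer(seed),
                 uv_nuisance = uv_nuisance),
            class = "scene_spec")
}

# sum-of-Gaussian-bumps field, normalized to peak 1; the band-limited
# texture used for precipitate and for the occlusion veil
.bump_field <- function(S, xs, ys, centers, sigmas, amps) {
  f <- matrix(0, S, S)
  for (k in seq_len(nrow(centers))) {
    d2 <- (xs - centers[k, 1])^2 + (ys - centers[k, 2])^2
    f <- f + amps[k] * exp(-d2 / (2 * sigmas[k]^2))
  }
  if (max(f) > 0) f <- f / max(f)
  f
}

.convex_polygon_mask <- function(xs, ys, cx, cy, radii, angles) {
  px <- cx + radii * cos(angles)
  py <- cy + radii * sin(angles)
  hull <- grDevices::chull(px, py)
  px <- px[hull]; py <- py[hull]
  k <- length(px)
  # orient edge tests so the hull centroid (an interior point) passes them
  mx <- mean(px); my <- mean(py)
  mask <- matrix(TRUE, nrow(xs), ncol(xs))
  for (e in seq_len(k)) {
    x1 <- px[e]; y1 <- py[e]
    x2 <- px[e %% k + 1]; y2 <- py[e %% k + 1]
    side <- sign((x2 - x1) * (my - y1) - (y2 - y1) * (mx - x1))
    mask <- mask & (side * ((x2 - x1) * (ys - y1) - (y2 - y1) * (xs - x1)) >= 0)
  }
  mask
}

.rect_mask <- function(xs, ys, cx, cy, len, wid, theta) {
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

# realize the seeded geometry of a scene, independent of modality
.realize_scene <- function(spec) {
  set.seed(spec$seed)
  S <- spec$size; R <- spec$drop_radius_px
  xs <- matrix(seq_len(S), S, S)          # row coordinate
  ys <- matrix(seq_len(S), S, S, byrow = TRUE)
  cx <- (S + 1) / 2 + stats::runif(1, -1, 1)
  cy <- (S + 1) / 2 + stats::runif(1, -1, 1)
  d2 <- (xs - cx)^2 + (ys - cy)^2
  drop_mask <- d2 <= R^2
  rim <- abs(sqrt(d2) - R) <= 1
  inner <- function(frac) {
    list(x = cx + stats::runif(1, -frac, frac) * R,
         y = cy + stats::runif(1, -frac, frac) * R)
  }
  crystal_mask <- matrix(FALSE, S, S)
  precip_field <- matrix(0, S, S)
  phase_ring <- matrix(0, S, S)     # smooth rim profile: liquid interfaces
  phase_int <- matrix(FALSE, S, S)  # are defocused, unlike crystal facets
  ph <- spec$phenotype
  if (ph == "single_crystal") {
    p <- inner(0.35)
    k <- sample(4:7, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    rad <- stats::runif(k, 0.12, 0.28) * S / 2
    crystal_mask <- .convex_polygon_mask(xs, ys, p$x, p$y, rad, ang)
  } else if (ph == "needles_clusters") {
    for (cl in seq_len(sample(1:3, 1))) {
      p <- inner(0.45)
      for (nd in seq_len(sample(4:9, 1))) {
        theta <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.15, 0.35) * S
        crystal_mask <- crystal_mask |
          .rect_mask(xs, ys, p$x, p$y, len, stats::runif(1, 1, 2), theta)
      }
    }
  } else if (ph == "microcrystals") {
    for (mc in seq_len(sample(12:30, 1))) {
      p <- inner(0.6)
      sz <- stats::runif(1, 0.8, 2)
      crystal_mask <- crystal_mask |
        (abs(xs - p$x) + abs(ys - p$y) <= sz)
    }
  } else if (ph == "precipitate") {
    nb <- sample(25:45, 1)
    env <- inner(0.3)
    centers <- cbind(env$x + stats::rnorm(nb, 0, 0.35 * R),
                     env$y + stats::rnorm(nb, 0, 0.35 * R))
    precip_field <- .bump_field(S, xs, ys, centers,
                                stats::runif(nb, 1.5, 4), stats::runif(nb, 0.5, 1))
  } else if (ph == "phase_separation") {
    for (dr in seq_len(sample(3:7, 1))) {
      p <- inner(0.55)
      r <- stats::runif(1, 0.06, 0.15) * S
      dd <- sqrt((xs - p$x)^2 + (ys - p$y)^2)
      phase_ring <- pmax(phase_ring, exp(-(dd - r)^2 / (2 * 1.6^2)))
      phase_int <- phase_int | (dd < r - 1.6)
    }
  }
  crystal_mask <- crystal_mask & drop_mask
  precip_field <- precip_field * drop_mask
  phase_ring <- phase_ring * drop_mask
  phase_int <- phase_int & drop_mask
  # occlusion veil: a drop-wide precipitate layer (also used in UV where it
  # fluoresces at the nuisance intensity)
  veil <- matrix(0, S, S)
  if (spec$occlusion_level > 0 && any(crystal_mask)) {
    nb <- 40
    centers <- cbind(stats::runif(nb, cx - R, cx + R),
                     stats::runif(nb, cy - R, cy + R))
    veil <- .bump_field(S, xs, ys, centers,
                        stats::runif(nb, 2, 5), stats::runif(nb, 0.5, 1)) * drop_mask
  }
  list(S = S, R = R, cx = cx, cy = cy, d2 = d2, drop_mask = drop_mask,
       rim = rim, crystal_mask = crystal_mask, precip_field = precip_field,
       phase_ring = phase_ring, phase_int = phase_int, veil = veil)
}

#' Render one modality of a scene
#'
#' The same `scene_spec` (same seed) yields the same underlying geometry for
#' both modalities, so a visible/UV pair depicts one experiment. The visible
#' rendering shows the drop boundary, vignetted interior, phenotype texture
#' and the occlusion veil; the UV rendering shows fluorescence only from
#' fluorescent objects, plus the precipitate nuisance fluorescence.
#'
#' @param spec A [scene_spec()].
#' @param modality `"visible"` or `"uv"`.
#' @return An 8-bit grayscale image as an integer matrix in `[0, 255]` with
#'   attributes `drop_mask`, `object_mask`, `crystal_mask`, `phenotype` and
#'   `modality`.
#' @export
render_drop <- function(spec, modality = c("visible", "uv")) {
  if (!inherits(spec, "scene_spec")) {
    rlang::abort("spec must be a scene_spec", class = "dropvision_error_config")
  }
  if (!is.character(modality) || !all(modality %in% c("visible", "uv"))) {
    rlang::abort(paste0("unknown modality: ", paste(modality, collapse = ",")),
                 class = "dropvision_error_modality")
  }
  modality <- match.arg(modality)
  g <- .realize_scene(spec)
  S <- g$S
  if (modality == "visible") {
    img <- matrix(0.06, S, S)
    vign <- 1 - 0.5 * pmin(g$d2 / g$R^2, 1)
    img[g$drop_mask] <- 0.12 + 0.22 * vign[g$drop_mask]
    img[g$rim] <- 0.55
    img <- img + 0.30 * spec$contrast * g$precip_field
    img <- img + 0.25 * spec$contrast * g$phase_ring
    img[g$phase_int] <- img[g$phase_int] - 0.05
    a_vis <- 0.55 * spec$contrast * (1 - spec$occlusion_level)
    img[g$crystal_mask] <- img[g$crystal_mask] + a_vis
    img <- img + 0.28 * spec$occlusion_level * g$veil
    set.seed(spec$seed + 11L)
    img <- img + matrix(stats::rnorm(S * S, 0, 0.02), S, S)
  } else {
    img <- matrix(0.04, S, S)
    a_uv <- if (spec$uv_fluorescent) 0.80 * spec$contrast else 0.02
    img[g$crystal_mask] <- img[g$crystal_mask] + a_uv
    img <- img + 0.80 * spec$uv_nuisance * spec$contrast * g$precip_field
    img <- img + 0.30 * spec$uv_nuisance * spec$occlusion_level * g$veil
    set.seed(spec$seed + 23L)
    img <- img + matrix(stats::rnorm(S * S, 0, 0.015), S, S)
  }
  out <- matrix(as.integer(round(pmin(pmax(img, 0), 1) * 255)), S, S)
  attr(out, "drop_mask") <- g$drop_mask
  attr(out, "object_mask") <- g$crystal_mask | (g$precip_field > 0.35) |
    (g$phase_ring > 0.35) | g$phase_int
  attr(out, "crystal_mask") <- g$crystal_mask
  attr(out, "phenotype") <- spec$phenotype
  attr(out, "modality") <- modality
  out
}

#' Foreground contrast statistics of a rendered scene
#'
#' Measures how distinct the crystalline foreground is from the in-drop
#' background: `delta` is the mean foreground minus mean background
#' intensity on the `[0, 1]` scale, and `snr` is `delta` divided by the
#' background standard deviation. The generator's stated limits are
#' `VISIBLE_DETECTABILITY_FLOOR` (delta = 0.08) below which a visible
#' crystal counts as undetectable, and `UV_SNR_CEILING` (snr = 5) above
#' which a UV signal counts as unambiguous.
#'
#' @param img A rendered image from [render_drop()] (attributes intact), or
#'   any matrix if `mask` and `background` are supplied.
#' @param mask Logical foreground mask; default the image's `crystal_mask`.
#' @param background Logical background mask; default the drop interior
#'   minus all objects.
#' @return List with elements `delta` and `snr`.
#' @export
scene_contrast <- function(img, mask = attr(img, "crystal_mask"),
                           background = NULL) {
  if (is.null(background)) {
    background <- attr(img, "drop_mask") & !attr(img, "object_mask")
  }
  if (is.null(mask) || !any(mask) || !any(background)) {
    return(list(delta = NA_real_, snr = NA_real_))
  }
  v <- img / 255
  delta <- mean(v[mask]) - mean(v[background])
  list(delta = delta, snr = delta / stats::sd(v[background]))
}

#' Generate a plate of paired visible/UV experiments with a truth manifest
#'
#' Renders `sum(counts)` experiments (one visible and one UV image each) and
#' returns the images together with a ground-truth manifest. A stated
#' fraction of the crystal-bearing scenes is made UV-only detectable
#' (fluorescent crystals buried under a heavy precipitate veil) and another
#' fraction visible-only detectable (non-fluorescent, salt-like crystals);
#' assignment is deterministic round-robin over the crystal scenes, so
#' manifests are identical across seeds while pixel content varies.
#'
#' @param counts Named vector of experiments per phenotype (names from
#'   `phenotype_binary()`'s domain; counts >= 0). All-zero counts yield an
#'   empty set.
#' @param uv_only,visible_only Fractions in `[0, 1]` of crystal scenes made
#'   detectable in only one modality (defaults 0.2 / 0.2).
#' @param seed Integer master seed; per-scene seeds are drawn from it.
#' @param size Image side length in pixels.
#' @param uv_nuisance Precipitate fluorescence level, see [scene_spec()].
#' @param plate_prefix Prefix for synthetic plate identifiers.
#' @return An object of class `generated_set`: a list with `images` (named
#'   list of integer matrices keyed by `image_path`) and `manifest` (truth
#'   manifest including `phenotype` and `detectability` columns).
#' @export
generate_plate <- function(counts, uv_only = 0.2, visible_only = 0.2,
                           seed = 1L, size = 64L, uv_nuisance = 0.5,
                           plate_prefix = "SYNP") {
  counts <- unlist(counts)
  bad <- setdiff(names(counts), PHENOTYPES)
  if (length(bad)) {
    rlang::abort(paste0("unknown phenotype: ", paste(bad, collapse = ", ")),
                 class = "dropvision_error_phenotype")
  }
  if (any(counts < 0)) {
    rlang::abort("counts must be non-negative", class = "dropvision_error_config")
  }
  if (uv_only < 0 || uv_only > 1 || visible_only < 0 || visible_only > 1) {
    rlang::abort("complementarity fractions must lie in [0, 1]",
                 class = "dropvision_error_config")
  }
  phen <- rep(names(counts), counts)
  n <- length(phen)
  detect <- rep(NA_character_, n)
  cr <- which(phen %in% CRYSTAL_PHENOTYPES)
  detect[cr] <- "both"
  n_uv <- round(uv_only * length(cr))
  n_vo <- round(visible_only * length(cr))
  if (n_uv + n_vo > length(cr)) {
    rlang::abort("complementarity fractions exceed the crystal scene count",
                 class = "dropvision_error_config")
  }
  if (length(cr)) {
    # round-robin across phenotype groups so single-modality scenes are
    # spread over all crystal types
    within <- stats::ave(seq_along(cr), phen[cr], FUN = seq_along)
    ord <- cr[order(within, phen[cr])]
    if (n_uv > 0) detect[ord[seq_len(n_uv)]] <- "uv_only"
    if (n_vo > 0) detect[ord[n_uv + seq_len(n_vo)]] <- "visible_only"
  }
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))
  images <- list()
  rows <- vector("list", n)
  for (e in seq_len(n)) {
    plate <- sprintf("%s%02d", plate_prefix, (e - 1L) %/% 96L + 1L)
    wi <- (e - 1L) %% 96L
    well <- paste0(LETTERS[wi %/% 12L + 1L], wi %% 12L + 1L)
    dt <- detect[e]
    if (is.na(dt)) {              # non-crystal scene
      occl <- 0; contr <- stats::runif(1, 0.7, 1); fluo <- TRUE
    } else if (dt == "both") {
      occl <- stats::runif(1, 0, 0.15); contr <- stats::runif(1, 0.75, 1); fluo <- TRUE
    } else if (dt == "uv_only") {
      occl <- stats::runif(1, 0.88, 0.97); contr <- stats::runif(1, 0.8, 1); fluo <- TRUE
    } else {                      # visible_only: salt-like crystal
      occl <- stats::runif(1, 0, 0.1); contr <- stats::runif(1, 0.75, 1); fluo <- FALSE
    }
    spec <- scene_spec(phen[e], uv_fluorescent = fluo, occlusion_level = occl,
                       contrast = contr, size = size, seed = scene_seeds[e],
                       uv_nuisance = uv_nuisance)
    for (mod in c("visible", "uv")) {
      path <- sprintf("%s_%s_1_%s.png", plate, well, mod)
      images[[path]] <- render_drop(spec, mod)
    }
    raw4 <- switch(phen[e], clear = "clear", precipitate = "precipitate",
                   phase_separation = "other", "crystal")
    rows[[e]] <- tibble::tibble(
      image_path = sprintf("%s_%s_1_%s.png", plate, well, c("visible", "uv")),
      modality = c("visible", "uv"),
      plate_id = plate, well = well, drop = 1L, inspection_id = 1L,
      plate_purpose = "screening",
      raw_label = raw4,
      binary_label = phenotype_binary(phen[e]),
      crystal_type = if (phen[e] %in% CRYSTAL_PHENOTYPES) phen[e] else NA_character_,
      phenotype = phen[e],
      detectability = detect[e],
      uv_fluorescent = fluo
    )
  }
  man <- if (n > 0) manifest(dplyr::bind_rows(rows)) else manifest(NULL)
  structure(list(images = images, manifest = man,
                 params = list(counts = counts, uv_only = uv_only,
                               visible_only = visible_only, seed = seed,
                               size = size, uv_nuisance = uv_nuisance)),
            class = "generated_set")
}

#' Write a generated set to disk
#'
#' Writes each image as an 8-bit grayscale PNG and the truth manifest as
#' `manifest.csv` in `dir`.
#'
#' @param gs A `generated_set` from [generate_plate()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_generated_set <- function(gs, dir) {
  stopifnot(inherits(gs, "generated_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (path in names(gs$images)) {
    png::writePNG(gs$images[[path]] / 255, file.path(dir, path))
  }
  write_manifest(gs$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}
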