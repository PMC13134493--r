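# Standardization of micrographs to the model input contract: grayscale,
# fixed size, mean/sd normalization; flip-only augmentation (crops could cut
# crystals, and shape transforms would distort their characteristic
# geometry, so neither is ever applied).

#' Preprocessing configuration
#'
#' @param target_size Output side length in pixels (default 64 for the desk
#'   preset; 518 matches the base-scale backbone contract). Must divide by
#'   the backbone patch size; this is checked at training time.
#' @param norm_mean,norm_sd Normalization constants applied as
#'   `(x - mean) / sd` after grayscale conversion and resizing, on the
#'   `[0, 1]` intensity scale. `NULL` means identity at standardization time;
#'   [fit()] fills them with the training-set mean and standard deviation and
#'   stores the resolved values on the model.
#' @param augment_flips Apply random horizontal/vertical flips in training.
#' @param interpolation Resampling filter, recorded for reproducibility;
#'   only `"bilinear"` is implemented (with antialiasing on downscale).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 64L, norm_mean = NULL,
                              norm_sd = NULL, augment_flips = TRUE,
                              interpolation = "bilinear") {
  target_size <- as.integer(target_size)
  if (is.na(target_size) || target_size <= 0L) {
    rlang::abort("target_size must be a positive integer",
                 class = "dropvision_error_config")
  }
  if (!identical(interpolation, "bilinear")) {
    rlang::abort("only bilinear interpolation is implemented",
                 class = "dropvision_error_config")
  }
  structure(list(target_size = target_size, norm_mean = norm_mean,
                 norm_sd = norm_sd, augment_flips = isTRUE(augment_flips),
                 interpolation = interpolation),
            class = "preprocess_config")
}

#' Standardize an image to the model input contract
#'
#' Accepts 8- or 16-bit, single-channel or RGB input (a matrix, or an array
#' with a trailing channel dimension). The image is rescaled to `[0, 1]`,
#' converted to grayscale with fixed luma weights 0.299/0.587/0.114, resized
#' to `target_size` with bilinear interpolation (antialiased on downscale),
#' and normalized as `(x - mean) / sd` when constants are configured.
#'
#' @param image Numeric matrix or 3-d array (rows x cols x channels). Values
#'   may be on the `[0, 1]`, 8-bit or 16-bit scale; the scale is inferred
#'   from the value range.
#' @param cfg A [preprocess_config()].
#' @return A `target_size` x `target_size` numeric matrix.
#' @export
standardize <- function(image, cfg = preprocess_config()) {
  if (length(image) == 0L || is.null(dim(image))) {
    rlang::abort("zero-sized or dimensionless image", class = "dropvision_error_shape")
  }
  x <- image
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1]
    } else if (dim(x)[3] >= 3L) {
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      rlang::abort("images must have 1 or 3 channels", class = "dropvision_error_shape")
    }
  }
  x <- x * 1.0  # drop integer storage
  mx <- max(x)
  if (mx > 255.5) x <- x / 65535 else if (mx > 1.5) x <- x / 255
  if (nrow(x) != cfg$target_size || ncol(x) != cfg$target_size) {
    x <- EBImage::resize(x, w = cfg$target_size, h = cfg$target_size,
                         filter = "bilinear",
                         antialias = cfg$target_size < max(dim(x)))
    x <- matrix(as.numeric(x), cfg$target_size, cfg$target_size)
  }
  if (!is.null(cfg$norm_mean) && !is.null(cfg$norm_sd)) {
    x <- (x - cfg$norm_mean) / cfg$norm_sd
  }
  x
}

#' Dataset normalization constants
#'
#' Global mean and standard deviation over all pixels of a set of
#' standardized (grayscale, `[0, 1]`) images.
#'
#' @param images List of image matrices.
#' @return List with elements `mean` and `sd`.
#' @export
compute_normalization <- function(images) {
  v <- unlist(images, use.names = FALSE)
  list(mean = mean(v), sd = stats::sd(v))
}

#' Flip-only augmentation
#'
#' Flips the array horizontally and/or vertically, each with probability
#' 0.5, drawn independently. No crops, rotations or scale changes are ever
#' applied. The pixel multiset, shape and label are preserved.
#'
#' @param x Standardized image matrix.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param p Per-axis flip probability.
#' @return The (possibly flipped) matrix.
#' @export
augment <- function(x, seed = NULL, p = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  r <- stats::runif(2)
  if (r[1] < p) x <- x[, rev(seq_len(ncol(x)))]
  if (r[2] < p) x <- x[rev(seq_len(nrow(x))), ]
  x
}
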