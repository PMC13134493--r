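# Lab-in-the-Loop engine: compare model scores against user scores in
# production, queue the disagreements for expert adjudication, and assemble
# the curated outcomes (plus all agreements) into a new versioned training
# set with a full accounting of where every scored experiment went.

CURATOR_LABELS <- c("crystal", "other", "uncertain", "unusable")

#' Detect user-vs-model score discrepancies
#'
#' Partitions the scored experiments into agreements and discrepancies by
#' comparing the model's binary call (`fused_p >= tau`) with the user's
#' binary score. Experiments lacking a user score are neither: they are
#' returned separately. Duplicate experiment keys in either table are an
#' error.
#'
#' @param scores Tibble with columns `experiment_key`, `fused_p`.
#' @param user_scores Tibble with columns `experiment_key` and either
#'   `user_binary` (`"crystal"`/`"other"`) or a 7-class `user_score`
#'   (mapped via the user-score consolidation rule).
#' @param tau Decision threshold on the crystal probability (default 0.5,
#'   shared with training and fusion).
#' @return A list with tibbles `agreements`, `discrepancies` (columns
#'   include `model_binary`, `user_binary`, `fused_p`, `status = "open"`)
#'   and `unscored`.
#' @export
detect_discrepancies <- function(scores, user_scores, tau = 0.5) {
  if (anyDuplicated(scores$experiment_key) ||
      anyDuplicated(user_scores$experiment_key)) {
    rlang::abort("duplicate experiment keys in a score table",
                 class = "dropvision_error_duplicate_keys")
  }
  if (!"user_binary" %in% names(user_scores)) {
    bad <- !user_scores$user_score %in% USER_SCORES
    if (any(bad)) {
      rlang::abort("unknown user scores", class = "dropvision_error_unknown_label",
                   rejected = user_scores[bad, , drop = FALSE])
    }
    user_scores$user_binary <- unname(USER_TO_BINARY[user_scores$user_score])
  }
  tab <- dplyr::left_join(scores,
                          user_scores[, c("experiment_key", "user_binary")],
                          by = "experiment_key")
  tab$model_binary <- ifelse(tab$fused_p >= tau, "crystal", "other")
  unscored <- tab[is.na(tab$user_binary), , drop = FALSE]
  tab <- tab[!is.na(tab$user_binary), , drop = FALSE]
  agree <- tab$model_binary == tab$user_binary
  disc <- tab[!agree, , drop = FALSE]
  disc$status <- if (nrow(disc)) "open" else character(0)
  list(agreements = tab[agree, , drop = FALSE],
       discrepancies = disc,
       unscored = unscored)
}

#' Adjudicate a discrepancy queue with curator labels
#'
#' Each queued item must receive at least one curator label from
#' `crystal`, `other`, `uncertain`, `unusable`. Items whose labels agree
#' unanimously on `crystal` or `other` are resolved with that label; items
#' carrying any `uncertain`/`unusable` label, or conflicting
#' `crystal`/`other` labels, are excluded from training but retained in the
#' quarantine table (curated images on which agreement cannot be reached
#' are stored, never deleted). A `"majority"` consensus rule is available
#' as an alternative to the default unanimity.
#'
#' @param queue The `discrepancies` tibble from [detect_discrepancies()].
#' @param labels Tibble with columns `experiment_key`, `curator`, `label`.
#' @param consensus `"unanimity"` (default) or `"majority"`.
#' @return A list with tibbles `resolved` (with `curator_label`, `status =
#'   "resolved"`) and `excluded` (with `reason`, `status = "excluded"`).
#' @export
adjudicate <- function(queue, labels, consensus = c("unanimity", "majority")) {
  consensus <- match.arg(consensus)
  bad <- setdiff(unique(labels$label), CURATOR_LABELS)
  if (length(bad)) {
    rlang::abort(paste0("curator labels outside the four-value set: ",
                        paste(bad, collapse = ", ")),
                 class = "dropvision_error_unknown_label")
  }
  missing <- setdiff(queue$experiment_key, labels$experiment_key)
  if (length(missing)) {
    rlang::abort(paste0(length(missing), " queued items received no curator label"),
                 class = "dropvision_error_unlabelled")
  }
  if (nrow(queue) == 0L) {
    empty <- queue
    empty$curator_label <- character(0)
    excl <- queue
    excl$reason <- character(0)
    return(list(resolved = empty, excluded = excl))
  }
  verdict <- labels %>%
    dplyr::filter(.data$experiment_key %in% queue$experiment_key) %>%
    dplyr::group_by(.data$experiment_key) %>%
    dplyr::summarise(outcome = {
      ls <- .data$label
      if (any(ls %in% c("uncertain", "unusable"))) "excluded:uncertain_or_unusable"
      else if (consensus == "unanimity" && length(unique(ls)) > 1L) "excluded:curator_conflict"
      else if (consensus == "majority") {
        tb <- sort(table(ls), decreasing = TRUE)
        if (length(tb) > 1L && tb[1] == tb[2]) "excluded:curator_conflict"
        else names(tb)[1]
      }
      else unique(ls)
    }, .groups = "drop")
  out <- dplyr::left_join(queue, verdict, by = "experiment_key")
  excl <- grepl("^excluded:", out$outcome)
  resolved <- out[!excl, , drop = FALSE]
  resolved$curator_label <- resolved$outcome
  resolved$outcome <- NULL
  resolved$status <- rep("resolved", nrow(resolved))
  excluded <- out[excl, , drop = FALSE]
  excluded$reason <- sub("^excluded:", "", excluded$outcome)
  excluded$outcome <- NULL
  excluded$status <- rep("excluded", nrow(excluded))
  list(resolved = resolved, excluded = excluded)
}

#' Assemble a curated dataset version with its accounting report
#'
#' The new training set is the union of the agreements and the
#' curator-resolved discrepancies; experiments present in the test manifest
#' are excluded from it (train/test hygiene) and their number is recorded in
#' the accounting, never silently discarded. The accounting report places
#' every scored experiment in exactly one bucket and its sums must
#' reconcile exactly, which is asserted on every call.
#'
#' @param detection The list returned by [detect_discrepancies()].
#' @param adjudication The list returned by [adjudicate()] (may cover an
#'   empty queue).
#' @param manifest The image manifest whose rows back the scored
#'   experiments (used to collect image rows for the new version).
#' @param test_manifest Manifest of held-out experiments to exclude.
#' @param version_tag Tag for the new dataset version.
#' @param parent Parent version tag.
#' @return A list with the new `dataset_version` and the
#'   `accounting` report (class `accounting_report`).
#' @export
assemble_version <- function(detection, adjudication, manifest,
                             test_manifest = NULL, version_tag = "v2",
                             parent = NULL) {
  agr <- detection$agreements
  res <- adjudication$resolved
  exc <- adjudication$excluded
  n_scored <- nrow(agr) + nrow(detection$discrepancies)
  acc <- list(
    n_scored = n_scored,
    n_agreements = nrow(agr),
    n_discrepancies = nrow(detection$discrepancies),
    n_model_false_crystal = sum(res$model_binary == "crystal" &
                                  res$curator_label == "other"),
    n_user_missed = sum(res$model_binary == "crystal" &
                          res$curator_label == "crystal"),
    n_model_missed = sum(res$model_binary == "other" &
                           res$curator_label == "crystal"),
    n_user_false_crystal = sum(res$model_binary == "other" &
                                 res$curator_label == "other"),
    n_unresolved = nrow(exc)
  )
  train_keys <- c(agr$experiment_key, res$experiment_key)
  test_keys <- if (is.null(test_manifest)) character(0) else
    unique(test_manifest$experiment_key)
  overlap <- intersect(train_keys, test_keys)
  acc$n_excluded_test_overlap <- length(overlap)
  train_keys <- setdiff(train_keys, test_keys)
  acc$n_included_in_training <- length(train_keys)
  acc <- structure(acc, class = "accounting_report")
  validate_accounting(acc)

  rows <- manifest[manifest$experiment_key %in% train_keys, , drop = FALSE]
  # curated labels overwrite: resolved experiments take the curator label,
  # agreements keep the agreed model/user call
  lab <- dplyr::bind_rows(
    tibble::tibble(experiment_key = agr$experiment_key,
                   new_label = agr$model_binary),
    tibble::tibble(experiment_key = res$experiment_key,
                   new_label = res$curator_label)
  )
  rows <- dplyr::left_join(rows, lab, by = "experiment_key")
  rows$binary_label <- rows$new_label
  rows$new_label <- NULL
  rows$split <- rep("train", nrow(rows))
  rows$version_tag <- rep(version_tag, nrow(rows))
  if (length(intersect(unique(rows$experiment_key), test_keys))) {
    rlang::abort("assembled version overlaps the test set",
                 class = "dropvision_error_split")
  }
  dv <- dataset_version(rows, version_tag, parent = parent, accounting = acc)
  list(version = dv, accounting = acc)
}

#' @rdname assemble_version
#' @param acc An `accounting_report`.
#' @export
validate_accounting <- function(acc) {
  ok <- acc$n_agreements + acc$n_discrepancies == acc$n_scored &&
    acc$n_model_false_crystal + acc$n_user_missed + acc$n_model_missed +
    acc$n_user_false_crystal + acc$n_unresolved == acc$n_discrepancies
  if (!ok) {
    rlang::abort("accounting buckets do not reconcile",
                 class = "dropvision_error_accounting")
  }
  invisible(acc)
}

#' @export
print.accounting_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-28s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Non-linear display scale for crystal probabilities
#'
#' Maps a crystal probability to a display colour intensity so that low
#' probabilities stay nearly invisible and intensity grows rapidly beyond
#' 40%: linear from 0 to 0.1 over `[0, 0.4]`, then
#' `0.1 + 0.9 * ((p - 0.4) / 0.6)^0.7`. Monotone non-decreasing with
#' `intensity(0) = 0` and `intensity(1) = 1`.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Display intensities in `[0, 1]`.
#' @export
colour_scale <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("probabilities must lie in [0, 1]",
                 class = "dropvision_error_config")
  }
  ifelse(p <= 0.4, 0.25 * p, 0.1 + 0.9 * ((p - 0.4) / 0.6)^0.7)
}
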