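# Imbalance-aware evaluation. The positive class is always "crystal":
# crystallization screens are heavily skewed towards non-crystal outcomes
# (95% or more), so raw accuracy is uninformative and the metrics of record
# are crystal recall and balanced accuracy.

#' Confusion matrix for binary crystal/other labels
#'
#' @param truth,pred Equal-length character vectors over
#'   `c("crystal", "other")`; `"crystal"` is the positive class.
#' @return An object of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    rlang::abort("truth and pred lengths differ", class = "dropvision_error_shape")
  }
  bad <- setdiff(unique(c(truth, pred)), BINARY_CLASSES)
  if (length(bad)) {
    rlang::abort(paste0("labels outside {crystal, other}: ",
                        paste(bad, collapse = ", ")),
                 class = "dropvision_error_unknown_label")
  }
  structure(list(tp = sum(truth == "crystal" & pred == "crystal"),
                 fp = sum(truth == "other" & pred == "crystal"),
                 tn = sum(truth == "other" & pred == "other"),
                 fn = sum(truth == "crystal" & pred == "other")),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Computes recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy,
#' specificity `TN/(TN+FP)`, balanced accuracy (the mean of recall and
#' specificity — equivalently the unweighted mean of per-class recalls) and
#' the F1 score. Degenerate divisions are reported as `NA` ("undefined"),
#' never as zero, with one exception fixed by convention: F1 is 0 when
#' `TP = 0` but false calls exist, and undefined only when
#' `TP = FP = FN = 0`.
#'
#' @param cm A [confusion()] result.
#' @return An object of class `metrics_report`: a list of the metrics above
#'   plus the total count `n`.
#' @export
cls_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- div(cm$tp, cm$tp + cm$fn)
  precision <- div(cm$tp, cm$tp + cm$fp)
  specificity <- div(cm$tn, cm$tn + cm$fp)
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  accuracy <- div(cm$tp + cm$tn, n)
  balanced <- if (is.na(recall) || is.na(specificity)) NA_real_ else
    (recall + specificity) / 2
  f1 <- if (cm$tp == 0 && cm$fp == 0 && cm$fn == 0) {
    NA_real_
  } else if (cm$tp == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(recall = recall, precision = precision, accuracy = accuracy,
                 specificity = specificity, balanced_accuracy = balanced,
                 f1 = f1, n = n, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "undef" else sprintf("%.2f%%", 100 * v)
  cat("crystal recall    ", pc(x$recall), "\n",
      "precision         ", pc(x$precision), "\n",
      "accuracy          ", pc(x$accuracy), "\n",
      "balanced accuracy ", pc(x$balanced_accuracy), "\n",
      "F1                ", pc(x$f1), "\n", sep = "")
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("crystal", "other"),
                              predicted = c("crystal", "other")))
  print(m)
  invisible(x)
}

#' Per-crystal-type recall
#'
#' Recall computed within each crystal type (`microcrystals`,
#' `needles_clusters`, `single_crystal`) over the true-crystal rows of a
#' manifest. Types with zero members are absent from the result; rows with
#' an unknown type are quarantined into the `quarantine` attribute and
#' reported via a warning.
#'
#' @param m A manifest (one row per evaluated experiment) with
#'   `binary_label` and `crystal_type` columns.
#' @param pred Character vector of predicted binary labels aligned with the
#'   rows of `m`.
#' @return A tibble with columns `crystal_type`, `n`, `detected`, `recall`.
#' @export
recall_by_type <- function(m, pred) {
  if (nrow(m) != length(pred)) {
    rlang::abort("pred must align with manifest rows",
                 class = "dropvision_error_shape")
  }
  cr <- m$binary_label == "crystal"
  types <- m$crystal_type[cr]
  known <- types %in% CRYSTAL_PHENOTYPES
  out_q <- NULL
  if (any(!known)) {
    out_q <- m[cr, , drop = FALSE][!known, , drop = FALSE]
    rlang::warn(paste0(sum(!known), " crystal rows with unknown crystal_type quarantined"),
                class = "dropvision_warning_quarantine")
  }
  tab <- tibble::tibble(crystal_type = types[known],
                        hit = (pred[cr])[known] == "crystal") %>%
    dplyr::group_by(.data$crystal_type) %>%
    dplyr::summarise(n = dplyr::n(), detected = sum(.data$hit),
                     recall = mean(.data$hit), .groups = "drop")
  attr(tab, "quarantine") <- out_q
  tab
}
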