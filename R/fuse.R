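# Late fusion of per-experiment visible and UV crystal probabilities into
# one consolidated score. Three rules are supported: the arithmetic mean,
# the product, and the maximum of the two probabilities ("argmax" - the
# score of whichever model is more confident about a crystal). When one
# modality is missing the present score is used directly, whatever rule was
# requested. The max rule dominates either single modality at any decision
# threshold, which is why it is the default.

FUSION_METHODS <- c("argmax", "mean", "product")

#' Fuse a pair of modality scores
#'
#' @param p_visible,p_uv Crystal probabilities in `[0, 1]`; either may be
#'   `NA` (missing modality) but not both. Vectorized.
#' @param method `"argmax"` (default), `"mean"`, or `"product"`.
#' @return A tibble with columns `fused_p`, `method` (the method actually
#'   applied: `"single_modality"` when one side was absent) and
#'   `winning_modality` (`"visible"`, `"uv"`, `"both"` on an argmax tie, or
#'   `NA` for non-argmax rules).
#' @export
fuse_scores <- function(p_visible, p_uv, method = c("argmax", "mean", "product")) {
  method <- match.arg(method)
  n <- max(length(p_visible), length(p_uv))
  p_visible <- rep_len(as.numeric(p_visible), n)
  p_uv <- rep_len(as.numeric(p_uv), n)
  if (any(is.na(p_visible) & is.na(p_uv))) {
    rlang::abort("both modality scores absent for at least one experiment",
                 class = "dropvision_error_missing_scores")
  }
  ok <- function(p) !is.na(p) & p >= 0 & p <= 1
  if (any(!ok(p_visible) & !is.na(p_visible)) || any(!ok(p_uv) & !is.na(p_uv))) {
    rlang::abort("scores must lie in [0, 1]", class = "dropvision_error_config")
  }
  single <- is.na(p_visible) | is.na(p_uv)
  fused <- numeric(n); win <- rep(NA_character_, n)
  meth <- rep(method, n)
  meth[single] <- "single_modality"
  fused[single] <- ifelse(is.na(p_uv[single]), p_visible[single], p_uv[single])
  win[single] <- ifelse(is.na(p_uv[single]), "visible", "uv")
  both <- !single
  if (any(both)) {
    pv <- p_visible[both]; pu <- p_uv[both]
    fused[both] <- switch(method,
                          argmax = pmax(pv, pu),
                          mean = (pv + pu) / 2,
                          product = pv * pu)
    if (method == "argmax") {
      win[both] <- dplyr::case_when(pv > pu ~ "visible", pu > pv ~ "uv",
                                    TRUE ~ "both")
    }
  }
  tibble::tibble(fused_p = fused, method = meth, winning_modality = win)
}

#' Fuse score tables over a paired manifest
#'
#' Evaluates each experiment of a paired manifest from its per-modality
#' score tables. Experiments with both scores are fused with the requested
#' rule; experiments with one score fall back to it; scores whose key is
#' absent from the manifest are not fused and are reported in the
#' `orphans` attribute.
#'
#' @param paired A manifest processed by [pair_modalities()].
#' @param vis_scores,uv_scores Tibbles with columns `experiment_key` and
#'   `p` (crystal probability); either may be empty.
#' @param method Fusion rule, see [fuse_scores()].
#' @return A tibble with one row per scored experiment: `experiment_key`,
#'   `p_visible`, `p_uv`, `fused_p`, `method`, `winning_modality`.
#' @export
fuse_manifest <- function(paired, vis_scores, uv_scores,
                          method = c("argmax", "mean", "product")) {
  method <- match.arg(method)
  keys <- unique(paired$experiment_key)
  orphans <- dplyr::bind_rows(
    vis_scores[!vis_scores$experiment_key %in% keys, , drop = FALSE],
    uv_scores[!uv_scores$experiment_key %in% keys, , drop = FALSE]
  )
  if (nrow(orphans)) {
    rlang::warn(paste0(nrow(orphans), " scores without a manifest entry were not fused"),
                class = "dropvision_warning_orphan_scores")
  }
  tab <- tibble::tibble(experiment_key = keys) %>%
    dplyr::left_join(dplyr::rename(vis_scores, p_visible = "p"),
                     by = "experiment_key") %>%
    dplyr::left_join(dplyr::rename(uv_scores, p_uv = "p"),
                     by = "experiment_key")
  scored <- !(is.na(tab$p_visible) & is.na(tab$p_uv))
  tab <- tab[scored, , drop = FALSE]
  fr <- fuse_scores(tab$p_visible, tab$p_uv, method)
  out <- dplyr::bind_cols(tab, fr)
  attr(out, "orphans") <- orphans
  out
}
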