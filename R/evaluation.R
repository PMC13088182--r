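#' Confusion metrics of a reliable-negative extraction
#'
#' Compares the extracted RN set against the concealed ground truth of
#' the unlabeled pool. Negative precision is the fraction of RN that are
#' true negatives (label fidelity: a latent positive flagged as RN
#' injects severe label noise downstream); negative recall is the
#' fraction of all true negatives in the unlabeled pool that were
#' captured (data-set balancing power). The mean true yield of the RN
#' set is the chemistry-facing validation: a well-chosen threshold
#' isolates non-functioning reactions, so it should sit near zero.
#'
#' @param rn an `rn_set` from [extract_reliable_negatives()].
#' @param pu the [make_pu_dataset()] result carrying `hidden_truth`.
#' @return A [metrics_report()] fragment with `negative_precision`
#'   (`NA` when the RN set is empty — 0/0 is undefined and downstream
#'   aggregation skips such folds), `negative_recall`,
#'   `rn_mean_yield_pct`, the four confusion fractions of the unlabeled
#'   pool (`rn_true_negative`, `rn_latent_positive`,
#'   `undecisive_true_negative`, `undecisive_latent_positive`), and the
#'   false-positive rate (latent positives flagged RN, as a fraction of
#'   the whole unlabeled pool, the Fig.-style partition convention).
#' @export
rn_confusion_metrics <- function(rn, pu) {
  U <- pu$unlabeled
  if (length(U) == 0L) return(metrics_report(n_rn = 0L))
  truth <- pu$hidden_truth[U]
  if (anyNA(truth)) stopf("unlabeled pool has no hidden ground truth")
  is_rn <- U %in% rn$rn_ids
  neg <- truth == 0L
  n_u <- length(U)
  cf <- c(rn_true_negative = sum(is_rn & neg),
          rn_latent_positive = sum(is_rn & !neg),
          undecisive_true_negative = sum(!is_rn & neg),
          undecisive_latent_positive = sum(!is_rn & !neg)) / n_u
  precision <- if (any(is_rn)) sum(is_rn & neg) / sum(is_rn) else NA_real_
  recall <- if (any(neg)) sum(is_rn & neg) / sum(neg) else NA_real_
  mean_yield <- if (any(is_rn)) mean(pu$hidden_yield[U[is_rn]]) else NA_real_
  rep <- metrics_report(negative_precision = precision,
                        negative_recall = recall,
                        rn_mean_yield_pct = mean_yield,
                        confusion_fractions = cf,
                        n_rn = sum(is_rn))
  rep$false_positive_rate <- unname(cf["rn_latent_positive"])
  rep
}

#' Sweep the RN threshold over a grid
#'
#' Recomputes precision, recall, and mean RN yield of the selection
#' `score <= t` for every `t` on the grid, exposing the trade-off the
#' spy-derived threshold automates: a higher threshold raises recall but
#' contaminates the RN set with latent positives (visible as climbing
#' mean yield), a conservative one discards usable negatives.
#'
#' @param scores named numeric vector of classifier scores over the
#'   unlabeled pool (e.g. the `scores` field of an `rn_set`).
#' @param pu the [make_pu_dataset()] result carrying `hidden_truth`.
#' @param grid ascending numeric vector of thresholds in `[0, 1]`.
#' @return A data frame of class `payn_sweep` with columns `threshold`,
#'   `negative_precision`, `negative_recall`, `rn_mean_yield_pct`,
#'   `n_rn`. Recall is non-decreasing along the grid (selections are
#'   nested).
#' @export
threshold_sweep <- function(scores, pu, grid = seq(0, 1, by = 0.02)) {
  if (length(grid) == 0L) stopf("threshold grid is empty")
  grid <- sort(grid)
  U <- pu$unlabeled
  truth <- pu$hidden_truth[U]
  if (anyNA(truth)) stopf("unlabeled pool has no hidden ground truth")
  sc <- scores[U]
  neg <- truth == 0L
  rows <- lapply(grid, function(t) {
    sel <- sc <= t
    data.frame(
      threshold = t,
      negative_precision = if (any(sel)) sum(sel & neg) / sum(sel) else NA_real_,
      negative_recall = if (any(neg)) sum(sel & neg) / sum(neg) else NA_real_,
      rn_mean_yield_pct = if (any(sel)) mean(pu$hidden_yield[U[sel]]) else NA_real_,
      n_rn = sum(sel))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("payn_sweep", "data.frame")
  out
}

#' Gap-closed percentage
#'
#' The share of the performance gap between the positives-only lower
#' benchmark and the fully labeled upper benchmark that the augmented
#' model bridges:
#' `100 * (mae_pos - mae_aug) / (mae_pos - mae_full)`.
#' Values above 100 (augmented beats the fully labeled model) or below 0
#' (augmentation hurt) are reported unclipped.
#'
#' @param mae_pos MAE of the positives-only model (percent yield).
#' @param mae_aug MAE of the augmented model.
#' @param mae_full MAE of the fully labeled model.
#' @return The gap-closed value in percent.
#' @export
gap_closed <- function(mae_pos, mae_aug, mae_full) {
  if (!(mae_pos > mae_full))
    stopf(paste0("no performance gap to close: positives-only MAE (%s) ",
                 "must exceed the fully labeled MAE (%s)"), mae_pos, mae_full)
  100 * (mae_pos - mae_aug) / (mae_pos - mae_full)
}
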