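#' Inject spies into the unlabeled pool
#'
#' A uniform random subset of the known positives is selected as spies
#' and moved into the unlabeled set with labels concealed. Because the
#' spies are drawn at random from the positives, their score
#' distribution under the trained PU classifier empirically models the
#' latent positives hiding in the unlabeled pool, which is what makes
#' the threshold derivation possible.
#'
#' @param pu a [make_pu_dataset()] result.
#' @param spy_rate fraction of the positives to conceal; the spy count
#'   is `round(spy_rate * |P|)` and must be at least 1.
#' @param seed integer seed for the spy draw.
#' @param n_spies optional explicit spy count, overriding `spy_rate`.
#' @return An object of class `spy_assignment`: id sets `spy_ids`,
#'   `reduced_positives` (`P` minus spies) and `spiked_unlabeled`
#'   (`U` plus spies), with the rate and seed recorded.
#' @export
inject_spies <- function(pu, spy_rate = 0.1, seed = 1L, n_spies = NULL) {
  P <- pu$positives
  if (length(P) < 2L) stopf("need at least 2 known positives to spare a spy")
  if (is.null(n_spies)) {
    assert_scalar_number(spy_rate, "spy_rate")
    if (spy_rate <= 0 || spy_rate >= 1)
      stopf("spy_rate must be in (0, 1): all-or-none spies leave nothing to train on")
    n_spies <- round(spy_rate * length(P))
  } else {
    spy_rate <- n_spies / length(P)
  }
  if (n_spies < 1L)
    stopf("spy_rate %s of %d positives rounds to 0 spies", spy_rate, length(P))
  if (n_spies >= length(P))
    stopf("spy count %d would leave no positives to train on", n_spies)
  spies <- local_seed(seed, sample(P, n_spies))
  structure(list(
    spy_ids = spies,
    reduced_positives = setdiff(P, spies),
    spiked_unlabeled = c(pu$unlabeled, spies),
    spy_rate = spy_rate,
    seed = as.integer(seed)
  ), class = "spy_assignment")
}

# Translate the user-facing parameter mapping (depth, learning_rate,
# iterations, plus any native booster parameter) into xgboost arguments.
# nthread is pinned to 1 so a fixed seed reproduces bit-identical models.
resolve_model_params <- function(model_params, objective) {
  mp <- as.list(model_params %||% list())
  nrounds <- as.integer(mp$iterations %||% 300L)
  params <- list(
    objective = objective,
    max_depth = as.integer(mp$depth %||% 6L),
    learning_rate = as.numeric(mp$learning_rate %||% 0.1),
    nthread = 1L
  )
  extra <- mp[setdiff(names(mp), c("iterations", "depth", "learning_rate"))]
  list(params = c(params, extra), nrounds = nrounds)
}

#' Fit the PU classifier
#'
#' Trains a probabilistic binary classifier to separate the reduced
#' positives (label 1) from the spy-containing unlabeled pool (label 0).
#' The default base learner is a gradient-boosted decision-tree ensemble
#' with a logistic objective; any model producing class probabilities in
#' `[0, 1]` fits the contract and can be substituted via
#' [fit_pu_classifier_raw()].
#'
#' @param features a `payn_features` matrix covering all involved ids.
#' @param assignment a [inject_spies()] result.
#' @param model_params flat list understood keys: `depth` (default 6),
#'   `learning_rate` (0.1), `iterations` (300); further entries are
#'   passed to the booster verbatim (e.g. `scale_pos_weight`).
#' @return An object of class `payn_pu_classifier`.
#' @export
fit_pu_classifier <- function(features, assignment, model_params = list()) {
  fit_pu_classifier_raw(features,
                        pos_ids = assignment$reduced_positives,
                        neg_ids = assignment$spiked_unlabeled,
                        model_params = model_params)
}

#' Fit a PU classifier from explicit id sets
#'
#' Lower-level variant of [fit_pu_classifier()] taking the two training
#' sides directly; used for the spy-free classifier of the label
#' frequency estimator.
#'
#' @inheritParams fit_pu_classifier
#' @param pos_ids,neg_ids record ids of the positive-labeled and
#'   unlabeled-labeled training sides.
#' @export
fit_pu_classifier_raw <- function(features, pos_ids, neg_ids,
                                  model_params = list()) {
  if (length(pos_ids) == 0L || length(neg_ids) == 0L)
    stopf("degenerate training set: need records on both sides")
  rp <- resolve_model_params(model_params, "binary:logistic")
  X <- rbind(features_for(features, pos_ids), features_for(features, neg_ids))
  lab <- c(rep(1, length(pos_ids)), rep(0, length(neg_ids)))
  dtrain <- xgboost::xgb.DMatrix(unclass_features(X), label = lab, nthread = 1L)
  booster <- xgboost::xgb.train(params = rp$params, data = dtrain,
                                nrounds = rp$nrounds, verbose = 0)
  structure(list(booster = booster, params = rp$params, nrounds = rp$nrounds),
            class = "payn_pu_classifier")
}

unclass_features <- function(x) {
  attr(x, "block_map") <- NULL
  class(x) <- "matrix"
  unclass(x)
}

#' Score records with a PU classifier
#'
#' @param object a `payn_pu_classifier`.
#' @param features a `payn_features` matrix.
#' @param ids optional record ids to score (default: all rows).
#' @param ... unused.
#' @return Named numeric vector of scores in `[0, 1]` — the estimated
#'   probability of the record being a reported positive, `p(s=1|x)`.
#' @export
predict.payn_pu_classifier <- function(object, features, ids = NULL, ...) {
  if (!is.null(ids)) features <- features_for(features, ids)
  sc <- stats::predict(object$booster,
                       xgboost::xgb.DMatrix(unclass_features(features), nthread = 1L))
  stats::setNames(pmin(1, pmax(0, as.numeric(sc))), rownames(features))
}

#' Derive the spy threshold
#'
#' Places the threshold at the `k`-th smallest spy score with
#' `k = floor(tolerance * n_spies)` (the lower empirical quantile,
#' without interpolation). This guarantees that at least a
#' `1 - tolerance` fraction of the spies score strictly above the
#' threshold; a tolerance of 5% therefore sets the threshold such that
#' 95% of the spies are recognized as positive. With `k = 0` no spy may
#' be sacrificed and the threshold is 0.
#'
#' @param spy_scores numeric vector of spy classifier scores.
#' @param tolerance fraction of spies allowed at or below the threshold,
#'   in `[0, 1)`.
#' @return An object of class `threshold_result`: `t_spies`, the
#'   recorded `spy_scores`, `tolerance`, and `k`.
#' @export
compute_spy_threshold <- function(spy_scores, tolerance = 0.05) {
  if (length(spy_scores) == 0L) stopf("no spy scores: cannot derive a threshold")
  assert_scalar_number(tolerance, "tolerance", 0, 1)
  if (tolerance >= 1) stopf("tolerance must be below 1")
  k <- floor(tolerance * length(spy_scores))
  t_spies <- if (k >= 1L) sort(spy_scores, partial = k)[k] else 0
  structure(list(t_spies = t_spies, spy_scores = spy_scores,
                 tolerance = tolerance, k = as.integer(k)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t_spies = %.4f (tolerance %.3f, k = %d of %d spies)\n",
              x$t_spies, x$tolerance, x$k, length(x$spy_scores)))
  invisible(x)
}

#' Extract reliable negatives from the unlabeled pool
#'
#' Scores every originally unlabeled record and classifies those with
#' `score <= t_spies` as reliable negatives (RN); the rest are
#' "undecisive" and are discarded from downstream training. Spies are
#' never members of either set — they return to the positive pool.
#'
#' @param pu a [make_pu_dataset()] result.
#' @param assignment the [inject_spies()] result of the same fold.
#' @param clf the fitted [fit_pu_classifier()].
#' @param features a `payn_features` matrix.
#' @param thr the [compute_spy_threshold()] result derived from the same
#'   fold's spies.
#' @return An object of class `rn_set`: `rn_ids`, `undecisive_ids`
#'   (partitioning `U`), `scores` (named, over `U`), and `t_spies`.
#' @export
extract_reliable_negatives <- function(pu, assignment, clf, features, thr) {
  U <- pu$unlabeled
  stopifnot(length(intersect(U, assignment$spy_ids)) == 0L)
  if (length(U) == 0L)
    return(structure(list(rn_ids = character(0), undecisive_ids = character(0),
                          scores = stats::setNames(numeric(0), character(0)),
                          t_spies = thr$t_spies), class = "rn_set"))
  scores <- predict(clf, features, ids = U)
  rn <- U[scores[U] <= thr$t_spies]
  structure(list(rn_ids = rn,
                 undecisive_ids = setdiff(U, rn),
                 scores = scores,
                 t_spies = thr$t_spies),
            class = "rn_set")
}

#' @export
print.rn_set <- function(x, ...) {
  cat(sprintf("<rn_set> %d reliable negatives, %d undecisive (t_spies = %.4f)\n",
              length(x$rn_ids), length(x$undecisive_ids), x$t_spies))
  invisible(x)
}

#' Estimate the SCAR label frequency from held-out positives
#'
#' Under the selected-completely-at-random assumption the non-traditional
#' classifier's score factorizes as `p(s=1|x) = c * p(y=1|x)`, so on
#' held-out known positives (where `p(y=1|x)` is close to 1 for
#' well-separated classes) the mean score estimates the label frequency
#' `c = p(s=1|y=1)`. The holdout must not have been used to train `clf`,
#' and must come from a uniform holdout of the whole PU data set —
#' holding out positives only would dilute the labeled class during
#' training and bias the estimate downward.
#'
#' @param clf a fitted `payn_pu_classifier` trained without the holdout.
#' @param holdout_positive_features `payn_features` rows of held-out
#'   known positives.
#' @return An object of class `label_frequency_estimate`: `c_hat` in
#'   `(0, 1]` and `n_holdout`.
#' @export
estimate_label_frequency <- function(clf, holdout_positive_features) {
  if (is.null(nrow(holdout_positive_features)) ||
      nrow(holdout_positive_features) == 0L)
    stopf("label-frequency estimation needs at least one holdout positive")
  c_hat <- mean(predict(clf, holdout_positive_features))
  c_hat <- min(1, max(.Machine$double.eps, c_hat))
  structure(list(c_hat = c_hat,
                 n_holdout = nrow(holdout_positive_features)),
            class = "label_frequency_estimate")
}

#' Cross-fitted label-frequency estimate
#'
#' Standard practice for the mean-score estimator: split the PU data set
#' (positives and unlabeled together, uniformly) into `n_folds`, train a
#' spy-free PU classifier on each training complement, score the labeled
#' positives of the held-out fold, and average all out-of-fold scores.
#' Every known positive contributes, which lowers the variance relative
#' to a single holdout.
#'
#' @param pu a [make_pu_dataset()] result.
#' @param features a `payn_features` matrix.
#' @param n_folds number of cross-fitting folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param model_params classifier parameters, see [fit_pu_classifier()].
#' @return A `label_frequency_estimate` (with `n_holdout` = `|P|`).
#' @export
estimate_label_frequency_cv <- function(pu, features, n_folds = 5L,
                                        seed = 1L, model_params = list()) {
  pool <- c(pu$positives, pu$unlabeled)
  lab <- c(rep(1L, length(pu$positives)), rep(0L, length(pu$unlabeled)))
  fold <- local_seed(seed, sample(rep(seq_len(n_folds), length.out = length(pool))))
  oof <- rep(NA_real_, length(pool))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    clf <- fit_pu_classifier_raw(features,
                                 pos_ids = pool[tr & lab == 1L],
                                 neg_ids = pool[tr & lab == 0L],
                                 model_params = model_params)
    oof[!tr] <- predict(clf, features, ids = pool[!tr])
  }
  c_hat <- min(1, max(.Machine$double.eps, mean(oof[lab == 1L])))
  structure(list(c_hat = c_hat, n_holdout = sum(lab == 1L)),
            class = "label_frequency_estimate")
}
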