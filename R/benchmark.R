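#' Cross-validation specification for the benchmark
#'
#' @param n_folds number of cross-validation folds (default 5).
#' @param validation_fraction fraction of each model's training rows
#'   held out as a validation set during hyperparameter search (default
#'   0.10).
#' @param seed integer seed controlling fold assignment and all
#'   per-fold randomness (deterministically split per stage).
#' @param hpo_trials number of random-search trials per model; 0 (the
#'   default) skips the search and uses the fixed `model_params`, which
#'   keeps the whole benchmark deterministic.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 5L, validation_fraction = 0.10, seed = 1L,
                    hpo_trials = 0L) {
  if (n_folds < 2L) stopf("n_folds must be at least 2")
  assert_scalar_number(validation_fraction, "validation_fraction")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stopf("validation_fraction must be strictly inside (0, 1)")
  if (hpo_trials < 0) stopf("hpo_trials must be non-negative")
  structure(list(n_folds = as.integer(n_folds),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 hpo_trials = as.integer(hpo_trials)),
            class = "cv_spec")
}

#' Build the augmented training set
#'
#' Combines the known positives (with their true yields) and the
#' extracted reliable negatives (with an imputed failed-reaction yield)
#' into the balanced training set for downstream regression. Undecisive
#' records never enter. Spies are members of `pu$positives` and hence
#' return to the training set with their true yields.
#'
#' @param pu a [make_pu_dataset()] result.
#' @param rn the `rn_set` derived from `pu`.
#' @param table the originating [reaction_table()].
#' @param rn_yield_pct constant regression target assigned to reliable
#'   negatives, in `[0, yield_threshold]`; default 0, the natural
#'   failed-reaction yield.
#' @return An object of class `augmented_set`: data frame with columns
#'   `record_id`, `target` (percent yield) and `provenance`
#'   (`"known_positive"` or `"reliable_negative"`).
#' @export
build_augmented_set <- function(pu, rn, table, rn_yield_pct = 0) {
  if (length(pu$positives) == 0L) stopf("no known positives to train on")
  assert_scalar_number(rn_yield_pct, "rn_yield_pct", 0, pu$yield_threshold_pct)
  bad <- setdiff(rn$rn_ids, pu$unlabeled)
  if (length(bad)) stopf("RN id '%s' is not in the unlabeled pool", bad[1L])
  ys <- yields(table)
  out <- data.frame(
    record_id = c(pu$positives, rn$rn_ids),
    target = c(unname(ys[pu$positives]), rep(rn_yield_pct, length(rn$rn_ids))),
    provenance = c(rep("known_positive", length(pu$positives)),
                   rep("reliable_negative", length(rn$rn_ids))),
    stringsAsFactors = FALSE)
  class(out) <- c("augmented_set", "data.frame")
  out
}

#' Fit a yield regressor
#'
#' Gradient-boosted regression on percent yield with a mean-absolute-
#' error objective. Constant-target input yields a constant predictor
#' (no error). Predictions are clipped to `[0, 100]` at prediction
#' time.
#'
#' @param features a `payn_features` matrix covering the training ids.
#' @param ids record ids of the training rows.
#' @param target numeric yield targets aligned to `ids`.
#' @param model_params see [fit_pu_classifier()] (`depth`,
#'   `learning_rate`, `iterations`, plus native booster parameters).
#' @return An object of class `payn_regressor`.
#' @export
fit_yield_regressor <- function(features, ids, target, model_params = list()) {
  if (length(ids) < 2L) stopf("need at least 2 training rows")
  if (length(target) != length(ids))
    stopf("target length %d does not match %d ids", length(target), length(ids))
  rp <- resolve_model_params(model_params, "reg:absoluteerror")
  X <- features_for(features, ids)
  dtrain <- xgboost::xgb.DMatrix(unclass_features(X), label = target, nthread = 1L)
  booster <- xgboost::xgb.train(params = rp$params, data = dtrain,
                                nrounds = rp$nrounds, verbose = 0)
  structure(list(booster = booster, params = rp$params, nrounds = rp$nrounds),
            class = "payn_regressor")
}

#' Predict yields
#'
#' @param object a `payn_regressor`.
#' @param features a `payn_features` matrix.
#' @param ids optional record ids to predict (default: all rows).
#' @param ... unused.
#' @return Named numeric vector of predicted yields, clipped to
#'   `[0, 100]`.
#' @export
predict.payn_regressor <- function(object, features, ids = NULL, ...) {
  if (!is.null(ids)) features <- features_for(features, ids)
  p <- stats::predict(object$booster,
                      xgboost::xgb.DMatrix(unclass_features(features), nthread = 1L))
  stats::setNames(pmin(100, pmax(0, as.numeric(p))), rownames(features))
}

# Random search over the tunable space (depth 3..10, learning rate
# log-uniform on [1e-3, 0.3], iterations 100..1000), scored by
# validation MAE; returns the winning parameter list.
hpo_search <- function(features, ids, target, n_trials, val_fraction, seed,
                       base_params = list()) {
  if (n_trials <= 0L) return(base_params)
  local_seed(seed, {
    n <- length(ids)
    vi <- sample(n, max(1L, round(val_fraction * n)))
    best <- base_params
    best_mae <- Inf
    for (trial in seq_len(n_trials)) {
      cand <- list(depth = sample(3:10, 1L),
                   learning_rate = exp(stats::runif(1, log(1e-3), log(0.3))),
                   iterations = sample(100:1000, 1L))
      fit <- fit_yield_regressor(features, ids[-vi], target[-vi],
                                 model_params = cand)
      pred <- predict(fit, features, ids = ids[vi])
      mae <- mean(abs(pred - target[vi]))
      if (mae < best_mae) { best_mae <- mae; best <- cand }
    }
    best
  })
}

#' Run the three-model cross-validated benchmark
#'
#' For each fold: (i) the test fold is held out with its true yields and
#' never touches any training stage; (ii) on the training folds the
#' reporting-bias simulation, spy injection, PU classifier, threshold
#' derivation, and reliable-negative extraction are run from scratch;
#' (iii) three yield regressors are trained on identical splits — fully
#' labeled (all training yields, the upper benchmark), positives-only
#' (the known positives' yields, the lower benchmark mimicking
#' literature data), and augmented (positives plus RN at the imputed
#' yield); (iv) each model's MAE is measured on the untouched test
#' fold, over its natural class mix. Mean and standard deviation are
#' aggregated over folds and the gap-closed percentage is computed from
#' the mean MAEs.
#'
#' @param table a fully labeled [reaction_table()].
#' @param features a `payn_features` matrix aligned to `table`.
#' @param bias a [bias_spec()].
#' @param spy_rate,tolerance spy technique parameters
#'   (see [inject_spies()], [compute_spy_threshold()]).
#' @param cv a [cv_spec()].
#' @param model_params shared base parameters for all boosters.
#' @param rn_yield_pct imputed RN regression target, default 0.
#' @return An object of class `benchmark_report`: per-fold MAE vectors
#'   (`mae_full`, `mae_augmented`, `mae_positives_only`), their
#'   mean/sd, `gap_closed_pct`, per-fold RN quality metrics, labeled
#'   row counts, and the skipped folds if any.
#' @export
run_benchmark_cv <- function(table, features, bias = bias_spec(),
                             spy_rate = 0.1, tolerance = 0.05,
                             cv = cv_spec(), model_params = list(),
                             rn_yield_pct = 0) {
  ids <- record_ids(table)
  n <- length(ids)
  fold_of <- local_seed(derive_seed(cv$seed, "folds"),
                        sample(rep(seq_len(cv$n_folds), length.out = n)))
  names(fold_of) <- ids
  per_fold <- list()
  skipped <- integer(0)
  for (k in seq_len(cv$n_folds)) {
    test_ids <- ids[fold_of == k]
    train_ids <- ids[fold_of != k]
    sub <- table[table$record_id %in% train_ids, , drop = FALSE]
    attr(sub, "roles") <- roles(table)
    class(sub) <- class(table)
    labels <- binarize_yields(sub, bias$yield_threshold_pct)
    fold_bias <- bias_spec(bias$yield_threshold_pct, bias$pu_ratio,
                           derive_seed(bias$seed, "bias", k))
    pu <- tryCatch(make_pu_dataset(sub, labels, fold_bias),
                   error = function(e) NULL)
    if (is.null(pu) || length(pu$positives) == 0L) {
      warning(sprintf("fold %d skipped: no positives after the PU split", k))
      skipped <- c(skipped, k)
      next
    }
    assignment <- inject_spies(pu, spy_rate = spy_rate,
                               seed = derive_seed(cv$seed, "spies", k))
    clf <- fit_pu_classifier(features, assignment, model_params)
    thr <- compute_spy_threshold(predict(clf, features, ids = assignment$spy_ids),
                                 tolerance)
    rn <- extract_reliable_negatives(pu, assignment, clf, features, thr)
    aug <- build_augmented_set(pu, rn, sub, rn_yield_pct)
    ys <- yields(table)
    specs <- list(
      full = list(ids = train_ids, target = unname(ys[train_ids])),
      augmented = list(ids = aug$record_id, target = aug$target),
      positives_only = list(ids = pu$positives,
                            target = unname(ys[pu$positives])))
    mae <- vapply(names(specs), function(m) {
      s <- specs[[m]]
      params <- if (cv$hpo_trials > 0L)
        hpo_search(features, s$ids, s$target, cv$hpo_trials,
                   cv$validation_fraction,
                   derive_seed(cv$seed, paste0("hpo_", m), k),
                   base_params = model_params)
      else model_params
      fit <- fit_yield_regressor(features, s$ids, s$target, params)
      mean(abs(predict(fit, features, ids = test_ids) - ys[test_ids]))
    }, numeric(1))
    per_fold[[length(per_fold) + 1L]] <- list(
      fold = k, mae = mae,
      rn_metrics = rn_confusion_metrics(rn, pu),
      n_labeled = c(full = length(train_ids),
                    augmented = nrow(aug),
                    positives_only = length(pu$positives)))
  }
  if (!length(per_fold)) stopf("every fold was skipped; no benchmark to report")
  mae_mat <- t(vapply(per_fold, function(f) f$mae, numeric(3)))
  colnames(mae_mat) <- c("full", "augmented", "positives_only")
  means <- colMeans(mae_mat)
  sds <- apply(mae_mat, 2, stats::sd)
  gap <- tryCatch(gap_closed(means["positives_only"], means["augmented"],
                             means["full"]),
                  error = function(e) NA_real_)
  structure(list(
    mae_full = unname(mae_mat[, "full"]),
    mae_augmented = unname(mae_mat[, "augmented"]),
    mae_positives_only = unname(mae_mat[, "positives_only"]),
    mean_mae = means, sd_mae = sds,
    gap_closed_pct = unname(gap),
    per_fold = per_fold,
    skipped_folds = skipped,
    n_folds = cv$n_folds
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d folds (%d skipped)\n",
              x$n_folds, length(x$skipped_folds)))
  cat(sprintf("  MAE positives-only %.2f +/- %.2f | augmented %.2f +/- %.2f | full %.2f +/- %.2f\n",
              x$mean_mae["positives_only"], x$sd_mae["positives_only"],
              x$mean_mae["augmented"], x$sd_mae["augmented"],
              x$mean_mae["full"], x$sd_mae["full"]))
  cat(sprintf("  gap closed: %.1f%%\n", x$gap_closed_pct))
  invisible(x)
}

#' Serialize a benchmark report to JSON
#'
#' @param report a `benchmark_report`.
#' @param path output path (`benchmark.json`).
#' @param provenance optional named list (seed, config hash) embedded in
#'   the JSON.
#' @return `path`, invisibly.
#' @export
write_benchmark_json <- function(report, path, provenance = NULL) {
  payload <- list(
    mae_full = report$mae_full,
    mae_augmented = report$mae_augmented,
    mae_positives_only = report$mae_positives_only,
    mean_mae = as.list(report$mean_mae),
    sd_mae = as.list(report$sd_mae),
    gap_closed_pct = report$gap_closed_pct,
    skipped_folds = report$skipped_folds,
    n_folds = report$n_folds,
    per_fold_rn = lapply(report$per_fold, function(f) list(
      fold = f$fold,
      negative_precision = f$rn_metrics$negative_precision,
      negative_recall = f$rn_metrics$negative_recall,
      rn_mean_yield_pct = f$rn_metrics$rn_mean_yield_pct,
      n_rn = f$rn_metrics$n_rn)))
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
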