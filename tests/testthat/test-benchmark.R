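test_that("the augmented set combines positives and RN, never undecisives", {
  scen <- cached_scenario("separable", seed = 1L)
  pipe <- run_spy_pipeline(scen, seed = 101L)
  aug <- build_augmented_set(pipe$pu, pipe$rn, scen$table, rn_yield_pct = 0)
  expect_equal(nrow(aug), length(pipe$pu$positives) + length(pipe$rn$rn_ids))
  expect_length(intersect(aug$record_id, pipe$rn$undecisive_ids), 0L)
  # positives carry their true yields, RN the imputed constant
  ys <- yields(scen$table)
  kp <- aug$provenance == "known_positive"
  expect_equal(aug$target[kp], unname(ys[aug$record_id[kp]]))
  expect_true(all(aug$target[!kp] == 0))

  # empty RN degenerates to the positives-only set
  rn0 <- structure(list(rn_ids = character(0),
                        undecisive_ids = pipe$pu$unlabeled,
                        scores = pipe$rn$scores, t_spies = 0),
                   class = "rn_set")
  aug0 <- build_augmented_set(pipe$pu, rn0, scen$table)
  expect_setequal(aug0$record_id, pipe$pu$positives)

  expect_error(build_augmented_set(pipe$pu, pipe$rn, scen$table,
                                   rn_yield_pct = 50), "\\[0, 20\\]")
})

test_that("counting example: 10 positives + 8 RN at policy 0 gives 18 rows", {
  ids <- sprintf("r%02d", 1:30)
  tab <- reaction_table(data.frame(a = ids, stringsAsFactors = FALSE),
                        c(rep(90, 10), rep(1, 20)), record_id = ids)
  pu <- structure(list(positives = ids[1:10], unlabeled = ids[11:30],
                       discarded = character(0),
                       hidden_truth = stats::setNames(c(rep(1L, 10), rep(0L, 20)), ids),
                       hidden_yield = yields(tab),
                       yield_threshold_pct = 20, pu_ratio = 0.5, seed = 1L),
                  class = "payn_pu")
  rn <- structure(list(rn_ids = ids[11:18], undecisive_ids = ids[19:30],
                       scores = stats::setNames(rep(0.01, 20), ids[11:30]),
                       t_spies = 0.1), class = "rn_set")
  aug <- build_augmented_set(pu, rn, tab, rn_yield_pct = 0)
  expect_equal(nrow(aug), 18L)
  expect_equal(sum(aug$target == 0), 8L)
})

test_that("the yield regressor beats a mean-only baseline and respects [0,100]", {
  scen <- cached_scenario("separable", seed = 1L)
  ids <- record_ids(scen$table)
  set.seed(11)
  tr <- sample(ids, 1500)
  te <- setdiff(ids, tr)
  ys <- yields(scen$table)
  fit <- fit_yield_regressor(scen$features, tr, unname(ys[tr]))
  pred <- predict(fit, scen$features, ids = te)
  expect_true(all(pred >= 0 & pred <= 100))
  mae_model <- mean(abs(pred - ys[te]))
  mae_mean <- mean(abs(mean(ys[tr]) - ys[te]))
  expect_lt(mae_model, mae_mean)

  # constant-target input yields a constant predictor, not an error
  cfit <- fit_yield_regressor(scen$features, tr[1:50], rep(40, 50))
  cpred <- predict(cfit, scen$features, ids = te[1:20])
  expect_equal(unname(cpred), rep(40, 20), tolerance = 1e-6)
})

test_that("cross-validated benchmark isolates test folds and aggregates exactly", {
  scen <- cached_scenario("separable", seed = 1L)
  rep <- run_benchmark_cv(scen$table, scen$features,
                          bias = bias_spec(pu_ratio = 0.5, seed = 51),
                          cv = cv_spec(n_folds = 5, seed = 52))
  expect_length(rep$mae_full, 5L)
  expect_length(rep$mae_augmented, 5L)
  expect_length(rep$mae_positives_only, 5L)
  expect_equal(unname(rep$mean_mae["full"]), mean(rep$mae_full))
  expect_equal(unname(rep$sd_mae["augmented"]), stats::sd(rep$mae_augmented))
  expect_equal(rep$gap_closed_pct,
               unname(gap_closed(rep$mean_mae["positives_only"],
                                 rep$mean_mae["augmented"],
                                 rep$mean_mae["full"])))
  # the fully labeled model is the upper bound in most folds
  expect_gte(sum(rep$mae_full <= rep$mae_augmented), 4L)
  # no test-fold leakage: each fold trains on exactly n minus its test
  # fold, and the five training counts sum to (n_folds - 1) * n
  folds_n <- vapply(rep$per_fold, function(f) unname(f$n_labeled["full"]),
                    numeric(1))
  expect_true(all(folds_n < nrow(scen$table)))
  expect_equal(sum(folds_n), (5 - 1) * nrow(scen$table))
})

test_that("benchmark is deterministic with hpo disabled and responds to hpo", {
  scen <- cached_scenario("separable", seed = 2L)
  small <- scen$table[1:600, ]
  attr(small, "roles") <- roles(scen$table)
  attr(small, "component_features") <- attr(scen$table, "component_features")
  class(small) <- class(scen$table)
  feats <- featurize_reaction(small, featurizer_spec(mode = "passthrough"))
  r1 <- run_benchmark_cv(small, feats, bias = bias_spec(pu_ratio = 0.6, seed = 1),
                         cv = cv_spec(n_folds = 3, seed = 2),
                         model_params = list(iterations = 80))
  r2 <- run_benchmark_cv(small, feats, bias = bias_spec(pu_ratio = 0.6, seed = 1),
                         cv = cv_spec(n_folds = 3, seed = 2),
                         model_params = list(iterations = 80))
  expect_identical(r1$mae_full, r2$mae_full)
  expect_identical(r1$mae_augmented, r2$mae_augmented)
  expect_identical(r1$gap_closed_pct, r2$gap_closed_pct)

  # a short random search runs and returns finite MAEs
  r3 <- run_benchmark_cv(small, feats, bias = bias_spec(pu_ratio = 0.6, seed = 1),
                         cv = cv_spec(n_folds = 2, seed = 2, hpo_trials = 2),
                         model_params = list(iterations = 60))
  expect_true(all(is.finite(r3$mae_augmented)))
})

test_that("pu_ratio 1 collapses augmented onto positives-only", {
  scen <- cached_scenario("separable", seed = 3L)
  small <- scen$table[1:500, ]
  attr(small, "roles") <- roles(scen$table)
  attr(small, "component_features") <- attr(scen$table, "component_features")
  class(small) <- class(scen$table)
  feats <- featurize_reaction(small, featurizer_spec(mode = "passthrough"))
  rep <- run_benchmark_cv(small, feats, bias = bias_spec(pu_ratio = 1, seed = 4),
                          cv = cv_spec(n_folds = 3, seed = 5),
                          model_params = list(iterations = 60))
  # U empty => RN empty => identical training sets => identical MAEs
  expect_equal(rep$mae_augmented, rep$mae_positives_only, tolerance = 1e-12)
})
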