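test_that("spy injection counts, reproducibility, and error paths", {
  tab <- reaction_table(data.frame(a = sprintf("c%03d", 1:220),
                                   stringsAsFactors = FALSE),
                        c(rep(90, 120), rep(2, 100)))
  pu <- make_pu_dataset(tab, binarize_yields(tab),
                        bias_spec(pu_ratio = 0.5, seed = 5))
  P <- length(pu$positives)
  asg <- inject_spies(pu, spy_rate = 0.1, seed = 9)
  expect_length(asg$spy_ids, round(0.1 * P))
  expect_length(asg$reduced_positives, P - round(0.1 * P))
  expect_length(asg$spiked_unlabeled, length(pu$unlabeled) + round(0.1 * P))
  expect_true(all(asg$spy_ids %in% pu$positives))
  expect_length(intersect(asg$spy_ids, asg$reduced_positives), 0L)

  asg2 <- inject_spies(pu, spy_rate = 0.1, seed = 9)
  asg3 <- inject_spies(pu, spy_rate = 0.1, seed = 10)
  expect_identical(asg$spy_ids, asg2$spy_ids)
  expect_false(identical(sort(asg$spy_ids), sort(asg3$spy_ids)))

  expect_error(inject_spies(pu, spy_rate = 0.001, seed = 1), "0 spies")
  expect_error(inject_spies(pu, spy_rate = 1, seed = 1), "\\(0, 1\\)")
  expect_error(inject_spies(pu, spy_rate = 0.99999, seed = 1, n_spies = P),
               "no positives")
})

test_that("the PU classifier separates positives from true negatives and honors [0,1]", {
  # linearly separated scenario: positive features centered +2,
  # negative centered -2, unit variance
  set.seed(42)
  n <- 1000
  y <- rep(c(1L, 0L), each = n / 2)
  X <- matrix(rnorm(n * 4), n)
  X[, 1] <- X[, 1] + ifelse(y == 1L, 2, -2)
  rownames(X) <- as.character(seq_len(n) - 1L)
  tab <- reaction_table(data.frame(a = rownames(X), stringsAsFactors = FALSE),
                        ifelse(y == 1L, 90, 1))
  feats <- structure(X, block_map = list(a = 1:4),
                     class = c("payn_features", class(X)))
  pu <- make_pu_dataset(tab, binarize_yields(tab),
                        bias_spec(pu_ratio = 0.5, seed = 2))
  asg <- inject_spies(pu, 0.1, seed = 3)
  clf <- fit_pu_classifier(feats, asg)
  sc_all <- predict(clf, feats)
  expect_true(all(sc_all >= 0 & sc_all <= 1))
  true_neg_u <- pu$unlabeled[pu$hidden_truth[pu$unlabeled] == 0L]
  expect_gt(mean(sc_all[asg$reduced_positives]), mean(sc_all[true_neg_u]))
})

test_that("identical feature vectors give identical (constant) scores", {
  n <- 40
  X <- matrix(1, n, 3)
  rownames(X) <- as.character(seq_len(n) - 1L)
  feats <- structure(X, block_map = list(a = 1:3),
                     class = c("payn_features", class(X)))
  tab <- reaction_table(data.frame(a = rownames(X), stringsAsFactors = FALSE),
                        rep(c(90, 1), each = n / 2))
  pu <- make_pu_dataset(tab, binarize_yields(tab),
                        bias_spec(pu_ratio = 0.5, seed = 2))
  asg <- inject_spies(pu, 0.2, seed = 3)
  clf <- fit_pu_classifier(feats, asg)
  sc <- predict(clf, feats)
  expect_equal(length(unique(round(sc, 10))), 1L)
  # the constant-score classifier makes the mean-score estimator exact
  est <- estimate_label_frequency(clf, feats[1:10, , drop = FALSE])
  expect_equal(est$c_hat, unname(sc[1]), tolerance = 1e-10)
  expect_lte(est$c_hat, 1)
})

test_that("spy threshold follows the k-th order statistic with floor(tol * n)", {
  scores <- (1:100) / 100
  thr <- compute_spy_threshold(scores, 0.05)
  expect_equal(thr$t_spies, 0.05)   # 5th smallest of 100
  expect_equal(thr$k, 5L)

  # permutation invariance
  thr_perm <- compute_spy_threshold(sample(scores), 0.05)
  expect_equal(thr_perm$t_spies, thr$t_spies)

  # k = 0 branches: tolerance 0, or too few spies to sacrifice one
  expect_equal(compute_spy_threshold(scores, 0)$t_spies, 0)
  set.seed(1)
  s20 <- runif(20)
  expect_equal(compute_spy_threshold(s20, 0.05)$t_spies, min(s20))
  expect_error(compute_spy_threshold(numeric(0), 0.05), "no spy scores")
})

test_that("threshold is monotone in tolerance and guarantees spy recognition", {
  set.seed(7)
  scores <- runif(137)
  tols <- c(0, 0.01, 0.05, 0.1, 0.3, 0.6, 0.9)
  ts <- vapply(tols, function(tl) compute_spy_threshold(scores, tl)$t_spies,
               numeric(1))
  expect_true(!is.unsorted(ts))
  for (tl in tols) {
    t <- compute_spy_threshold(scores, tl)$t_spies
    expect_gte(mean(scores > t), 1 - tl)
  }
})

test_that("RN extraction partitions U, respects the boundary, and excludes spies", {
  scen <- cached_scenario("separable", seed = 1L)
  pipe <- run_spy_pipeline(scen, seed = 101L)
  U <- pipe$pu$unlabeled
  expect_setequal(c(pipe$rn$rn_ids, pipe$rn$undecisive_ids), U)
  expect_length(intersect(pipe$rn$rn_ids, pipe$rn$undecisive_ids), 0L)
  expect_length(intersect(pipe$rn$rn_ids, pipe$assignment$spy_ids), 0L)
  # boundary inclusive: score == t_spies is RN
  sc <- pipe$rn$scores
  expect_true(all(sc[pipe$rn$rn_ids] <= pipe$thr$t_spies))
  expect_true(all(sc[pipe$rn$undecisive_ids] > pipe$thr$t_spies))

  # explicit boundary case on a hand-made score set
  fake_thr <- structure(list(t_spies = 0.2, spy_scores = c(0.2, 0.9),
                             tolerance = 0.5, k = 1L),
                        class = "threshold_result")
  fake_clf <- pipe$clf
  # threshold below every unlabeled score leaves RN empty
  lo_thr <- structure(list(t_spies = min(sc[U]) - 1e-9, spy_scores = 0,
                           tolerance = 0, k = 0L), class = "threshold_result")
  rn0 <- extract_reliable_negatives(pipe$pu, pipe$assignment, fake_clf,
                                    scen$features, lo_thr)
  expect_length(rn0$rn_ids, 0L)
  expect_setequal(rn0$undecisive_ids, U)
})

test_that("label frequency recovery is unbiased on a separable SCAR draw", {
  # moderate size for speed; the acceptance suite runs the full n = 5000
  scen <- cached_scenario("separable", seed = 3L)
  lab <- binarize_yields(scen$table)
  pu <- make_pu_dataset(scen$table, lab, bias_spec(pu_ratio = 0.6, seed = 31))
  est <- estimate_label_frequency_cv(pu, scen$features, seed = 32)
  expect_gt(est$c_hat, 0.6 - 0.08)
  expect_lt(est$c_hat, 0.6 + 0.08)
  expect_error(estimate_label_frequency(NULL, scen$features[0, , drop = FALSE]),
               "holdout")
})
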