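test_that("confusion metrics match brute-force counting", {
  # U of 10: 6 true negatives, 4 latent positives; RN of 5 with 4 negatives
  ids <- sprintf("u%02d", 1:10)
  truth <- stats::setNames(c(rep(0L, 6), rep(1L, 4)), ids)
  yield <- stats::setNames(c(rep(2, 6), rep(80, 4)), ids)
  pu <- structure(list(positives = "p1", unlabeled = ids,
                       discarded = character(0),
                       hidden_truth = c(p1 = 1L, truth),
                       hidden_yield = c(p1 = 90, yield),
                       yield_threshold_pct = 20, pu_ratio = 0.5, seed = 1L),
                  class = "payn_pu")
  rn <- structure(list(rn_ids = c(ids[1:4], ids[7]),
                       undecisive_ids = setdiff(ids, c(ids[1:4], ids[7])),
                       scores = stats::setNames(rep(0.1, 10), ids),
                       t_spies = 0.2), class = "rn_set")
  m <- rn_confusion_metrics(rn, pu)
  expect_equal(m$negative_precision, 4 / 5)
  expect_equal(m$negative_recall, 4 / 6)
  expect_equal(m$rn_mean_yield_pct, mean(c(rep(2, 4), 80)))
  expect_equal(sum(m$confusion_fractions), 1, tolerance = 1e-12)
  expect_equal(unname(m$confusion_fractions["rn_latent_positive"]), 1 / 10)
  expect_equal(m$false_positive_rate, 1 / 10)

  # perfect extraction: RN = exactly the true negatives
  rn_perf <- structure(list(rn_ids = ids[1:6], undecisive_ids = ids[7:10],
                            scores = rn$scores, t_spies = 0.2),
                       class = "rn_set")
  mp <- rn_confusion_metrics(rn_perf, pu)
  expect_equal(mp$negative_precision, 1)
  expect_equal(mp$negative_recall, 1)

  # empty RN: precision undefined, reported as missing with the count flag
  rn0 <- structure(list(rn_ids = character(0), undecisive_ids = ids,
                        scores = rn$scores, t_spies = 0), class = "rn_set")
  m0 <- rn_confusion_metrics(rn0, pu)
  expect_true(is.na(m0$negative_precision))
  expect_equal(m0$n_rn, 0L)
  expect_equal(m0$negative_recall, 0)
})

test_that("threshold sweep boundaries, monotone recall, and consistency with extraction", {
  scen <- cached_scenario("separable", seed = 2L)
  pipe <- run_spy_pipeline(scen, seed = 201L)
  grid <- seq(0, 1, by = 0.05)
  sw <- threshold_sweep(pipe$rn$scores, pipe$pu, grid)
  expect_equal(nrow(sw), length(grid))
  expect_true(!is.unsorted(sw$negative_recall))        # nested selections
  expect_equal(sw$negative_recall[nrow(sw)], 1)        # t = 1 captures all
  # at t = 0 only zero-score points qualify
  expect_equal(sw$n_rn[1], sum(pipe$rn$scores[pipe$pu$unlabeled] <= 0))

  # sweep evaluated exactly at the spy threshold reproduces the
  # extraction-time confusion metrics
  at_t <- threshold_sweep(pipe$rn$scores, pipe$pu, pipe$thr$t_spies)
  m <- rn_confusion_metrics(pipe$rn, pipe$pu)
  expect_equal(at_t$negative_precision, m$negative_precision)
  expect_equal(at_t$negative_recall, m$negative_recall)
  expect_equal(at_t$rn_mean_yield_pct, m$rn_mean_yield_pct)
  expect_error(threshold_sweep(pipe$rn$scores, pipe$pu, numeric(0)), "empty")
})

test_that("precision holds high until the threshold crosses the score gap", {
  # synthetic score supports: negatives score below 0.3, positives above 0.6
  ids <- sprintf("u%03d", 1:200)
  truth <- stats::setNames(rep(c(0L, 1L), each = 100), ids)
  set.seed(5)
  sc <- stats::setNames(c(runif(100, 0, 0.3), runif(100, 0.6, 1)), ids)
  pu <- structure(list(positives = "p1", unlabeled = ids,
                       discarded = character(0),
                       hidden_truth = c(p1 = 1L, truth),
                       hidden_yield = c(p1 = 90,
                                        stats::setNames(ifelse(truth == 1L, 80, 3), ids)),
                       yield_threshold_pct = 20, pu_ratio = 0.5, seed = 1L),
                  class = "payn_pu")
  sw <- threshold_sweep(sc, pu, seq(0.05, 0.95, by = 0.05))
  below_gap <- sw$threshold < 0.6
  expect_true(all(sw$negative_precision[below_gap & sw$n_rn > 0] >= 0.95))
  expect_lt(min(sw$negative_precision[!below_gap]), 0.95)
})

test_that("gap-closed is a scale-free interpolation between the two benchmarks", {
  expect_equal(gap_closed(10, 10, 5), 0)      # no improvement
  expect_equal(gap_closed(10, 5, 5), 100)     # reaches the upper bound
  expect_gt(gap_closed(10, 4, 5), 100)        # beats it: unclipped
  expect_lt(gap_closed(10, 12, 5), 0)         # augmentation hurt: unclipped
  # invariant under common rescaling of all three MAEs
  expect_equal(gap_closed(11.1, 6.8, 4.0), gap_closed(111, 68, 40))
  expect_error(gap_closed(4, 3, 4), "gap")
  expect_error(gap_closed(3, 3, 4), "gap")
})
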