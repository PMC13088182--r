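#' Reporting-bias specification
#'
#' Parameters of the simulated reporting bias that turns a fully labeled
#' reaction table into a positive-unlabeled (PU) data set.
#'
#' @param yield_threshold_pct yield above which (strictly) a reaction
#'   counts as positive; default 20 percent.
#' @param pu_ratio fraction of the table drawn (uniformly at random)
#'   into the "reported" portion: positives in the draw become the known
#'   positives, negatives in the draw are discarded, mimicking failures
#'   that were run but never published. The rest becomes the unlabeled
#'   pool. Under this construction the labeling is independent of the
#'   features given the true class (the SCAR assumption holds by
#'   design), and the label frequency `p(s=1|y=1)` equals `pu_ratio`.
#' @param seed integer seed for the uniform draw.
#' @return An object of class `bias_spec`.
#' @export
bias_spec <- function(yield_threshold_pct = 20, pu_ratio = 0.5, seed = 1L) {
  assert_scalar_number(yield_threshold_pct, "yield_threshold_pct")
  assert_scalar_number(pu_ratio, "pu_ratio", 0, 1)
  structure(list(yield_threshold_pct = yield_threshold_pct,
                 pu_ratio = pu_ratio, seed = as.integer(seed)),
            class = "bias_spec")
}

#' Binarize continuous yields
#'
#' A reaction is classified as positive (`y = 1`) if its yield strictly
#' exceeds the threshold; exactly-threshold yields are negative.
#'
#' @param table a [reaction_table()].
#' @param threshold_pct yield cutoff in percent (default 20).
#' @return An object of class `payn_labels`: list with `y` (named 0/1
#'   integer vector, one per record) and `threshold_pct`.
#' @export
binarize_yields <- function(table, threshold_pct = 20) {
  y <- as.integer(table$yield_pct > threshold_pct)
  structure(list(y = stats::setNames(y, table$record_id),
                 threshold_pct = threshold_pct),
            class = "payn_labels")
}

#' Simulate reporting bias: build a PU data set
#'
#' Draws `floor(pu_ratio * N)` records uniformly without replacement.
#' Positives in the draw become the known-positive set `P` (reported,
#' `s = 1`); negatives in the draw are moved to `discarded` (failures
#' that were run but never reported and are lost to training). All
#' remaining records form the unlabeled pool `U` (`s = 0`) with their
#' true labels and yields concealed but retained for evaluation.
#'
#' @param table a [reaction_table()].
#' @param labels a [binarize_yields()] result aligned to `table`.
#' @param spec a [bias_spec()].
#' @return An object of class `payn_pu`: list with character id sets
#'   `positives`, `unlabeled`, `discarded` (pairwise disjoint, union =
#'   all ids), `hidden_truth` (named 0/1 over `P` and `U`),
#'   `hidden_yield` (named numeric over `P` and `U`), and the spec
#'   fields.
#' @export
make_pu_dataset <- function(table, labels, spec) {
  ids <- record_ids(table)
  if (!identical(names(labels$y), ids))
    stopf("labels are not aligned to the table")
  n_draw <- floor(spec$pu_ratio * length(ids))
  drawn <- local_seed(spec$seed, sample(ids, n_draw))
  pos <- drawn[labels$y[drawn] == 1L]
  if (length(pos) == 0L)
    stopf(paste0("the drawn sample contains no positive reactions ",
                 "(yield > %s): no positive class to learn from; ",
                 "increase pu_ratio or lower the threshold"),
          labels$threshold_pct)
  disc <- setdiff(drawn, pos)
  unl <- setdiff(ids, drawn)
  keep <- c(pos, unl)
  structure(list(
    positives = pos,
    unlabeled = unl,
    discarded = disc,
    hidden_truth = labels$y[keep],
    hidden_yield = yields(table)[keep],
    yield_threshold_pct = labels$threshold_pct,
    pu_ratio = spec$pu_ratio,
    seed = spec$seed
  ), class = "payn_pu")
}

#' @export
print.payn_pu <- function(x, ...) {
  cat(sprintf("<payn_pu> |P| = %d, |U| = %d, discarded = %d (pu_ratio %.2f, threshold %s%%)\n",
              length(x$positives), length(x$unlabeled), length(x$discarded),
              x$pu_ratio, x$yield_threshold_pct))
  invisible(x)
}
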