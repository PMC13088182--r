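#' Construct a reaction table
#'
#' A reaction table is the core data container: one row per reaction, one
#' character column per variable reaction component (a "role", e.g.
#' substrate, ligand, base, holding a SMILES string or a component
#' identifier), and a continuous yield in percent.
#'
#' @param components data frame of character columns, one per role.
#' @param yield_pct numeric vector of yields in `[0, 100]`, one per row.
#' @param record_id optional character vector of unique record
#'   identifiers. Defaults to the 0-based row index, which makes joins
#'   across pipeline stages deterministic.
#' @return An object of class `reaction_table`: a data frame with a
#'   `record_id` column, the role columns, and a `yield_pct` column; the
#'   role names are kept in the `"roles"` attribute in declared order.
#' @export
reaction_table <- function(components, yield_pct, record_id = NULL) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  if (nrow(components) == 0L) stopf("a reaction table needs at least one record")
  roles <- names(components)
  if (length(roles) == 0L) stopf("at least one component role column is required")
  if (length(yield_pct) != nrow(components))
    stopf("yield_pct has %d values for %d records", length(yield_pct), nrow(components))
  validate_yields(yield_pct)
  record_id <- record_id %||% as.character(seq_len(nrow(components)) - 1L)
  record_id <- as.character(record_id)
  if (anyDuplicated(record_id))
    stopf("record ids must be unique (duplicate: %s)",
          record_id[duplicated(record_id)][1L])
  out <- data.frame(record_id = record_id, components,
                    yield_pct = as.numeric(yield_pct),
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "roles") <- roles
  class(out) <- c("reaction_table", "data.frame")
  out
}

validate_yields <- function(yield_pct) {
  bad <- which(is.na(yield_pct))
  if (length(bad))
    stopf("yield is missing or non-numeric in row %d", bad[1L])
  out <- which(yield_pct < 0 | yield_pct > 100)
  if (length(out))
    stopf("yield %s in row %d is outside [0, 100]", yield_pct[out[1L]], out[1L])
  invisible(yield_pct)
}

#' @export
print.reaction_table <- function(x, ...) {
  cat(sprintf("<reaction_table> %d records, roles: %s\n",
              nrow(x), paste(roles(x), collapse = ", ")))
  print.data.frame(utils::head(x, 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("... %d more records\n", nrow(x) - 6L))
  invisible(x)
}

#' Role names of a reaction table
#' @param table a [reaction_table()].
#' @return Character vector of role column names in declared order.
#' @export
roles <- function(table) attr(table, "roles")

#' Record identifiers of a reaction table
#' @param table a [reaction_table()].
#' @export
record_ids <- function(table) table$record_id

#' Yields of a reaction table, named by record id
#' @param table a [reaction_table()].
#' @export
yields <- function(table) stats::setNames(table$yield_pct, table$record_id)

#' Read a reaction table from CSV
#'
#' The expected dialect is comma-separated UTF-8 with a mandatory header
#' row; yields are plain decimals in percent (no `%` sign), matching the
#' public HTE data releases. Any yield outside `[0, 100]`, or one that
#' does not parse as a number, is an error naming the offending row.
#'
#' @param path CSV file path.
#' @param role_columns character vector naming the component columns, in
#'   the role order to adopt.
#' @param yield_column name of the yield column.
#' @param id_column optional name of a unique-identifier column; when
#'   absent, ids default to the 0-based row index.
#' @return A [reaction_table()]. Extra columns present in the file are
#'   carried along untouched (e.g. precomputed numeric feature columns).
#' @export
read_reaction_table <- function(path, role_columns, yield_column,
                                id_column = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(role_columns, yield_column, id_column)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("column(s) missing from %s: %s", path, paste(miss, collapse = ", "))
  yraw <- df[[yield_column]]
  y <- suppressWarnings(as.numeric(yraw))
  bad <- which(is.na(y))
  if (length(bad))
    stopf("yield '%s' in row %d is not numeric", as.character(yraw[bad[1L]]), bad[1L])
  tab <- reaction_table(df[role_columns], y,
                        record_id = if (!is.null(id_column)) df[[id_column]])
  extra <- setdiff(names(df), c(role_columns, yield_column, id_column))
  if (length(extra)) {
    for (col in extra) tab[[col]] <- df[[col]]
    attr(tab, "extra_columns") <- extra
  }
  tab
}

#' Write a reaction table to CSV
#'
#' Inverse of [read_reaction_table()]; round trips are lossless for all
#' fields at printed precision (15 significant digits).
#'
#' @param table a [reaction_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a metrics report
#'
#' Collects the reliable-negative quality metrics (negative precision and
#' recall, mean true yield of the RN set, the four-cell confusion
#' partition of the unlabeled pool) and the three-benchmark regression
#' MAEs with the derived gap-closed percentage.
#'
#' @param negative_precision,negative_recall reals in `[0, 1]` (`NA` when
#'   undefined, e.g. empty RN set).
#' @param rn_mean_yield_pct mean true yield over the RN set, percent.
#' @param confusion_fractions named numeric of length 4
#'   (`rn_true_negative`, `rn_latent_positive`, `undecisive_true_negative`,
#'   `undecisive_latent_positive`) summing to 1 over the unlabeled pool.
#' @param mae_positives_only,mae_augmented,mae_full mean absolute errors
#'   in percent yield (`NA` when not computed).
#' @param gap_closed_pct percent of the positives-only-to-fully-labeled
#'   gap bridged by augmentation.
#' @param n_rn number of reliable negatives behind the metrics.
#' @return An object of class `payn_metrics` (a named list).
#' @export
metrics_report <- function(negative_precision = NA_real_,
                           negative_recall = NA_real_,
                           rn_mean_yield_pct = NA_real_,
                           confusion_fractions = NULL,
                           mae_positives_only = NA_real_,
                           mae_augmented = NA_real_,
                           mae_full = NA_real_,
                           gap_closed_pct = NA_real_,
                           n_rn = NA_integer_) {
  if (!is.null(confusion_fractions)) {
    if (length(confusion_fractions) != 4L)
      stopf("confusion_fractions must have 4 cells")
    if (abs(sum(confusion_fractions) - 1) > 1e-9)
      stopf("confusion_fractions must sum to 1 (got %.12f)",
            sum(confusion_fractions))
  }
  structure(list(
    negative_precision = negative_precision,
    negative_recall = negative_recall,
    rn_mean_yield_pct = rn_mean_yield_pct,
    confusion_fractions = confusion_fractions,
    mae_positives_only = mae_positives_only,
    mae_augmented = mae_augmented,
    mae_full = mae_full,
    gap_closed_pct = gap_closed_pct,
    n_rn = n_rn
  ), class = "payn_metrics")
}

#' @export
print.payn_metrics <- function(x, ...) {
  cat("<payn_metrics>\n")
  cat(sprintf("  negative precision: %s  recall: %s  mean RN yield: %s%%\n",
              format(x$negative_precision, digits = 3),
              format(x$negative_recall, digits = 3),
              format(x$rn_mean_yield_pct, digits = 3)))
  if (!is.na(x$mae_positives_only))
    cat(sprintf("  MAE positives-only %.2f | augmented %.2f | full %.2f | gap closed %.1f%%\n",
                x$mae_positives_only, x$mae_augmented, x$mae_full, x$gap_closed_pct))
  invisible(x)
}

#' Write reliable negatives and metrics to disk
#'
#' Writes `reliable_negatives.csv` (record id, classifier score, imputed
#' binary label, sorted by ascending score) and `metrics.json` with every
#' field of the [metrics_report()].
#'
#' @param rn an `rn_set` from [extract_reliable_negatives()].
#' @param report a [metrics_report()].
#' @param out_dir output directory, created if needed.
#' @param provenance optional named list (seed, config hash, counts)
#'   embedded in the JSON for reproducibility.
#' @return Character vector of the written file paths.
#' @export
write_outputs <- function(rn, report, out_dir, provenance = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stopf("output directory is not writable: %s", out_dir)
  rn_path <- file.path(out_dir, "reliable_negatives.csv")
  ids <- rn$rn_ids
  df <- data.frame(record_id = ids,
                   score = unname(rn$scores[ids]),
                   imputed_label = rep(0L, length(ids)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$score), , drop = FALSE]
  utils::write.csv(df, rn_path, row.names = FALSE, quote = FALSE)
  json_path <- file.path(out_dir, "metrics.json")
  payload <- unclass(report)
  payload$confusion_fractions <- as.list(payload$confusion_fractions)
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  c(rn_path, json_path)
}

#' Read a metrics report back from JSON
#'
#' @param path a `metrics.json` written by [write_outputs()].
#' @return A [metrics_report()].
#' @export
read_metrics <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  metrics_report(
    negative_precision = num(p$negative_precision),
    negative_recall = num(p$negative_recall),
    rn_mean_yield_pct = num(p$rn_mean_yield_pct),
    confusion_fractions = if (!is.null(p$confusion_fractions))
      unlist(p$confusion_fractions),
    mae_positives_only = num(p$mae_positives_only),
    mae_augmented = num(p$mae_augmented),
    mae_full = num(p$mae_full),
    gap_closed_pct = num(p$gap_closed_pct),
    n_rn = if (is.null(p$n_rn)) NA_integer_ else as.integer(p$n_rn)
  )
}
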