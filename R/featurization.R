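#' Featurizer specification
#'
#' Controls how reaction components become fixed-length numeric vectors.
#' Three modes are supported:
#' \describe{
#'   \item{`"fingerprint"`}{extended-connectivity (circular)
#'     fingerprints of the component SMILES, one block per role,
#'     concatenated in role order.}
#'   \item{`"passthrough"`}{components are opaque identifiers with
#'     precomputed real-valued vectors attached to the table (the
#'     synthetic generator's default); the PU mathematics is
#'     feature-agnostic, so this mode keeps tests chemistry-free.}
#'   \item{`"numeric"`}{feature values live in numeric columns of the
#'     table itself, selected by `numeric_prefix` (used for precomputed
#'     descriptors, e.g. DFT columns, and for synthetic CSV round
#'     trips).}
#' }
#'
#' @param radius fingerprint radius (number of bond-growth iterations);
#'   radius 2 corresponds to the widely used 4-diameter variant.
#' @param n_bits folded fingerprint length per role. Powers of two are
#'   conventional but any positive integer is accepted.
#' @param per_role if `TRUE` (default) each role gets its own
#'   fingerprint block; the blocks are concatenated in role order.
#' @param mode one of `"fingerprint"`, `"passthrough"`, `"numeric"`.
#' @param numeric_prefix column-name prefix selecting feature columns in
#'   `"numeric"` mode.
#' @return An object of class `featurizer_spec`.
#' @export
featurizer_spec <- function(radius = 2L, n_bits = 2048L, per_role = TRUE,
                            mode = c("fingerprint", "passthrough", "numeric"),
                            numeric_prefix = "x_") {
  mode <- match.arg(mode)
  if (!is.numeric(radius) || radius < 0 || radius != round(radius))
    stopf("radius must be a non-negative integer")
  if (radius > 5) stopf("radius above 5 is not supported by the fingerprint backend")
  if (!is.numeric(n_bits) || n_bits < 1 || n_bits != round(n_bits))
    stopf("n_bits must be a positive integer")
  structure(list(radius = as.integer(radius), n_bits = as.integer(n_bits),
                 per_role = isTRUE(per_role), mode = mode,
                 numeric_prefix = numeric_prefix),
            class = "featurizer_spec")
}

# Raw 4096-bit extended-connectivity fingerprint from the chemistry
# backend (OpenBabel via ChemmineOB). Radius r maps onto the diameter-2r
# fingerprint family.
ecfp_raw <- function(smiles, radius) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stopf("fingerprint mode requires the ChemmineOB package")
  name <- paste0("ECFP", 2L * radius)
  fp <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), name),
    error = function(e) NULL)
  if (is.null(fp) || length(fp) == 0L)
    stopf("cannot featurize SMILES '%s': not a parseable molecule", smiles)
  if (is.matrix(fp)) as.numeric(fp[1L, ]) else as.numeric(fp)
}

# OR-fold a raw bit vector down (or map it up) to n_bits. Folding by OR
# preserves bit-subset relations between fingerprints of different radii.
fold_bits <- function(bits, n_bits) {
  if (length(bits) == n_bits) return(bits)
  idx <- (seq_along(bits) - 1L) %% n_bits
  out <- numeric(n_bits)
  set <- which(bits != 0)
  out[unique(idx[set]) + 1L] <- 1
  out
}

#' Circular fingerprint of a single SMILES string
#'
#' Computes the hashed extended-connectivity fingerprint of a molecule
#' and folds it to `spec$n_bits`. The computation is canonical: two
#' SMILES notations of the same molecule give bit-identical vectors.
#' Hash collisions introduced by folding are accepted as-is, as is
#' standard for hashed fingerprints.
#'
#' @param smiles a SMILES string (non-empty).
#' @param spec a [featurizer_spec()] in `"fingerprint"` mode.
#' @return Numeric 0/1 vector of length `spec$n_bits`.
#' @export
circular_fingerprint <- function(smiles, spec = featurizer_spec()) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stopf("cannot featurize SMILES '%s': empty or not a string",
          paste(smiles, collapse = ","))
  fold_bits(ecfp_raw(smiles, spec$radius), spec$n_bits)
}

#' Featurize every record of a reaction table
#'
#' Produces the model-ready feature matrix: one row per record, aligned
#' 1:1 with the table, with one feature block per role concatenated in
#' the table's role order. Featurization is a pure function of the table
#' and spec — no randomness, no hidden state — so subsetting rows of the
#' result is equivalent to featurizing the subsetted table.
#'
#' @param table a [reaction_table()].
#' @param spec a [featurizer_spec()].
#' @param component_features for `"passthrough"` mode: named list
#'   (role -> numeric matrix with component identifiers as rownames).
#'   Defaults to the `"component_features"` attribute the synthetic
#'   generator attaches to its tables.
#' @return Numeric matrix of class `payn_features` with record ids as
#'   rownames and a `"block_map"` attribute mapping each role to its
#'   column indices.
#' @export
featurize_reaction <- function(table, spec = featurizer_spec(),
                               component_features = NULL) {
  rs <- roles(table)
  ids <- record_ids(table)
  if (spec$mode == "numeric") {
    cols <- grep(paste0("^", spec$numeric_prefix), names(table), value = TRUE)
    if (!length(cols))
      stopf("no feature columns with prefix '%s' found", spec$numeric_prefix)
    mat <- as.matrix(as.data.frame(table)[cols])
    storage.mode(mat) <- "double"
    rownames(mat) <- ids
    block <- lapply(rs, function(r) which(startsWith(cols, paste0(spec$numeric_prefix, r))))
    names(block) <- rs
    return(structure(mat, block_map = block, class = c("payn_features", class(mat))))
  }
  if (spec$mode == "passthrough") {
    component_features <- component_features %||% attr(table, "component_features")
    if (is.null(component_features))
      stopf("passthrough mode needs component_features (role -> matrix)")
    blocks <- lapply(rs, function(r) {
      lk <- component_features[[r]]
      if (is.null(lk)) stopf("no component features for role '%s'", r)
      comp <- table[[r]]
      miss <- setdiff(unique(comp), rownames(lk))
      if (length(miss))
        stopf("role '%s': no features for component '%s'", r, miss[1L])
      lk[comp, , drop = FALSE]
    })
  } else {
    cache <- new.env(parent = emptyenv())
    fp_of <- function(smi, r, id) {
      key <- smi
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <- tryCatch(circular_fingerprint(smi, spec), error = function(e) {
        stopf("record '%s', role '%s': %s", id, r, conditionMessage(e))
      })
      cache[[key]] <- v
      v
    }
    blocks <- lapply(rs, function(r) {
      t(vapply(seq_along(ids),
               function(i) fp_of(table[[r]][i], r, ids[i]),
               numeric(spec$n_bits)))
    })
  }
  mat <- do.call(cbind, blocks)
  rownames(mat) <- ids
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  block <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(block) <- rs
  colnames(mat) <- unlist(Map(function(r, ix) paste0(r, "_f", seq_along(ix)), rs, block),
                          use.names = FALSE)
  structure(mat, block_map = block, class = c("payn_features", class(mat)))
}

# Subset a feature matrix by record id, keeping the block map.
features_for <- function(features, ids) {
  miss <- setdiff(ids, rownames(features))
  if (length(miss)) stopf("no feature row for record '%s'", miss[1L])
  out <- features[ids, , drop = FALSE]
  attr(out, "block_map") <- attr(features, "block_map")
  out
}
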