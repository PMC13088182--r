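#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministically derive a stage seed from a global seed. Keeps results
# of different pipeline stages (bias sampling, spy draw, folds, models)
# decoupled while exposing a single reproducibility knob. Always < 2^31.
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + h * 7919 + as.numeric(index) * 104729) %% m
  as.integer(max(1, s))
}

# 32-bit FNV-1a over a character scalar; used to stamp artifacts with a
# short provenance hash of the effective configuration. The byte xor only
# touches the low 8 bits, so it is done in double precision directly.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single number", name)
  if (x < lo || x > hi)
    stopf("`%s` must be in [%s, %s], got %s", name, lo, hi, x)
  invisible(x)
}
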