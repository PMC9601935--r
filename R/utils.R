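#' @keywords internal
"_PACKAGE"

# Deterministic derivation of sub-seeds from one global seed, so that each
# pipeline component (fold assignment, oversampling, network init, ...) has
# its own reproducible RNG stream. Kept below 2^31 - 1.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  salt_num <- if (is.character(salt)) {
    sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  } else {
    as.numeric(salt)
  }
  as.integer((abs(seed) + 104729 * (salt_num + 1)) %% (.Machine$integer.max - 1) + 1)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gamlp_log <- function(..., verbose = getOption("gamlp.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[gamlp] ", ...)
  invisible(NULL)
}
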