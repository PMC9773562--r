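#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no save/restore).
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive independent sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  local_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_phenoprop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phenoprop_error")))
}
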