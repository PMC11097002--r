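#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a named substream seed from a master seed, kept inside 32-bit range.
substream_seed <- function(seed, stream) {
  offsets <- c(env = 101L, occurrences = 211L, crops = 307L, pipeline = 401L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  (as.integer(seed) %% 2000000000L) + offsets[[stream]]
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("field '", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
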