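# Internal helpers shared across modules.

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library code never clobbers the user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Abbreviate a vector for error messages: "a, b, c, ... (12 total)"
abbrev <- function(x, max = 5L) {
  x <- as.character(x)
  if (length(x) <= max) return(paste(x, collapse = ", "))
  paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
}

# Input/validation errors carry a dedicated condition class so callers
# (notably the command-line wrapper) can distinguish bad input from an
# internal assertion failure.
stopf <- function(fmt, ...) {
  stop(structure(
    class = c("rpikrls_input_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}
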