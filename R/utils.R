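# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x))
    stop_config("`%s` must be a single finite number", name)
  if (strict_min && x <= min)
    stop_config("`%s` must be > %s", name, format(min))
  if (!strict_min && x < min)
    stop_config("`%s` must be >= %s", name, format(min))
  if (x > max)
    stop_config("`%s` must be <= %s", name, format(max))
  invisible(x)
}

check_fraction <- function(x, name) check_scalar_number(x, name, min = 0, max = 1)

# The 20 standard amino acids, used by synthetic peptide/CDR3 generators.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, length = 9L) {
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
    character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
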