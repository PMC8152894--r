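# Internal helpers shared across modules.

# Deterministic sub-seed derivation so that each pipeline stage / animal / day
# draws from its own reproducible stream. Keeps results stable when individual
# stages are toggled. All seeds stay below 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- list(...)
  out <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    if (is.character(idx[[k]])) {
      token <- sum(utf8ToInt(idx[[k]]) * seq_along(utf8ToInt(idx[[k]])))
    } else {
      token <- as.double(idx[[k]])
    }
    out <- (out * 48271 + token * 7919 + k * 104729) %% 2147483647
  }
  as.integer(out)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; if `seed` is
# NULL, use (and advance) the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Shortest decimal representation that parses back bit-exact (up to 17
# significant digits).
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  for (digits in c("%.16g", "%.17g")) {
    bad <- which(as.numeric(out) != x)
    if (!length(bad)) break
    out[bad] <- sprintf(digits, x[bad])
  }
  out[is.na(x)] <- ""
  out
}

join_list_num <- function(x) {
  vapply(x, function(v) paste(fmt_num(v), collapse = ";"), character(1))
}

split_list_num <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(numeric(0))
    }
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

is_ascending <- function(x, strict = TRUE) {
  if (length(x) < 2L) {
    return(TRUE)
  }
  d <- diff(x)
  if (strict) all(d > 0) else all(d >= 0)
}
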