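# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without touching the caller's RNG
# stream. All user-facing stochastic operations funnel through this so that
# the same seed always yields the same result regardless of call order.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  } else {
    force(code)
  }
}

# Derive a stage-specific 31-bit seed from a global seed so pipeline stages
# are independently reproducible.
derive_seed <- function(seed, label) {
  stopifnot(length(label) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Expand "200k" / "1.5M" style strings to numbers; numerics pass through.
expand_units <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.character(x)) abort("cannot interpret value as a number")
  vapply(x, function(v) {
    m <- regmatches(v, regexec("^\\s*([0-9.]+)\\s*([kKmMgG]?)\\s*$", v))[[1]]
    if (length(m) == 0) abort(sprintf("cannot parse numeric value '%s'", v))
    mult <- switch(tolower(m[3]), "k" = 1e3, "m" = 1e6, "g" = 1e9, 1)
    as.numeric(m[2]) * mult
  }, numeric(1), USE.NAMES = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
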