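# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (length(x) == 0 || anyNA(x) || any(x <= 0)) {
    stopf("`%s` must be positive and non-missing (got %s)", name,
          paste(utils::head(format(x), 3L), collapse = ", "))
  }
  invisible(x)
}

check_same_length <- function(x, y, xname, yname) {
  if (length(x) != length(y)) {
    stopf("`%s` (n=%d) and `%s` (n=%d) must have the same length",
          xname, length(x), yname, length(y))
  }
  invisible(NULL)
}

# Q1/median/Q3 by linear interpolation of order statistics (quantile type 7,
# position 1 + (n-1)p) -- the convention all report tables use.
quartiles <- function(x) {
  unname(stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

fmt_iqr <- function(med, q1, q3, digits = 2) {
  sprintf("%.*f (%.*f, %.*f)", digits, med, digits, q1, digits, q3)
}
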