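# internal helpers: argument checking and seed plumbing

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L,
          sprintf("`%s` must be a single number", name))
  if (allow_na && is.na(x)) return(invisible(x))
  stop_if(is.na(x), sprintf("`%s` must not be NA", name))
  if (strict_lower) {
    stop_if(x <= lower, sprintf("`%s` must be > %s", name, lower))
  } else {
    stop_if(x < lower, sprintf("`%s` must be >= %s", name, lower))
  }
  stop_if(x > upper, sprintf("`%s` must be <= %s", name, upper))
  invisible(x)
}

check_seed <- function(seed) {
  stop_if(!is.numeric(seed) || length(seed) != 1L || is.na(seed),
          "`seed` must be a single integer")
  as.integer(seed)
}

# Deterministic sub-seed derived from a numeric series' content, so that
# operations which bootstrap two series independently give each series the
# same resamples regardless of argument order (exact dm antisymmetry).
# Hashing at 8 significant digits keeps the sub-seed stable across a CSV
# round trip of the data.
series_seed <- function(seed, x) {
  h <- sum(utf8ToInt(paste(format(x, digits = 8L), collapse = ",")))
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}
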