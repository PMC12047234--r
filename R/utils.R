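# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' @noRd
stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' @noRd
assert_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  stop_if(!is.numeric(x) || anyNA(x), sprintf("`%s` must be numeric", name))
  lo_ok <- if (open_left) all(x > 0) else all(x >= 0)
  hi_ok <- if (open_right) all(x < 1) else all(x <= 1)
  stop_if(!lo_ok || !hi_ok, sprintf(
    "`%s` must lie in %s0, 1%s", name,
    if (open_left) "(" else "[", if (open_right) ")" else "]"
  ))
  invisible(x)
}

#' @noRd
assert_count <- function(x, name, min = 1L) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
            x != floor(x),
          sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Evaluate `code` under a fixed RNG seed without touching the caller's RNG
# state; a NULL seed runs in the ambient RNG stream.
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' @noRd
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}
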