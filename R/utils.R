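# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a named substream seed from a master seed; stays below 2^31.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.numeric(seed) * 48271 + h * 16807) %% 2147483587
}

stop_input <- function(...) {
  rlang::abort(paste0(...), class = "focuscrawl_input_error")
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_input(name, " must be a single number in [0, 1], got ", deparse(x))
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop_input(name, " must be a ", if (positive) "positive" else "nonnegative",
               " integer, got ", deparse(x))
  }
  invisible(as.integer(x))
}

# Largest-remainder apportionment of `total` items proportional to `shares`.
largest_remainder <- function(total, shares) {
  quota <- total * shares / sum(shares)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    # deterministic: largest fractional remainders first, ties by position
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
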