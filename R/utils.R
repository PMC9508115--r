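#' Derive a child seed from a master seed and a stream name
#'
#' All randomness in the package flows from a single master seed through
#' named substreams ("environment", "ages", "nests", "iter<k>", ...), so each
#' pipeline stage can be re-run in isolation and still reproduce exactly what
#' the full pipeline produced.
#'
#' @param master integer master seed.
#' @param name character stream label.
#' @return an integer seed in `[0, 2^31 - 2]`, deterministic in `(master, name)`.
#' @export
#' @examples
#' substream_seed(42, "ages")
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; doubles stay exact well below 2^53
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(name)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# stop() with the calling function's name stripped of namespace noise
abort_arg <- function(msg) stop(msg, call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort_arg(sprintf("`%s` must be a single number", name))
  }
  if (x < lower || x > upper) {
    abort_arg(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) abort_arg(sprintf("`%s` must be an integer count", name))
  invisible(as.integer(x))
}

# Tiny stable FNV-1a hash of a character scalar, for run-metadata config hashes.
fnv1a_hash <- function(x) {
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
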