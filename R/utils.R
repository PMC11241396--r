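#' @importFrom stats rnorm runif prcomp quantile median sd var cov dist rpois
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics points legend
NULL

# Internal argument checks ----------------------------------------------------

abort_mp <- function(msg, class) {
  stop(structure(
    class = c(class, "morphoprompt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort_mp(sprintf("`%s` must be a single integer >= %d (got %s)",
                     name, min, deparse(x)), "mp_invalid_argument")
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_mp(sprintf("`%s` must be a single number in [0, 1]", name),
             "mp_invalid_argument")
  }
  as.numeric(x)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || (positive && x <= 0)) {
    abort_mp(sprintf("`%s` must be a single finite%s number", name,
                     if (positive) " positive" else ""), "mp_invalid_argument")
  }
  as.numeric(x)
}

# C-locale (radix) ordering so that id ordering never depends on the locale.
order_lex <- function(x) order(x, method = "radix")
sort_lex <- function(x) sort(x, method = "radix")

# Run `code` under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  seed <- check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}
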