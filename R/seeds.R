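#' Derive a reproducible substream seed
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (behaviour name, repetition index, purpose tag, ...) into a 31-bit
#' integer seed.  Each (labels) combination gets its own deterministic
#' stream, so repetitions are reproducible independently of the order in
#' which they are executed.
#'
#' A multiplicative string hash (mod the Mersenne prime 2^31 - 1) is used
#' rather than R's RNG itself so that deriving a seed never perturbs the
#' global random stream.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "smoking", 17, "pairs")
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.character(as.integer(seed)),
             vapply(list(...), as.character, character(1)))
  m <- 2147483647  # 2^31 - 1
  h <- 17
  for (part in parts) {
    for (code in utf8ToInt(part)) {
      h <- (h * 131 + code) %% m
    }
    h <- (h * 131 + 7L) %% m  # separator so c("ab","c") != c("a","bc")
  }
  as.integer(h)
}

# Run code with a temporary RNG seed, restoring the caller's stream.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
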