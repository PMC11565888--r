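#' Derive a reproducible child seed from a parent seed and a label
#'
#' All stochastic generators in evorepair accept a single integer seed. When
#' one run needs several independent random streams (one per population, one
#' per assay), child seeds are derived deterministically from the parent seed
#' and a text label, so that the whole run is reproducible from one integer
#' and streams do not collide.
#'
#' The splitting rule is a multiplicative string hash: the label is folded
#' into an integer `h` via `h <- (h * 31 + byte) mod (2^31 - 1)` over its
#' UTF-8 bytes, and the child seed is `(parent * 48271 + h) mod (2^31 - 1)`.
#' The modulus keeps every derived seed a valid 32-bit R integer.
#'
#' @param seed Parent seed, a single integer.
#' @param label Character label identifying the stream (e.g. `"pop3"`).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "pop1")
#' derive_seed(1L, "pop2") # different stream
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label),
            length(label) == 1)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer((abs(seed) * 48271 + h) %% m)
}

# Set the RNG locally (caller's RNG state is untouched); NULL seed leaves the
# current stream in place.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(seed)
}
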