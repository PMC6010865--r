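#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit sub-seed from a base seed and arbitrary string keys.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() is safe.
derive_seed <- function(seed, ...) {
  keys <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(keys)) h <- (h * 31 + cp) %% 2147483647L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483646) + 1L
}

# Round half away from zero (base round() is round-half-even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mutaccum <- function(msg, class, ...) {
  stop(structure(class = c(class, "mutaccum_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
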