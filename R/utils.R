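#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------

rs_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "reactsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

rs_warn <- function(msg, class = "reactsim_warning") {
  warning(structure(
    class = c(class, "reactsim_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Deterministic string hash ---------------------------------------------------

# djb2 polynomial hash reduced modulo the Mersenne prime 2^31 - 1.  All
# arithmetic stays below 2^53 so the result is identical on every platform
# and every run; fingerprint bit positions depend on nothing else.
rs_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  h
}

# Vectorised convenience: hash each string to a bit position in [1, length].
rs_hash_bit <- function(strings, length) {
  vapply(strings, function(s) (rs_hash(s) %% length) + 1L, numeric(1),
         USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
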