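# Internal helpers shared across modules.

# Derive a child RNG seed from a master seed and a stream index.
# Kept below 2^31-1 so it is always a valid R integer.
derive_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- (as.double(master_seed) * 48271 + as.double(stream) * 16807 + 11) %%
    2147483629
  as.integer(h)
}

# Floor a POSIXct timestamp to the enclosing 30-min grid boundary (UTC).
floor_bin <- function(time, bin_seconds = 1800) {
  structure(floor(as.numeric(time) / bin_seconds) * bin_seconds,
            class = c("POSIXct", "POSIXt"), tzone = "UTC")
}

# Format timestamps the way every CSV writer in the package does, so that
# identical data always serialize to identical bytes.
format_utc <- function(time) {
  format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_utc <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
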