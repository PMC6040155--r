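# internal helpers shared across modules

# deterministic 31-bit hash of a string, for per-target / per-tissue seed streams
.hash_string <- function(s) {
  h <- 0
  for (x in utf8ToInt(as.character(s))) h <- (h * 31 + x) %% 2147483029
  h
}

# derive a reproducible sub-seed from a master seed and a stream key;
# stays below 2^31 so it is a valid R integer seed
.derive_seed <- function(master, key) {
  as.integer((as.numeric(master) %% 1000003 * 2654435 + .hash_string(key)) %% 2147483629)
}

.stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}
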