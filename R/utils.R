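# Internal helpers: argument checks and reproducible RNG substreams.

stop_domain <- function(msg) abort(msg, class = "cdrice_domain_error")
stop_schema <- function(msg) abort(msg, class = "cdrice_schema_error")
stop_validation <- function(msg) abort(msg, class = "cdrice_validation_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_domain(sprintf("`%s` must be in [%s, %s], got %s.",
                        name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Deterministic, platform-independent substream seed derived from a master
# seed and a character key (group or region label). Keying by label rather
# than position makes per-group results invariant to input ordering. All
# arithmetic stays below 2^53 so it is exact in doubles; the result fits in
# a 32-bit integer as required by set.seed().
substream_seed <- function(master_seed, key) {
  m <- 2147483629 # largest prime below 2^31
  h <- 0
  for (b in utf8ToInt(enc2utf8(as.character(key)))) {
    h <- (h * 31 + b) %% m
  }
  s <- as.numeric(master_seed) %% m
  as.integer((h + s * 48271) %% m)
}

# Set the RNG state for a scoped computation when a seed is supplied;
# NULL means "continue the caller's RNG stream".
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
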