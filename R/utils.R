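`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit seed derivation so that pipeline stages and
# simulation trials each get their own reproducible stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.double(seed) * 48271 + as.double(stage) * 10007 + 1) %%
               2147483647)
}

fmt_pct <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f%%"), 100 * x))
}

stop_df <- function(...) stop(..., call. = FALSE)
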