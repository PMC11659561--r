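# Small programmatic fixtures shared across test files.

# Build a dataset from compact per-eye vectors; two eyes per participant
# unless ids are given explicitly.
make_eyes <- function(base, dme = FALSE, ai = NA_character_,
                      level2 = NA_character_, pid = NULL) {
  m <- length(base)
  if (is.null(pid)) {
    pid <- sprintf("T%03d", rep(seq_len(ceiling(m / 2)), each = 2)[seq_len(m)])
  }
  lat <- unlist(lapply(split(seq_len(m), pid)[unique(pid)], function(r)
    c("right", "left")[seq_along(r)]), use.names = FALSE)
  trial_dataset(data.frame(
    participant_id = pid,
    laterality = lat,
    etdrs_base = as.integer(base),
    dme_level1 = rep_len(dme, m),
    ai_output = rep_len(ai, m),
    level2_grade = rep_len(level2, m),
    stringsAsFactors = FALSE))
}

# A dataset where every eye is vtDRD-positive and detected, so the
# bootstrap sensitivity is exactly 1 in every replicate.
perfect_dataset <- function(n_participants = 3) {
  make_eyes(rep(60L, 2 * n_participants), dme = FALSE, ai = "detected")
}

random_trial <- function(n = 50, seed = 1) {
  generate_trial(sim_config(n_participants = n, seed = seed))
}

# plain data.frame comparison, ignoring container metadata
strip_ds <- function(ds) {
  d <- as.data.frame(ds)
  attr(d, "metadata") <- NULL
  rownames(d) <- NULL
  d
}
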