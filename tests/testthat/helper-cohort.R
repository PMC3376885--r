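# One default-parameter cohort (11 sequences x 13 agents, seed 42),
# simulated lazily and shared across test files to keep the suite fast.
.swg_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.swg_cache$cohort)) {
    seqs <- bundled_sequences(warn = FALSE)
    .swg_cache$cohort <- simulate_cohort(seqs, n_per_sequence = 13,
                                         seed = 42L)
  }
  .swg_cache$cohort
}

default_features <- function() {
  if (is.null(.swg_cache$features)) {
    .swg_cache$features <- trial_features(default_cohort())
  }
  .swg_cache$features
}

default_trial_data <- function() {
  if (is.null(.swg_cache$trial_data)) {
    co <- default_cohort()
    ev <- cohort_events(co)
    pa <- cohort_participants(co)
    td <- merge(ev, pa[, c("participant_id", "g")], by = "participant_id")
    td$rt <- td$click_ms - td$onset_ms
    .swg_cache$trial_data <- td
  }
  .swg_cache$trial_data
}

default_participants <- function() {
  cohort_participants(default_cohort())
}
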