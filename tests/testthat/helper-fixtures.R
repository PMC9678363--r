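## Shared fixture builders for the test suite.

## a strictly periodic train
periodic_train <- function(ioi = 0.5, n = 20, start = ioi, id = "p1",
                           source = "human") {
  onset_train(start + ioi * (seq_len(n) - 1), performer_id = id,
              source = source)
}

## an ensemble of independently jittered trains on a common beat grid
jittered_ensemble <- function(n_perf = 3, ioi = 0.5, n_beats = 20,
                              jitter_sd = 0.01, seed = 1) {
  set.seed(seed)
  grid <- ioi * seq_len(n_beats)
  lapply(seq_len(n_perf), function(p) {
    tt <- sort(grid + rnorm(n_beats, 0, jitter_sd))
    onset_train(tt, performer_id = paste0("p", p))
  })
}

## quick CoV of cycle durations
cv_of <- function(times) {
  d <- diff(as.numeric(times))
  sd(d) / mean(d)
}
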