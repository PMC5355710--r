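# Shared fixture builders. Everything is generated in code; no stored data.

# Gaussian R-wave template used to build synthetic ECG traces
make_rwave <- function(fs) 800 * exp(-((seq(-0.02, 0.02, by = 1 / fs)) / 0.008)^2)

# ECG trace with R peaks at the given sample positions
make_ecg <- function(nsamp, peak_at, fs) {
  rw <- make_rwave(fs)
  half <- (length(rw) - 1L) %/% 2L
  ecg <- numeric(nsamp)
  for (pk in peak_at) {
    idx <- (pk - half):(pk + half)
    keep <- idx >= 1 & idx <= nsamp
    ecg[idx[keep]] <- ecg[idx[keep]] + rw[keep]
  }
  ecg
}

# Small K x 56 feature matrix with matching performance, for reduction tests
make_feature_session <- function(K = 60, seed = 42) {
  set.seed(seed)
  load <- rep(c(1, 3, 4), length.out = K)
  y <- pmin(1, pmax(0, 0.9 - 0.07 * load + rnorm(K, 0, 0.03)))
  cols <- as.vector(t(outer(ctl_eeg_channels(), names(ctl_bands()),
                            paste, sep = "_")))
  m <- sapply(cols, function(cn) -load + rnorm(K, 0, 1))
  m <- cbind(m, HR = 60 + 3 * load + rnorm(K, 0, 2))
  list(features = normalize_features(m), y = y)
}

# Small two-session synthetic participant (150 epochs per session) shared
# across test files; cached so it is only generated once per test run.
small_participant <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_participant(operator_profile(),
                                     load_schedule(block_len = 25), seed = 7)
    cache
  }
})
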