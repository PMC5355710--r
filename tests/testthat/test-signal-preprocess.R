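test_that("low-pass filter preserves DC and zero signals and rejects bad cutoffs", {
  fs <- 500
  dc <- ctl_recording(rbind(a = rep(3.3, 2000)), fs, "a")
  out <- lowpass_filter(dc)$samples[1, ]
  expect_lt(max(abs(out - 3.3)) / 3.3, 1e-6)

  z <- ctl_recording(rbind(a = numeric(2000)), fs, "a")
  expect_equal(lowpass_filter(z)$samples[1, ], numeric(2000))

  expect_error(lowpass_filter(dc, cutoff = 250), "Nyquist")
})

test_that("low-pass attenuation at 100 Hz matches the closed-form Butterworth magnitude", {
  fs <- 500
  x <- sin(2 * pi * 100 * seq(0, 4, by = 1 / fs))
  y <- lowpass_filter(ctl_recording(rbind(a = x), fs, "a"))$samples[1, ]
  gain <- sqrt(mean(y[500:length(y)]^2)) / sqrt(0.5)
  # 3rd-order low-pass designed by bilinear transform: magnitude is the
  # analog prototype evaluated at the tan-warped frequency
  expected <- 1 / sqrt(1 + (tan(pi * 100 / fs) / tan(pi * 40 / fs))^6)
  expect_lt(abs(gain - expected) / expected, 0.05)
})

test_that("RLS ocular filter passes clean EEG through and learns a scalar leak", {
  set.seed(11)
  eeg <- rnorm(2000)
  res <- remove_eog_rls(eeg, numeric(2000))
  expect_equal(res$cleaned, eeg)

  eog <- rnorm(5000)
  res <- remove_eog_rls(0.5 * eog, eog, rls_filter_state(order = 1))
  expect_equal(res$coefficients, 0.5, tolerance = 1e-6)
  last <- 2501:5000
  expect_lt(mean(res$cleaned[last]^2) / mean((0.5 * eog[last])^2), 1e-4)
})

test_that("RLS with no forgetting converges to the batch least-squares solution", {
  set.seed(12)
  r <- rnorm(3000)
  s <- rnorm(3000)
  contaminated <- s + 0.8 * r - 0.3 * c(0, r[-3000])
  res <- remove_eog_rls(contaminated, r, rls_filter_state(order = 2, lambda = 1))
  X <- cbind(r, c(0, r[-3000]))
  h_ols <- as.numeric(solve(crossprod(X), crossprod(X, contaminated)))
  expect_lt(max(abs(res$coefficients - h_ols)), 1e-6)
})

test_that("RLS attenuates an injected blink artifact at least tenfold", {
  set.seed(13)
  fs <- 500
  n <- 20000
  eeg_clean <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive"))
  pulse <- 150 * (1 - cos(2 * pi * seq(0, 0.3, by = 1 / fs) / 0.3)) / 2
  eog <- numeric(n)
  for (a in seq(500, n - 500, by = 1500)) {
    idx <- a:(a + length(pulse) - 1L)
    eog[idx] <- eog[idx] + pulse
  }
  contaminated <- eeg_clean + 0.4 * eog
  cleaned <- remove_eog_rls(contaminated, eog)$cleaned
  artifact_before <- mean((contaminated - eeg_clean)^2)
  artifact_after <- mean((cleaned - eeg_clean)^2)
  expect_gt(artifact_before / artifact_after, 10)
})

test_that("epoching yields the documented epoch counts and discards the tail", {
  fs <- 500
  rec <- ctl_recording(rbind(a = numeric(90 * 60 * fs)), fs, "a")
  expect_length(epoch_signal(rec), 540)

  rec10 <- ctl_recording(rbind(a = seq_len(10 * fs)), fs, "a")
  expect_length(epoch_signal(rec10), 1)

  rec25 <- ctl_recording(rbind(a = seq_len(25 * fs)), fs, "a")
  eps <- epoch_signal(rec25)
  expect_length(eps, 2)
  # concatenating the epochs reproduces the record minus the discarded tail
  expect_equal(unlist(lapply(eps, function(e) e$samples[1, ])),
               seq_len(20 * fs), ignore_attr = TRUE)

  short <- ctl_recording(rbind(a = numeric(100)), fs, "a")
  expect_error(epoch_signal(short), "shorter")
})

test_that("epoch periodogram is bin-exact for tones and satisfies Parseval", {
  fs <- 500
  tone <- sin(2 * pi * 10 * seq(0, 10 - 1 / fs, by = 1 / fs))
  sp <- epoch_psd(tone, fs)
  expect_length(sp$power, 400)
  expect_equal(sp$freqs[1], 1.0)
  expect_equal(diff(sp$freqs)[1], 0.1, tolerance = 1e-9)
  in_bin <- sp$power[which.min(abs(sp$freqs - 10))]
  expect_gt(in_bin / sum(sp$power), 0.99)

  expect_equal(epoch_psd(numeric(10 * fs), fs)$power, numeric(400))

  # multi-tone signal entirely inside the 1-40.9 Hz grid: the grid power
  # must carry the whole time-domain mean square (Parseval)
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- 2 * sin(2 * pi * 5 * t) + sin(2 * pi * 12.3 * t) +
    0.5 * cos(2 * pi * 33.7 * t)
  spx <- epoch_psd(x, fs)
  expect_equal(sum(spx$power), mean(x^2), tolerance = 0.01)

  expect_error(epoch_psd(numeric(123), fs), "fs \\* 10")
})

test_that("band powers average the correct bins", {
  uniform <- list(freqs = seq(1, by = 0.1, length.out = 400),
                  power = rep(2.5, 400))
  expect_equal(unname(band_powers(uniform)), rep(2.5, 5))

  spike <- uniform
  spike$power <- ifelse(abs(spike$freqs - 10) < 1e-9, 7, 0)
  bp <- band_powers(spike)
  expect_gt(bp[["alpha"]], 0)
  expect_equal(unname(bp[c("delta", "theta", "beta", "gamma")]), rep(0, 4))

  # brute-force bin-enumeration oracle for the delta band
  hand <- uniform
  hand$power <- numeric(400)
  hand$power[abs(hand$freqs - 2) < 1e-9] <- 4
  hand$power[abs(hand$freqs - 3) < 1e-9] <- 2
  delta_bins <- which(hand$freqs >= 1 - 1e-9 & hand$freqs <= 4 + 1e-9)
  expect_equal(band_powers(hand)[["delta"]], sum(hand$power[delta_bins]) / length(delta_bins))
  expect_length(delta_bins, 31)
})

test_that("heart rate is the mean instantaneous rate over R-R intervals", {
  fs <- 500
  expect_equal(compute_hr(make_ecg(5000, seq(250, 4750, by = 500), fs), fs), 60)
  expect_equal(compute_hr(make_ecg(5000, seq(250, 4750, by = 250), fs), fs), 120)
  expect_equal(compute_hr(make_ecg(5000, cumsum(c(500, 400, 500)), fs), fs), 67.5)
  expect_true(is.na(compute_hr(make_ecg(5000, 2500, fs), fs)))
})

test_that("feature assembly yields 56 normalized columns and handles degeneracy", {
  set.seed(21)
  K <- 8
  band_list <- lapply(seq_len(K), function(k)
    matrix(abs(rnorm(55)), 11, 5,
           dimnames = list(ctl_eeg_channels(), names(ctl_bands()))))
  hr <- c(NA, 62, 65, NA, 70, 68, 64, 66)
  fm <- assemble_and_normalize(band_list, hr)
  expect_equal(ncol(fm), 56)
  expect_equal(nrow(fm), K)
  nonconst <- apply(fm, 2, sd) > 0
  expect_lt(max(abs(colMeans(fm))), 1e-9)
  expect_lt(max(abs(apply(fm[, nonconst], 2, sd) - 1)), 1e-9)

  # constant HR column degenerates to zeros with a warning
  expect_warning(fm2 <- assemble_and_normalize(band_list, rep(60, K)),
                 "zero-variance")
  expect_equal(unname(fm2[, "HR"]), rep(0, K))
})

test_that("normalization is idempotent", {
  set.seed(22)
  m <- matrix(rnorm(200), 20, 10)
  colnames(m) <- paste0("c", 1:10)
  n1 <- normalize_features(m)
  expect_lt(max(abs(normalize_features(n1) - n1)), 1e-12)
})

test_that("the full raw-to-feature path produces a valid session matrix", {
  prof <- operator_profile()
  sched <- load_schedule(counts = c(1, 3, 4, 4, 3, 1), block_len = 1)
  rec <- generate_raw_recording(prof, sched, seed = 3)
  fm <- preprocess_session(rec)
  expect_s3_class(fm, "ctl_features")
  expect_equal(dim(fm), c(6L, 56L))
  expect_lt(max(abs(colMeans(fm))), 1e-9)
})
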