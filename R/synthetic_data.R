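# Synthetic operator data with the statistical structure the monitoring
# method assumes: load-coupled band powers and salient features, performance
# declining with task load, AR(1) temporal noise, and ocular/cardiac
# artifacts in the raw recordings. All fixtures are synthetic stand-ins for
# the (undeposited) human recordings.

ar1_noise <- function(n, phi, sd) {
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

#' Task-load schedule of a session
#'
#' @param counts per-block task counts (default 1, 3, 4, 4, 3, 1).
#' @param block_len epochs per block (default 90, i.e. 15 min of 10-s
#'   epochs; the default session is 540 epochs).
#' @return list with `counts`, `block_len`, `n` (per-epoch task count) and
#'   `total` epochs.
#' @export
load_schedule <- function(counts = c(1, 3, 4, 4, 3, 1), block_len = 90) {
  if (!all(counts %in% c(1, 3, 4))) stop("task counts must be 1, 3 or 4")
  n <- rep(as.integer(counts), each = block_len)
  list(counts = counts, block_len = block_len, n = n, total = length(n))
}

#' Synthetic operator profile
#'
#' The per-channel coupling noise scales are calibrated so that, with the
#' default performance curve, each channel's feature-performance
#' correlation matches published reference levels for the aCAMS operator
#' study (strong for the EEG channels, ~0.74 at F3, weak for heart rate,
#' ~0.32); see [ctl_reference_tables()].
#'
#' @param target_r per-channel target absolute feature-performance
#'   correlations (11 EEG channels + HR).
#' @param y_base,y_slope performance-load line: mean performance is
#'   `y_base - y_slope * n`.
#' @param y_noise_sd,y_phi AR(1) performance noise (stationary s.d. and
#'   lag-1 coefficient).
#' @param feat_phi AR(1) coefficient of the feature noise.
#' @param z discretization coefficients used for the generated labels.
#' @param hr_base,hr_gain heart-rate baseline (beats/min) and per-task
#'   gain for the raw generator.
#' @param blink_rate eye-blink rate (events/min) for the raw generator.
#' @return list of class `ctl_profile`.
#' @export
operator_profile <- function(target_r = NULL,
                             y_base = 0.95, y_slope = 0.07,
                             y_noise_sd = 0.04, y_phi = 0.6,
                             feat_phi = 0.6,
                             z = c(2.3, 2.7, 3.0),
                             hr_base = 65, hr_gain = 4,
                             blink_rate = 12) {
  if (is.null(target_r)) {
    ref <- ctl_reference_tables()$feature_correlation
    target_r <- stats::setNames(ref$mean, ref$feature)
  }
  stopifnot(length(target_r) == 12L, all(target_r > 0 & target_r < 1))
  structure(list(target_r = target_r, y_base = y_base, y_slope = y_slope,
                 y_noise_sd = y_noise_sd, y_phi = y_phi,
                 feat_phi = feat_phi, z = z,
                 hr_base = hr_base, hr_gain = hr_gain,
                 blink_rate = blink_rate),
            class = "ctl_profile")
}

#' Generate one session of salient features, performance and labels
#'
#' Features are a negative linear coupling to the task load plus AR(1)
#' noise; performance is a declining linear function of load plus AR(1)
#' noise, clipped to \[0, 1\]. The per-channel noise scales are derived in
#' closed form from the profile's target correlations so that the realized
#' feature-performance correlations land near them. Labels use the
#' profile's z coefficients with sigma_o estimated from the generated
#' performance unless supplied.
#'
#' @param profile an [operator_profile()].
#' @param schedule a [load_schedule()].
#' @param seed RNG seed.
#' @param sigma_o optional fixed discretization s.d. (e.g. from the
#'   concatenated pair of sessions).
#' @return list with `xprime` (K x 12 matrix), `y`, `C`, `n` (task counts),
#'   `sigma_o`.
#' @export
generate_session_features <- function(profile, schedule = load_schedule(),
                                      seed = 0, sigma_o = NULL) {
  stopifnot(inherits(profile, "ctl_profile"))
  set.seed(seed)
  n <- schedule$n
  K <- schedule$total
  load_sd <- stats::sd(n) * sqrt((K - 1) / K)
  y_load_sd <- profile$y_slope * load_sd
  y_tot_sd <- sqrt(y_load_sd^2 + profile$y_noise_sd^2)
  rho_y <- y_load_sd / y_tot_sd
  y <- profile$y_base - profile$y_slope * n +
    ar1_noise(K, profile$y_phi, profile$y_noise_sd)
  y <- pmin(1, pmax(0, y))
  # per-channel noise s.d. giving corr ~ target: r = rho_f * rho_y with
  # rho_f the load share of the feature s.d. (unit coupling coefficient)
  xprime <- vapply(profile$target_r, function(r) {
    rho_f <- min(r / rho_y, 0.999)
    noise_sd <- load_sd * sqrt(1 / rho_f^2 - 1)
    -n + ar1_noise(K, profile$feat_phi, noise_sd)
  }, numeric(K))
  colnames(xprime) <- names(profile$target_r)
  if (is.null(sigma_o)) sigma_o <- stats::sd(y)
  list(xprime = xprime, y = y,
       C = discretize_performance(y, sigma_o, profile$z),
       n = n, sigma_o = sigma_o)
}

# band-limited noise carrier with per-sample amplitude modulation
band_noise <- function(nsamp, fs, band, amp) {
  lo <- max(band[1], 0.5) / (fs / 2)
  hi <- min(band[2], fs / 2 * 0.95) / (fs / 2)
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  x <- as.numeric(signal::filter(bf$b, bf$a, stats::rnorm(nsamp)))
  x / stats::sd(x) * amp
}

# raised-cosine blink pulse
blink_pulse <- function(fs, dur = 0.3, amp = 150) {
  t <- seq(0, dur, by = 1 / fs)
  amp * (1 - cos(2 * pi * t / dur)) / 2
}

#' Generate a raw multichannel recording
#'
#' EEG channels are sums of band-limited noise carriers whose band
#' amplitudes are modulated by the task load (theta/beta up, alpha down
#' with load); the EOG channel carries a Poisson train of raised-cosine
#' blink pulses which also leaks, scaled, into the frontal EEG channels;
#' the ECG channel is an R-wave impulse train whose rate increases with
#' load.
#'
#' @param profile an [operator_profile()].
#' @param schedule a [load_schedule()]; one epoch is `epoch_len` seconds.
#' @param fs sampling rate (default 500 Hz).
#' @param seed RNG seed.
#' @param epoch_len epoch length in seconds (default 10).
#' @param theta_coupling amplitude scale of the theta carrier (default 1);
#'   doubling it doubles the theta-band amplitude and so quadruples the
#'   theta band power.
#' @param blink_leak fraction of the blink pulse leaking into frontal EEG
#'   (default 0.4; 0 disables leakage).
#' @return a [ctl_recording()] with the canonical 13 channels.
#' @export
generate_raw_recording <- function(profile, schedule = load_schedule(),
                                   fs = 500, seed = 0, epoch_len = 10,
                                   theta_coupling = 1, blink_leak = 0.4) {
  stopifnot(inherits(profile, "ctl_profile"))
  set.seed(seed)
  spe <- round(fs * epoch_len)
  nsamp <- schedule$total * spe
  load_per_sample <- rep(schedule$n, each = spe)
  bands <- ctl_bands()
  base_amp <- c(delta = 8, theta = 6 * theta_coupling, alpha = 10,
                beta = 4, gamma = 2)
  # per-band load modulation (relative amplitude change per manual task)
  mod <- c(delta = 0.05, theta = 0.25, alpha = -0.12,
           beta = 0.15, gamma = 0.08)
  eeg <- vapply(ctl_eeg_channels(), function(ch) {
    sig <- numeric(nsamp)
    for (b in names(bands)) {
      carrier <- band_noise(nsamp, fs, bands[[b]], base_amp[[b]])
      sig <- sig + carrier * (1 + mod[[b]] * (load_per_sample - 1))
    }
    sig
  }, numeric(nsamp))
  # EOG: blink pulse train
  eog <- numeric(nsamp)
  pulse <- blink_pulse(fs)
  n_blinks <- stats::rpois(1, profile$blink_rate * nsamp / fs / 60)
  if (n_blinks > 0) {
    at <- sort(sample.int(nsamp - length(pulse), n_blinks))
    for (a in at) {
      idx <- a:(a + length(pulse) - 1L)
      eog[idx] <- eog[idx] + pulse
    }
  }
  eog <- eog + stats::rnorm(nsamp, 0, 2)
  for (ch in c("F3", "F4", "Fz"))
    eeg[, ch] <- eeg[, ch] + blink_leak * eog
  # ECG: R-wave spikes at a load-dependent rate
  ecg <- numeric(nsamp)
  rwave <- 800 * exp(-((seq(-0.02, 0.02, by = 1 / fs)) / 0.008)^2)
  pos <- 1L
  while (pos < nsamp - length(rwave)) {
    hr <- profile$hr_base + profile$hr_gain * (load_per_sample[pos] - 1)
    rr <- round(60 / hr * fs * stats::runif(1, 0.95, 1.05))
    idx <- pos:(pos + length(rwave) - 1L)
    ecg[idx] <- ecg[idx] + rwave
    pos <- pos + rr
  }
  ecg <- ecg + stats::rnorm(nsamp, 0, 5)
  samples <- rbind(t(eeg), ECG = ecg, EOG = eog)
  rownames(samples) <- c(colnames(eeg), "ECG", "EOG")
  ctl_recording(samples[ctl_channels(), ], fs = fs, labels = ctl_channels())
}

#' Generate a linear NARX process with known structure
#'
#' y(k) = intercept + sum_i bx\[i\] x(k - i + 1) + sum_j by\[j\] y(k - j)
#' + Gaussian noise, with an AR(1) exogenous input. Used as the ground
#' truth for structure-order recovery and predictor tests.
#'
#' @param d1_true,d2_true true exogenous and autoregressive orders.
#' @param bx exogenous coefficients, length `d1_true`.
#' @param by autoregressive coefficients, length `d2_true`; the AR
#'   polynomial must be stable (roots of 1 - sum by_j z^j outside the unit
#'   disk in z^-1).
#' @param noise_sd innovation s.d.
#' @param length_out series length.
#' @param seed RNG seed.
#' @param intercept constant term (default 0.5).
#' @return list with `xprime` (length_out x 1 matrix) and `y`.
#' @export
generate_narx_process <- function(d1_true, d2_true, bx = NULL, by = NULL,
                                  noise_sd = 0.05, length_out = 300,
                                  seed = 0, intercept = 0.5) {
  # defaults put substantial weight on the boundary lags so the true orders
  # are identifiable against the parsimony pressure of the selection
  # objective
  if (is.null(bx)) bx <- 0.5 * 0.8^(seq_len(d1_true) - 1)
  if (is.null(by)) by <- if (d2_true == 0) numeric(0)
                         else if (d2_true == 1) 0.55
                         else c(0.15, rep(0.1, d2_true - 2), 0.55)
  stopifnot(length(bx) == d1_true, length(by) == d2_true)
  if (d2_true > 0 && any(Mod(polyroot(c(1, -by))) <= 1))
    stop("unstable autoregressive coefficients")
  set.seed(seed)
  x <- ar1_noise(length_out, 0.5, 1)
  y <- numeric(length_out)
  burn <- max(d1_true, d2_true, 1)
  y[seq_len(burn)] <- intercept
  for (k in (burn + 1):length_out) {
    ar_term <- if (d2_true > 0)
      sum(by * (y[(k - 1):(k - d2_true)] - intercept)) else 0
    y[k] <- intercept +
      sum(bx * x[k:(k - d1_true + 1)]) + ar_term +
      stats::rnorm(1, 0, noise_sd)
  }
  list(xprime = matrix(x, ncol = 1), y = y)
}

#' Generate a paired two-session synthetic participant
#'
#' Two sessions from one profile with different seeds; the discretization
#' s.d. is computed from the concatenated performance of both sessions, as
#' the labeling procedure prescribes, and applied to both.
#'
#' @param profile an [operator_profile()].
#' @param schedule a [load_schedule()].
#' @param seed master seed (session 1 uses `seed`, session 2 `seed + 1`).
#' @return list with `session1`, `session2` (each as
#'   [generate_session_features()]) and the shared `sigma_o`.
#' @export
generate_participant <- function(profile = operator_profile(),
                                 schedule = load_schedule(), seed = 0) {
  s1 <- generate_session_features(profile, schedule, seed = seed)
  s2 <- generate_session_features(profile, schedule, seed = seed + 1)
  sigma_o <- stats::sd(c(s1$y, s2$y))
  s1$sigma_o <- sigma_o
  s2$sigma_o <- sigma_o
  s1$C <- discretize_performance(s1$y, sigma_o, profile$z)
  s2$C <- discretize_performance(s2$y, sigma_o, profile$z)
  list(session1 = s1, session2 = s2, sigma_o = sigma_o, z = profile$z)
}
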