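# Raw-signal preprocessing: low-pass filtering, RLS ocular artifact removal,
# epoching, spectral band powers, heart rate, and feature-matrix assembly.

#' Canonical channel layout of a recording session
#'
#' Eleven EEG channels (10-20 placement), one ECG and one EOG channel, in the
#' order the rest of the package expects.
#' @export
ctl_channels <- function() {
  c("F3", "F4", "Fz", "C3", "C4", "Cz", "P3", "P4", "Pz", "O1", "O2",
    "ECG", "EOG")
}

#' EEG channel names (the 11 scalp channels, without ECG/EOG)
#' @export
ctl_eeg_channels <- function() ctl_channels()[1:11]

#' Construct a raw multichannel recording
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels channel names, one per row of `samples`.
#' @return an object of class `ctl_recording`.
#' @export
ctl_recording <- function(samples, fs = 500, labels = rownames(samples)) {
  samples <- as.matrix(samples)
  if (is.null(labels)) stop("channel labels are required")
  if (length(labels) != nrow(samples))
    stop("one label per channel row is required")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels),
            class = "ctl_recording")
}

#' @export
print.ctl_recording <- function(x, ...) {
  cat(sprintf("ctl_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# Causal IIR filtering with a constant-level start-up pad so that a signal
# already at steady state (e.g. a DC channel) passes through without an
# initialization transient.
iir_filter_padded <- function(b, a, x, pad = 500L) {
  pad <- min(as.integer(pad), length(x))
  xp <- c(rep(x[1], pad), x)
  yp <- as.numeric(signal::filter(b, a, xp))
  yp[(pad + 1L):length(xp)]
}

#' Low-pass filter all channels of a recording
#'
#' Applies the same causal Butterworth low-pass response to every channel;
#' used to suppress high-frequency EMG contamination before feature
#' extraction.
#'
#' @param rec a [ctl_recording()].
#' @param cutoff cutoff frequency in Hz (default 40).
#' @param order filter order (default 3).
#' @return a filtered `ctl_recording` of identical shape.
#' @export
lowpass_filter <- function(rec, cutoff = 40, order = 3) {
  stopifnot(inherits(rec, "ctl_recording"))
  if (cutoff >= rec$fs / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (rec$fs / 2), type = "low")
  out <- t(apply(rec$samples, 1L, function(ch)
    iir_filter_padded(bf$b, bf$a, ch)))
  ctl_recording(out, fs = rec$fs, labels = rec$labels)
}

#' Create the state of the recursive-least-squares ocular filter
#'
#' @param order filter order M (number of EOG taps), default 3.
#' @param lambda exponential forgetting factor in (0, 1], default 0.99.
#' @param delta inverse-correlation initialization scale; the accumulator
#'   starts at `diag(1/delta, order)`.
#' @export
rls_filter_state <- function(order = 3, lambda = 0.99, delta = 1e-3) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  structure(list(order = order, lambda = lambda,
                 h = numeric(order),
                 P = diag(1 / delta, order)),
            class = "ctl_rls_state")
}

#' Remove ocular artifacts by recursive least squares
#'
#' Adaptive noise cancellation: the EOG reference is passed through an
#' M-tap FIR filter whose coefficients are updated sample-by-sample to
#' minimize the exponentially forgotten squared error between the filter
#' output and the contaminated EEG. The cleaned signal is the a priori
#' residual e(i) = s(i) - v(i).
#'
#' @param eeg contaminated EEG channel (numeric vector).
#' @param eog EOG reference of the same length.
#' @param state a [rls_filter_state()].
#' @return list with `cleaned` (residual series), `coefficients` (final
#'   taps) and `state` (updated filter state).
#' @export
remove_eog_rls <- function(eeg, eog, state = rls_filter_state()) {
  stopifnot(inherits(state, "ctl_rls_state"))
  n <- length(eeg)
  if (length(eog) != n) stop("eeg and eog must have equal length")
  M <- state$order
  if (M > n) stop("filter order exceeds record length")
  lambda <- state$lambda
  h <- state$h
  P <- state$P
  cleaned <- numeric(n)
  # reference regressor at time k is r(k), r(k-1), ..., r(k-M+1)
  for (k in seq_len(n)) {
    idx <- k - seq_len(M) + 1L
    phi <- ifelse(idx >= 1L, eog[pmax(idx, 1L)], 0)
    v <- sum(h * phi)
    e <- eeg[k] - v
    cleaned[k] <- e
    Pphi <- P %*% phi
    denom <- lambda + sum(phi * Pphi)
    gain <- as.numeric(Pphi) / denom
    h <- h + gain * e
    P <- (P - tcrossprod(gain, as.numeric(Pphi))) / lambda
    P <- (P + t(P)) / 2
  }
  state$h <- h
  state$P <- P
  list(cleaned = cleaned, coefficients = h, state = state)
}

#' Split a recording into consecutive non-overlapping epochs
#'
#' @param rec a [ctl_recording()].
#' @param epoch_len epoch length in seconds (default 10).
#' @return list of `ctl_recording` objects, one per complete epoch; a
#'   trailing partial window is discarded.
#' @export
epoch_signal <- function(rec, epoch_len = 10) {
  stopifnot(inherits(rec, "ctl_recording"))
  spe <- round(epoch_len * rec$fs)
  n <- ncol(rec$samples)
  k <- n %/% spe
  if (k < 1L) stop("record is shorter than one epoch")
  lapply(seq_len(k), function(i) {
    ctl_recording(rec$samples[, ((i - 1L) * spe + 1L):(i * spe), drop = FALSE],
                  fs = rec$fs, labels = rec$labels)
  })
}

#' Power spectrum of one 10-s epoch on a 0.1 Hz grid
#'
#' Single rectangular-window periodogram of the full epoch (the epoch length
#' sets the 0.1 Hz resolution), restricted to the 400 bins with centers
#' 1.0, 1.1, ..., 40.9 Hz. Powers are scaled so that the full one-sided
#' periodogram sums to the time-domain mean square (Parseval).
#'
#' @param epoch single-channel numeric vector of exactly `fs * 10` samples.
#' @param fs sampling rate in Hz.
#' @return list with `freqs` (400 bin centers) and `power` (nonnegative).
#' @export
epoch_psd <- function(epoch, fs) {
  n <- length(epoch)
  if (n != round(fs * 10))
    stop("epoch must contain exactly fs * 10 samples")
  X <- stats::fft(epoch)
  # one-sided power: bins 2..n/2 doubled, DC and Nyquist not
  p_full <- Mod(X)^2 / n^2
  half <- n %/% 2
  p <- p_full[2:(half)] * 2
  freqs_all <- (1:(half - 1)) * fs / n        # 0.1 Hz grid when fs*10 = n
  sel <- 1:400 + (round(1 / (fs / n)) - 1L)   # centers 1.0 .. 40.9 Hz
  list(freqs = freqs_all[sel], power = p[sel])
}

#' Band definitions used for feature extraction
#'
#' Delta is evaluated over 1-4 Hz because the spectral grid starts at 1 Hz.
#' @return named list of `c(low, high)` band edges in Hz.
#' @export
ctl_bands <- function() {
  list(delta = c(1, 4), theta = c(5, 8), alpha = c(9, 12),
       beta = c(13, 32), gamma = c(33, 40))
}

#' Average spectral power in the five EEG rhythm bands
#'
#' A bin belongs to a band when `low <= center <= high`; each band power is
#' the mean over its bins.
#'
#' @param spec a spectrum from [epoch_psd()].
#' @param bands band definition list, default [ctl_bands()].
#' @return named numeric vector (delta, theta, alpha, beta, gamma).
#' @export
band_powers <- function(spec, bands = ctl_bands()) {
  vapply(bands, function(b) {
    sel <- spec$freqs >= b[1] - 1e-9 & spec$freqs <= b[2] + 1e-9
    mean(spec$power[sel])
  }, numeric(1))
}

#' Detect R peaks in an ECG segment
#'
#' Band-pass 5-15 Hz (3rd-order Butterworth), then peak picking above an
#' adaptive threshold of 0.6 x the rolling maximum of the filtered signal,
#' with a 250 ms refractory period.
#'
#' @param ecg numeric vector.
#' @param fs sampling rate in Hz.
#' @return integer vector of peak sample indices (possibly empty).
#' @export
detect_rpeaks <- function(ecg, fs) {
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  f <- iir_filter_padded(bf$b, bf$a, ecg - mean(ecg))
  f <- abs(f)
  # rolling maximum over 2-s windows (capped at the record length)
  w <- min(length(f), round(2 * fs))
  nblk <- ceiling(length(f) / w)
  thr <- numeric(length(f))
  for (i in seq_len(nblk)) {
    idx <- ((i - 1L) * w + 1L):min(i * w, length(f))
    thr[idx] <- 0.6 * max(f[idx])
  }
  # floor the local threshold so windows without any beat do not fire on
  # filter ringing or baseline noise
  thr <- pmax(thr, 0.2 * max(f))
  refractory <- round(0.25 * fs)
  peaks <- integer(0)
  k <- 2L
  while (k < length(f)) {
    if (f[k] > thr[k] && f[k] >= f[k - 1L] && f[k] >= f[k + 1L]) {
      peaks <- c(peaks, k)
      k <- k + refractory
    } else {
      k <- k + 1L
    }
  }
  peaks
}

#' Heart rate of one epoch from R-R intervals
#'
#' Mean of the instantaneous rates 60/RR over the R-R intervals within the
#' epoch. Returns `NA` when fewer than two peaks are found; callers forward-
#' fill the previous epoch's value.
#'
#' @param ecg_epoch single-channel ECG vector.
#' @param fs sampling rate in Hz.
#' @return heart rate in beats/min, or `NA_real_`.
#' @export
compute_hr <- function(ecg_epoch, fs) {
  peaks <- detect_rpeaks(ecg_epoch, fs)
  if (length(peaks) < 2L) return(NA_real_)
  rr <- diff(peaks) / fs
  mean(60 / rr)
}

#' Z-score the columns of a feature matrix
#'
#' Each column is centered and scaled by its sample standard deviation over
#' the session. Zero-variance columns are set to all zeros with a warning.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
normalize_features <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  zero <- !is.finite(sdv) | sdv < .Machine$double.eps
  if (any(zero)) {
    warning(sprintf("zero-variance feature column(s) set to zero: %s",
                    paste(colnames(m)[zero], collapse = ", ")))
    sdv[zero] <- 1
  }
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
  out[, zero] <- 0
  out
}

#' Assemble and normalize the per-epoch feature matrix
#'
#' Combines per-channel band powers and heart rate into the K x 56 session
#' feature matrix (11 channels x 5 bands + HR) and z-scores every column.
#' Missing HR values are forward-filled from the previous epoch.
#'
#' @param band_feats numeric matrix K x 55 with columns `{channel}_{band}`
#'   in channel-major order, or a list of per-epoch 11 x 5 matrices.
#' @param hr numeric vector of K heart rates (may contain leading/interior
#'   `NA`s, which are forward-filled; a leading `NA` run takes the first
#'   observed value).
#' @return K x 56 normalized matrix with class `ctl_features`.
#' @export
assemble_and_normalize <- function(band_feats, hr) {
  if (is.list(band_feats)) {
    band_feats <- do.call(rbind, lapply(band_feats, function(m)
      as.numeric(t(m))))
    colnames(band_feats) <- as.vector(t(outer(ctl_eeg_channels(),
                                              names(ctl_bands()),
                                              paste, sep = "_")))
  }
  band_feats <- as.matrix(band_feats)
  K <- nrow(band_feats)
  if (length(hr) != K) stop("band features and HR must cover the same epochs")
  if (ncol(band_feats) != 55L)
    stop("expected 55 band-power columns (11 channels x 5 bands)")
  # forward-fill missing heart rates
  if (all(is.na(hr))) stop("no epoch has a valid heart rate")
  for (k in seq_along(hr)) {
    if (is.na(hr[k])) hr[k] <- if (k > 1L) hr[k - 1L] else hr[which(!is.na(hr))[1L]]
  }
  m <- cbind(band_feats, HR = hr)
  if (is.null(colnames(m)) || anyNA(colnames(m)))
    stop("band feature columns must be named")
  out <- normalize_features(m)
  structure(out, class = c("ctl_features", class(out)))
}

#' Full raw-to-features preprocessing of one session
#'
#' Low-pass filters the recording, removes ocular artifacts from every EEG
#' channel with the RLS filter, cuts 10-s epochs, computes per-channel band
#' powers and per-epoch heart rate, and assembles the normalized K x 56
#' feature matrix.
#'
#' @param rec a [ctl_recording()] with the canonical 13 channels.
#' @param config pipeline configuration, see [ctl_config()].
#' @return K x 56 `ctl_features` matrix.
#' @export
preprocess_session <- function(rec, config = ctl_config()) {
  stopifnot(inherits(rec, "ctl_recording"))
  need <- ctl_channels()
  if (!all(need %in% rec$labels))
    stop("recording must contain channels: ", paste(need, collapse = ", "))
  rec <- ctl_recording(rec$samples[need, , drop = FALSE], rec$fs, need)
  pp <- config$preprocess
  rec <- lowpass_filter(rec, cutoff = pp$lowpass_cutoff,
                        order = pp$lowpass_order)
  eog <- rec$samples["EOG", ]
  for (ch in ctl_eeg_channels()) {
    st <- rls_filter_state(order = pp$rls_order, lambda = pp$rls_lambda)
    rec$samples[ch, ] <- remove_eog_rls(rec$samples[ch, ], eog, st)$cleaned
  }
  epochs <- epoch_signal(rec, epoch_len = pp$epoch_len)
  bands <- config$bands
  band_feats <- lapply(epochs, function(ep) {
    t(vapply(ctl_eeg_channels(), function(ch) {
      band_powers(epoch_psd(ep$samples[ch, ], ep$fs), bands)
    }, numeric(5)))
  })
  hr <- vapply(epochs, function(ep) compute_hr(ep$samples["ECG", ], ep$fs),
               numeric(1))
  assemble_and_normalize(band_feats, hr)
}
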