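# Operator performance indices and five-class cognitive task-load labels.

#' Time-in-error-range performance index
#'
#' Mean over the manually controlled subsystems of the fraction of the
#' segment spent inside the error range. A very low value indicates
#' operator performance breakdown.
#'
#' @param p per-subsystem durations (seconds) inside the error range.
#' @param T segment length in seconds (default 10).
#' @return scalar in \[0, 1\].
#' @export
compute_sie <- function(p, T = 10) {
  if (length(p) == 0L) stop("at least one subsystem is required")
  if (any(p < 0 | p > T)) stop("durations must lie in [0, T]")
  mean(p / T)
}

#' Time-in-transition-zone performance index
#'
#' Same form as [compute_sie()] with the in-transition durations; a low
#' value indicates a vulnerable operator state.
#'
#' @param q per-subsystem durations (seconds) inside the transition zone.
#' @param T segment length in seconds.
#' @return scalar in \[0, 1\].
#' @export
compute_sit <- function(q, T = 10) compute_sie(q, T)

#' Absolute set-point error performance index
#'
#' Mean over subsystems and seconds of |output - set-point| normalized by
#' the error-range length of each subsystem. Higher values indicate lower
#' operator performance.
#'
#' @param d matrix of subsystem outputs, n subsystems x T seconds.
#' @param c set-points, length n.
#' @param L error-range lengths, length n or scalar; must be positive.
#' @return nonnegative scalar.
#' @export
compute_ase <- function(d, c, L) {
  d <- as.matrix(d)
  n <- nrow(d)
  T <- ncol(d)
  if (length(c) == 1L) c <- rep(c, n)
  if (length(L) == 1L) L <- rep(L, n)
  if (length(c) != n || length(L) != n)
    stop("set-points and range lengths must match the number of subsystems")
  if (any(L <= 0)) stop("error-range lengths must be positive")
  sum(abs(d - c) / L) / (n * T)
}

#' Overall operator performance
#'
#' y(k) = min(s_e, s_t)/2 + (1 - s_a_hat)/2, where s_a_hat is the
#' normalized absolute set-point error. Lower y indicates higher cognitive
#' task-load.
#'
#' @param s_e,s_t,s_a_hat index values in \[0, 1\].
#' @return scalar in \[0, 1\] (vectorized over epochs).
#' @export
compute_performance <- function(s_e, s_t, s_a_hat) {
  0.5 * pmin(s_e, s_t) + 0.5 * (1 - s_a_hat)
}

#' Min-max normalize the absolute-error index over a session pair
#'
#' The overall performance formula requires s_a on a \[0, 1\] scale; the
#' raw index is normalized by min-max over the participant's concatenated
#' sessions and clipped to \[0, 1\].
#'
#' @param s_a raw index values.
#' @param lo,hi optional normalization bounds (default the range of `s_a`).
#' @return normalized values in \[0, 1\].
#' @export
normalize_ase <- function(s_a, lo = min(s_a), hi = max(s_a)) {
  if (hi <= lo) return(rep(0, length(s_a)))
  pmin(1, pmax(0, (s_a - lo) / (hi - lo)))
}

#' Discretize performance into the five task-load classes
#'
#' Classes are cut from the top of the performance scale in multiples of
#' the performance standard deviation sigma_o:
#' class 1 for y in \[1 - sigma_o, 1\], class 2 for \[1 - z1 sigma_o,
#' 1 - sigma_o), class 3 for \[1 - z2 sigma_o, 1 - z1 sigma_o), class 4
#' for \[1 - z3 sigma_o, 1 - z2 sigma_o), and class 5 otherwise.
#' Class 1 is "very low" load, class 5 "very high".
#'
#' @param y performance value(s).
#' @param sigma_o standard deviation of the performance series (positive).
#' @param z numeric length-3 vector `c(z1, z2, z3)` with z1 < z2 < z3.
#' @return integer class(es) in 1..5.
#' @export
discretize_performance <- function(y, sigma_o, z) {
  if (sigma_o <= 0) stop("sigma_o must be positive")
  if (length(z) != 3L || any(diff(z) <= 0) || z[1] <= 1)
    stop("z must be increasing with 1 < z1 < z2 < z3")
  cls <- rep(5L, length(y))
  cls[y >= 1 - z[3] * sigma_o] <- 4L
  cls[y >= 1 - z[2] * sigma_o] <- 3L
  cls[y >= 1 - z[1] * sigma_o] <- 2L
  cls[y >= 1 - sigma_o] <- 1L
  cls
}

#' Per-epoch performance series from a per-second subsystem trace
#'
#' Segments a long-form subsystem trace into epochs of `T` seconds, computes
#' the three indices and the overall performance per epoch, and attaches the
#' five-class labels.
#'
#' @param trace data.frame with columns `time_s`, `subsystem`, `value`,
#'   `setpoint`, `L`, `in_error` (0/1, inside the error range),
#'   `in_transition` (0/1, inside the transition zone), `n`.
#' @param T segment length in seconds.
#' @param sigma_o,z discretization parameters; when `sigma_o` is `NULL` it
#'   is estimated as the s.d. of the computed y series.
#' @param ase_bounds optional `c(lo, hi)` normalization bounds for the
#'   absolute-error index (to normalize consistently across sessions).
#' @return data.frame with columns `epoch, s_e, s_t, s_a, y, C`.
#' @export
label_performance <- function(trace, T = 10, sigma_o = NULL,
                              z = c(2.3, 2.7, 3.0), ase_bounds = NULL) {
  need <- c("time_s", "subsystem", "value", "setpoint", "L",
            "in_error", "in_transition")
  if (!all(need %in% names(trace)))
    stop("trace is missing column(s): ",
         paste(setdiff(need, names(trace)), collapse = ", "))
  trace$epoch <- (trace$time_s - min(trace$time_s)) %/% T + 1L
  K <- max(trace$epoch)
  idx <- split(seq_len(nrow(trace)), trace$epoch)
  per <- lapply(idx, function(i) {
    seg <- trace[i, ]
    subs <- split(seq_len(nrow(seg)), seg$subsystem)
    p <- vapply(subs, function(j) sum(seg$in_error[j]), numeric(1))
    q <- vapply(subs, function(j) sum(seg$in_transition[j]), numeric(1))
    d <- t(vapply(subs, function(j) seg$value[j], numeric(length(subs[[1]]))))
    cset <- vapply(subs, function(j) seg$setpoint[j][1], numeric(1))
    Lset <- vapply(subs, function(j) seg$L[j][1], numeric(1))
    c(s_e = compute_sie(p, T), s_t = compute_sit(q, T),
      s_a = compute_ase(d, cset, Lset))
  })
  per <- do.call(rbind, per)
  s_a_hat <- if (is.null(ase_bounds)) normalize_ase(per[, "s_a"])
             else normalize_ase(per[, "s_a"], ase_bounds[1], ase_bounds[2])
  y <- compute_performance(per[, "s_e"], per[, "s_t"], s_a_hat)
  if (is.null(sigma_o)) sigma_o <- stats::sd(y)
  data.frame(epoch = seq_len(K), s_e = per[, "s_e"], s_t = per[, "s_t"],
             s_a = per[, "s_a"], y = y,
             C = discretize_performance(y, sigma_o, z),
             row.names = NULL)
}
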