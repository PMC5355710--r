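# Feature conditioning: adaptive exponential smoothing of the 56 raw
# features and per-channel locality preserving projection down to the
# 12-dimensional salient feature vector.

#' Adaptive exponential smoothing parameters
#'
#' The smoother gain switches among three values according to the size of
#' the innovation |x(k) - eps(k-1)| relative to the series standard
#' deviation: gain `g1` below `a` s.d., `g2` between `a` and `b` s.d.
#' (a suspected motion artifact is tracked more conservatively), and `g3`
#' at or beyond `b` s.d. (a genuine level shift is tracked faster).
#'
#' @param a,b innovation thresholds in s.d. multiples (defaults 1 and 2.2).
#' @param g1,g2,g3 smoothing gains in (0, 1\] (defaults 0.2, 0.1, 0.3).
#' @export
aes_params <- function(a = 1, b = 2.2, g1 = 0.2, g2 = 0.1, g3 = 0.3) {
  stopifnot(a < b, g1 > 0, g1 <= 1, g2 > 0, g2 <= 1, g3 > 0, g3 <= 1)
  list(a = a, b = b, g1 = g1, g2 = g2, g3 = g3)
}

#' Adaptive exponential smoothing of one feature series
#'
#' Recursion eps(k) = (1 - g) eps(k-1) + g x(k) with the step gain g picked
#' by [aes_params()] thresholds; eps(1) = x(1). With a convex gain the
#' smoothed series is a running weighted average, so constant series are
#' fixed points and the output stays within the observed range.
#'
#' @param x numeric series.
#' @param params an [aes_params()] list.
#' @param sigma series scale used by the thresholds; defaults to `sd(x)`.
#'   A zero scale returns the input unchanged with a warning.
#' @return smoothed series of the same length.
#' @export
smooth_aes <- function(x, params = aes_params(), sigma = stats::sd(x)) {
  if (length(x) == 0L) stop("series must be non-empty")
  if (!is.finite(sigma) || sigma <= 0) {
    warning("zero series scale; smoothing skipped")
    return(x)
  }
  out <- numeric(length(x))
  out[1] <- x[1]
  for (k in seq_along(x)[-1]) {
    dev <- abs(x[k] - out[k - 1])
    g <- if (dev < params$a * sigma) params$g1
         else if (dev < params$b * sigma) params$g2
         else params$g3
    out[k] <- (1 - g) * out[k - 1] + g * x[k]
  }
  out
}

#' Smooth every column of a feature matrix
#'
#' @param fm K x p feature matrix (e.g. the 56-column session matrix).
#' @param params an [aes_params()] list.
#' @param sigma optional per-column scales; defaults to column s.d.
#' @return smoothed matrix of the same shape.
#' @export
smooth_features <- function(fm, params = aes_params(), sigma = NULL) {
  fm <- as.matrix(fm)
  if (is.null(sigma)) sigma <- apply(fm, 2L, stats::sd)
  out <- fm
  for (j in seq_len(ncol(fm)))
    out[, j] <- smooth_aes(fm[, j], params, sigma[j])
  out
}

#' Fit a locality preserving projection for one channel
#'
#' Builds a symmetric k-nearest-neighbour graph with heat-kernel weights
#' w_ij = exp(-||x_i - x_j||^2 / t), forms the graph Laplacian L = D - W,
#' and solves the generalized eigenproblem X' L X a = lambda X' D X a for
#' the eigenvector with the smallest eigenvalue (the direction along which
#' neighbouring epochs stay close). The projection vector is unit-
#' normalized; rank-deficient scatter is handled by solving in the span of
#' the non-null eigendirections of X' D X.
#'
#' @param X K x p matrix (p = 5 band powers for one channel).
#' @param neighbors neighbour count for the graph (default 5).
#' @param heat_width heat-kernel width t; default is the median squared
#'   pairwise distance.
#' @return list of class `ctl_lpp` with `mu` (unit projection vector),
#'   `sign` (orientation, set by [orient_lpp()], default +1), `neighbors`
#'   and `heat_width`.
#' @export
fit_lpp <- function(X, neighbors = 5, heat_width = NULL) {
  X <- as.matrix(X)
  K <- nrow(X)
  p <- ncol(X)
  if (K < neighbors + 1) stop("need more rows than neighbours")
  D2 <- as.matrix(stats::dist(X))^2
  if (is.null(heat_width)) {
    hw <- stats::median(D2[upper.tri(D2)])
    if (!is.finite(hw) || hw <= 0) hw <- 1
  } else hw <- heat_width
  # symmetric kNN adjacency
  W <- matrix(0, K, K)
  for (i in seq_len(K)) {
    ord <- order(D2[i, ])
    nb <- setdiff(ord, i)[seq_len(neighbors)]
    W[i, nb] <- exp(-D2[i, nb] / hw)
  }
  W <- pmax(W, t(W))
  Dg <- diag(rowSums(W))
  L <- Dg - W
  A <- crossprod(X, L %*% X)   # X' L X
  B <- crossprod(X, Dg %*% X)  # X' D X
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  # solve in the non-null subspace of B
  eb <- eigen(B, symmetric = TRUE)
  tol <- max(eb$values) * 1e-10
  keep <- eb$values > tol
  if (!any(keep)) stop("degenerate scatter: all band columns constant")
  if (!all(keep)) warning("rank-deficient scatter; solving in subspace")
  V <- eb$vectors[, keep, drop = FALSE]
  S <- V %*% diag(1 / sqrt(eb$values[keep]), sum(keep))  # whitening map
  M <- crossprod(S, A %*% S)
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  mu <- S %*% em$vectors[, which.min(em$values)]
  mu <- as.numeric(mu) / sqrt(sum(mu^2))
  # deterministic base orientation: largest-|entry| component positive
  j <- which.max(abs(mu))
  if (mu[j] < 0) mu <- -mu
  structure(list(mu = mu, sign = 1, neighbors = neighbors, heat_width = hw),
            class = "ctl_lpp")
}

#' Orient a fitted projection against the training performance
#'
#' Fixes the projection sign so that the training-set projection correlates
#' nonnegatively with performance.
#'
#' @param mapping a `ctl_lpp` object.
#' @param X training matrix used for the fit.
#' @param y training performance series.
#' @return the mapping with `sign` set to +1 or -1.
#' @export
orient_lpp <- function(mapping, X, y) {
  sc <- as.numeric(as.matrix(X) %*% mapping$mu)
  r <- suppressWarnings(stats::cor(sc, y))
  mapping$sign <- if (is.finite(r) && r < 0) -1 else 1
  mapping
}

#' Project band powers to the channel's scalar feature
#'
#' @param mapping a fitted `ctl_lpp`.
#' @param X K x p matrix with the fitting dimensionality.
#' @return numeric vector `sign * X mu`.
#' @export
project_lpp <- function(mapping, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(mapping$mu)) stop("dimension mismatch")
  mapping$sign * as.numeric(X %*% mapping$mu)
}

#' Absolute feature-performance correlation
#'
#' @param x feature series.
#' @param y performance series of the same length (>= 3).
#' @return |Pearson r| in \[0, 1\], or `NA` if either series has zero
#'   variance.
#' @export
feature_performance_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("series must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  abs(stats::cor(x, y))
}

# column indices of one channel's five bands in the 56-column matrix
channel_band_cols <- function(channel) {
  paste(channel, names(ctl_bands()), sep = "_")
}

#' Fit the per-channel feature reduction on a training session
#'
#' Smooths all 56 feature columns with adaptive exponential smoothing, fits
#' one locality preserving projection per EEG channel on its 5 smoothed band
#' powers, and orients each projection against the training performance.
#'
#' @param fm_train K x 56 training feature matrix (normalized).
#' @param y_train training performance series (length K).
#' @param config pipeline configuration, see [ctl_config()].
#' @return list of class `ctl_reduction` with per-channel mappings, the AES
#'   parameters and the training column scales.
#' @export
fit_feature_reduction <- function(fm_train, y_train, config = ctl_config()) {
  fm_train <- as.matrix(fm_train)
  stopifnot(ncol(fm_train) == 56L, nrow(fm_train) == length(y_train))
  params <- do.call(aes_params, config$aes)
  sigma <- apply(fm_train, 2L, stats::sd)
  names(sigma) <- colnames(fm_train)
  sm <- smooth_features(fm_train, params, sigma)
  maps <- lapply(ctl_eeg_channels(), function(ch) {
    Xc <- sm[, channel_band_cols(ch), drop = FALSE]
    m <- fit_lpp(Xc, neighbors = config$lpp$neighbors,
                 heat_width = config$lpp$heat_width)
    orient_lpp(m, Xc, y_train)
  })
  names(maps) <- ctl_eeg_channels()
  structure(list(mappings = maps, aes = params, sigma = sigma),
            class = "ctl_reduction")
}

#' Apply a fitted reduction to a session
#'
#' Smooths with the training-session scales and projects each channel with
#' its frozen mapping; heart rate is smoothed and passed through, giving the
#' K x 12 salient feature matrix (11 channel projections + HR).
#'
#' @param reduction a `ctl_reduction` from [fit_feature_reduction()].
#' @param fm K x 56 feature matrix.
#' @return K x 12 matrix with channel names plus `HR`.
#' @export
apply_feature_reduction <- function(reduction, fm) {
  fm <- as.matrix(fm)
  stopifnot(inherits(reduction, "ctl_reduction"), ncol(fm) == 56L)
  sm <- smooth_features(fm, reduction$aes, reduction$sigma[colnames(fm)])
  proj <- vapply(ctl_eeg_channels(), function(ch) {
    project_lpp(reduction$mappings[[ch]],
                sm[, channel_band_cols(ch), drop = FALSE])
  }, numeric(nrow(fm)))
  cbind(proj, HR = sm[, "HR"])
}
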