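# Dynamic task-load classification: least-squares SVM regression components,
# the two NARX predictor variants, structure-order selection, discretization
# and multiclass evaluation.

# kernel matrices ------------------------------------------------------------

kernel_rbf <- function(X1, X2, sigma2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-pmax(d2, 0) / sigma2)
}

kernel_linear <- function(X1, X2) tcrossprod(as.matrix(X1), as.matrix(X2))

kernel_matrix <- function(X1, X2, kernel, sigma2 = 500) {
  switch(kernel,
         rbf = kernel_rbf(X1, X2, sigma2),
         linear = kernel_linear(X1, X2),
         stop("unknown kernel: ", kernel))
}

# LSSVM regression component --------------------------------------------------

#' Train a least-squares SVM regression component
#'
#' Solves the equality-constrained dual linear system
#' \deqn{\begin{bmatrix} 0 & 1^\top \\ 1 & K + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}}
#' so that the predictor is f(x) = sum_i alpha_i K(x_i, x) + b and the
#' multipliers sum to zero.
#'
#' @param X n x p matrix of training inputs (a vector is treated as one
#'   column).
#' @param y length-n targets.
#' @param kernel `"rbf"` or `"linear"`.
#' @param gamma_reg regularization parameter (default 100).
#' @param sigma2 RBF kernel width sigma^2 (default 500).
#' @return list of class `ctl_lssvm` with `X`, `alpha`, `b`, `kernel`,
#'   `sigma2`, `gamma_reg`.
#' @export
train_lssvm <- function(X, y, kernel = c("rbf", "linear"),
                        gamma_reg = 100, sigma2 = 500) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L || length(y) != n) stop("X rows and y must match, n >= 1")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("training data must be finite")
  K <- kernel_matrix(X, X, kernel, sigma2)
  A <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(1 / gamma_reg, n)))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    warning("singular LSSVM system; ridge-perturbing the diagonal")
    A[-1, -1] <- A[-1, -1] + diag(1e-10, n)
    solve(A, rhs)
  })
  structure(list(X = X, alpha = sol[-1], b = sol[1], kernel = kernel,
                 sigma2 = sigma2, gamma_reg = gamma_reg),
            class = "ctl_lssvm")
}

#' Predict with a trained LSSVM component
#'
#' @param model a `ctl_lssvm` from [train_lssvm()].
#' @param X new inputs, m x p (a vector is one row when p > 1, else one
#'   column).
#' @return length-m numeric predictions.
#' @export
predict_lssvm <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$X) && nrow(X) == ncol(model$X)) X <- t(X)
  if (ncol(X) != ncol(model$X)) stop("input dimension mismatch")
  K <- kernel_matrix(X, model$X, model$kernel, model$sigma2)
  as.numeric(K %*% model$alpha + model$b)
}

# NARX regressor construction -------------------------------------------------

#' Build supervised NARX regressor pairs from a session
#'
#' For each usable epoch k the exogenous block stacks the current and
#' d1 - 1 past salient feature vectors (p * d1 values) and the
#' autoregressive block stacks the d2 lagged performances; training uses
#' the measured performance in the AR slots (teacher forcing). The first
#' usable epoch is k0 = max(d1, d2 + 1).
#'
#' @param xprime K x p salient feature matrix (a vector is one column).
#' @param y measured performance, length K.
#' @param d1 exogenous order (>= 1).
#' @param d2 autoregressive order (>= 1).
#' @return list with `exo` (rows of stacked features), `ar` (lagged
#'   performances), `target`, and `k` (epoch indices of the rows).
#' @export
build_narx_regressors <- function(xprime, y, d1, d2) {
  xprime <- as.matrix(xprime)
  K <- nrow(xprime)
  if (length(y) != K) stop("feature and performance lengths differ")
  if (d1 < 1 || d2 < 1) stop("orders must be >= 1")
  k0 <- max(d1, d2 + 1)
  if (K <= k0) stop("series too short for the requested orders")
  ks <- k0:K
  stack_rows <- function(v) if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
  exo <- stack_rows(vapply(ks, function(k)
    as.numeric(t(xprime[k:(k - d1 + 1), , drop = FALSE])),
    numeric(ncol(xprime) * d1)))
  ar <- stack_rows(vapply(ks, function(k) y[(k - 1):(k - d2)], numeric(d2)))
  list(exo = exo, ar = ar, target = y[ks], k = ks)
}

#' Fit a dynamic NARX performance predictor
#'
#' Trains the two frozen LSSVM components on a training session: an RBF
#' component mapping the stacked exogenous features to performance, and a
#' linear component mapping the lagged performances to performance (teacher
#' forced). The prediction is a fixed convex combination of the component
#' outputs: weights (0.1, 0.9) for variant `lssvm1`, and (0.02, 0.18, 0.8)
#' for `lssvm2`, whose third component is a local linear regressor refit at
#' every prediction step on a sliding window of four recent measured
#' samples.
#'
#' @param xprime K x p training feature matrix.
#' @param y measured training performance, length K.
#' @param d1,d2 structure orders.
#' @param variant `"lssvm1"` or `"lssvm2"`.
#' @param gamma_reg,sigma2 LSSVM hyperparameters.
#' @param weights optional override of the combination weights (must sum
#'   to 1).
#' @return object of class `ctl_narx`.
#' @export
fit_narx <- function(xprime, y, d1, d2, variant = c("lssvm2", "lssvm1"),
                     gamma_reg = 100, sigma2 = 500, weights = NULL) {
  variant <- match.arg(variant)
  reg <- build_narx_regressors(xprime, y, d1, d2)
  if (is.null(weights))
    weights <- if (variant == "lssvm1") c(0.1, 0.9) else c(0.02, 0.18, 0.8)
  nw <- if (variant == "lssvm1") 2L else 3L
  if (length(weights) != nw || abs(sum(weights) - 1) > 1e-9)
    stop("variant ", variant, " needs ", nw, " weights summing to 1")
  comp_exo <- train_lssvm(reg$exo, reg$target, "rbf",
                          gamma_reg = gamma_reg, sigma2 = sigma2)
  comp_ar <- train_lssvm(reg$ar, reg$target, "linear",
                         gamma_reg = gamma_reg, sigma2 = sigma2)
  structure(list(d1 = d1, d2 = d2, variant = variant, weights = weights,
                 comp_exo = comp_exo, comp_ar = comp_ar,
                 gamma_reg = gamma_reg, sigma2 = sigma2, window = 4L,
                 p = ncol(as.matrix(xprime))),
            class = "ctl_narx")
}

# local four-sample regressor of the lssvm2 third term
local_lssvm_predict <- function(y, k, d2, gamma_reg) {
  js <- (k - 5):(k - 2)
  if (js[1] - d2 < 1) return(NA_real_)
  Xl <- t(vapply(js, function(j) y[(j - 1):(j - d2)], numeric(d2)))
  m <- train_lssvm(Xl, y[js], "linear", gamma_reg = gamma_reg)
  predict_lssvm(m, matrix(y[(k - 1):(k - d2)], nrow = 1))
}

#' Run a NARX predictor over a session
#'
#' Produces the predicted performance stream. In the default free-running
#' mode the autoregressive component runs on the predictor's own past
#' outputs; the first k0 - 1 epochs (k0 = max(d1, d2 + 1)) are warm-up and
#' copy the measured performance. In `"one_step"` mode the autoregressive
#' slots take the measured performance instead (teacher forcing), giving
#' one-step-ahead predictions. Variant `lssvm2` additionally refits its
#' local linear regressor at every step on the four measured samples
#' j = k-5 .. k-2 (skipped, with the remaining weights renormalized, while
#' the window is not yet fully inside the record).
#'
#' @param model a `ctl_narx` from [fit_narx()].
#' @param xprime K x p feature matrix of the session to predict.
#' @param y measured performance: required in full for `lssvm2` and for
#'   one-step mode; for free-running `lssvm1` only the first k0 - 1 values
#'   are used (warm-up).
#' @param mode `"free_run"` (default) or `"one_step"`.
#' @return numeric vector of K predicted performances.
#' @export
predict_narx <- function(model, xprime, y,
                         mode = c("free_run", "one_step")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ctl_narx"))
  xprime <- as.matrix(xprime)
  K <- nrow(xprime)
  d1 <- model$d1; d2 <- model$d2
  k0 <- max(d1, d2 + 1)
  if (K < k0) stop("session shorter than the warm-up length")
  if (length(y) < k0 - 1) stop("measured performance needed for warm-up")
  if (mode == "one_step" && length(y) < K)
    stop("one-step mode needs the full measured performance series")
  yhat <- numeric(K)
  if (k0 > 1) yhat[1:(k0 - 1)] <- y[1:(k0 - 1)]
  for (k in k0:K) {
    ar_hist <- if (mode == "one_step") y else yhat
    yhat[k] <- predict_narx_step(model, xprime, ar_hist, y, k)
  }
  yhat
}

# one prediction step: xprime rows and ar_hist/y entries before k must be
# populated; components are only evaluated when their weight is nonzero
predict_narx_step <- function(model, xprime, ar_hist, y, k) {
  d1 <- model$d1; d2 <- model$d2
  w <- model$weights
  f1 <- function() {
    exo <- as.numeric(t(xprime[k:(k - d1 + 1), , drop = FALSE]))
    predict_lssvm(model$comp_exo, matrix(exo, nrow = 1))
  }
  f2 <- function() predict_lssvm(model$comp_ar,
                                 matrix(ar_hist[(k - 1):(k - d2)], nrow = 1))
  wsum12 <- function(w1, w2) {
    out <- 0
    if (w1 != 0) out <- out + w1 * f1()
    if (w2 != 0) out <- out + w2 * f2()
    out
  }
  if (model$variant == "lssvm1") return(wsum12(w[1], w[2]))
  if (length(y) < k - 1) stop("lssvm2 needs measured performance to k - 1")
  f3 <- if (k - 5 - d2 >= 1) local_lssvm_predict(y, k, d2, model$gamma_reg)
        else NA_real_
  if (is.na(f3)) {
    # local window not yet inside the record: renormalize the frozen
    # weights; if they are both zero, hold the last measured performance
    if (sum(w[1:2]) == 0) return(y[k - 1])
    wsum12(w[1] / sum(w[1:2]), w[2] / sum(w[1:2]))
  } else {
    wsum12(w[1], w[2]) + w[3] * f3
  }
}

# teacher-forced fitted values on the training series (used by structure
# scoring: AR slots take measured performance)
narx_training_fit <- function(model, xprime, y) {
  reg <- build_narx_regressors(xprime, y, model$d1, model$d2)
  f1 <- predict_lssvm(model$comp_exo, reg$exo)
  f2 <- predict_lssvm(model$comp_ar, reg$ar)
  if (model$variant == "lssvm1") {
    fit <- model$weights[1] * f1 + model$weights[2] * f2
  } else {
    fit <- numeric(length(reg$k))
    for (i in seq_along(reg$k)) {
      k <- reg$k[i]
      f3 <- if (k - 5 - model$d2 >= 1)
        local_lssvm_predict(y, k, model$d2, model$gamma_reg) else NA_real_
      w <- model$weights
      fit[i] <- if (is.na(f3)) {
        w12 <- w[1:2] / sum(w[1:2])
        w12[1] * f1[i] + w12[2] * f2[i]
      } else w[1] * f1[i] + w[2] * f2[i] + w[3] * f3
    }
  }
  list(fitted = fit, target = reg$target, k = reg$k)
}

#' Select the NARX structure orders on a grid
#'
#' Evaluates J(d1, d2) = tau1 * r_e + tau2 * n_theta / n_theta_max over the
#' integer grid, where r_e is the teacher-forced training RMSE and
#' n_theta = p * d1 + 2 * d2 counts the regressor length (the model
#' complexity; the AR order enters both the frozen and the local
#' autoregressive terms). Ties are broken by smaller d1 + d2, then smaller
#' d1.
#'
#' @param xprime K x p training features.
#' @param y measured training performance.
#' @param variant `"lssvm1"` or `"lssvm2"`.
#' @param d1_grid,d2_grid candidate orders (defaults 1..15).
#' @param tau objective weights `c(tau1, tau2)` (default `c(0.8, 0.2)`).
#' @param gamma_reg,sigma2 LSSVM hyperparameters.
#' @return list of class `ctl_structure_search` with `J` (matrix indexed
#'   \[d1, d2\]), `r_e` matrix, `d1`, `d2` (selected), `n_cells`.
#' @export
select_structure <- function(xprime, y, variant = c("lssvm1", "lssvm2"),
                             d1_grid = 1:15, d2_grid = 1:15,
                             tau = c(0.8, 0.2),
                             gamma_reg = 100, sigma2 = 500) {
  variant <- match.arg(variant)
  xprime <- as.matrix(xprime)
  p <- ncol(xprime)
  n_theta_max <- p * max(d1_grid) + 2 * max(d2_grid)
  J <- matrix(NA_real_, length(d1_grid), length(d2_grid),
              dimnames = list(d1_grid, d2_grid))
  r_e <- J
  for (i in seq_along(d1_grid)) for (j in seq_along(d2_grid)) {
    d1 <- d1_grid[i]; d2 <- d2_grid[j]
    m <- fit_narx(xprime, y, d1, d2, variant,
                  gamma_reg = gamma_reg, sigma2 = sigma2)
    tf <- narx_training_fit(m, xprime, y)
    r <- sqrt(mean((tf$target - tf$fitted)^2))
    r_e[i, j] <- r
    J[i, j] <- tau[1] * r + tau[2] * (p * d1 + 2 * d2) / n_theta_max
  }
  # argmin with deterministic tie-breaking
  cand <- which(J <= min(J) + 1e-12, arr.ind = TRUE)
  d1c <- d1_grid[cand[, 1]]; d2c <- d2_grid[cand[, 2]]
  ord <- order(d1c + d2c, d1c)
  sel <- ord[1]
  structure(list(J = J, r_e = r_e, d1 = d1c[sel], d2 = d2c[sel],
                 n_cells = length(J), tau = tau, variant = variant),
            class = "ctl_structure_search")
}

#' Discretize predicted performance into task-load classes
#'
#' @param yhat predicted performance stream.
#' @param sigma_o,z discretization parameters (see
#'   [discretize_performance()]).
#' @return integer classes in 1..5.
#' @export
classify_ctl <- function(yhat, sigma_o, z) {
  discretize_performance(yhat, sigma_o, z)
}

#' Evaluate a five-class task-load classification
#'
#' Builds the 5 x 5 confusion matrix (rows = predicted class, columns =
#' target class), the overall accuracy, the per-class accuracy (column
#' recall; `NA` for classes absent from the targets), and false
#' positive/negative rates for the four cumulative binary splits: in case
#' m the negative class is classes 1..m and the positive class is classes
#' m+1..5, FPR = FP / (FP + TN), FNR = FN / (FN + TP).
#'
#' @param predicted,target integer class vectors (1..5) of equal length,
#'   or `predicted` may be a ready 5 x 5 confusion matrix (rows =
#'   predicted) with `target` missing.
#' @return list of class `ctl_evaluation` with `confusion`, `acc`,
#'   `acc_class`, and `cases` (data.frame with case, fpr, fnr).
#' @export
evaluate_classification <- function(predicted, target = NULL) {
  if (is.matrix(predicted) && is.null(target)) {
    if (!all(dim(predicted) == c(5L, 5L)))
      stop("confusion matrix must be 5 x 5")
    cm <- predicted
  } else {
    if (length(predicted) != length(target)) stop("length mismatch")
    cm <- table(factor(predicted, levels = 1:5),
                factor(target, levels = 1:5))
    cm <- matrix(as.numeric(cm), 5, 5)
  }
  dimnames(cm) <- list(predicted = 1:5, target = 1:5)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  colsum <- colSums(cm)
  acc_class <- ifelse(colsum > 0, diag(cm) / colsum, NA_real_)
  cases <- data.frame(case = 1:4, fpr = NA_real_, fnr = NA_real_)
  for (m in 1:4) {
    neg <- 1:m; pos <- (m + 1):5
    tn <- sum(cm[neg, neg]); fp <- sum(cm[pos, neg])
    fn <- sum(cm[neg, pos]); tp <- sum(cm[pos, pos])
    cases$fpr[m] <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
    cases$fnr[m] <- if (fn + tp > 0) fn / (fn + tp) else NA_real_
  }
  structure(list(confusion = cm, acc = acc, acc_class = acc_class,
                 cases = cases, n = total),
            class = "ctl_evaluation")
}

#' @export
print.ctl_evaluation <- function(x, ...) {
  cat(sprintf("5-class evaluation of %d epochs, overall accuracy %.4f\n",
              x$n, x$acc))
  print(x$confusion)
  cat("per-class accuracy:",
      paste(sprintf("%.4f", x$acc_class), collapse = " "), "\n")
  invisible(x)
}

#' Paired Cohen's d effect size
#'
#' mean(a - b) / sd(a - b); `NA` when the differences have zero spread.
#'
#' @param a,b paired samples of equal length >= 2.
#' @return scalar effect size.
#' @export
cohens_d_paired <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired samples of equal length >= 2 required")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) return(NA_real_)
  mean(d) / s
}
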