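test_that("LSSVM training satisfies the constrained-dual structure", {
  # one sample: the sum constraint forces alpha = 0, so f is constant y1
  m <- train_lssvm(matrix(2.5), 0.7, "rbf")
  expect_equal(m$alpha, 0)
  expect_equal(m$b, 0.7)
  expect_equal(predict_lssvm(m, matrix(c(-10, 0, 10))), rep(0.7, 3))

  # antisymmetric pair with a linear kernel: zero bias by symmetry
  m2 <- train_lssvm(matrix(c(-1, 1)), c(-1, 1), "linear")
  expect_equal(m2$b, 0, tolerance = 1e-12)
  expect_equal(sum(m2$alpha), 0, tolerance = 1e-12)

  # interpolation limit: large gamma drives training error to zero
  set.seed(51)
  x <- matrix(seq(0, 3, length.out = 10))
  y <- sin(x[, 1])
  m3 <- train_lssvm(x, y, "rbf", gamma_reg = 1e6, sigma2 = 1)
  expect_lt(mean((predict_lssvm(m3, x) - y)^2), 1e-6)
})

test_that("LSSVM predictions match an independent two-solve dual oracle", {
  set.seed(52)
  for (kernel in c("rbf", "linear")) {
    X <- matrix(rnorm(50 * 3), 50, 3)
    y <- X[, 1] - 0.5 * X[, 2]^2 + rnorm(50, 0, 0.1)
    m <- train_lssvm(X, y, kernel)
    # oracle: eliminate the bias analytically (two solves against the
    # regularized kernel matrix) instead of solving the bordered system
    K <- if (kernel == "rbf")
      exp(-as.matrix(dist(X))^2 / m$sigma2) else tcrossprod(X)
    H <- K + diag(1 / m$gamma_reg, 50)
    eta <- solve(H, rep(1, 50))
    nu <- solve(H, y)
    b <- sum(nu) / sum(eta)
    alpha <- nu - b * eta
    Xnew <- matrix(rnorm(10 * 3), 10, 3)
    Knew <- if (kernel == "rbf") {
      d2 <- outer(rowSums(Xnew^2), rowSums(X^2), "+") - 2 * Xnew %*% t(X)
      exp(-pmax(d2, 0) / m$sigma2)
    } else Xnew %*% t(X)
    expect_lt(max(abs(predict_lssvm(m, Xnew) -
                      as.numeric(Knew %*% alpha + b))), 1e-8)
    expect_equal(sum(m$alpha), 0, tolerance = 1e-8)
  }
})

test_that("NARX regressor construction does the index bookkeeping", {
  set.seed(53)
  K <- 30
  xp <- matrix(rnorm(K * 12), K, 12)
  y <- runif(K)
  r11 <- build_narx_regressors(xp, y, 1, 1)
  expect_equal(r11$exo[1, ], xp[2, ], ignore_attr = TRUE)
  expect_equal(r11$ar[1, 1], y[1])
  expect_equal(nrow(r11$exo), K - 2 + 1)

  r35 <- build_narx_regressors(xp, y, 3, 5)
  expect_equal(ncol(r35$exo), 36)
  expect_equal(ncol(r35$ar), 5)
  expect_equal(nrow(r35$exo), K - max(3, 5 + 1) + 1)
  expect_equal(r35$ar[1, ], y[5:1], ignore_attr = TRUE)
  expect_error(build_narx_regressors(xp[1:5, ], y[1:5], 3, 5), "short")
})

test_that("the combined predictor is a convex combination of its components", {
  # constant training performance makes every component predict the same
  # constant, so the combination returns it for any weights
  set.seed(54)
  xp <- matrix(rnorm(40 * 2), 40, 2)
  y <- rep(0.6, 40)
  for (variant in c("lssvm1", "lssvm2")) {
    m <- fit_narx(xp, y, 2, 3, variant)
    yh <- predict_narx(m, xp, y)
    expect_equal(yh, rep(0.6, 40), tolerance = 1e-6)
  }

  # degenerate weights reduce the model to the static exogenous regression
  y2 <- 0.5 + 0.3 * sin(seq_len(40) / 5) + rnorm(40, 0, 0.01)
  m1 <- fit_narx(xp, y2, 2, 3, "lssvm1", weights = c(1, 0))
  yh1 <- predict_narx(m1, xp, y2)
  reg <- build_narx_regressors(xp, y2, 2, 3)
  static <- predict_lssvm(m1$comp_exo, reg$exo)
  expect_equal(yh1[reg$k], static)
})

test_that("one-step prediction tracks a noiseless performance-scaled NARX process", {
  # exogenous gains scaled so the performance series has the spread of an
  # operator session (s.d. ~ 0.1 on the [0, 1] performance scale)
  proc <- generate_narx_process(2, 3, bx = c(0.04, 0.03), noise_sd = 0,
                                length_out = 200, seed = 55)
  m <- fit_narx(proc$xprime, proc$y, 2, 3, "lssvm1")
  yh <- predict_narx(m, proc$xprime, proc$y, mode = "one_step")
  warm <- 20:200
  expect_lt(sqrt(mean((yh[warm] - proc$y[warm])^2)), 0.05)
  # free running degrades gracefully but stays well inside the series range
  yf <- predict_narx(m, proc$xprime, proc$y)
  expect_true(all(yf[warm] > min(proc$y) - 0.2 & yf[warm] < max(proc$y) + 0.2))
})

test_that("local measured-history regressor reproduces constant performance", {
  set.seed(56)
  xp <- matrix(rnorm(60), 30, 2)
  y <- c(runif(10), rep(0.8, 20))
  m <- fit_narx(xp, y, 1, 2, "lssvm2", weights = c(0, 0, 1))
  yh <- predict_narx(m, xp, y)
  # once the 4-sample window sits in the constant stretch, the local fit
  # returns the constant exactly
  expect_equal(yh[20:30], rep(0.8, 11), tolerance = 1e-6)
})

test_that("structure search scores the grid with the documented objective", {
  proc <- generate_narx_process(1, 2, length_out = 80, seed = 57)
  ss <- select_structure(proc$xprime, proc$y, "lssvm1",
                         d1_grid = 1:3, d2_grid = 1:3)
  expect_equal(length(ss$J), 9)
  # J decomposes exactly into accuracy and complexity terms, so a cell
  # with zero training error and maximal complexity would score tau2
  p <- 1
  n_theta <- outer(1:3 * p, 2 * (1:3), "+")
  n_theta_max <- p * 3 + 2 * 3
  expect_equal(ss$J, 0.8 * ss$r_e + 0.2 * n_theta / n_theta_max,
               ignore_attr = TRUE)
  expect_equal(unname(ss$J[3, 3] - 0.8 * ss$r_e[3, 3]), 0.2)
})

test_that("classification delegates to the performance discretization", {
  z <- c(2.3, 2.7, 3.0)
  expect_equal(classify_ctl(1, 0.1, z), 1L)
  set.seed(58)
  y <- runif(100)
  expect_equal(classify_ctl(y, 0.1, z), discretize_performance(y, 0.1, z))
  # predictions shifted far down leave the top class
  y1 <- rep(0.99, 10)
  expect_true(all(classify_ctl(y1 - 4 * 0.1, 0.1, z) >= 4))
})

test_that("evaluation metrics satisfy conservation and perfection checks", {
  set.seed(59)
  target <- sample(1:5, 400, replace = TRUE)
  pred <- target
  flip <- sample(400, 60)
  pred[flip] <- sample(1:5, 60, replace = TRUE)
  ev <- evaluate_classification(pred, target)
  expect_equal(sum(ev$confusion), 400)
  expect_equal(unname(colSums(ev$confusion)),
               as.numeric(table(factor(target, levels = 1:5))))
  expect_equal(unname(rowSums(ev$confusion)),
               as.numeric(table(factor(pred, levels = 1:5))))
  expect_equal(ev$acc, mean(pred == target))
  expect_true(all(ev$cases$fpr >= 0 & ev$cases$fpr <= 1))

  perfect <- evaluate_classification(target, target)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$cases$fpr, rep(0, 4))
  expect_equal(perfect$cases$fnr, rep(0, 4))

  # absent target class yields an undefined per-class accuracy
  ev2 <- evaluate_classification(c(1, 1, 2), c(1, 1, 2))
  expect_true(all(is.na(ev2$acc_class[3:5])))
})

test_that("paired effect size matches hand arithmetic and is antisymmetric", {
  expect_equal(cohens_d_paired(1:5, 1:5), NA_real_)
  a <- c(1.9, 2.0, 2.1)
  b <- c(1.0, 1.0, 1.0)
  expect_equal(cohens_d_paired(a, b), 10.0)
  set.seed(60)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(cohens_d_paired(x, y), -cohens_d_paired(y, x))
})
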