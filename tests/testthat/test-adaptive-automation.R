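# fixture: small pool + lssvm2 model shared across blocks
aa_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- small_participant()
      model <- fit_narx(p$session1$xprime, p$session1$y, 2, 3, "lssvm2")
      pool <- session_pool(p$session2$xprime, p$session2$y, p$session2$n)
      cache <<- list(p = p, model = model, pool = pool)
    }
    cache
  }
})

test_that("the generator draws from the requested task-count bin", {
  fx <- aa_fixture()
  pool <- fx$pool
  set.seed(61)
  for (i in 1:20) {
    n <- sample(c(1, 2, 3, 4), 1)
    d <- generator_step(n, pool)
    key <- as.character(if (n == 2) 1 else n)
    expect_true(d$index %in% pool$bins[[key]])
  }

  # a single-record bin always returns that record
  tiny <- session_pool(matrix(1:3, 3, 1), c(0.9, 0.7, 0.6), c(1, 3, 4))
  expect_equal(generator_step(4, tiny)$y, 0.6)

  # two-record bin: seeded draw frequencies are near one half
  two <- session_pool(matrix(1:4, 4, 1), c(0.9, 0.8, 0.7, 0.6),
                      c(1, 1, 3, 4))
  set.seed(62)
  draws <- replicate(10000, generator_step(1, two)$index)
  expect_lt(abs(mean(draws == 1) - 0.5), 0.02)

  expect_error(session_pool(matrix(1:2, 2, 1), c(0.9, 0.8), c(1, 3)),
               "non-empty")
})

test_that("the proportional-threshold law maps error bands to task decrements", {
  expect_equal(proportional_threshold_control(0.1), 0L)
  expect_equal(proportional_threshold_control(0.5), 1L)
  expect_equal(proportional_threshold_control(0.9), 2L)
  expect_equal(proportional_threshold_control(0.2), 1L)
  expect_equal(proportional_threshold_control(0.8), 2L)
  # gain scales the error before thresholding
  expect_equal(proportional_threshold_control(0.1, gain = 5), 1L)
})

test_that("the rule-based law freezes the allocation after a change", {
  st <- list(hold = 0L, gain = 1)
  r1 <- rule_based_control(0.1, st)
  expect_equal(r1$dn, 0L)
  expect_equal(r1$state$hold, 0L)

  r2 <- rule_based_control(0.5, st)
  expect_equal(r2$dn, 1L)
  expect_equal(r2$state$hold, 2L)

  # a large error arriving during the hold is ignored and the hold decays
  r3 <- rule_based_control(0.9, r2$state)
  expect_equal(r3$dn, 0L)
  expect_equal(r3$state$hold, 1L)
  r4 <- rule_based_control(0.9, r3$state)
  expect_equal(r4$dn, 0L)
  expect_equal(r4$state$hold, 0L)
  r5 <- rule_based_control(0.9, r4$state)
  expect_equal(r5$dn, 2L)
})

test_that("without reallocation the task count follows the schedule", {
  fx <- aa_fixture()
  sim <- run_simulation(fx$pool, fx$model, "none", fx$p$sigma_o, fx$p$z,
                        steps = 90, runs = 2, seed = 63)
  sched <- default_task_schedule()
  for (r in sim$runs) expect_equal(r$n, sched)
  expect_equal(round(sim$summary[["n_mean"]], 1), 2.7)
})

test_that("simulations are reproducible and task moves are one-directional", {
  fx <- aa_fixture()
  s1 <- run_simulation(fx$pool, fx$model, "rule", fx$p$sigma_o, fx$p$z,
                       steps = 90, runs = 3, seed = 64)
  s2 <- run_simulation(fx$pool, fx$model, "rule", fx$p$sigma_o, fx$p$z,
                       steps = 90, runs = 3, seed = 64)
  expect_identical(s1$runs, s2$runs)

  sched <- default_task_schedule()
  block_start <- c(TRUE, diff(sched) != 0)
  for (ctrl in c("prop", "rule")) {
    sim <- run_simulation(fx$pool, fx$model, ctrl, fx$p$sigma_o, fx$p$z,
                          steps = 90, runs = 3, seed = 65)
    for (r in sim$runs) {
      expect_true(all(r$n >= 1 & r$n <= 4))
      # within a block the operator only hands tasks to the machine
      within <- !block_start
      expect_true(all(diff(r$n)[within[-1]] <= 0))
    }
  }
})

test_that("rule-based changes are followed by at least two frozen steps", {
  fx <- aa_fixture()
  sched <- default_task_schedule()
  block_start <- which(c(TRUE, diff(sched) != 0))
  sim <- run_simulation(fx$pool, fx$model, "rule", fx$p$sigma_o, fx$p$z,
                        steps = 90, runs = 5, seed = 66)
  for (r in sim$runs) {
    for (k in 2:88) {
      if ((k + 1) %in% block_start || (k + 2) %in% block_start) next
      if (k %in% block_start) next
      if (r$n[k] != r$n[k - 1]) {
        expect_equal(r$n[k + 1], r$n[k])
        expect_equal(r$n[k + 2], r$n[k])
      }
    }
  }
})

test_that("summaries are plain arithmetic means over runs and steps", {
  fake <- structure(list(runs = list(
    list(n = rep(3, 4), yhat = rep(1, 4), class = c(1L, 2L, 1L, 2L),
         y = c(0.6, 0.8, 1.0, 0.8)),
    list(n = rep(3, 4), yhat = rep(1, 4), class = c(2L, 1L, 2L, 1L),
         y = c(0.8, 0.6, 1.0, 0.8))),
    controller = "none", steps = 4, seed = 1), class = "ctl_simulation")
  s <- summarize_simulation(fake)
  expect_equal(s[["n_mean"]], 3)
  expect_equal(s[["c_mean"]], 1.5)
  expect_equal(s[["y_mean"]], 0.8)
})
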