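# Closed-loop adaptive automation: an operator data generator driven by the
# current task count, the dynamic task-load predictor, and two
# task-reallocation controllers.

#' Build a session pool for the operator data generator
#'
#' Bins the epochs of a (test) session by task count so the generator can
#' draw operator data matching the current number of manual tasks. A
#' requested count of 2 is served from the n = 1 bin (that condition is
#' not part of the task schedule).
#'
#' @param xprime K x p salient feature matrix of the session.
#' @param y measured performance, length K.
#' @param n_sched task count of each epoch, length K (values in 1, 3, 4).
#' @return list of class `ctl_session_pool` with per-count bins of epoch
#'   indices plus the data.
#' @export
session_pool <- function(xprime, y, n_sched) {
  xprime <- as.matrix(xprime)
  K <- nrow(xprime)
  stopifnot(length(y) == K, length(n_sched) == K)
  bins <- lapply(c(`1` = 1, `3` = 3, `4` = 4),
                 function(n) which(n_sched == n))
  if (any(vapply(bins, length, integer(1)) == 0L))
    stop("every task-count bin (1, 3, 4) must be non-empty")
  structure(list(xprime = xprime, y = y, bins = bins),
            class = "ctl_session_pool")
}

#' Draw one operator epoch for the current task count
#'
#' Samples uniformly with replacement from the pool bin of the requested
#' task count; n = 2 maps to the n = 1 bin.
#'
#' @param n current task count (1..4).
#' @param pool a [session_pool()].
#' @return list with `xprime` (feature row) and `y` (performance).
#' @export
generator_step <- function(n, pool) {
  stopifnot(inherits(pool, "ctl_session_pool"))
  key <- as.character(if (n == 2) 1 else n)
  bin <- pool$bins[[key]]
  if (is.null(bin) || length(bin) == 0L) stop("no pool bin for n = ", n)
  i <- bin[sample.int(length(bin), 1L)]
  list(xprime = pool$xprime[i, , drop = FALSE], y = pool$y[i], index = i)
}

#' Proportional-plus-threshold control action
#'
#' Maps the gained tracking error K e into the number of tasks to hand to
#' the machine: 0 below 0.2, 1 in \[0.2, 0.8), 2 otherwise.
#'
#' @param e tracking error r - y_hat (set-point r = 1).
#' @param gain proportional gain K (default 1).
#' @return integer task decrement in 0..2.
#' @export
proportional_threshold_control <- function(e, gain = 1) {
  ke <- gain * e
  if (ke < 0.2) 0L else if (ke < 0.8) 1L else 2L
}

#' Rule-based control action with a reallocation hold
#'
#' Same thresholds as [proportional_threshold_control()], but any
#' reallocation freezes the task count for the next two steps (30 s), giving
#' the operator time to recover before the automation level moves again.
#'
#' @param e tracking error.
#' @param state list with `hold` (steps remaining frozen) and `gain`.
#' @return list with `dn` (task decrement) and the updated `state`.
#' @export
rule_based_control <- function(e, state = list(hold = 0L, gain = 1)) {
  if (state$hold > 0L) {
    state$hold <- state$hold - 1L
    return(list(dn = 0L, state = state))
  }
  dn <- proportional_threshold_control(e, state$gain)
  if (dn > 0L) state$hold <- 2L
  list(dn = dn, state = state)
}

#' Default without-automation task schedule
#'
#' Six consecutive task-load blocks with counts 1, 3, 4, 4, 3, 1.
#'
#' @param block_len steps per block (default 15, i.e. 150 s of 10-s
#'   epochs in a 90-step run).
#' @return integer vector of task counts.
#' @export
default_task_schedule <- function(block_len = 15) {
  rep(c(1L, 3L, 4L, 4L, 3L, 1L), each = block_len)
}

#' Run the closed-loop adaptive automation simulation
#'
#' Per step: the task schedule (re)sets the baseline task count at each
#' block start; otherwise the controller may reallocate tasks to the
#' machine based on the previous step's tracking error e = 1 - y_hat. The
#' generator then draws operator data for the current count, the predictor
#' estimates performance, and the estimate is discretized into a task-load
#' class. The task count is clamped to \[1, 4\] and only ever reduced by
#' the controller (tasks move to the machine, never back within a block).
#'
#' @param pool a [session_pool()] built from the test session.
#' @param model a `ctl_narx` predictor trained on the paired training
#'   session (the simulator feeds it the generated measured performance
#'   history).
#' @param controller `"rule"`, `"prop"`, or `"none"` (follow the schedule,
#'   no reallocation).
#' @param sigma_o,z discretization parameters for the predicted class.
#' @param steps steps per run (default 90).
#' @param runs number of runs (default 10).
#' @param seed master seed; run i uses seed + i.
#' @param schedule without-automation task schedule (default
#'   [default_task_schedule()] stretched to `steps`).
#' @param gain controller gain (default 1).
#' @return list of class `ctl_simulation` with per-run trajectories
#'   (`n`, `yhat`, `class`, `y`) and the run-averaged summaries `n_mean`,
#'   `c_mean`, `y_mean`.
#' @export
run_simulation <- function(pool, model, controller = c("rule", "prop", "none"),
                           sigma_o, z, steps = 90, runs = 10, seed = 1,
                           schedule = NULL, gain = 1) {
  controller <- match.arg(controller)
  stopifnot(inherits(pool, "ctl_session_pool"), inherits(model, "ctl_narx"))
  if (is.null(schedule))
    schedule <- default_task_schedule(block_len = ceiling(steps / 6))[1:steps]
  if (length(schedule) != steps) stop("schedule must cover all steps")
  block_start <- c(TRUE, diff(schedule) != 0)
  d1 <- model$d1; d2 <- model$d2
  runs_out <- vector("list", runs)
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    n_tr <- integer(steps); y_tr <- numeric(steps)
    yhat <- numeric(steps); cls <- integer(steps)
    xbuf <- matrix(0, steps, model$p)
    st <- list(hold = 0L, gain = gain)
    for (k in seq_len(steps)) {
      if (block_start[k]) {
        n_tr[k] <- schedule[k]
        st$hold <- 0L
      } else {
        e_prev <- 1 - yhat[k - 1]
        dn <- 0L
        if (controller == "prop") {
          dn <- proportional_threshold_control(e_prev, gain)
        } else if (controller == "rule") {
          rb <- rule_based_control(e_prev, st)
          dn <- rb$dn
          st <- rb$state
        }
        n_tr[k] <- max(1L, min(4L, n_tr[k - 1] - dn))
      }
      draw <- generator_step(n_tr[k], pool)
      xbuf[k, ] <- draw$xprime
      y_tr[k] <- draw$y
      k0 <- max(d1, d2 + 1)
      yhat[k] <- if (k < k0) y_tr[k]
                 else predict_narx_step(model, xbuf, yhat, y_tr[1:(k - 1)], k)
      cls[k] <- discretize_performance(yhat[k], sigma_o, z)
    }
    runs_out[[r]] <- list(n = n_tr, yhat = yhat, class = cls, y = y_tr)
  }
  res <- structure(list(runs = runs_out, controller = controller,
                        steps = steps, seed = seed),
                   class = "ctl_simulation")
  res$summary <- summarize_simulation(res)
  res
}

#' Run-averaged simulation summaries
#'
#' Arithmetic means of the task count, predicted task-load class, and
#' measured performance over all steps and runs.
#'
#' @param result a `ctl_simulation`.
#' @return named numeric vector `c(n_mean, c_mean, y_mean)`.
#' @export
summarize_simulation <- function(result) {
  stopifnot(inherits(result, "ctl_simulation"))
  c(n_mean = mean(vapply(result$runs, function(r) mean(r$n), numeric(1))),
    c_mean = mean(vapply(result$runs, function(r) mean(r$class), numeric(1))),
    y_mean = mean(vapply(result$runs, function(r) mean(r$y), numeric(1))))
}

#' @export
print.ctl_simulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "closed-loop simulation (%s controller): %d runs x %d steps\n",
    x$controller, length(x$runs), x$steps))
  cat(sprintf("n_mean = %.2f, c_mean = %.2f, y_mean = %.4f\n",
              s["n_mean"], s["c_mean"], s["y_mean"]))
  invisible(x)
}
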