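# Configuration, session I/O and the end-to-end pipeline runner.

#' Default pipeline configuration
#'
#' All numeric defaults are the method's standard operating constants:
#' 3rd-order 40 Hz low-pass, 3-tap RLS ocular filter with forgetting 0.99,
#' 10-s epochs, the five rhythm bands, adaptive-smoothing constants
#' (a = 1, b = 2.2, gains 0.2/0.1/0.3), a 5-neighbour LPP graph,
#' LSSVM regularization 100 with RBF width sigma^2 = 500, combination
#' weights (0.1, 0.9) and (0.02, 0.18, 0.8), structure-search grid
#' 1..15 x 1..15 with objective weights (0.8, 0.2), discretization
#' coefficients (2.3, 2.7, 3.0), and controller gain 1 with thresholds
#' (0.2, 0.8).
#'
#' @return nested named list of class `ctl_config`.
#' @export
ctl_config <- function() {
  structure(list(
    preprocess = list(lowpass_cutoff = 40, lowpass_order = 3,
                      rls_order = 3, rls_lambda = 0.99, epoch_len = 10),
    bands = ctl_bands(),
    aes = list(a = 1, b = 2.2, g1 = 0.2, g2 = 0.1, g3 = 0.3),
    lpp = list(neighbors = 5, heat_width = NULL),
    lssvm = list(gamma_reg = 100, sigma2 = 500,
                 weights_lssvm1 = c(0.1, 0.9),
                 weights_lssvm2 = c(0.02, 0.18, 0.8)),
    structure = list(grid_max = 15, tau = c(0.8, 0.2)),
    discretization = list(z = c(2.3, 2.7, 3.0)),
    controller = list(gain = 1, thresholds = c(0.2, 0.8), setpoint = 1),
    simulation = list(steps = 90, runs = 10),
    seed = 1
  ), class = "ctl_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @param config a `ctl_config` list (for writing).
#' @return `read_config` returns a `ctl_config`; missing entries are
#'   filled from the defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- ctl_config()
  for (section in names(user)) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      for (key in names(user[[section]]))
        cfg[[section]][[key]] <- user[[section]][[key]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a recording or feature table from disk
#'
#' Two CSV schemas are supported: a long-form raw recording
#' (`time_s,channel,value_uV`) which is returned as a [ctl_recording()]
#' with channels re-ordered canonically, and a feature table
#' (`epoch,<55 band columns>,HR`) returned as a `ctl_features` matrix.
#'
#' @param path CSV file path.
#' @param format `"raw"` or `"features"`; guessed from the header when
#'   omitted.
#' @return a `ctl_recording` or a feature matrix.
#' @export
read_session <- function(path, format = c("auto", "raw", "features")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (format == "auto")
    format <- if (all(c("time_s", "channel", "value_uV") %in% names(df)))
      "raw" else "features"
  if (format == "raw") {
    need <- c("time_s", "channel", "value_uV")
    if (!all(need %in% names(df)))
      stop("raw CSV must have columns: ", paste(need, collapse = ", "))
    chans <- unique(df$channel)
    unknown <- setdiff(chans, ctl_channels())
    if (length(unknown) > 0)
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
    missing <- setdiff(ctl_channels(), chans)
    if (length(missing) > 0)
      stop("missing channel(s): ", paste(missing, collapse = ", "))
    times <- sort(unique(df$time_s))
    fs <- 1 / stats::median(diff(times))
    wide <- vapply(ctl_channels(), function(ch) {
      sub <- df[df$channel == ch, ]
      sub$value_uV[order(sub$time_s)]
    }, numeric(length(times)))
    ctl_recording(t(wide), fs = round(fs, 6), labels = ctl_channels())
  } else {
    if (!"HR" %in% names(df)) stop("feature CSV is missing the HR column")
    expected <- c(as.vector(t(outer(ctl_eeg_channels(), names(ctl_bands()),
                                    paste, sep = "_"))), "HR")
    missing <- setdiff(expected, names(df))
    if (length(missing) > 0)
      stop("feature CSV is missing column(s): ",
           paste(missing, collapse = ", "))
    m <- as.matrix(df[, expected])
    structure(m, class = c("ctl_features", class(m)))
  }
}

#' Write a recording or feature table to disk
#'
#' @param x a `ctl_recording` or feature matrix.
#' @param path output CSV path.
#' @export
write_session <- function(x, path) {
  if (inherits(x, "ctl_recording")) {
    n <- ncol(x$samples)
    df <- data.frame(
      time_s = rep((seq_len(n) - 1) / x$fs, times = length(x$labels)),
      channel = rep(x$labels, each = n),
      value_uV = as.numeric(t(x$samples)))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    df <- data.frame(epoch = seq_len(nrow(x)), as.data.frame(unclass(x)),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Run the full monitoring and adaptive-automation pipeline
#'
#' Given a paired pair of sessions (raw recordings or ready feature
#' matrices plus performance), the runner preprocesses, fits the feature
#' reduction and the two NARX predictors on session 1, evaluates both on
#' session 2, and simulates the closed loop with both controllers against
#' the without-automation schedule. Stages are timed; a stage failure
#' marks the report and skips downstream stages.
#'
#' @param session1,session2 lists with either `recording` (a
#'   `ctl_recording`) or `features` (K x 56 matrix) or `xprime` (ready
#'   K x 12 salient features), plus `y` (measured performance) and
#'   optionally `n` (task counts per epoch; defaults to the standard
#'   schedule stretched over K).
#' @param config a [ctl_config()].
#' @param orders optional `c(d1, d2)`; when omitted they are selected on
#'   the session-1 grid search (slow).
#' @return list of class `ctl_report` with per-stage results, the
#'   evaluation of both model variants, and the simulation summaries.
#' @export
run_pipeline <- function(session1, session2, config = ctl_config(),
                         orders = c(3, 5)) {
  report <- list(config = config, stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    out <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    out$seconds <- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    report$stages[[name]] <<- out[names(out) != "value"]
    if (!out$ok) stop("stage '", name, "' failed: ", out$error, call. = FALSE)
    out$value
  }
  get_xprime <- function(sess, reduction = NULL, y = NULL) {
    if (!is.null(sess$xprime)) return(as.matrix(sess$xprime))
    fm <- if (!is.null(sess$features)) as.matrix(sess$features)
          else preprocess_session(sess$recording, config)
    if (is.null(reduction))
      stop("a fitted reduction is required to project features")
    apply_feature_reduction(reduction, fm)
  }
  out <- tryCatch({
    red <- NULL
    if (is.null(session1$xprime)) {
      fm1 <- stage("preprocess_session1", {
        if (!is.null(session1$features)) as.matrix(session1$features)
        else preprocess_session(session1$recording, config)
      })
      red <- stage("fit_reduction",
                   fit_feature_reduction(fm1, session1$y, config))
      x1 <- apply_feature_reduction(red, fm1)
    } else x1 <- as.matrix(session1$xprime)
    x2 <- stage("prepare_session2", get_xprime(session2, red))
    sigma_o <- stats::sd(c(session1$y, session2$y))
    z <- config$discretization$z
    if (is.null(orders)) {
      ss <- stage("select_structure",
                  select_structure(x1, session1$y, "lssvm1",
                                   1:config$structure$grid_max,
                                   1:config$structure$grid_max,
                                   tau = config$structure$tau,
                                   gamma_reg = config$lssvm$gamma_reg,
                                   sigma2 = config$lssvm$sigma2))
      orders <- c(ss$d1, ss$d2)
    }
    models <- stage("train", lapply(
      stats::setNames(c("lssvm1", "lssvm2"), c("lssvm1", "lssvm2")),
      function(v) fit_narx(x1, session1$y, orders[1], orders[2], v,
                           gamma_reg = config$lssvm$gamma_reg,
                           sigma2 = config$lssvm$sigma2)))
    evals <- stage("evaluate", lapply(models, function(m) {
      yhat <- predict_narx(m, x2, session2$y)
      evaluate_classification(classify_ctl(yhat, sigma_o, z),
                              discretize_performance(session2$y, sigma_o, z))
    }))
    n2 <- session2$n
    if (is.null(n2))
      n2 <- rep(c(1L, 3L, 4L, 4L, 3L, 1L), each = ceiling(nrow(x2) / 6))[
        seq_len(nrow(x2))]
    pool <- session_pool(x2, session2$y, n2)
    sims <- stage("simulate", {
      lapply(stats::setNames(c("none", "prop", "rule"),
                             c("without", "proportional", "rule")),
             function(ctrl) run_simulation(
               pool, models$lssvm2, ctrl, sigma_o, z,
               steps = config$simulation$steps,
               runs = config$simulation$runs,
               seed = config$seed, gain = config$controller$gain))
    })
    list(orders = orders, sigma_o = sigma_o,
         evaluation = evals,
         simulation = lapply(sims, function(s) s$summary))
  }, error = function(e) list(failed = conditionMessage(e)))
  report <- c(report["stages"], out)
  report$seconds_total <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "ctl_report"
  report
}

#' Serialize a pipeline report to JSON
#'
#' Confusion matrices are written row-major with explicit predicted/target
#' axis labels.
#'
#' @param report a `ctl_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  enc <- report
  if (!is.null(enc$evaluation)) {
    enc$evaluation <- lapply(enc$evaluation, function(ev) {
      list(confusion = list(axis = c("rows_predicted", "cols_target"),
                            matrix = unname(apply(ev$confusion, 1, as.numeric,
                                                  simplify = FALSE))),
           acc = ev$acc, acc_class = as.numeric(ev$acc_class),
           cases = ev$cases, n = ev$n)
    })
  }
  enc$config <- NULL
  jsonlite::write_json(unclass(enc), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
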