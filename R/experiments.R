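#' Experiment sweep specification
#'
#' Describes a one-factor sweep (or a stiffness x frequency grid) over the
#' tracking-balance study conditions. `sweep_values()` returns the full
#' published condition lists; the `desk` profile typically uses a 2-3 value
#' subset of them with scaled-down training.
#'
#' @param variable One of `"frequency"` (target frequency, Hz), `"gamma"`
#'   (energy-penalty weight), `"hip_stiffness"` (Nm/rad), `"added_mass"`
#'   (kg, evaluation-only transfer of a fixed multi-frequency policy) or
#'   `"grid"` (hip stiffness x frequency).
#' @param values Numeric vector of condition values; for `"grid"`, a data
#'   frame with columns `hip_stiffness` and `frequency`.
#' @param seeds Integer vector of training seeds per condition. Default 1:3.
#' @param profile `"desk"` or `"paper"`; selects the [ppo_config()] profile
#'   and the evaluation episode length (50 s desk, 100 s paper).
#' @param task Base [task_spec()] (frequency overridden by frequency
#'   sweeps). Default f = 0.4 Hz, A = 0.1 m, 20 s training episodes.
#' @param params Base plant parameters.
#' @param weights Base [reward_weights()]; gamma overridden by gamma
#'   sweeps. Defaults to training weights (normalized-torque penalties).
#' @param ppo Base [ppo_config()] (seed overridden per run); defaults to
#'   the profile's configuration.
#' @param eval_duration Evaluation episode length (s); defaults by profile.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(variable = c("frequency", "gamma", "hip_stiffness",
                                    "added_mass", "grid"),
                       values, seeds = 1:3, profile = c("desk", "paper"),
                       task = task_spec(), params = derive_segment_parameters(),
                       weights = NULL, ppo = NULL, eval_duration = NULL) {
  variable <- match.arg(variable)
  profile <- match.arg(profile)
  if (variable == "grid") {
    if (!is.data.frame(values) ||
        !all(c("hip_stiffness", "frequency") %in% names(values)))
      stop("grid sweeps need a data frame with hip_stiffness and frequency columns")
    if (nrow(values) == 0) stop("values must be non-empty")
  } else {
    if (length(values) == 0) stop("values must be non-empty")
  }
  if (is.null(weights))
    weights <- reward_weights(torque_scale = params$torque_limit)
  if (is.null(ppo)) ppo <- ppo_config(profile = profile)
  if (is.null(eval_duration))
    eval_duration <- if (profile == "paper") 100 else 50
  structure(list(variable = variable, values = values, seeds = seeds,
                 profile = profile, task = task, params = params,
                 weights = weights, ppo = ppo,
                 eval_duration = eval_duration), class = "sweep_spec")
}

#' @rdname sweep_spec
#' @export
sweep_values <- function(variable = c("frequency", "gamma", "hip_stiffness",
                                      "added_mass", "grid")) {
  variable <- match.arg(variable)
  switch(variable,
         frequency = seq(0.15, 1.50, by = 0.15),
         gamma = seq(0, 40, by = 5),
         hip_stiffness = seq(25, 200, by = 25),
         added_mass = seq(0, 4, by = 0.5),
         grid = expand.grid(hip_stiffness = seq(25, 200, by = 25),
                            frequency = seq(0.05, 0.5, by = 0.05)))
}

# Build the per-condition task/params/weights for one sweep row.
sweep_condition <- function(ss, value) {
  task <- ss$task; params <- ss$params; w <- ss$weights
  if (ss$variable == "frequency") task$frequency_f <- value
  else if (ss$variable == "gamma") w$gamma <- value
  else if (ss$variable == "hip_stiffness") params$hip_stiffness <- value
  else if (ss$variable == "added_mass") params$added_mass <- value
  else if (ss$variable == "grid") {
    params$hip_stiffness <- value$hip_stiffness
    task$frequency_f <- value$frequency
  }
  list(task = task, params = params, weights = w)
}

#' Run an experiment sweep
#'
#' Trains (or reuses) one policy per (condition, seed), evaluates it on a
#' deterministic episode and summarizes the coordination indices into a tidy
#' table with one row per run. Failed runs are recorded with
#' `status = "failed"` rather than dropped. When `out_dir` is given each
#' completed row is cached and skipped on re-run (keyed by a hash of
#' condition, seed and configuration).
#'
#' Added-mass sweeps do not retrain: they evaluate the transfer of a single
#' pre-trained multi-frequency `policy` across payloads.
#'
#' @param ss A [sweep_spec()].
#' @param policy Optional fixed policy evaluated for every condition
#'   (bypasses training; required for `variable = "added_mass"`).
#' @param policy_factory Optional function `(task, params, weights, seed)`
#'   returning a policy, replacing PPO training (used for fixture-driven
#'   plumbing tests).
#' @param out_dir Optional cache/output directory.
#' @param verbose Forwarded to [ppo_train()].
#' @return A `sweep_result` data frame: condition value(s), seed, status,
#'   the [summarize_episode()] fields, final mean training return and step
#'   count.
#' @export
run_sweep <- function(ss, policy = NULL, policy_factory = NULL,
                      out_dir = NULL, verbose = 0) {
  stopifnot(inherits(ss, "sweep_spec"))
  if (ss$variable == "added_mass" && is.null(policy))
    stop("added_mass sweeps evaluate a pre-trained multi-frequency policy; ",
         "pass one via `policy`")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  vals <- if (ss$variable == "grid") seq_len(nrow(ss$values)) else ss$values
  rows <- list()
  for (vi in seq_along(vals)) {
    value <- if (ss$variable == "grid") ss$values[vi, ] else vals[vi]
    cond <- sweep_condition(ss, value)
    for (seed in ss$seeds) {
      key <- NULL
      if (!is.null(out_dir)) {
        tf <- tempfile()
        saveRDS(list(value, seed, ss$ppo, cond), tf)
        key <- file.path(out_dir, paste0("row-", unname(tools::md5sum(tf)), ".rds"))
        unlink(tf)
        if (file.exists(key)) { rows[[length(rows) + 1L]] <- readRDS(key); next }
      }
      row <- tryCatch({
        pol <- policy
        final_ret <- NA_real_; steps <- NA_real_
        if (is.null(pol) && !is.null(policy_factory)) {
          pol <- policy_factory(cond$task, cond$params, cond$weights, seed)
        } else if (is.null(pol)) {
          cfg <- ss$ppo; cfg$seed <- as.integer(seed)
          fit <- ppo_train(make_tracking_env(cond$task, cond$params,
                                             cond$weights),
                           cfg, verbose = verbose)
          final_ret <- utils::tail(fit$diagnostics$mean_return, 1)
          steps <- utils::tail(fit$diagnostics$steps, 1)
          pol <- fit
        }
        eval_spec <- cond$task
        eval_spec$episode_duration <- ss$eval_duration
        log <- run_episode(pol, eval_spec, cond$params, cond$weights,
                           seed = seed, deterministic = TRUE)
        sm <- as.data.frame(summarize_episode(log, eval_spec))
        cbind(condition_frame(ss, value, seed), status = "ok", sm,
              final_mean_return = final_ret, train_steps = steps)
      }, error = function(e) {
        cbind(condition_frame(ss, value, seed), status = "failed",
              error = conditionMessage(e))
      })
      if (!is.null(key)) saveRDS(row, key)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind_fill, list(rows))
  class(out) <- c("sweep_result", "data.frame")
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "sweep_result.csv"),
                     row.names = FALSE)
  out
}

condition_frame <- function(ss, value, seed) {
  if (ss$variable == "grid")
    data.frame(hip_stiffness = value$hip_stiffness,
               frequency_condition = value$frequency, seed = seed)
  else {
    df <- data.frame(value = as.numeric(value), seed = seed)
    names(df)[1] <- ss$variable
    df
  }
}

# rbind data frames with unequal columns (missing filled with NA).
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
}

#' Evaluate a policy under a frequency chirp
#'
#' Runs one episode in which the target frequency grows linearly (default
#' 0.036 Hz/s for 25 s), computes the sliding-window hip-ankle correlation
#' (default window 300 control steps) and the mode-transition frequency at
#' its first sign change. If the model falls the partial series is returned
#' with the fall time.
#'
#' @param policy A policy (typically trained on the multi-frequency
#'   curriculum; scripted policies and fixture logs can stand in for
#'   plumbing tests).
#' @param start_f Chirp start frequency (Hz). Default 0.15.
#' @param rate Chirp rate (Hz/s). Default 0.036.
#' @param duration Episode length (s). Default 25.
#' @param window Correlation window (control steps). Default 300.
#' @param stride Window stride (control steps). Default 10.
#' @param params,w Plant and reward configuration.
#' @param amplitude_A Target amplitude (m). Default 0.1.
#' @param seed Evaluation seed.
#' @return A list with `correlation` (data frame: window center time,
#'   instantaneous frequency, correlation), `transition_frequency`, `fell`
#'   and `fall_time`.
#' @export
run_chirp_eval <- function(policy, start_f = 0.15, rate = 0.036,
                           duration = 25, window = 300L, stride = 10L,
                           params = derive_segment_parameters(),
                           w = reward_weights(torque_scale = params$torque_limit),
                           amplitude_A = 0.1, seed = 1L) {
  spec <- task_spec(amplitude_A = amplitude_A, frequency_f = start_f,
                    chirp_rate = rate, episode_duration = duration)
  log <- run_episode(policy, spec, params, w, seed = seed,
                     deterministic = TRUE)
  chirp_transition(log, start_f = start_f, rate = rate, window = window,
                   stride = stride)
}

#' Transition analysis of a chirp trajectory log
#'
#' The analysis half of [run_chirp_eval()], applicable directly to a log
#' (e.g. a [gen_mode_switch_series()] fixture).
#'
#' @param log A `trajectory_log` under a frequency chirp.
#' @param start_f,rate Chirp parameters (default from the log's spec).
#' @param window,stride Correlation window and stride in samples.
#' @return Same structure as [run_chirp_eval()].
#' @export
chirp_transition <- function(log, start_f = NULL, rate = NULL, window = 300L,
                             stride = 10L) {
  spec <- attr(log, "spec")
  if (is.null(start_f)) start_f <- spec$frequency_f
  if (is.null(rate)) rate <- spec$chirp_rate
  fell <- any(log$fallen)
  fall_time <- if (fell) log$time[which(log$fallen)[1]] else NA_real_
  wc <- windowed_correlation(log$theta_ankle, log$theta_hip,
                             window = min(window, nrow(log)),
                             stride = stride, times = log$time)
  wc$frequency <- start_f + rate * wc$center
  tf <- transition_frequency(wc$correlation, wc$frequency)
  list(correlation = wc, transition_frequency = tf, fell = fell,
       fall_time = fall_time)
}

#' Render tables and figures from sweep results
#'
#' Writes a tidy CSV per sweep and, where the sweep shape allows, standard
#' figures: condition-wise correlation/relative-phase curves, CoP box plots
#' for frequency sweeps, and a correlation heat map for stiffness x
#' frequency grids. Single-row inputs render tables only (plots are skipped
#' with a notice).
#'
#' @param results A `sweep_result` (or plain data frame from
#'   [run_sweep()]).
#' @param out_dir Output directory (created if needed).
#' @param name Base name for the output files.
#' @return Invisibly, the paths of the files written.
#' @export
make_report <- function(results, out_dir, name = "sweep") {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  needed <- c("status", "hip_ankle_correlation")
  miss <- setdiff(needed, names(results))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)

  tab <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(results, tab, row.names = FALSE)
  paths <- c(paths, tab)

  ok <- results[results$status == "ok", , drop = FALSE]
  if (nrow(ok) < 2) {
    message("make_report: fewer than 2 successful rows; plots skipped")
    return(invisible(paths))
  }

  is_grid <- all(c("hip_stiffness", "frequency_condition") %in% names(ok))
  if (is_grid) {
    fig <- file.path(out_dir, paste0(name, "-heatmap.png"))
    grDevices::png(fig, width = 800, height = 600)
    agg <- stats::aggregate(hip_ankle_correlation ~ hip_stiffness +
                              frequency_condition, data = ok, FUN = mean)
    ks <- sort(unique(agg$hip_stiffness))
    fqs <- sort(unique(agg$frequency_condition))
    z <- matrix(NA_real_, length(ks), length(fqs))
    for (i in seq_len(nrow(agg)))
      z[match(agg$hip_stiffness[i], ks),
        match(agg$frequency_condition[i], fqs)] <- agg$hip_ankle_correlation[i]
    graphics::image(ks, fqs, z, xlab = "hip stiffness [Nm/rad]",
                    ylab = "target frequency [Hz]",
                    main = "hip-ankle correlation",
                    col = grDevices::hcl.colors(21, "Blue-Red 3", rev = TRUE),
                    zlim = c(-1, 1))
    grDevices::dev.off()
    paths <- c(paths, fig)
  } else {
    xcol <- setdiff(names(ok), c("seed", "status"))[1]
    fig <- file.path(out_dir, paste0(name, "-correlation.png"))
    grDevices::png(fig, width = 800, height = 600)
    graphics::par(mar = c(5, 4, 2, 4))
    graphics::plot(ok[[xcol]], ok$hip_ankle_correlation, pch = 19,
                   xlab = xcol, ylab = "hip-ankle correlation",
                   ylim = c(-1, 1))
    graphics::abline(h = 0, lty = 2)
    if ("relative_phase" %in% names(ok)) {
      graphics::par(new = TRUE)
      graphics::plot(ok[[xcol]], ok$relative_phase, type = "p", pch = 1,
                     col = "darkgreen", axes = FALSE, xlab = "", ylab = "")
      graphics::axis(4, col.axis = "darkgreen")
      graphics::mtext("relative phase [rad]", side = 4, line = 2,
                      col = "darkgreen")
    }
    grDevices::dev.off()
    paths <- c(paths, fig)

    qcols <- c("cop_min", "cop_q1", "cop_median", "cop_q3", "cop_max")
    if (all(qcols %in% names(ok)) && "frequency" %in% names(ok) &&
        any(stats::complete.cases(ok[qcols]))) {
      fig2 <- file.path(out_dir, paste0(name, "-cop.png"))
      grDevices::png(fig2, width = 800, height = 600)
      okq <- ok[stats::complete.cases(ok[qcols]), , drop = FALSE]
      agg <- stats::aggregate(okq[qcols], by = list(x = okq[[xcol]]), FUN = mean)
      bx <- list(stats = t(as.matrix(agg[qcols])), n = rep(1, nrow(agg)),
                 names = as.character(agg$x))
      graphics::bxp(bx, xlab = xcol, ylab = "CoP [m]",
                    main = "CoP distribution")
      grDevices::dev.off()
      paths <- c(paths, fig2)
    }
  }
  invisible(paths)
}
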