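#' PPO learner configuration
#'
#' Hyper-parameters of the actor-critic proximal policy optimization
#' learner. The `paper` profile mirrors the published large-scale settings
#' (8192 environments, minibatch 8192, hidden layers 256/256, 5e6 steps);
#' the default `desk` profile scales the computation to a single CPU
#' (64 environments, minibatch 2048, hidden layers 64/64, 3e5 steps) while
#' keeping the learning rule identical: KL threshold 0.002, horizon 32,
#' 5 PPO epochs.
#'
#' @param profile `"desk"` (default) or `"paper"`; sets the scale-dependent
#'   defaults below, each individually overridable.
#' @param hidden_layers Integer vector of hidden-layer widths (both nets).
#' @param clip_epsilon Surrogate clipping parameter in (0, 1). Default 0.2.
#' @param kl_threshold Target per-update KL divergence driving the adaptive
#'   learning rate. Default 0.002.
#' @param n_envs Parallel environments.
#' @param horizon Rollout length per environment per update. Default 32.
#' @param minibatch_size Minibatch size for the gradient steps.
#' @param ppo_epochs Optimization epochs per update. Default 5.
#' @param total_steps Total environment steps to collect.
#' @param discount Reward discount factor. Default 0.99.
#' @param gae_lambda Generalized-advantage-estimation lambda. Default 0.95.
#' @param learning_rate Initial Adam learning rate; adapted by the KL rule
#'   (halved when KL > 2x threshold, x1.5 when below half the threshold,
#'   bounded to \[1e-6, 1e-2\]).
#' @param action_std_init Initial policy standard deviation (normalized
#'   action units); the log-std is a learned state-independent parameter.
#'   Default 0.2.
#' @param entropy_coef Entropy bonus coefficient. Default 1e-3.
#' @param vf_coef Value-loss coefficient. Default 0.5.
#' @param reward_scale Factor applied to rewards inside the learner (GAE and
#'   value targets only; reported returns are unscaled). Keeps the critic's
#'   targets O(1) when per-step rewards are large. Default 0.01.
#' @param grad_clip Global gradient-norm clip. Default 1.
#' @param normalize_advantages Normalize advantages to zero mean / unit
#'   variance per update. Default TRUE.
#' @param seed Integer RNG seed; training is bit-reproducible per seed.
#' @return An object of class `ppo_config`.
#' @export
ppo_config <- function(profile = c("desk", "paper"),
                       hidden_layers = NULL,
                       clip_epsilon = 0.2,
                       kl_threshold = 0.002,
                       n_envs = NULL,
                       horizon = 32L,
                       minibatch_size = NULL,
                       ppo_epochs = 5L,
                       total_steps = NULL,
                       discount = 0.99,
                       gae_lambda = 0.95,
                       learning_rate = 1e-3,
                       action_std_init = 0.2,
                       entropy_coef = 1e-3,
                       vf_coef = 0.5,
                       reward_scale = 0.01,
                       grad_clip = 1,
                       normalize_advantages = TRUE,
                       seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") {
    list(hidden_layers = c(256L, 256L), n_envs = 8192L,
         minibatch_size = 8192L, total_steps = 5e6)
  } else {
    list(hidden_layers = c(64L, 64L), n_envs = 64L,
         minibatch_size = 2048L, total_steps = 3e5)
  }
  if (is.null(hidden_layers)) hidden_layers <- defaults$hidden_layers
  if (is.null(n_envs)) n_envs <- defaults$n_envs
  if (is.null(minibatch_size)) minibatch_size <- defaults$minibatch_size
  if (is.null(total_steps)) total_steps <- defaults$total_steps
  stopifnot(clip_epsilon > 0, clip_epsilon < 1,
            discount > 0, discount <= 1,
            gae_lambda >= 0, gae_lambda <= 1,
            kl_threshold > 0, horizon >= 1, ppo_epochs >= 1,
            n_envs >= 1, minibatch_size >= 1, total_steps >= 1,
            learning_rate > 0, action_std_init > 0)
  structure(list(profile = profile, hidden_layers = as.integer(hidden_layers),
                 clip_epsilon = clip_epsilon, kl_threshold = kl_threshold,
                 n_envs = as.integer(n_envs), horizon = as.integer(horizon),
                 minibatch_size = as.integer(minibatch_size),
                 ppo_epochs = as.integer(ppo_epochs),
                 total_steps = total_steps, discount = discount,
                 gae_lambda = gae_lambda, learning_rate = learning_rate,
                 action_std_init = action_std_init,
                 entropy_coef = entropy_coef, vf_coef = vf_coef,
                 reward_scale = reward_scale, grad_clip = grad_clip,
                 normalize_advantages = normalize_advantages,
                 seed = as.integer(seed)),
            class = "ppo_config")
}

#' Probability ratio between new and old policies
#'
#' `exp(logp_new - logp_old)`, the likelihood ratio
#' `pi_theta(a|s) / pi_theta_old(a|s)` at the heart of the clipped
#' surrogate. The exponent is clamped to +/-30 (with a warning) to guard
#' against overflow.
#'
#' @param logp_new,logp_old Log-probabilities of the taken actions under the
#'   new and old policies (vectorized).
#' @return The elementwise probability ratio.
#' @export
probability_ratio <- function(logp_new, logp_old) {
  stopifnot(all(is.finite(logp_new)), all(is.finite(logp_old)))
  d <- logp_new - logp_old
  if (any(abs(d) > 30)) {
    warning("probability ratio exponent clamped to +/-30")
    d <- pmin(pmax(d, -30), 30)
  }
  exp(d)
}

#' Clipped surrogate objective (per sample)
#'
#' `min(ratio * A, clip(ratio, 1 - eps, 1 + eps) * A)`. The policy loss is
#' the negative mean of this quantity.
#'
#' @param ratio Probability ratios ([probability_ratio()]).
#' @param advantage Advantage estimates.
#' @param clip_epsilon Clipping parameter in (0, 1).
#' @return Per-sample objective values.
#' @export
clipped_surrogate <- function(ratio, advantage, clip_epsilon) {
  stopifnot(clip_epsilon > 0, clip_epsilon < 1)
  pmin(ratio * advantage,
       pmin(pmax(ratio, 1 - clip_epsilon), 1 + clip_epsilon) * advantage)
}

#' Critic loss
#'
#' Mean squared error between value estimates and value targets.
#'
#' @param v_estimate,v_target Vectors of value estimates and targets.
#' @return Scalar mean squared error.
#' @export
value_loss <- function(v_estimate, v_target) {
  stopifnot(length(v_estimate) == length(v_target),
            all(is.finite(v_estimate)), all(is.finite(v_target)))
  mean((v_estimate - v_target)^2)
}

#' Generalized advantage estimation
#'
#' Computes GAE advantages and value targets over a rollout, resetting the
#' recursion at episode boundaries and bootstrapping truncated tails with
#' `bootstrap` (the critic's value of the state following the last step).
#'
#' @param rewards,values Numeric T x n matrices (or length-T vectors for
#'   n = 1): per-step rewards and value estimates `V(s_t)`.
#' @param dones Logical T x n matrix (or vector): TRUE where the transition
#'   ended its episode.
#' @param discount,gae_lambda Discount factor and GAE lambda.
#' @param bootstrap Length-n vector `V(s_T)` for truncated tails; defaults
#'   to zeros.
#' @return A list with `advantages` and `value_targets`
#'   (`advantages + values`), shaped like `rewards`.
#' @export
compute_advantages <- function(rewards, values, dones, discount = 0.99,
                               gae_lambda = 0.95, bootstrap = NULL) {
  vec_in <- is.null(dim(rewards))
  if (vec_in) {
    rewards <- matrix(rewards); values <- matrix(values)
    dones <- matrix(dones)
  }
  if (!all(dim(rewards) == dim(values)) || !all(dim(rewards) == dim(dones)))
    stop("rewards, values and dones must have matching dimensions")
  Tn <- nrow(rewards); n <- ncol(rewards)
  if (is.null(bootstrap)) bootstrap <- numeric(n)
  adv <- matrix(0, Tn, n)
  lastgae <- numeric(n)
  for (t in rev(seq_len(Tn))) {
    nonterm <- 1 - as.numeric(dones[t, ])
    nextv <- if (t == Tn) bootstrap else values[t + 1L, ]
    delta <- rewards[t, ] + discount * nextv * nonterm - values[t, ]
    lastgae <- delta + discount * gae_lambda * nonterm * lastgae
    adv[t, ] <- lastgae
  }
  vt <- adv + values
  if (vec_in) list(advantages = adv[, 1], value_targets = vt[, 1])
  else list(advantages = adv, value_targets = vt)
}


# Adaptive-learning-rate rule driven by the per-update KL divergence:
# halve above 2x the threshold, grow 1.5x below half of it, keep within
# [1e-6, 1e-2].
kl_lr_update <- function(lr, kl, kl_threshold) {
  if (kl > 2 * kl_threshold) max(lr / 2, 1e-6)
  else if (kl < kl_threshold / 2) min(lr * 1.5, 1e-2)
  else lr
}

# Policy loss and gradients for one minibatch. The gradient flows through
# the unclipped branch of the surrogate wherever it attains the min (ties
# resolve to the unclipped branch); the clipped branch is constant in theta.
ppo_actor_grads <- function(actor, log_std, Xb, Ab, logp_old, advb,
                            clip_epsilon, entropy_coef) {
  m <- nrow(Xb)
  fw <- mlp_forward(actor, Xb)
  mu <- fw$out
  logp <- gaussian_logp(Ab, mu, log_std)
  ratio <- exp(pmin(pmax(logp - logp_old, -30), 30))
  rclip <- pmin(pmax(ratio, 1 - clip_epsilon), 1 + clip_epsilon)
  surr <- pmin(ratio * advb, rclip * advb)
  loss <- -mean(surr)
  active <- (ratio * advb) <= (rclip * advb)
  coef <- -(ratio * advb * active) / m          # d(policy loss)/d(logp)
  sigma2 <- exp(2 * log_std)
  dmu <- sweep((Ab - mu), 2, sigma2, "/") * coef
  grads <- mlp_backward(actor, fw, dmu)
  dls <- colSums((sweep((Ab - mu)^2, 2, sigma2, "/") - 1) * coef) -
    entropy_coef
  list(loss = loss, grads = grads, dls = dls,
       n_clipped = sum(ratio != rclip), m = m)
}

# Gaussian log-density of actions under mean matrix mu and std vector sigma.
gaussian_logp <- function(actions, mu, log_std) {
  sigma2 <- exp(2 * log_std)
  z <- sweep((actions - mu)^2, 2, sigma2, "/")
  -0.5 * rowSums(z) - sum(log_std) - 0.5 * ncol(mu) * log(2 * pi)
}

#' Train a PPO policy
#'
#' Fits an actor-critic pair by proximal policy optimization: rollouts of
#' `horizon` steps are collected across `n_envs` parallel environments, then
#' the clipped-surrogate policy loss and squared-error value loss are
#' minimized by Adam for `ppo_epochs` epochs of minibatches, with the
#' learning rate adapted to hold the per-update KL divergence near
#' `kl_threshold`. The action distribution is a diagonal Gaussian with
#' state-independent learned log-std; actions live in `[-1, 1]` (scaled to
#' torques by the environment).
#'
#' Training is bit-reproducible for a fixed seed (single worker).
#'
#' @param make_env Environment factory `(n_envs, seed) -> env`; see
#'   [make_tracking_env()] and [make_toy_env()].
#' @param config A [ppo_config()].
#' @param verbose Print per-update diagnostics every `verbose` updates
#'   (0 = silent).
#' @param diagnostics_csv Optional path; per-update diagnostics are appended
#'   as CSV rows.
#' @return An object of class `ppo_policy`: actor/critic networks, learned
#'   log-std, observation scaling, the configuration, and a `diagnostics`
#'   data frame (update, steps, mean_return, kl, clip_fraction, lr,
#'   policy_loss, value_loss). Use [policy_action()], [predict.ppo_policy()]
#'   or [run_episode()] with it.
#' @export
ppo_train <- function(make_env, config = ppo_config(), verbose = 0,
                      diagnostics_csv = NULL) {
  set.seed(config$seed)
  env <- make_env(config$n_envs, config$seed)
  obs_dim <- env$obs_dim; act_dim <- env$act_dim
  obs_scale <- env$obs_scale
  n <- config$n_envs; Tn <- config$horizon
  N <- n * Tn

  actor <- mlp_init(obs_dim, config$hidden_layers, act_dim, out_scale = 0.01)
  critic <- mlp_init(obs_dim, config$hidden_layers, 1L, out_scale = 1)
  log_std <- rep(log(config$action_std_init), act_dim)
  opt_a <- adam_init(actor); opt_c <- adam_init(critic)
  ls_m <- numeric(act_dim); ls_v <- numeric(act_dim)  # Adam state for log_std
  lr <- config$learning_rate

  n_updates <- max(1L, as.integer(floor(config$total_steps / N)))
  diag_rows <- vector("list", n_updates)
  mean_ret <- NA_real_

  obs <- env$reset()
  for (upd in seq_len(n_updates)) {
    OBS <- matrix(0, N, obs_dim); ACT <- matrix(0, N, act_dim)
    MU <- matrix(0, N, act_dim)
    LOGP <- numeric(N)
    REW <- matrix(0, Tn, n); DONE <- matrix(FALSE, Tn, n)
    VAL <- matrix(0, Tn, n)
    fin_returns <- numeric(0)

    for (t in seq_len(Tn)) {
      X <- sweep(obs, 2, obs_scale, "*")
      mu <- mlp_forward(actor, X)$out
      eps <- matrix(stats::rnorm(n * act_dim), n, act_dim)
      a <- mu + sweep(eps, 2, exp(log_std), "*")
      idx <- ((t - 1L) * n + 1L):(t * n)
      OBS[idx, ] <- X
      ACT[idx, ] <- a
      MU[idx, ] <- mu
      LOGP[idx] <- gaussian_logp(a, mu, log_std)
      VAL[t, ] <- mlp_forward(critic, X)$out[, 1]
      sr <- env$step(a)
      REW[t, ] <- sr$reward
      DONE[t, ] <- sr$done
      fin_returns <- c(fin_returns, sr$finished_returns)
      obs <- sr$obs
    }
    Xlast <- sweep(obs, 2, obs_scale, "*")
    bootstrap <- mlp_forward(critic, Xlast)$out[, 1]
    ga <- compute_advantages(REW * config$reward_scale, VAL, DONE,
                             config$discount, config$gae_lambda, bootstrap)
    # flatten in the same (t, env) order as OBS/ACT
    adv <- as.numeric(t(ga$advantages))
    vt <- as.numeric(t(ga$value_targets))
    if (config$normalize_advantages) {
      adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
    }

    old_log_std <- log_std
    clip_hits <- 0L; clip_tot <- 0L
    pl_last <- vl_last <- NA_real_
    mb <- min(config$minibatch_size, N)
    for (ep in seq_len(config$ppo_epochs)) {
      perm <- sample.int(N)
      nb <- ceiling(N / mb)
      for (b in seq_len(nb)) {
        ii <- perm[(((b - 1L) * mb + 1L):min(b * mb, N))]
        Xb <- OBS[ii, , drop = FALSE]; Ab <- ACT[ii, , drop = FALSE]
        advb <- adv[ii]; vtb <- vt[ii]
        m <- length(ii)

        ag <- ppo_actor_grads(actor, log_std, Xb, Ab, LOGP[ii], advb,
                              config$clip_epsilon, config$entropy_coef)
        pl <- ag$loss
        clip_hits <- clip_hits + ag$n_clipped
        clip_tot <- clip_tot + m
        if (!is.finite(pl)) stop("NaN policy loss at update ", upd)

        st <- adam_step(actor, ag$grads, opt_a, lr,
                        grad_clip = config$grad_clip)
        actor <- st$net; opt_a <- st$opt
        # Adam on log_std (shares the learning rate)
        ls_m <- 0.9 * ls_m + 0.1 * ag$dls
        ls_v <- 0.999 * ls_v + 0.001 * ag$dls^2
        tstep <- opt_a$t
        log_std <- log_std - lr * (ls_m / (1 - 0.9^tstep)) /
          (sqrt(ls_v / (1 - 0.999^tstep)) + 1e-8)
        log_std <- pmin(pmax(log_std, -4), 1)

        fwc <- mlp_forward(critic, Xb)
        verr <- fwc$out[, 1] - vtb
        vl <- mean(verr^2)
        if (!is.finite(vl)) stop("NaN value loss at update ", upd)
        dv <- matrix(config$vf_coef * 2 * verr / m, m, 1)
        gc_ <- mlp_backward(critic, fwc, dv)
        st <- adam_step(critic, gc_, opt_c, lr, grad_clip = config$grad_clip)
        critic <- st$net; opt_c <- st$opt
        pl_last <- pl; vl_last <- vl
      }
    }

    # analytic diagonal-Gaussian KL(old || new) on the full batch
    mu_new <- mlp_forward(actor, OBS)$out
    s2o <- exp(2 * old_log_std); s2n <- exp(2 * log_std)
    klmat <- sweep(sweep((MU - mu_new)^2, 2, s2o, "+"), 2, 2 * s2n, "/")
    kl <- mean(rowSums(sweep(klmat, 2, log_std - old_log_std, "+") - 0.5))
    lr <- kl_lr_update(lr, kl, config$kl_threshold)

    if (length(fin_returns) > 0) mean_ret <- mean(fin_returns)
    diag_rows[[upd]] <- data.frame(
      update = upd, steps = upd * N, mean_return = mean_ret, kl = kl,
      clip_fraction = clip_hits / max(clip_tot, 1L), lr = lr,
      policy_loss = pl_last, value_loss = vl_last)
    if (verbose > 0 && upd %% verbose == 0)
      message(sprintf("update %d/%d  return %.2f  kl %.4f  lr %.2g",
                      upd, n_updates, mean_ret, kl, lr))
  }

  diagnostics <- do.call(rbind, diag_rows)
  if (!is.null(diagnostics_csv))
    utils::write.table(diagnostics, diagnostics_csv, sep = ",",
                       row.names = FALSE,
                       col.names = !file.exists(diagnostics_csv),
                       append = file.exists(diagnostics_csv))

  structure(list(actor = actor, critic = critic, log_std = log_std,
                 obs_scale = obs_scale, obs_dim = obs_dim, act_dim = act_dim,
                 config = config, diagnostics = diagnostics),
            class = c("ppo_policy", "postcoord_policy"))
}

#' @export
policy_action.ppo_policy <- function(policy, obs, deterministic = FALSE, ...) {
  X <- sweep(obs, 2, policy$obs_scale, "*")
  mu <- mlp_forward(policy$actor, X)$out
  if (deterministic) return(mu)
  mu + sweep(matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)), 2,
             exp(policy$log_std), "*")
}

#' Predict method for PPO policies
#'
#' @param object A `ppo_policy`.
#' @param newdata Observation matrix (rows = states) or a single observation
#'   vector.
#' @param type `"action"` (actor mean) or `"value"` (critic estimate).
#' @param ... Unused.
#' @return Action matrix or value vector.
#' @export
predict.ppo_policy <- function(object, newdata, type = c("action", "value"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  X <- sweep(newdata, 2, object$obs_scale, "*")
  if (type == "action") mlp_forward(object$actor, X)$out
  else mlp_forward(object$critic, X)$out[, 1]
}

#' @export
print.ppo_policy <- function(x, ...) {
  cfg <- x$config
  d <- x$diagnostics
  cat(sprintf("PPO policy (%s profile): obs %d -> hidden [%s] -> act %d\n",
              cfg$profile, x$obs_dim,
              paste(cfg$hidden_layers, collapse = ", "), x$act_dim))
  cat(sprintf("  trained %d updates (%.3g env steps), final mean return %.3f\n",
              nrow(d), utils::tail(d$steps, 1), utils::tail(d$mean_return, 1)))
  cat(sprintf("  action std %s, final lr %.2g, final KL %.4g\n",
              paste(signif(exp(x$log_std), 3), collapse = "/"),
              utils::tail(d$lr, 1), utils::tail(d$kl, 1)))
  invisible(x)
}

#' @export
summary.ppo_policy <- function(object, ...) {
  print(object)
  cat("\nTraining diagnostics (last 5 updates):\n")
  print(utils::tail(object$diagnostics, 5), row.names = FALSE)
  invisible(object$diagnostics)
}

#' @export
plot.ppo_policy <- function(x, ...) {
  d <- x$diagnostics
  graphics::plot(d$update, d$mean_return, type = "l", xlab = "update",
                 ylab = "mean episode return", main = "PPO training curve", ...)
  invisible(x)
}

#' Save / load a policy checkpoint
#'
#' Writes the policy to `path` (RDS) with a JSON metadata sidecar
#' (`<path>.json`) recording the package version, seed, configuration hash
#' and step count.
#'
#' @param policy A `ppo_policy`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the policy.
#' @export
save_checkpoint <- function(policy, path) {
  saveRDS(policy, path)
  cfg_file <- tempfile()
  saveRDS(policy$config, cfg_file)
  meta <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("postcoord")),
    seed = policy$config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    steps = utils::tail(policy$diagnostics$steps, 1)
  )
  unlink(cfg_file)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
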