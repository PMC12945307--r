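#' Reward configuration for the dosing MDP
#'
#' @param G_target set-point glucose (mg/dl) at which the per-step reward
#'   attains its maximum of 0.
#' @param G_min,G_max admissible glucose range (mg/dl); readings outside it
#'   receive the fixed `penalty`.
#' @param penalty reward for out-of-range glucose.
#' @param gamma discount factor in (0, 1].
#' @return A named list of class `reward_config`.
#' @export
reward_config <- function(G_target = 120, G_min = 80, G_max = 180,
                          penalty = -10, gamma = 0.99) {
  stopifnot(G_min < G_target, G_target < G_max, gamma > 0, gamma <= 1)
  structure(list(G_target = G_target, G_min = G_min, G_max = G_max,
                 penalty = penalty, gamma = gamma),
            class = "reward_config")
}

#' Per-step reward of the glucose-regulation MDP
#'
#' \deqn{r_t = -\left(\frac{G_t - G_{target}}{G_{target}}\right)^2 \ \ \text{if }
#'   G_{min} \le G_t \le G_{max}; \quad -10 \ \text{otherwise.}}
#' The reward is never positive and equals 0 only at the set-point.
#'
#' @param G glucose reading(s) in mg/dl.
#' @param cfg a [reward_config()].
#' @return Numeric vector of rewards.
#' @export
reward <- function(G, cfg = reward_config()) {
  stopifnot(all(is.finite(G)))
  ifelse(G >= cfg$G_min & G <= cfg$G_max,
         -((G - cfg$G_target) / cfg$G_target)^2,
         cfg$penalty)
}

#' Discounted return of a reward sequence
#'
#' \eqn{R = \sum_{i=0}^{T} \gamma^i r_i}; an empty sequence returns 0.
#'
#' @param rewards numeric vector of per-step rewards.
#' @param gamma discount factor in (0, 1].
#' @return The discounted return (scalar).
#' @export
episode_return <- function(rewards, gamma = 0.99) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 1) {
    stop("gamma must lie in (0, 1]", call. = FALSE)
  }
  if (length(rewards) == 0L) return(0)
  sum(gamma^(seq_along(rewards) - 1L) * rewards)
}

#' Build an offline replay buffer from a coarse (t, G, u1) table
#'
#' Forms sliding-window transitions on the decision grid (1 h by default):
#' the state is the window of the last `w` glucose values, the action is the
#' insulin rate held over the next interval, and the reward is computed from
#' the glucose observed at the next step.  Actions are clamped to
#' `[0, a_max]`, where by default `a_max = min(2 * max(observed u1), cap)` —
#' the agent is allowed up to twice the strongest documented infusion rate,
#' never exceeding the clinically safe 90 mU/min.
#'
#' @param tab data.frame with columns `t`, `G`, `u1` on a regular coarse grid.
#' @param cfg a [reward_config()].
#' @param w state window length (number of past glucose values).
#' @param a_max optional action bound (mU/min); computed from the data when
#'   `NULL`.
#' @param cap hard upper bound on `a_max` (mU/min).
#' @return An object of class `replay_buffer`: matrices `states`,
#'   `next_states` (rows are windows), vectors `actions`, `rewards`,
#'   `dones`, plus `w`, `a_max`, `gamma` and z-score `norm` statistics.
#' @export
build_buffer <- function(tab, cfg = reward_config(), w = 5L, a_max = NULL,
                         cap = 90) {
  stopifnot(all(c("t", "G", "u1") %in% names(tab)))
  L <- nrow(tab)
  if (L < w + 1L) stop("table shorter than w + 1", call. = FALSE)
  if (is.null(a_max)) a_max <- min(2 * max(tab$u1), cap)
  stopifnot(a_max > 0, a_max <= cap)
  idx <- w:(L - 1L)
  states <- t(vapply(idx, function(i) tab$G[(i - w + 1L):i], numeric(w)))
  next_states <- t(vapply(idx, function(i) tab$G[(i - w + 2L):(i + 1L)],
                          numeric(w)))
  actions <- pmin(pmax(tab$u1[idx], 0), a_max)
  rewards <- reward(tab$G[idx + 1L], cfg)
  dones <- as.numeric(idx + 1L == L)
  structure(list(
    states = states, actions = actions, rewards = rewards,
    next_states = next_states, dones = dones,
    w = as.integer(w), a_max = a_max, gamma = cfg$gamma, cfg = cfg,
    norm = list(mean = mean(states), sd = max(sd(states), 1e-8))
  ), class = "replay_buffer")
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat(sprintf("<replay_buffer> %d transitions, w = %d, a_max = %.3g mU/min\n",
              length(x$actions), x$w, x$a_max))
  invisible(x)
}

#' Save / load a replay buffer as plain text
#'
#' The transition arrays go to a CSV at full double precision and the
#' metadata to a JSON sidecar, so a round-trip reproduces every transition
#' bitwise.
#'
#' @param buffer a [build_buffer()] result.
#' @param path base path (without extension); writes `path.csv` and
#'   `path.json`.
#' @return `path` (for `save_buffer`); a `replay_buffer` (for `load_buffer`).
#' @export
save_buffer <- function(buffer, path) {
  w <- buffer$w
  df <- data.frame(buffer$states, action = buffer$actions,
                   reward = buffer$rewards, buffer$next_states,
                   done = buffer$dones)
  names(df) <- c(paste0("s", seq_len(w)), "action", "reward",
                 paste0("ns", seq_len(w)), "done")
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(w = buffer$w, a_max = buffer$a_max, gamma = buffer$gamma,
               norm = buffer$norm,
               cfg = unclass(buffer$cfg))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_buffer
#' @export
load_buffer <- function(path) {
  df <- read.csv(paste0(path, ".csv"), colClasses = "character")
  df[] <- lapply(df, as.numeric)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- meta$w
  structure(list(
    states = as.matrix(df[paste0("s", seq_len(w))]),
    actions = df$action, rewards = df$reward,
    next_states = as.matrix(df[paste0("ns", seq_len(w))]),
    dones = df$done, w = as.integer(w), a_max = as.numeric(meta$a_max),
    gamma = as.numeric(meta$gamma),
    cfg = do.call(reward_config,
                  lapply(meta$cfg[c("G_target", "G_min", "G_max",
                                    "penalty", "gamma")], as.numeric)),
    norm = list(mean = as.numeric(meta$norm$mean),
                sd = as.numeric(meta$norm$sd))
  ), class = "replay_buffer")
}

# ---------------------------------------------------------------------------
# Closed-loop twin environment

#' Closed-loop evaluation environment on the digital twin
#'
#' Wraps a patient twin with fixed meal (`u2`) and exercise (`u3`) forcings
#' into an episodic environment on the coarse decision grid: at each step the
#' agent observes the window of the last `w` glucose values, chooses the
#' insulin rate `u1` for the next interval, and the twin integrates forward.
#' Episodes partition the forcing span; each episode restarts the twin from
#' its basal state (window seeded with the basal glucose).
#'
#' @param params a [patient_params()] (ground truth or SBINN-inferred).
#' @param forcing a [forcing_set()]; `u1` is ignored during closed loop.
#' @param cfg a [reward_config()].
#' @param dt_step decision interval in minutes.
#' @param w state window length.
#' @param a_max action bound (mU/min).
#' @param episode_steps steps per episode.
#' @return An object of class `twin_env`.
#' @export
twin_env <- function(params, forcing, cfg = reward_config(), dt_step = 60,
                     w = 5L, a_max = 90, episode_steps = 24L) {
  span <- series_end(forcing$u1) - forcing$u1$t0
  n_steps <- floor(span / dt_step)
  structure(list(
    params = params, forcing = forcing, cfg = cfg, dt_step = dt_step,
    w = as.integer(w), a_max = a_max,
    episode_steps = as.integer(episode_steps),
    n_episodes = max(1L, floor(n_steps / episode_steps))
  ), class = "twin_env")
}

# One environment step: integrate the twin over [t, t + dt) with u1 = action.
env_step <- function(env, twin_state, t, action) {
  p <- env$params
  u2c <- crop_series(env$forcing$u2, t, t + env$dt_step)
  u3c <- crop_series(env$forcing$u3, t, t + env$dt_step)
  f <- forcing_set(
    uniform_series(rep(action, length(u2c$values)), t0 = u2c$t0,
                   dt = u2c$dt, unit = "mU/min"),
    u2c, u3c
  )
  tr <- twin_simulate(p, f, s0 = twin_state, times = c(t, t + env$dt_step),
                      rtol = 1e-6, atol = 1e-6)
  s_next <- unlist(tr[2L, TWIN_STATES])
  list(state = s_next, G = s_next[["G"]])
}

# Crop a uniform series to [a, b) (at least one sample).
crop_series <- function(x, a, b) {
  tt <- series_times(x)
  keep <- tt >= a - x$dt & tt < b
  if (!any(keep)) keep <- which.min(abs(tt - a))
  uniform_series(x$values[keep], t0 = max(x$t0, a), dt = x$dt, unit = x$unit)
}

#' Roll out a policy on the twin environment
#'
#' Runs closed-loop episodes and scores them with the discounted return.
#' The policy may be an agent artifact from [train_td3bc()] / [train_bcq()],
#' or a plain function `(window, step_index) -> u1` (e.g. a replay of logged
#' behavior).  Failed twin integrations mark the episode as failed and
#' exclude it with a warning.
#'
#' @param policy agent artifact or function.
#' @param env a [twin_env()].
#' @param episodes episode indices to run (default all).
#' @param seed seed for any stochastic action sampling (BCQ candidates).
#' @return List with `returns` (one per completed episode) and `trajectory`
#'   (data.frame `episode, step, t, G, u1, reward`).
#' @export
evaluate_policy <- function(policy, env, episodes = NULL, seed = 0L) {
  if (is.null(episodes)) episodes <- seq_len(env$n_episodes)
  act <- policy_fun(policy, env)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  returns <- numeric(0)
  rows <- list()
  for (ep in episodes) {
    t0 <- env$forcing$u1$t0 + (ep - 1L) * env$episode_steps * env$dt_step
    twin_state <- basal_state(env$params)
    window <- rep(env$params$Gb, env$w)
    rew <- numeric(env$episode_steps)
    ok <- TRUE
    for (k in seq_len(env$episode_steps)) {
      t <- t0 + (k - 1L) * env$dt_step
      a <- min(max(act(window, (ep - 1L) * env$episode_steps + k), 0),
               env$a_max)
      step <- tryCatch(env_step(env, twin_state, t, a),
                       error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      twin_state <- step$state
      window <- c(window[-1L], step$G)
      rew[k] <- reward(step$G, env$cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        episode = ep, step = k, t = t, G = step$G, u1 = a, reward = rew[k])
    }
    if (ok) {
      returns <- c(returns, episode_return(rew, env$cfg$gamma))
    } else {
      warning("episode ", ep, " failed during twin integration; excluded")
    }
  }
  list(returns = returns, trajectory = do.call(rbind, rows))
}

# Normalize helpers: states are z-scored with the buffer statistics; actions
# are mapped to [-1, 1] internally and back to [0, a_max] at the interface.
norm_state <- function(S, norm) (S - norm$mean) / norm$sd
norm_action <- function(a, a_max) 2 * a / a_max - 1
denorm_action <- function(an, a_max) (pmin(pmax(an, -1), 1) + 1) / 2 * a_max

# Resolve a policy object into an action function (window, step) -> u1.
policy_fun <- function(policy, env) {
  if (is.function(policy)) return(policy)
  stopifnot(inherits(policy, "rl_agent"))
  function(window, step) agent_act(policy, window)
}

#' Action of a trained agent for a raw glucose window
#'
#' @param agent an `rl_agent` artifact.
#' @param window numeric vector of the last `w` glucose values (mg/dl).
#' @return Insulin rate in `[0, a_max]` (mU/min).
#' @export
agent_act <- function(agent, window) {
  s <- matrix(norm_state(window, agent$norm), nrow = 1L)
  if (agent$algo == "td3bc") {
    an <- mlp_forward(agent$actor, s)
    return(denorm_action(an[1L], agent$a_max))
  }
  # BCQ: sample candidate actions from the VAE decoder, perturb, pick argmax-Q
  m <- agent$hyper$n_candidates
  S <- s[rep(1L, m), , drop = FALSE]
  Z <- matrix(pmin(pmax(rnorm(m * agent$hyper$latent_dim), -0.5), 0.5),
              m, agent$hyper$latent_dim)
  A <- mlp_forward(agent$decoder, cbind(S, Z))
  A <- pmin(pmax(A + agent$hyper$phi *
                   mlp_forward(agent$perturb, cbind(S, A)), -1), 1)
  q <- mlp_forward(agent$critic1, cbind(S, A))
  denorm_action(A[which.max(q), 1L], agent$a_max)
}

# ---------------------------------------------------------------------------
# TD3+BC

#' Train a TD3+BC agent on an offline buffer
#'
#' Twin Delayed DDPG with target-policy smoothing, clipped double-Q targets
#' and delayed policy updates, plus a behavior-cloning regularizer: the
#' policy maximizes \eqn{\lambda Q(s, \pi(s)) - (\pi(s) - a)^2} with the
#' normalizer \eqn{\lambda = \alpha / (\frac{1}{N}\sum |Q(s,a)|)} recomputed
#' per minibatch, so `alpha` trades off reinforcement learning (high) against
#' imitation (low).
#'
#' When an evaluation environment is supplied, the agent is rolled out every
#' `eval_every` iterations and the artifact returned is the checkpoint with
#' the highest mean evaluation return.
#'
#' @param buffer a [build_buffer()] result.
#' @param hyper named list of hyperparameters; see Details for defaults
#'   (`alpha = 2.5`, `hidden = c(64, 64)`, `lr = 3e-4`, `tau = 0.005`,
#'   `policy_noise = 0.2`, `noise_clip = 0.5`, `policy_freq = 2`,
#'   `batch = 128`, `iters = 2000`, `reward_scale = 10`).
#' @param seed integer seed (weights, minibatches, smoothing noise).
#' @param env optional [twin_env()] for periodic evaluation.
#' @param eval_every,eval_episodes evaluation cadence and episode count.
#' @return An object of class `rl_agent` (`algo = "td3bc"`) with the actor
#'   and critic networks, hyperparameters, training `history`, and
#'   `best_iter`.
#' @export
train_td3bc <- function(buffer, hyper = list(), seed = 0L, env = NULL,
                        eval_every = 500L, eval_episodes = NULL) {
  h <- modifyList(list(alpha = 2.5, hidden = c(64L, 64L), lr = 3e-4,
                       tau = 0.005, policy_noise = 0.2, noise_clip = 0.5,
                       policy_freq = 2L, batch = 128L, iters = 2000L,
                       reward_scale = 10), hyper)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  w <- buffer$w
  S <- norm_state(buffer$states, buffer$norm)
  S2 <- norm_state(buffer$next_states, buffer$norm)
  A <- matrix(norm_action(buffer$actions, buffer$a_max), ncol = 1L)
  R <- buffer$rewards / h$reward_scale
  D <- buffer$dones
  N <- nrow(S); gamma <- buffer$gamma

  actor <- mlp_new(c(w, h$hidden, 1L), out_act = "tanh")
  critic1 <- mlp_new(c(w + 1L, h$hidden, 1L))
  critic2 <- mlp_new(c(w + 1L, h$hidden, 1L))
  actor_t <- actor; critic1_t <- critic1; critic2_t <- critic2
  oa <- adam_new(actor); oc1 <- adam_new(critic1); oc2 <- adam_new(critic2)

  best <- list(ret = -Inf, actor = actor, critic1 = critic1,
               critic2 = critic2, iter = 0L)
  hist <- vector("list", h$iters)

  for (it in seq_len(h$iters)) {
    idx <- sample.int(N, h$batch, replace = TRUE)
    s <- S[idx, , drop = FALSE]; s2 <- S2[idx, , drop = FALSE]
    a <- A[idx, , drop = FALSE]; r <- R[idx]; d <- D[idx]

    noise <- pmin(pmax(rnorm(h$batch, 0, h$policy_noise),
                       -h$noise_clip), h$noise_clip)
    a2 <- pmin(pmax(mlp_forward(actor_t, s2) + noise, -1), 1)
    q2 <- pmin(mlp_forward(critic1_t, cbind(s2, a2)),
               mlp_forward(critic2_t, cbind(s2, a2)))
    y <- r + gamma * (1 - d) * q2

    sa <- cbind(s, a)
    f1 <- mlp_forward(critic1, sa, keep_cache = TRUE)
    f2 <- mlp_forward(critic2, sa, keep_cache = TRUE)
    e1 <- f1$out - y; e2 <- f2$out - y
    closs <- mean(e1^2) + mean(e2^2)
    g1 <- mlp_backward(critic1, f1, 2 * e1 / h$batch)
    g2 <- mlp_backward(critic2, f2, 2 * e2 / h$batch)
    up <- adam_step(critic1, g1, oc1, h$lr); critic1 <- up$net; oc1 <- up$st
    up <- adam_step(critic2, g2, oc2, h$lr); critic2 <- up$net; oc2 <- up$st

    aloss <- NA_real_
    if (it %% h$policy_freq == 0L) {
      fa <- mlp_forward(actor, s, keep_cache = TRUE)
      a_pi <- fa$out
      fq <- mlp_forward(critic1, cbind(s, a_pi), keep_cache = TRUE)
      lambda <- td3bc_lambda(h$alpha, fq$out)
      aloss <- -lambda * mean(fq$out) + mean((a_pi - a)^2)
      # dQ/da through the critic input, plus the BC term
      gq <- mlp_backward(critic1, fq, matrix(-lambda / h$batch, h$batch, 1L))
      dA <- gq$dX[, w + 1L, drop = FALSE] + 2 * (a_pi - a) / h$batch
      ga <- mlp_backward(actor, fa, dA)
      up <- adam_step(actor, ga, oa, h$lr); actor <- up$net; oa <- up$st
      critic1_t <- soft_update(critic1_t, critic1, h$tau)
      critic2_t <- soft_update(critic2_t, critic2, h$tau)
      actor_t <- soft_update(actor_t, actor, h$tau)
    }

    ev <- NA_real_
    if (!is.null(env) && (it %% eval_every == 0L || it == h$iters)) {
      cand <- structure(list(algo = "td3bc", actor = actor,
                             norm = buffer$norm, a_max = buffer$a_max),
                        class = "rl_agent")
      ev <- mean(evaluate_policy(cand, env, episodes = eval_episodes,
                                 seed = seed + 10000L)$returns)
      if (ev > best$ret) best <- list(ret = ev, actor = actor,
                                      critic1 = critic1, critic2 = critic2,
                                      iter = it)
    }
    hist[[it]] <- c(iter = it, critic_loss = closs, actor_loss = aloss,
                    eval_return = ev)
  }
  if (is.null(env)) best <- list(ret = NA_real_, actor = actor,
                                 critic1 = critic1, critic2 = critic2,
                                 iter = h$iters)
  structure(list(
    algo = "td3bc", actor = best$actor, critic1 = best$critic1,
    critic2 = best$critic2, hyper = h, seed = seed,
    best_iter = best$iter, best_return = best$ret,
    norm = buffer$norm, a_max = buffer$a_max, w = w,
    history = as.data.frame(do.call(rbind, hist))
  ), class = "rl_agent")
}

#' Behavior-cloning weight of TD3+BC
#'
#' \eqn{\lambda = \alpha / (\frac{1}{N} \sum |Q(s,a)|)}, with an epsilon
#' floor on the denominator guarding all-zero Q batches.
#'
#' @param alpha RL-vs-imitation trade-off.
#' @param qvals critic values of the minibatch.
#' @param eps denominator floor.
#' @return The scalar weight.
#' @export
td3bc_lambda <- function(alpha, qvals, eps = 1e-8) {
  denom <- mean(abs(qvals))
  if (denom < eps) {
    warning("batch with ~zero |Q|; lambda floored")
    denom <- eps
  }
  alpha / denom
}

# ---------------------------------------------------------------------------
# BCQ (continuous)

#' Train a continuous BCQ agent on an offline buffer
#'
#' Batch-Constrained Q-learning for continuous actions: a conditional
#' variational autoencoder models the behavior-policy action distribution
#' (reconstruction loss plus `wKL`-weighted Kullback-Leibler divergence), a
#' perturbation network adjusts sampled actions within `±phi`, and twin
#' Q-networks with the convex min/max-weighted clipped double-Q target score
#' candidate actions.  Action selection is argmax-Q over `n_candidates`
#' VAE-sampled perturbed candidates, which constrains the policy near the
#' support of the data.
#'
#' @param buffer a [build_buffer()] result.
#' @param hyper named list; defaults: `wKL = 0.5`, `latent_dim = 2`,
#'   `n_candidates = 10`, `phi = 0.05`, `lambda_q = 0.75`,
#'   `hidden = c(64, 64)`, `lr = 3e-4`, `tau = 0.005`, `batch = 128`,
#'   `iters = 2000`, `reward_scale = 10`.
#' @param seed integer seed.
#' @param env optional [twin_env()] for periodic evaluation; the returned
#'   artifact is the best-evaluation checkpoint.
#' @param eval_every,eval_episodes evaluation cadence and episode count.
#' @return An object of class `rl_agent` (`algo = "bcq"`).
#' @export
train_bcq <- function(buffer, hyper = list(), seed = 0L, env = NULL,
                      eval_every = 500L, eval_episodes = NULL) {
  h <- modifyList(list(wKL = 0.5, latent_dim = 2L, n_candidates = 10L,
                       phi = 0.05, lambda_q = 0.75, hidden = c(64L, 64L),
                       lr = 3e-4, tau = 0.005, batch = 128L, iters = 2000L,
                       reward_scale = 10), hyper)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  w <- buffer$w; ld <- h$latent_dim
  S <- norm_state(buffer$states, buffer$norm)
  S2 <- norm_state(buffer$next_states, buffer$norm)
  A <- matrix(norm_action(buffer$actions, buffer$a_max), ncol = 1L)
  R <- buffer$rewards / h$reward_scale
  D <- buffer$dones
  N <- nrow(S); gamma <- buffer$gamma

  encoder <- mlp_new(c(w + 1L, h$hidden, 2L * ld))      # -> (mu, log sd)
  decoder <- mlp_new(c(w + ld, h$hidden, 1L), out_act = "tanh")
  perturb <- mlp_new(c(w + 1L, h$hidden, 1L), out_act = "tanh")
  critic1 <- mlp_new(c(w + 1L, h$hidden, 1L))
  critic2 <- mlp_new(c(w + 1L, h$hidden, 1L))
  perturb_t <- perturb; critic1_t <- critic1; critic2_t <- critic2
  decoder_t <- decoder
  oe <- adam_new(encoder); od <- adam_new(decoder); op <- adam_new(perturb)
  oc1 <- adam_new(critic1); oc2 <- adam_new(critic2)

  # candidate actions from a decoder for a batch of states
  sample_actions <- function(dec, per, Sb, n_cand, clip_z = 0.5) {
    nb <- nrow(Sb)
    Srep <- Sb[rep(seq_len(nb), each = n_cand), , drop = FALSE]
    Z <- matrix(pmin(pmax(rnorm(nb * n_cand * ld), -clip_z), clip_z),
                nb * n_cand, ld)
    Arep <- mlp_forward(dec, cbind(Srep, Z))
    Arep <- pmin(pmax(Arep + h$phi * mlp_forward(per, cbind(Srep, Arep)),
                      -1), 1)
    list(S = Srep, A = Arep, nb = nb)
  }

  best <- list(ret = -Inf, nets = NULL, iter = 0L)
  snapshot <- function() list(decoder = decoder, perturb = perturb,
                              critic1 = critic1, critic2 = critic2)
  hist <- vector("list", h$iters)

  for (it in seq_len(h$iters)) {
    idx <- sample.int(N, h$batch, replace = TRUE)
    s <- S[idx, , drop = FALSE]; s2 <- S2[idx, , drop = FALSE]
    a <- A[idx, , drop = FALSE]; r <- R[idx]; d <- D[idx]
    nb <- h$batch

    # --- VAE update -------------------------------------------------------
    fe <- mlp_forward(encoder, cbind(s, a), keep_cache = TRUE)
    mu <- fe$out[, seq_len(ld), drop = FALSE]
    logsd <- pmin(pmax(fe$out[, ld + seq_len(ld), drop = FALSE], -4), 4)
    sdv <- exp(logsd)
    epsz <- matrix(rnorm(nb * ld), nb, ld)
    z <- mu + sdv * epsz
    fd <- mlp_forward(decoder, cbind(s, z), keep_cache = TRUE)
    recon_err <- fd$out - a
    recon <- mean(recon_err^2)
    kl <- mean(rowSums(-0.5 * (1 + 2 * logsd - mu^2 - sdv^2)))
    vae_loss <- recon + h$wKL * kl

    gd <- mlp_backward(decoder, fd, 2 * recon_err / nb)
    dZ <- gd$dX[, w + seq_len(ld), drop = FALSE]
    dMu <- dZ + h$wKL * mu / nb
    dLogsd <- dZ * sdv * epsz + h$wKL * (sdv^2 - 1) / nb
    # clamp gradient gate on log sd
    gate <- fe$out[, ld + seq_len(ld), drop = FALSE]
    dLogsd[gate < -4 | gate > 4] <- 0
    ge <- mlp_backward(encoder, fe, cbind(dMu, dLogsd))
    up <- adam_step(encoder, ge, oe, h$lr); encoder <- up$net; oe <- up$st
    up <- adam_step(decoder, gd, od, h$lr); decoder <- up$net; od <- up$st

    # --- critic update ----------------------------------------------------
    cand <- sample_actions(decoder_t, perturb_t, s2, h$n_candidates)
    q1c <- mlp_forward(critic1_t, cbind(cand$S, cand$A))
    q2c <- mlp_forward(critic2_t, cbind(cand$S, cand$A))
    qc <- h$lambda_q * pmin(q1c, q2c) + (1 - h$lambda_q) * pmax(q1c, q2c)
    qmat <- matrix(qc, nrow = h$n_candidates)
    v2 <- qmat[cbind(max.col(t(qmat), ties.method = "first"),
                     seq_len(ncol(qmat)))]
    y <- r + gamma * (1 - d) * v2

    sa <- cbind(s, a)
    f1 <- mlp_forward(critic1, sa, keep_cache = TRUE)
    f2 <- mlp_forward(critic2, sa, keep_cache = TRUE)
    e1 <- f1$out - y; e2 <- f2$out - y
    closs <- mean(e1^2) + mean(e2^2)
    g1 <- mlp_backward(critic1, f1, 2 * e1 / nb)
    g2 <- mlp_backward(critic2, f2, 2 * e2 / nb)
    up <- adam_step(critic1, g1, oc1, h$lr); critic1 <- up$net; oc1 <- up$st
    up <- adam_step(critic2, g2, oc2, h$lr); critic2 <- up$net; oc2 <- up$st

    # --- perturbation model update ---------------------------------------
    Zp <- matrix(pmin(pmax(rnorm(nb * ld), -0.5), 0.5), nb, ld)
    a_dec <- mlp_forward(decoder, cbind(s, Zp))
    fp <- mlp_forward(perturb, cbind(s, a_dec), keep_cache = TRUE)
    a_per <- a_dec + h$phi * fp$out
    inb <- a_per > -1 & a_per < 1        # clamp gate
    fq <- mlp_forward(critic1, cbind(s, pmin(pmax(a_per, -1), 1)),
                      keep_cache = TRUE)
    ploss <- -mean(fq$out)
    gq <- mlp_backward(critic1, fq, matrix(-1 / nb, nb, 1L))
    dAper <- gq$dX[, w + 1L, drop = FALSE] * inb
    gp <- mlp_backward(perturb, fp, h$phi * dAper)
    up <- adam_step(perturb, gp, op, h$lr); perturb <- up$net; op <- up$st

    critic1_t <- soft_update(critic1_t, critic1, h$tau)
    critic2_t <- soft_update(critic2_t, critic2, h$tau)
    perturb_t <- soft_update(perturb_t, perturb, h$tau)
    decoder_t <- soft_update(decoder_t, decoder, h$tau)

    ev <- NA_real_
    if (!is.null(env) && (it %% eval_every == 0L || it == h$iters)) {
      cand_agent <- structure(
        c(snapshot(), list(algo = "bcq", hyper = h, norm = buffer$norm,
                           a_max = buffer$a_max)), class = "rl_agent")
      ev <- mean(evaluate_policy(cand_agent, env, episodes = eval_episodes,
                                 seed = seed + 10000L)$returns)
      if (ev > best$ret) best <- list(ret = ev, nets = snapshot(), iter = it)
    }
    hist[[it]] <- c(iter = it, vae_loss = vae_loss, recon = recon, kl = kl,
                    critic_loss = closs, perturb_loss = ploss,
                    eval_return = ev)
  }
  nets <- if (!is.null(env) && !is.null(best$nets)) best$nets else snapshot()
  structure(c(nets, list(
    algo = "bcq", encoder = encoder, hyper = h, seed = seed,
    best_iter = if (is.null(env)) h$iters else best$iter,
    best_return = if (is.null(env)) NA_real_ else best$ret,
    norm = buffer$norm, a_max = buffer$a_max, w = w,
    history = as.data.frame(do.call(rbind, hist))
  )), class = "rl_agent")
}

#' @export
print.rl_agent <- function(x, ...) {
  cat(sprintf("<rl_agent> %s, w = %d, a_max = %.3g mU/min, best iter %d\n",
              x$algo, x$w, x$a_max, x$best_iter))
  invisible(x)
}
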