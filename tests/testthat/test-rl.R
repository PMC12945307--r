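test_that("the reward is maximal only at the set-point and penalizes out-of-range readings", {
  cfg <- reward_config()
  expect_equal(reward(120, cfg), 0)
  expect_equal(reward(180, cfg), -0.25)
  expect_equal(reward(80, cfg), -((80 - 120) / 120)^2)
  expect_equal(reward(60, cfg), -10)
  expect_equal(reward(180.0001, cfg), -10)
  g <- seq(40, 400, by = 0.5)
  r <- reward(g, cfg)
  expect_true(all(r <= 0))
  expect_equal(g[r == 0], 120)
  expect_error(reward_config(G_min = 130), "G_min")
})

test_that("episode returns discount geometrically and respect monotonicity", {
  expect_equal(episode_return(c(0, -10), gamma = 1), -10)
  expect_equal(episode_return(c(-1, -1), gamma = 0.5), -1.5)
  expect_equal(episode_return(numeric(0)), 0)
  expect_error(episode_return(c(-1), gamma = 0), "gamma")
  expect_error(episode_return(c(-1), gamma = 1.1), "gamma")
  set.seed(3)
  r <- -runif(20)
  for (k in sample(20, 5)) {
    r2 <- r; r2[k] <- r2[k] + 0.1   # raising any single reward
    expect_gt(episode_return(r2, 0.9), episode_return(r, 0.9))
  }
})

test_that("buffers contain L - w sliding-window transitions with next-step rewards", {
  tab <- data.frame(t = seq(0, by = 60, length.out = 30),
                    G = seq(100, 158, by = 2), u1 = rep(10, 30))
  buf <- build_buffer(tab, w = 5)
  expect_equal(length(buf$actions), 30 - 5)
  expect_equal(buf$states[1, ], tab$G[1:5])
  expect_equal(buf$next_states[1, ], tab$G[2:6])
  expect_equal(buf$rewards[1], reward(tab$G[6]))
  expect_equal(buf$dones, c(rep(0, 24), 1))
  expect_error(build_buffer(tab[1:5, ], w = 5), "shorter")

  # all-target glucose gives all-zero rewards
  tab120 <- data.frame(t = tab$t, G = rep(120, 30), u1 = rep(10, 30))
  expect_true(all(build_buffer(tab120, w = 5)$rewards == 0))

  # doubling rule under the 90 mU/min cap
  tab$u1[10] <- 30
  expect_equal(build_buffer(tab, w = 5)$a_max, 60)
  tab$u1[10] <- 80
  expect_equal(build_buffer(tab, w = 5)$a_max, 90)
})

test_that("buffers round-trip bitwise through the plain-text serialization", {
  p <- patient_params(Gb = 155)
  sc <- make_scenario(21, duration_days = 2,
                      cfg = scenario_config(dose_fraction = 0.5))
  buf <- build_buffer(coarse_grain(simulate_patient(sc, p)$table))
  path <- file.path(tempdir(), "buf")
  save_buffer(buf, path)
  buf2 <- load_buffer(path)
  expect_identical(unname(buf2$states), unname(buf$states))
  expect_identical(buf2$actions, buf$actions)
  expect_identical(buf2$rewards, buf$rewards)
  expect_identical(unname(buf2$next_states), unname(buf$next_states))
  expect_identical(buf2$dones, buf$dones)
  expect_identical(buf2$a_max, buf$a_max)
})

test_that("the TD3+BC behavior-cloning weight follows the batch normalization rule", {
  expect_equal(td3bc_lambda(2.5, rep(2, 64)), 1.25)
  expect_equal(td3bc_lambda(2.5, c(-2, 2, -2, 2)), 1.25)
  expect_warning(l0 <- td3bc_lambda(2.5, rep(0, 8)), "floored")
  expect_true(is.finite(l0))
})

# shared tiny buffer/env for the agent contract tests
local({
  p <- patient_params(Gb = 155)
  sc <- make_scenario(21, duration_days = 3,
                      cfg = scenario_config(dose_fraction = 0.5))
  sim <- simulate_patient(sc, p)
  buf <- build_buffer(coarse_grain(sim$table))
  hyper <- list(iters = 120L, batch = 32L)

  test_that("TD3+BC training is reproducible and emits bounded actions", {
    a1 <- train_td3bc(buf, hyper, seed = 7)
    a2 <- train_td3bc(buf, hyper, seed = 7)
    expect_identical(a1$history, a2$history)
    expect_identical(a1$actor, a2$actor)
    a3 <- train_td3bc(buf, hyper, seed = 8)
    expect_false(identical(a3$actor, a1$actor))
    set.seed(99)
    for (k in 1:25) {
      win <- runif(buf$w, 40, 400)
      act <- agent_act(a1, win)
      expect_gte(act, 0); expect_lte(act, buf$a_max)
    }
  })

  test_that("alpha -> 0 reduces the TD3+BC policy loss to behavior cloning", {
    a_bc <- train_td3bc(buf, c(hyper, list(alpha = 0)), seed = 7)
    # the cloned policy should track the buffer actions on buffer states
    pred <- vapply(seq_len(nrow(buf$states)), function(i)
      agent_act(a_bc, buf$states[i, ]), numeric(1))
    expect_lt(mean(abs(pred - buf$actions)), 0.25 * buf$a_max)
  })

  test_that("BCQ training is reproducible, bounded, and wKL = 0 removes the KL term", {
    b1 <- train_bcq(buf, hyper, seed = 7)
    b2 <- train_bcq(buf, hyper, seed = 7)
    expect_identical(b1$history, b2$history)
    set.seed(99)
    for (k in 1:25) {
      win <- runif(buf$w, 40, 400)
      act <- agent_act(b1, win)
      expect_gte(act, 0); expect_lte(act, buf$a_max)
    }
    b0 <- train_bcq(buf, c(hyper, list(wKL = 0)), seed = 7)
    expect_equal(b0$history$vae_loss, b0$history$recon)
    expect_false(isTRUE(all.equal(b1$history$vae_loss, b1$history$recon)))
  })

  test_that("the BCQ generative model concentrates near a deterministic behavior policy", {
    # one-action buffer: behavior always doses 12 mU/min
    tab1 <- data.frame(t = seq(0, by = 60, length.out = 80),
                       G = 130 + 20 * sin(seq_len(80) / 5), u1 = rep(12, 80))
    bufc <- build_buffer(tab1, a_max = 24)
    bc <- train_bcq(bufc, list(iters = 400L, batch = 32L), seed = 3)
    set.seed(5)
    acts <- vapply(seq_len(40), function(i)
      agent_act(bc, bufc$states[sample(nrow(bufc$states), 1), ]),
      numeric(1))
    expect_lt(mean(abs(acts - 12)), 4)   # mean abs deviation well under a_max/2
  })

  test_that("closed-loop evaluation returns per-episode discounted returns", {
    env <- twin_env(p, sc$forcing, w = buf$w, a_max = buf$a_max,
                    episode_steps = 12L)
    coarse <- coarse_grain(sim$table)
    behavior <- function(window, step) coarse$u1[min(step, nrow(coarse))]
    ev <- evaluate_policy(behavior, env, episodes = 1:2, seed = 1)
    expect_length(ev$returns, 2)
    expect_true(all(ev$returns <= 0))
    expect_equal(nrow(ev$trajectory), 2 * 12)
    expect_true(all(ev$trajectory$u1 >= 0 & ev$trajectory$u1 <= buf$a_max))
    # deterministic under the same seed
    ev2 <- evaluate_policy(behavior, env, episodes = 1:2, seed = 1)
    expect_identical(ev$returns, ev2$returns)
  })
})

test_that("a basal-stable patient at the set-point collects zero return under basal dosing", {
  p <- patient_params(Gb = 120)
  f <- basal_forcing(p, n = 24L * 12L)
  env <- twin_env(p, f, w = 5L, a_max = 90, episode_steps = 6L)
  ev <- evaluate_policy(function(window, step) p$u1b, env, episodes = 1,
                        seed = 0)
  expect_equal(ev$returns, 0, tolerance = 1e-8)
})
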