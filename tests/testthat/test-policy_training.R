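test_that("sample_location draws, clips and reproduces", {
  expect_error(sample_location(c(0, 0), 0), "sigma")
  # degenerate-sigma limit: the draw collapses onto the (clipped) mean
  s <- sample_location(c(0.25, -0.5), 1e-12)
  expect_equal(s$loc, c(0.25, -0.5), tolerance = 1e-9)
  # off-box mean is clipped to the corner
  s <- sample_location(c(5, 5), 0.2)
  expect_equal(s$loc, c(1, 1))
  set.seed(77); a <- sample_location(c(0, 0), 0.3)
  set.seed(77); b <- sample_location(c(0, 0), 0.3)
  expect_identical(a, b)
  # Monte-Carlo moments
  set.seed(5)
  draws <- t(replicate(20000, sample_location(c(0, 0), 0.2)$raw))
  expect_lt(max(abs(colMeans(draws))), 3 * 0.2 / sqrt(20000))
})

test_that("location_log_prob is the bivariate Gaussian log-density", {
  expect_equal(location_log_prob(c(0.1, -0.3), c(0.1, -0.3), 0.2),
               -log(2 * pi * 0.2^2))
  d <- c(0.07, -0.12)
  expect_equal(location_log_prob(c(0.1, 0.2) + d, c(0.1, 0.2), 0.15),
               location_log_prob(c(0.1, 0.2) - d, c(0.1, 0.2), 0.15))
  # quadrature: the density integrates to ~1
  gr <- seq(-2, 2, length.out = 801); h <- diff(gr)[1]
  dens <- outer(gr, gr, function(a, b)
    exp(vapply(seq_along(a), function(i)
      location_log_prob(c(a[i], b[i]), c(0.1, -0.2), 0.3), numeric(1))))
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-3)
  expect_error(location_log_prob(c(0, 0), c(0, 0), -1), "sigma")
})

test_that("step_reward implements the terminal-only 0/1 rule", {
  expect_equal(step_reward(2, 2, t = 6, T_total = 6), 1)
  expect_equal(step_reward(2, 3, t = 6, T_total = 6), 0)
  expect_equal(step_reward(2, 2, t = 3, T_total = 6), 0)
  expect_error(step_reward(0, 0, t = 0, T_total = 6), "out of range")
})

test_that("episode_return computes the discounted sum", {
  expect_equal(episode_return(c(0, 0, 1), gamma = 1), 1)
  expect_equal(episode_return(c(0, 0, 1), gamma = 0.5), 0.25)
  expect_equal(episode_return(rep(0, 5)), 0)
  expect_error(episode_return(numeric(0)), "non-empty")
})

test_that("rollout_episode follows the protocol and is seed-deterministic", {
  set.seed(10)
  ep <- gen_burst_eeg(1, channels = 8, timepoints = 60,
                      specs = default_burst_specs(2, 8, 60))[[1]]
  cfg <- glimpse_config(k = 2, base_rows = 2, base_cols = 5)
  p <- ram_params(2 * 2 * 5, 2, hidden = 16, glimpse_hidden = 8,
                  loc_hidden = 8, g_dim = 16, seed = 4)
  set.seed(123); tr1 <- rollout_episode(ep, p, 5, cfg)
  set.seed(123); tr2 <- rollout_episode(ep, p, 5, cfg)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1$locations), 5L)
  expect_equal(nrow(tr1$hidden_states), 5L)
  expect_length(tr1$log_probs, 5L)
  expect_length(tr1$rewards, 5L)
  expect_true(all(tr1$rewards[-5] == 0))
  expect_error(rollout_episode(ep, p, 0, cfg), "T_steps")

  # oracle action head forced to the true label -> return 1 at gamma = 1
  pf <- p; pf$W_a[] <- 0; pf$b_a[] <- -10; pf$b_a[ep$label + 1] <- 10
  trf <- rollout_episode(ep, pf, 4, cfg)
  expect_equal(trf$ret, 1)
  expect_equal(trf$action, ep$label)
})

test_that("mean return equals accuracy for greedy terminal 0/1 episodes", {
  set.seed(20)
  eps <- gen_burst_eeg(30, channels = 8, timepoints = 60,
                       specs = default_burst_specs(2, 8, 60))
  cfg <- glimpse_config(k = 2, base_rows = 2, base_cols = 5)
  p <- ram_params(20, 2, hidden = 12, glimpse_hidden = 6, loc_hidden = 6,
                  g_dim = 12, seed = 8)
  trs <- lapply(eps, rollout_episode, params = p, T_steps = 4, gconfig = cfg,
                stochastic = FALSE)
  rets <- vapply(trs, `[[`, numeric(1), "ret")
  preds <- vapply(trs, `[[`, integer(1), "action")
  labs <- vapply(eps, `[[`, integer(1), "label")
  expect_equal(mean(rets), mean(preds == labs))
  expect_true(all(rets >= 0 & rets <= 1))
})

test_that("reinforce_loss has zero gradient under zero advantage", {
  set.seed(30)
  eps <- gen_burst_eeg(6, channels = 8, timepoints = 60,
                       specs = default_burst_specs(2, 8, 60))
  cfg <- glimpse_config(k = 2, base_rows = 2, base_cols = 5)
  p <- ram_params(20, 2, hidden = 12, glimpse_hidden = 6, loc_hidden = 6,
                  g_dim = 12, seed = 8)
  trs <- lapply(eps, rollout_episode, params = p, T_steps = 3, gconfig = cfg)
  batch <- list(trajectories = trs)
  rl <- reinforce_loss(batch, p,
                       baselines = lapply(trs, function(tr) rep(tr$ret, 3)))
  expect_equal(max(abs(rl$grad$W_loc)), 0)
  expect_equal(max(abs(rl$grad$b_loc)), 0)
  expect_error(reinforce_loss(list(trajectories = list()), p), "empty")
  # learned-baseline path runs and returns finite numbers
  rl2 <- reinforce_loss(batch, p)
  expect_true(all(is.finite(rl2$grad$W_loc)))
  expect_true(is.finite(rl2$surrogate))
})

test_that("score-function estimator is unbiased on the Gaussian bandit", {
  # 1-step policy l ~ N(mu, sigma^2), reward R(l) = -(l - l*)^2;
  # closed form dJ/dmu = -2 (mu - l*).
  set.seed(40)
  mu <- 0.3; lstar <- -0.2; sigma <- 0.25
  M <- 20000
  draws <- rnorm(M, mu, sigma)
  R <- -(draws - lstar)^2
  g_hat <- mean(score_grad_mean(draws, mu, sigma) * R)
  se <- sd(score_grad_mean(draws, mu, sigma) * R) / sqrt(M)
  expect_lt(abs(g_hat - (-2 * (mu - lstar))), 5 * se)
})

test_that("a constant baseline leaves the estimator mean unchanged and the learned one cuts variance", {
  set.seed(41)
  mu <- 0.1; lstar <- 0.4; sigma <- 0.3
  n_batches <- 2000; M <- 20
  # "learned" baseline: E[R] estimated once from an independent pilot sample,
  # so it enters the estimator as a constant
  pilot <- rnorm(5000, mu, sigma)
  b_learned <- mean(-(pilot - lstar)^2)
  est <- function(b) {
    vapply(seq_len(n_batches), function(i) {
      draws <- rnorm(M, mu, sigma)
      R <- -(draws - lstar)^2
      mean(score_grad_mean(draws, mu, sigma) * (R - b))
    }, numeric(1))
  }
  e0 <- est(0); eb <- est(b_learned)
  se <- sqrt(var(e0) / n_batches + var(eb) / n_batches)
  expect_lt(abs(mean(e0) - mean(eb)), 3 * se)
  expect_lt(var(eb), var(e0))
})

test_that("hybrid_update obeys basic contracts", {
  set.seed(50)
  eps <- gen_burst_eeg(16, channels = 8, timepoints = 60,
                       specs = default_burst_specs(2, 8, 60))
  cfg <- glimpse_config(k = 2, base_rows = 2, base_cols = 5)
  p <- ram_params(20, 2, hidden = 12, glimpse_hidden = 6, loc_hidden = 6,
                  g_dim = 12, seed = 8)
  sig <- lapply(eps, `[[`, "data"); labs <- vapply(eps, `[[`, integer(1), "label")
  # zero learning rate leaves every parameter unchanged
  upd0 <- hybrid_update(sig, labs, p, NULL, T_steps = 3, gconfig = cfg, lr = 0)
  for (nm in eegram:::param_names()) expect_equal(upd0$params[[nm]], p[[nm]])
  expect_gte(upd0$diagnostics$mean_return, 0)
  expect_lte(upd0$diagnostics$mean_return, 1)
  expect_error(hybrid_update(list(), integer(0), p, NULL, 3, cfg), "empty")

  # repeated steps on one fixed batch reduce the cross-entropy (windowed
  # averages: individual rollouts are stochastic)
  set.seed(51)
  ces <- numeric(40); q <- p; opt <- NULL
  for (i in 1:40) {
    upd <- hybrid_update(sig, labs, q, opt, T_steps = 3, gconfig = cfg,
                         lr = 3e-3)
    ces[i] <- upd$diagnostics$ce
    q <- upd$params; opt <- upd$opt
  }
  expect_lt(mean(ces[31:40]), mean(ces[1:10]))
})

test_that("ram_train runs, logs one row per epoch and reproduces under a seed", {
  set.seed(60)
  eps <- gen_burst_eeg(24, channels = 8, timepoints = 60,
                       specs = default_burst_specs(2, 8, 60))
  cfg <- glimpse_config(k = 2, base_rows = 2, base_cols = 5)
  fit <- ram_train(eps, cfg, n_classes = 2, T_steps = 3, epochs = 2,
                   batch_size = 8, hidden = 12, glimpse_hidden = 6,
                   loc_hidden = 6, g_dim = 12, seed = 9)
  expect_equal(nrow(fit$log), 2L)
  expect_true(all(c("epoch", "ce", "mean_return", "accuracy") %in%
                  names(fit$log)))
  fit2 <- ram_train(eps, cfg, n_classes = 2, T_steps = 3, epochs = 2,
                    batch_size = 8, hidden = 12, glimpse_hidden = 6,
                    loc_hidden = 6, g_dim = 12, seed = 9)
  expect_equal(fit$params$W_a, fit2$params$W_a)
  expect_equal(fit$log, fit2$log)
  expect_error(ram_train(list(), cfg, n_classes = 2), "empty")
})
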