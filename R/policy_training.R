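#' Policy training: rollouts, rewards and the REINFORCE estimator
#'
#' Training is hybrid: the action head, GRU core and glimpse network are
#' trained by backpropagation of the classification cross-entropy, while the
#' location head (the hard-attention policy) is trained by the REINFORCE
#' score-function estimator with a learned state-value baseline. No gradient
#' flows through the sampled location coordinates themselves.
#'
#' @name policy-training
NULL

#' Sample a location from the Gaussian policy
#'
#' Draws two independent Normal(mean_i, sigma^2) values and clips each into
#' \[-1, +1\]. The pre-clip draw is returned as well because the policy
#' log-density is evaluated at the raw draw (clipping is an environment
#' effect, not part of the policy).
#'
#' @param mean Numeric length-2 policy mean.
#' @param sigma Positive standard deviation (normalized units).
#' @return A list with `loc` (clipped coordinates) and `raw` (pre-clip draw).
#' @export
sample_location <- function(mean, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be > 0")
  raw <- stats::rnorm(2L, mean = mean, sd = sigma)
  list(loc = clip_location(raw), raw = raw)
}

#' Log-density of the Gaussian location policy
#'
#' Sum over the two axes of the Normal log-density
#' `-log(sigma * sqrt(2*pi)) - (x - mu)^2 / (2 sigma^2)`, evaluated at the
#' pre-clip draw.
#'
#' @param loc_raw Numeric length-2 pre-clip draw.
#' @param mean Numeric length-2 policy mean.
#' @param sigma Positive standard deviation.
#' @return A single numeric log-density.
#' @export
location_log_prob <- function(loc_raw, mean, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be > 0")
  sum(stats::dnorm(loc_raw, mean = mean, sd = sigma, log = TRUE))
}

#' Score-function gradient of the location log-density w.r.t. its mean
#'
#' `d log N(x | mu, sigma^2) / d mu = (x - mu) / sigma^2`, per axis. This is
#' the analytic kernel of the REINFORCE estimator.
#'
#' @inheritParams location_log_prob
#' @return Numeric vector, same length as `mean`.
#' @export
score_grad_mean <- function(loc_raw, mean, sigma) (loc_raw - mean) / sigma^2

#' Terminal 0/1 reward
#'
#' Reward is 1 only at the final step and only when the prediction equals
#' the label; all other time steps earn 0.
#'
#' @param prediction,label Class indices (0-based).
#' @param t Current step index (1-based).
#' @param T_total Total number of steps in the episode.
#' @return 0 or 1.
#' @export
step_reward <- function(prediction, label, t, T_total) {
  if (t < 1L || t > T_total) stop("step index out of range")
  as.numeric(t == T_total && prediction == label)
}

#' Discounted episode return
#'
#' `R = sum_t gamma^(t-1) r_t`. With the terminal-only 0/1 reward and
#' `gamma = 1` the return is exactly the correctness indicator.
#'
#' @param rewards Numeric vector of per-step rewards.
#' @param gamma Discount factor in (0, 1\].
#' @return A single numeric return.
#' @export
episode_return <- function(rewards, gamma = 1) {
  if (length(rewards) == 0L) stop("rewards must be non-empty")
  if (gamma <= 0) stop("gamma must be > 0")
  sum(gamma^(seq_along(rewards) - 1L) * rewards)
}

## ---- batched rollout (training workhorse) --------------------------------

# Roll a minibatch of signals through T glimpse/GRU steps, keeping every
# intermediate needed for backpropagation. Rows = samples throughout.
rollout_batch <- function(signals, params, T_steps, gconfig,
                          sample = TRUE, clamp_channels = TRUE) {
  d <- attr(params, "dims"); sigma <- attr(params, "sigma")
  B <- length(signals); nh <- d$hidden
  H <- matrix(0, B, nh)
  L <- if (sample) matrix(stats::runif(B * 2L, -1, 1), B, 2L) else matrix(0, B, 2L)
  cache <- vector("list", T_steps)
  Hs <- vector("list", T_steps); Mus <- vector("list", T_steps)
  Raws <- vector("list", T_steps); Ls <- vector("list", T_steps)
  impl_clamp <- isTRUE(clamp_channels)
  for (t in seq_len(T_steps)) {
    X <- matrix(0, B, d$input_dim)
    for (i in seq_len(B))
      X[i, ] <- as.numeric(extract_glimpse_impl(signals[[i]], L[i, ], gconfig,
                                                clamp_rows = impl_clamp))
    fw <- glimpse_forward_batch(X, L, params)
    st <- gru_step_batch(H, fw$G, params)
    Hprev <- H; H <- st$H
    Mu <- tanh(affine(H, params$W_loc, params$b_loc))
    if (sample) {
      Raw <- Mu + sigma * matrix(stats::rnorm(B * 2L), B, 2L)
    } else {
      Raw <- Mu
    }
    Lnext <- pmin(pmax(Raw, -1), 1)
    cache[[t]] <- list(X = X, Lprev = L, fw = fw, st = st, Hprev = Hprev)
    Hs[[t]] <- H; Mus[[t]] <- Mu; Raws[[t]] <- Raw; Ls[[t]] <- Lnext
    L <- Lnext
  }
  Logits <- affine(H, params$W_a, params$b_a)
  P <- softmax_rows(Logits)
  pred <- max.col(P, ties.method = "first") - 1L
  list(cache = cache, Hs = Hs, Mus = Mus, Raws = Raws, Ls = Ls,
       probs = P, pred = pred, H_T = H, B = B, T_steps = T_steps)
}

#' Roll out one episode
#'
#' Protocol: the initial location is drawn uniformly over \[-1, 1\]^2 (or
#' fixed at the centre when `sample = FALSE`); at each step the sensor
#' glimpses at the previous location, the glimpse network and GRU update the
#' hidden state, and the location policy emits the next focal point. At the
#' final step the class is the argmax of the softmax head, and the terminal
#' 0/1 reward is assigned.
#'
#' @param sample A [signal_epoch()] (or any list with `data` matrix and
#'   `label`).
#' @param params A [ram_params()] object.
#' @param T_steps Number of glimpses T (>= 1).
#' @param gconfig A [glimpse_config()].
#' @param gamma Discount factor (default 1; terminal-only reward makes
#'   discounting inert except for scaling by `gamma^(T-1)`).
#' @param stochastic Draw locations from the Gaussian policy (`TRUE`,
#'   training behaviour) or follow the deterministic policy mean (`FALSE`,
#'   evaluation behaviour).
#' @param clamp_channels Clamp over-wide scale windows to the channel extent
#'   (multichannel convention); set `FALSE` for plain images.
#' @return A `ram_trajectory`: locations, means, raw draws, log-probs,
#'   hidden states, action, rewards and return.
#' @export
rollout_episode <- function(sample, params, T_steps, gconfig, gamma = 1,
                            stochastic = TRUE, clamp_channels = TRUE) {
  T_steps <- as.integer(T_steps)
  if (is.na(T_steps) || T_steps < 1L) stop("T_steps must be >= 1")
  ro <- rollout_batch(list(sample$data), params, T_steps, gconfig,
                      sample = stochastic, clamp_channels = clamp_channels)
  sigma <- attr(params, "sigma")
  locs <- do.call(rbind, lapply(ro$Ls, function(m) m[1L, ]))
  mus <- do.call(rbind, lapply(ro$Mus, function(m) m[1L, ]))
  raws <- do.call(rbind, lapply(ro$Raws, function(m) m[1L, ]))
  hs <- do.call(rbind, lapply(ro$Hs, function(m) m[1L, ]))
  lps <- vapply(seq_len(T_steps),
                function(t) location_log_prob(raws[t, ], mus[t, ], sigma),
                numeric(1))
  action <- ro$pred[1L]
  rewards <- vapply(seq_len(T_steps),
                    function(t) step_reward(action, sample$label, t, T_steps),
                    numeric(1))
  structure(list(locations = locs, location_means = mus, raw_locations = raws,
                 log_probs = lps, hidden_states = hs,
                 action = action, action_log_prob = log(ro$probs[1L, action + 1L]),
                 probs = as.numeric(ro$probs[1L, ]),
                 rewards = rewards, ret = episode_return(rewards, gamma),
                 num_glimpses = T_steps, label = sample$label),
            class = "ram_trajectory")
}

#' @export
print.ram_trajectory <- function(x, ...) {
  cat(sprintf("<ram_trajectory> T = %d glimpses, action = %d, return = %g\n",
              x$num_glimpses, x$action, x$ret))
  invisible(x)
}

#' REINFORCE surrogate loss and location-head gradient
#'
#' For a batch of trajectories, computes the surrogate objective whose
#' gradient with respect to the location-head parameters is the
#' baseline-subtracted score-function estimator
#' `(1/M) sum_i sum_t grad log pi(l_t^i | s^i) * (R^i - b_t^i)`,
#' with `b_t^i` the state-value baseline evaluated at the stored hidden
#' states (treated as a constant: no gradient flows into the baseline head
#' or the core from this term).
#'
#' @param batch A list with `trajectories` (list of `ram_trajectory`).
#' @param params A [ram_params()] object.
#' @param baselines Optional numeric override: a list (one vector of length
#'   T per trajectory) or a single value recycled everywhere; defaults to
#'   the learned baseline head.
#' @return A list with `surrogate` (scalar, `-J` convention so that descent
#'   increases return) and `grad` (list with `W_loc`, `b_loc`, the ascent
#'   estimator of dJ/d psi_l).
#' @export
reinforce_loss <- function(batch, params, baselines = NULL) {
  check_params(params)
  trajs <- batch$trajectories
  M <- length(trajs)
  if (M == 0L) stop("empty batch")
  sigma <- attr(params, "sigma")
  gW <- params$W_loc * 0; gb <- params$b_loc * 0
  surrogate <- 0
  for (i in seq_len(M)) {
    tr <- trajs[[i]]
    Tn <- tr$num_glimpses
    b_i <- if (is.null(baselines)) {
      as.numeric(tr$hidden_states %*% params$W_b) + params$b_b
    } else if (is.list(baselines)) {
      rep_len(baselines[[i]], Tn)
    } else rep_len(baselines, Tn)
    adv <- tr$ret - b_i
    for (t in seq_len(Tn)) {
      dmu <- score_grad_mean(tr$raw_locations[t, ], tr$location_means[t, ], sigma) *
        adv[t]
      dz <- dmu * (1 - tr$location_means[t, ]^2)   # through the tanh squash
      gW <- gW + outer(tr$hidden_states[t, ], dz)
      gb <- gb + dz
      surrogate <- surrogate - tr$log_probs[t] * adv[t]
    }
  }
  list(surrogate = surrogate / M,
       grad = list(W_loc = gW / M, b_loc = gb / M))
}

## ---- optimizer -----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params[param_names()], function(a) a * 0),
       v = lapply(params[param_names()], function(a) a * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (nm in param_names()) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (nrm > max_norm) grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}

## ---- hybrid update -------------------------------------------------------

#' One hybrid training update on a minibatch
#'
#' Performs one rollout per sample, then one Adam step on the sum of
#' (i) the classification cross-entropy at the final step, backpropagated
#' through the action head, GRU core and glimpse network (the location input
#' path is non-differentiable), (ii) the REINFORCE surrogate for the
#' location head with the baseline-subtracted return, and (iii) the mean
#' squared error of the baseline head against the realized return.
#'
#' @param signals List of channels x time (or image) matrices.
#' @param labels Integer vector of 0-based class labels.
#' @param params A [ram_params()] object.
#' @param opt Adam state from a previous call, or `NULL` to initialize.
#' @param T_steps Number of glimpses.
#' @param gconfig A [glimpse_config()].
#' @param lr Learning rate.
#' @param gamma Discount factor.
#' @param grad_clip Global gradient-norm clip (`Inf` to disable).
#' @param clamp_channels See [rollout_episode()].
#' @return List with updated `params`, `opt` and `diagnostics` (ce,
#'   policy surrogate, baseline mse, mean return, batch accuracy).
#' @export
hybrid_update <- function(signals, labels, params, opt = NULL, T_steps, gconfig,
                          lr = 1e-3, gamma = 1, grad_clip = 5,
                          clamp_channels = TRUE) {
  check_params(params)
  B <- length(signals)
  if (B == 0L || B != length(labels)) stop("empty batch or label mismatch")
  d <- attr(params, "dims"); sigma <- attr(params, "sigma")
  if (is.null(opt)) opt <- adam_init(params)
  ro <- rollout_batch(signals, params, T_steps, gconfig,
                      sample = TRUE, clamp_channels = clamp_channels)
  correct <- as.numeric(ro$pred == labels)
  ret <- gamma^(T_steps - 1L) * correct           # terminal-only reward
  g <- empty_grads(params)

  # (i) classification cross-entropy, backprop through time
  Y <- matrix(0, B, d$n_classes); Y[cbind(seq_len(B), labels + 1L)] <- 1
  dLogits <- (ro$probs - Y) / B
  g$W_a <- t(ro$H_T) %*% dLogits; g$b_a <- colSums(dLogits)
  dH <- dLogits %*% t(params$W_a)
  pol_sur <- 0; base_mse <- 0
  for (t in rev(seq_len(T_steps))) {
    cc <- ro$cache[[t]]
    Hl <- ro$Hs[[t]]
    # (iii) baseline MSE on the detached hidden state
    V <- as.numeric(affine(Hl, params$W_b, params$b_b))
    dV <- matrix(2 * (V - ret) / (B * T_steps), B, 1L)
    g$W_b <- g$W_b + t(Hl) %*% dV
    g$b_b <- g$b_b + sum(dV)
    base_mse <- base_mse + sum((V - ret)^2) / (B * T_steps)
    # (ii) REINFORCE on the detached hidden state (location head only)
    adv <- ret - V
    Mu <- ro$Mus[[t]]
    dMu <- -(ro$Raws[[t]] - Mu) / sigma^2 * adv / B   # d(-J)/dMu
    dZl <- dMu * (1 - Mu^2)
    g$W_loc <- g$W_loc + t(Hl) %*% dZl
    g$b_loc <- g$b_loc + colSums(dZl)
    lp <- rowSums(stats::dnorm(ro$Raws[[t]], Mu, sigma, log = TRUE))
    pol_sur <- pol_sur - sum(lp * adv) / B
    # cross-entropy path through the GRU and glimpse network
    bk <- gru_backward_batch(params, cc$Hprev, cc$fw$G, cc$st, dH)
    g <- accumulate_gru_grads(g, bk)
    gb <- glimpse_backward_batch(params, cc$X, cc$Lprev, cc$fw, bk$dG)
    g <- accumulate_glimpse_grads(g, gb)
    dH <- bk$dHprev
  }
  if (any(!vapply(g, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite gradients in hybrid_update (check inputs and learning rate)")
  g <- clip_grads(g, grad_clip)
  upd <- adam_step(params, g, opt, lr)
  ce <- -mean(log(pmax(ro$probs[cbind(seq_len(B), labels + 1L)], 1e-12)))
  list(params = upd$params, opt = upd$opt,
       diagnostics = list(ce = ce, policy_surrogate = pol_sur,
                          baseline_mse = base_mse,
                          mean_return = mean(ret), accuracy = mean(correct)))
}

#' Train the recurrent attention model
#'
#' Runs epochs of [hybrid_update()] over shuffled minibatches.
#'
#' @param dataset List of [signal_epoch()] objects (or any lists with `data`
#'   and `label`).
#' @param gconfig A [glimpse_config()].
#' @param n_classes Number of classes.
#' @param T_steps Number of glimpses per episode (default 6, the optimum
#'   reported for the motor-imagery task).
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param hidden,glimpse_hidden,loc_hidden,g_dim Network widths, see
#'   [ram_params()].
#' @param sigma Location-policy standard deviation.
#' @param gamma Discount factor.
#' @param grad_clip Global gradient-norm clip.
#' @param seed Master seed (controls initialization, shuffling and rollout
#'   noise).
#' @param clamp_channels See [rollout_episode()].
#' @param params Optional warm-start parameters (resume training).
#' @param verbose Print one line per epoch.
#' @return List with `params` (trained [ram_params()]) and `log` (one
#'   data.frame row per epoch: ce, policy surrogate, baseline mse, mean
#'   return, accuracy).
#' @export
ram_train <- function(dataset, gconfig, n_classes, T_steps = 6L, epochs = 10L,
                      batch_size = 32L, lr = 1e-3, hidden = 256L,
                      glimpse_hidden = 128L, loc_hidden = 128L, g_dim = 256L,
                      sigma = 0.17, gamma = 1, grad_clip = 5, seed = NULL,
                      clamp_channels = TRUE, params = NULL, verbose = FALSE) {
  n <- length(dataset)
  if (n == 0L) stop("empty dataset")
  if (!is.null(seed)) set.seed(seed)
  input_dim <- gconfig$k * gconfig$base_rows * gconfig$base_cols
  if (is.null(params))
    params <- ram_params(input_dim, n_classes, hidden = hidden,
                         glimpse_hidden = glimpse_hidden,
                         loc_hidden = loc_hidden, g_dim = g_dim, sigma = sigma)
  opt <- NULL
  labels <- vapply(dataset, function(e) as.integer(e$label), integer(1))
  if (any(labels < 0L | labels >= n_classes)) stop("label outside 0..C-1")
  log_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    diag_acc <- NULL
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      upd <- hybrid_update(lapply(dataset[idx], `[[`, "data"), labels[idx],
                           params, opt, T_steps, gconfig, lr = lr,
                           gamma = gamma, grad_clip = grad_clip,
                           clamp_channels = clamp_channels)
      params <- upd$params; opt <- upd$opt
      dg <- unlist(upd$diagnostics)
      diag_acc <- if (is.null(diag_acc)) dg * length(idx) else diag_acc + dg * length(idx)
    }
    row <- as.list(diag_acc / n)
    log_rows[[ep]] <- data.frame(epoch = ep, as.list(row))
    if (verbose)
      message(sprintf("epoch %3d  ce %.4f  return %.3f  acc %.3f",
                      ep, row$ce, row$mean_return, row$accuracy))
  }
  list(params = params, log = do.call(rbind, log_rows))
}

#' Predict classes with a trained model
#'
#' Evaluation-time behaviour is deterministic: the initial location is the
#' centre and subsequent locations follow the policy mean (no sampling).
#'
#' @param dataset List of [signal_epoch()] objects or bare data matrices.
#' @param params Trained [ram_params()].
#' @param T_steps Number of glimpses.
#' @param gconfig A [glimpse_config()].
#' @param stochastic Sample locations instead of following the mean.
#' @param clamp_channels See [rollout_episode()].
#' @return List with `pred` (0-based classes), `probs` (n x C matrix) and
#'   `locations` (list of T x 2 matrices of visited policy means).
#' @export
ram_predict <- function(dataset, params, T_steps, gconfig, stochastic = FALSE,
                        clamp_channels = TRUE) {
  signals <- lapply(dataset, function(e) if (is.list(e)) e$data else e)
  ro <- rollout_batch(signals, params, T_steps, gconfig,
                      sample = stochastic, clamp_channels = clamp_channels)
  locs <- lapply(seq_along(signals), function(i)
    do.call(rbind, lapply(ro$Mus, function(m) m[i, ])))
  list(pred = ro$pred, probs = ro$probs, locations = locs)
}
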