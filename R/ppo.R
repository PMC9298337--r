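# --- Adam ---------------------------------------------------------------

adam_init <- function(net) {
  nm <- c("W1", "b1", "W2", "b2", "W3", "b3")
  list(m = lapply(net[nm], function(p) p * 0),
       v = lapply(net[nm], function(p) p * 0), t = 0)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(opt$m)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- opt$m[[nm]] / (1 - beta1^opt$t)
    vh <- opt$v[[nm]] / (1 - beta2^opt$t)
    net[[nm]] <- net[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(net = net, opt = opt)
}

#' Trial environment for reinforcement learning
#'
#' Wraps the block-sequential trial as an episodic environment with the
#' standard `reset()` / `step(action)` interface. At each episode a true
#' curve is drawn uniformly from the candidate models; `reset()` runs the
#' equal initial allocation and returns the encoded state; `step(k)` gives
#' all `N_block` subjects of the next block dose `k` (the training-time
#' action) and returns `list(state, reward, done)`. The reward is zero until
#' the final block, after which the end-of-trial analysis is run and the
#' configured metric's reward is returned.
#'
#' @param config a [trial_config] (its `metric` selects the reward).
#' @param seed seed for the environment's private RNG streams.
#' @return list with functions `reset()` and `step(action)` and fields
#'   `B`, `K`, `state_dim`.
#' @export
trial_mdp <- function(config = trial_config(), seed = 1L) {
  rng <- make_rng(seed, c("scenario", "noise"))
  curves <- config$cand$models
  fams <- names(curves)
  intervals <- lapply(curves, target_dose_interval, delta = config$delta,
                      eta = config$eta, grid = config$grid)
  e <- new.env()
  e$state <- NULL; e$b <- 0L; e$idx <- 1L

  terminal <- function() {
    gs <- state_summary(e$state, config)
    truth <- curves[[e$idx]]
    if (config$metric == "power") {
      return(as.numeric(mct_test(gs, config$cand, config$alpha)$significant))
    }
    an <- analyze_trial(gs, config$cand, alpha = config$alpha,
                        delta = config$delta, truth = truth)
    switch(config$metric,
      MS = as.numeric(identical(an$selected, fams[e$idx])),
      TD = {
        iv <- intervals[[e$idx]]
        as.numeric(!is.na(an$d_targ_hat) && an$d_targ_hat >= iv[1] &&
                     an$d_targ_hat <= iv[2])
      },
      MAE = 1 - 2 * an$mae)
  }

  list(
    B = config$B, K = config$K, state_dim = 3 * config$K - 1,
    reset = function() {
      e$idx <- with_stream(rng, "scenario", sample.int(length(curves), 1))
      e$state <- initialize_trial(config, curves[[e$idx]], rng)
      e$b <- 0L
      encode_state(e$state, config)
    },
    step = function(action) {
      alloc <- integer(config$K); alloc[action] <- config$N_block
      apply_block(e$state, alloc, curves[[e$idx]], config, rng)
      e$b <- e$b + 1L
      done <- e$b >= config$B
      list(state = encode_state(e$state, config),
           reward = if (done) terminal() else 0,
           done = done)
    })
}

#' Train an allocation policy with PPO
#'
#' Proximal policy optimization with the clipped surrogate objective, a
#' separate critic of the same architecture, Adam, and terminal-only reward
#' (discount 1 over the fixed horizon of B blocks). The policy is updated
#' after every `trials_per_update` simulated trials; advantages are the
#' terminal reward minus the critic's value, normalized per update.
#'
#' @param config a [trial_config]; its `metric` is the optimized reward.
#' @param episodes total number of simulated trials.
#' @param seed master seed (weights, environment, action sampling).
#' @param trials_per_update trials collected between policy updates.
#' @param hidden hidden-layer width of policy and critic.
#' @param lr Adam learning rate.
#' @param clip PPO clipping parameter epsilon.
#' @param epochs passes over each update's data.
#' @param minibatch minibatch size.
#' @param ent_coef entropy-bonus coefficient.
#' @param env_factory optional function(seed) returning an environment with
#'   the [trial_mdp()] interface; defaults to the trial environment itself.
#' @param log_path optional CSV path for the per-update training log.
#' @param verbose print per-update progress.
#' @return object of class `rl_policy`: `net` (policy), `vnet` (critic),
#'   `log` (data.frame with episodes, mean reward, entropy) and the
#'   hyperparameters used.
#' @export
train_policy <- function(config = trial_config(), episodes = 10000,
                         seed = 1L, trials_per_update = 1000, hidden = 256,
                         lr = 3e-4, clip = 0.2, epochs = 10, minibatch = 64,
                         ent_coef = 0, env_factory = NULL, log_path = NULL,
                         verbose = FALSE) {
  if (episodes %% trials_per_update != 0)
    stop("episodes must be divisible by trials_per_update")
  set.seed(seed)
  env <- if (is.null(env_factory)) trial_mdp(config, seed = seed + 1L)
         else env_factory(seed + 1L)
  K <- env$K; sdim <- env$state_dim; B <- env$B
  net <- policy_network(sdim, K, hidden)
  vnet <- mlp_init(sdim, hidden, 1, out_scale = 1 / sqrt(hidden))
  popt <- adam_init(net); vopt <- adam_init(vnet)
  n_updates <- episodes %/% trials_per_update
  trainlog <- data.frame(update = integer(), episodes = integer(),
                    mean_reward = numeric(), entropy = numeric())

  for (up in seq_len(n_updates)) {
    nsamp <- trials_per_update * B
    S <- matrix(0, nsamp, sdim); A <- integer(nsamp)
    logp_old <- numeric(nsamp); R <- numeric(nsamp)
    rewards <- numeric(trials_per_update)
    row <- 0L
    for (ep in seq_len(trials_per_update)) {
      s <- env$reset()
      first <- row + 1L
      repeat {
        row <- row + 1L
        p <- policy_forward(net, s)
        a <- sample.int(K, 1, prob = p)
        S[row, ] <- s; A[row] <- a; logp_old[row] <- log(p[a])
        out <- env$step(a)
        s <- out$state
        if (out$done) break
      }
      R[first:row] <- out$reward
      rewards[ep] <- out$reward
    }
    S <- S[seq_len(row), , drop = FALSE]
    A <- A[seq_len(row)]; logp_old <- logp_old[seq_len(row)]
    R <- R[seq_len(row)]

    Vhat <- drop(mlp_forward(vnet, S)$U)
    adv <- R - Vhat
    adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
    onehot <- matrix(0, length(A), K); onehot[cbind(seq_along(A), A)] <- 1

    ent <- NA_real_
    for (epch in seq_len(epochs)) {
      idx <- sample.int(length(A))
      for (start in seq(1, length(A), by = minibatch)) {
        mb <- idx[start:min(start + minibatch - 1, length(A))]
        nb <- length(mb)
        fw <- mlp_forward(net, S[mb, , drop = FALSE])
        P <- softmax_rows(fw$U)
        logp <- log(P[cbind(seq_len(nb), A[mb])] + 1e-12)
        ratio <- exp(logp - logp_old[mb])
        Ai <- adv[mb]
        active <- !((Ai > 0 & ratio > 1 + clip) |
                      (Ai < 0 & ratio < 1 - clip))
        coef <- ifelse(active, -Ai * ratio, 0) / nb
        dU <- coef * (onehot[mb, , drop = FALSE] - P)
        if (ent_coef > 0) {
          # d(-entropy)/dU for the bonus: P * (log P + H)
          H <- -rowSums(P * log(P + 1e-12))
          dU <- dU - ent_coef * (-P * (log(P + 1e-12) + H)) / nb
        }
        st <- adam_step(net, mlp_backward(net, fw, dU), popt, lr)
        net <- st$net; popt <- st$opt

        fv <- mlp_forward(vnet, S[mb, , drop = FALSE])
        dV <- matrix((drop(fv$U) - R[mb]) / nb, ncol = 1)
        sv <- adam_step(vnet, mlp_backward(vnet, fv, dV), vopt, lr)
        vnet <- sv$net; vopt <- sv$opt
      }
    }
    Pall <- policy_forward(net, S)
    ent <- mean(-rowSums(Pall * log(Pall + 1e-12)))
    trainlog <- rbind(trainlog, data.frame(update = up,
                                 episodes = up * trials_per_update,
                                 mean_reward = mean(rewards),
                                 entropy = ent))
    if (verbose)
      message(sprintf("update %d/%d  episodes %d  mean reward %.4f  entropy %.3f",
                      up, n_updates, up * trials_per_update,
                      mean(rewards), ent))
  }
  if (!is.null(log_path)) utils::write.csv(trainlog, log_path, row.names = FALSE)
  structure(list(net = net, vnet = vnet, log = trainlog, metric = config$metric,
                 hyper = list(lr = lr, clip = clip, epochs = epochs,
                              minibatch = minibatch, ent_coef = ent_coef,
                              hidden = hidden,
                              trials_per_update = trials_per_update,
                              episodes = episodes, seed = seed)),
            class = "rl_policy")
}

#' @export
print.rl_policy <- function(x, ...) {
  cat(sprintf("<rl_policy> metric=%s hidden=%d episodes=%d final entropy=%.3f\n",
              x$metric, x$hyper$hidden, x$hyper$episodes,
              utils::tail(x$log$entropy, 1)))
  invisible(x)
}
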