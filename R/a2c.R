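#' @name a2c
#' @title Advantage actor-critic training loop
#'
#' @description
#' Episodes apply `Time` fragment replacements to a seed molecule. Each step
#' samples a (position, replacement) action from the actor, applies it, and
#' scores the resulting structure with the multi-objective reward; an
#' invalid product earns reward 0 and the state reverts to the previous
#' valid state, so no stored state is ever invalid. Updates use the
#' synchronous one-step TD advantage
#' `A = r + gamma * V(s') * (1 - done) - V(s)`; the actor loss is
#' `-mean(log pi(a|s) * A) - entropy_coef * H` and the critic minimizes the
#' squared TD error. Valid generated molecules are fed back as inputs of the
#' next task. The `Time` parameter may follow a schedule: with
#' `time_schedule = "adaptive"` it is stepped up by one whenever the moving
#' average of the gate-pass fraction plateaus, mirroring the role of the
#' replacement-count dial in similarity/diversity trade-offs.
NULL

#' Training configuration
#'
#' @param gamma discount in `[0, 1]`
#' @param lr_actor,lr_critic Adam learning rates
#' @param entropy_coef entropy bonus coefficient
#' @param time replacements per episode (the Time parameter), >= 1
#' @param epochs training epochs
#' @param batch_size episodes per update
#' @param seed root seed; component streams are derived from it
#' @param ranges property ranges for the gate
#' @param weights reward weights
#' @param use_property_optimization ablation switch: FALSE leaves only the
#'   validity reward term
#' @param activity_fn optional activity oracle, function(smiles) -> logical
#' @param time_schedule "fixed" or "adaptive" (step `time` up by one when
#'   the `plateau_window`-epoch moving average of the gate-pass fraction
#'   improves by less than `plateau_tol`)
#' @param plateau_window,plateau_tol adaptive-schedule tuning
#' @return a `fragrl_train_config`
#' @export
train_config <- function(gamma = 0.99, lr_actor = 3e-4, lr_critic = 3e-4,
                         entropy_coef = 0.01, time = 1L, epochs = 100L,
                         batch_size = 32L, seed = 1L,
                         ranges = default_property_ranges(),
                         weights = default_reward_weights(),
                         use_property_optimization = TRUE,
                         activity_fn = NULL,
                         time_schedule = c("fixed", "adaptive"),
                         plateau_window = 50L, plateau_tol = 0.005) {
  stopifnot(gamma >= 0, gamma <= 1, time >= 1L)
  structure(list(gamma = gamma, lr_actor = lr_actor, lr_critic = lr_critic,
                 entropy_coef = entropy_coef, time = as.integer(time),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), ranges = ranges, weights = weights,
                 use_property_optimization =
                   isTRUE(use_property_optimization),
                 activity_fn = activity_fn,
                 time_schedule = match.arg(time_schedule),
                 plateau_window = as.integer(plateau_window),
                 plateau_tol = plateau_tol),
            class = "fragrl_train_config")
}

step_reward <- function(smiles, cfg) {
  total_reward(smiles, ranges = cfg$ranges, weights = cfg$weights,
               activity_fn = cfg$activity_fn,
               use_property_optimization = cfg$use_property_optimization)
}

#' Run one episode of fragment replacements
#'
#' @param initial a valid `fragrl_state`
#' @param policy a `fragrl_policy`
#' @param tree the `fragrl_tree`
#' @param lib the `fragrl_library`
#' @param cfg a `fragrl_train_config` (its `time` field sets the length)
#' @param rng an [rng_stream()]
#' @param time optional override of `cfg$time`
#' @return a `fragrl_trajectory`: list of transitions (state, action,
#'   reward, reward_components, next_state, done, valid_step)
#' @export
run_episode <- function(initial, policy, tree, lib, cfg, rng,
                        time = cfg$time) {
  stopifnot(isTRUE(initial$valid))
  state <- initial
  transitions <- vector("list", time)
  for (t in seq_len(time)) {
    dist <- actor_forward(state, tree, policy)
    action <- sample_action(dist, rng)
    nxt <- tryCatch(
      replace_fragment(state, action$position, action$replacement, lib),
      error = function(e) NULL)
    valid_step <- !is.null(nxt) && isTRUE(nxt$valid)
    if (valid_step) {
      rc <- step_reward(nxt$source, cfg)
    } else {
      rc <- step_reward(NA_character_, cfg)
      nxt <- state  # revert to the previous valid state
    }
    transitions[[t]] <- list(state = state, action = action,
                             reward = rc$total, reward_components = rc,
                             next_state = nxt, done = t == time,
                             valid_step = valid_step)
    state <- nxt
  }
  structure(transitions, class = "fragrl_trajectory")
}

#' One-step TD advantage
#'
#' `reward + gamma * next_value * (1 - done) - value`
#'
#' @param reward,value,next_value finite scalars
#' @param gamma discount
#' @param done logical end-of-episode flag
#' @return scalar advantage
#' @export
advantage <- function(reward, value, next_value, gamma, done) {
  reward + gamma * next_value * (1 - as.numeric(done)) - value
}

#' One A2C gradient update from a batch of trajectories
#'
#' Accumulates analytic gradients of the actor objective
#' (`-log pi * advantage` minus entropy bonus) and the critic squared TD
#' error over all transitions, averages them and applies one Adam step to
#' each head.
#'
#' @param batch list of `fragrl_trajectory`
#' @param policy a `fragrl_policy`
#' @param tree,lib library context
#' @param cfg a `fragrl_train_config`
#' @param opt optimizer state from a previous call, or NULL
#' @return list(policy, opt, losses = c(actor, critic), stats)
#' @export
a2c_update <- function(batch, policy, tree, lib, cfg, opt = NULL) {
  stopifnot(length(batch) > 0L)
  if (is.null(opt)) {
    opt <- list(actor = adam_init(policy$heads[c("pos", "repl")]),
                critic = adam_init(policy$heads$critic))
  }
  g_actor <- NULL
  g_critic <- NULL
  actor_loss <- 0
  critic_loss <- 0
  n <- 0L
  for (traj in batch) {
    for (tr in traj) {
      v <- critic_forward(tr$state, tree, policy)
      v_next <- if (tr$done) 0 else critic_forward(tr$next_state, tree,
                                                   policy)
      adv <- advantage(tr$reward, v, v_next, cfg$gamma, tr$done)
      target <- tr$reward + cfg$gamma * v_next * (1 - as.numeric(tr$done))
      dist <- actor_forward(tr$state, tree, policy)
      ga <- actor_grads(dist, tr$action, adv, cfg$entropy_coef, policy)
      gc <- critic_grads(tr$state, tree, policy, target)
      g_actor <- grads_add(g_actor, ga)
      g_critic <- grads_add(g_critic, gc$grads)
      logp <- log(dist$position_probs[tr$action$position]) +
        log(dist$replacement_probs[tr$action$position,
                                   tr$action$replacement])
      actor_loss <- actor_loss - logp * adv
      critic_loss <- critic_loss + gc$loss
      n <- n + 1L
    }
  }
  g_actor <- grads_scale(g_actor, 1 / n)
  g_critic <- grads_scale(g_critic, 1 / n)
  sa <- adam_step(policy$heads[c("pos", "repl")], g_actor, opt$actor,
                  cfg$lr_actor)
  sc <- adam_step(policy$heads$critic, g_critic, opt$critic, cfg$lr_critic)
  policy$heads$pos <- sa$params$pos
  policy$heads$repl <- sa$params$repl
  policy$heads$critic <- sc$params
  list(policy = policy, opt = list(actor = sa$opt, critic = sc$opt),
       losses = c(actor = actor_loss / n, critic = critic_loss / n))
}

traj_stats <- function(batch) {
  steps <- unlist(lapply(batch, function(tr) {
    vapply(tr, `[[`, logical(1), "valid_step")
  }))
  gates <- unlist(lapply(batch, function(tr) {
    vapply(tr, function(x) isTRUE(x$reward_components$gate_pass), logical(1))
  }))
  prew <- unlist(lapply(batch, function(tr) {
    vapply(tr, function(x) x$reward_components$property_reward, numeric(1))
  }))
  c(validity = mean(steps), gate = mean(gates), property_reward = mean(prew))
}

#' Train the policy with A2C
#'
#' @param seeds character vector of seed molecule SMILES (the lead set)
#' @param lib,tree fragment library and tree
#' @param policy optional pre-initialized `fragrl_policy`
#' @param cfg a `fragrl_train_config`
#' @param dims policy dimensions used when `policy` is NULL
#' @param verbose print a line every 10 epochs
#' @return list(policy, log) where `log` is a data.frame with one row per
#'   epoch: epoch, time, actor_loss, critic_loss, validity fraction,
#'   gate-pass fraction, mean property reward
#' @export
train <- function(seeds, lib, tree, policy = NULL, cfg = train_config(),
                  dims = policy_dims(), verbose = FALSE) {
  stopifnot(length(seeds) >= 1L)
  root <- rng_stream(cfg$seed)
  if (is.null(policy)) policy <- init_policy(lib, tree, dims, cfg$seed)
  ep_rng <- root$derive(7)
  states <- lapply(seeds, decompose, lib = lib)
  opt <- NULL
  time_now <- cfg$time
  log <- vector("list", cfg$epochs)
  gate_hist <- numeric()
  for (epoch in seq_len(cfg$epochs)) {
    pick <- ep_rng$sample_int(length(states), cfg$batch_size, replace = TRUE)
    batch <- lapply(pick, function(i) {
      run_episode(states[[i]], policy, tree, lib, cfg, ep_rng,
                  time = time_now)
    })
    upd <- a2c_update(batch, policy, tree, lib, cfg, opt)
    policy <- upd$policy
    opt <- upd$opt
    st <- traj_stats(batch)
    gate_hist <- c(gate_hist, st[["gate"]])
    if (cfg$time_schedule == "adaptive" &&
        length(gate_hist) >= 2L * cfg$plateau_window) {
      w <- cfg$plateau_window
      recent <- mean(utils::tail(gate_hist, w))
      before <- mean(utils::head(utils::tail(gate_hist, 2L * w), w))
      if (recent - before < cfg$plateau_tol) {
        time_now <- time_now + 1L
        gate_hist <- numeric()
      }
    }
    log[[epoch]] <- data.frame(epoch = epoch, time = time_now,
                               actor_loss = upd$losses[["actor"]],
                               critic_loss = upd$losses[["critic"]],
                               validity = st[["validity"]],
                               gate = st[["gate"]],
                               property_reward = st[["property_reward"]])
    if (verbose && epoch %% 10L == 0L) {
      message(sprintf("epoch %d: valid %.2f gate %.2f", epoch,
                      st[["validity"]], st[["gate"]]))
    }
  }
  list(policy = policy, log = do.call(rbind, log))
}

#' Generate molecules from a (trained) policy
#'
#' Runs `n` episodes of `time` replacements each, seeded round-robin from
#' the seed set, and returns the final molecules.
#'
#' @param policy a `fragrl_policy`
#' @param seeds seed molecule SMILES
#' @param lib,tree library context
#' @param n number of molecules to generate
#' @param time replacements per episode
#' @param rng an [rng_stream()]
#' @param cfg reward configuration (defaults suffice for generation)
#' @return character vector of canonical SMILES, length `n`
#' @export
generate <- function(policy, seeds, lib, tree, n, time = 1L,
                     rng = rng_stream(1L), cfg = train_config()) {
  if (n == 0L) return(character())
  states <- lapply(seeds, decompose, lib = lib)
  out <- character(n)
  for (i in seq_len(n)) {
    st <- states[[(i - 1L) %% length(states) + 1L]]
    traj <- run_episode(st, policy, tree, lib, cfg, rng, time = time)
    out[i] <- traj[[length(traj)]]$next_state$source
  }
  out
}
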