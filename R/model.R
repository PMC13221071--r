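#' Short-term synaptic plasticity parameter sets
#'
#' Two-variable dynamics per presynaptic neuron: the available-resource
#' fraction `x` and the utilization variable `u`, whose product is the
#' synaptic efficacy. Facilitating synapses use `tau_x = 0.2 s`,
#' `tau_u = 1.5 s`, `U = 0.15`; depressing synapses use `tau_x = 1.5 s`,
#' `tau_u = 0.2 s`, `U = 0.45`.
#'
#' @param kind `"facilitating"` or `"depressing"`.
#' @return List with `tau_x`, `tau_u`, `U` (seconds / unitless).
#' @export
stsp_params <- function(kind = c("facilitating", "depressing")) {
  switch(match.arg(kind),
         facilitating = list(tau_x = 0.2, tau_u = 1.5, U = 0.15),
         depressing = list(tau_x = 1.5, tau_u = 0.2, U = 0.45))
}

#' One forward-Euler step of the STSP variables
#'
#' `dx/dt = (1 - x)/tau_x - u x r` and
#' `du/dt = (U - u)/tau_u + U (1 - u) r`, integrated with step `dt` and
#' clipped to `[0, 1]`. At rate zero the fixed point is `x = 1`, `u = U`;
#' at constant rate `r` the algebraic steady state is
#' `u* = U (1 + tau_u r) / (1 + U tau_u r)`,
#' `x* = 1 / (1 + u* tau_x r)`.
#'
#' @param x,u Current state vectors in `[0, 1]`.
#' @param r Presynaptic rates, Hz (non-negative).
#' @param params A [stsp_params()] list (vectorized fields allowed).
#' @param dt Step, s (at most 0.01).
#' @return List with updated `x`, `u`.
#' @export
stsp_step <- function(x, u, r, params, dt = 0.01) {
  if (dt > 0.01 + 1e-12) stop("dt must be at most 10 ms")
  if (any(r < 0)) stop("rates must be non-negative")
  x1 <- x + dt * ((1 - x) / params$tau_x - u * x * r)
  u1 <- u + dt * ((params$U - u) / params$tau_u +
                    params$U * (1 - u) * r)
  list(x = pmin(pmax(x1, 0), 1), u = pmin(pmax(u1, 0), 1))
}

#' Algebraic STSP steady state at constant rate
#'
#' @param r Constant presynaptic rate, Hz.
#' @param params A [stsp_params()] list.
#' @return List with `x`, `u` at the fixed point.
#' @export
stsp_steady_state <- function(r, params) {
  u <- params$U * (1 + params$tau_u * r) / (1 + params$U * params$tau_u * r)
  list(x = 1 / (1 + u * params$tau_x * r), u = u)
}

# saturating rate nonlinearity bounded at [0, r_max]
rate_nl <- function(z, r_max = 100) r_max * tanh(pmax(z, 0))
rate_nl_grad <- function(z, r_max = 100) {
  g <- r_max * (1 - tanh(pmax(z, 0))^2)
  g[z <= 0] <- 0
  g
}

#' Build the two-subnetwork STSP navigation model
#'
#' A reward subnetwork (4 reward-input units onto recurrent neurons, 80%
#' excitatory) and a spatial subnetwork (10 place-input units onto
#' recurrent neurons, 90% excitatory) with recurrent connectivity inside
#' each subnetwork and, in the full variant, excitatory cross-subnetwork
#' connections. Excitatory neurons of both subnetworks drive two readout
#' units encoding x/y movement velocity. Variants: `"full"`, `"no_stsp"`
#' (synaptic efficacy frozen at its rest value) and `"no_cross"` (all
#' cross-subnetwork recurrent connections removed). Per presynaptic
#' neuron, cross-subnetwork excitatory synapses are facilitating and
#' within-subnetwork synapses depressing by default.
#'
#' @param n_reward,n_spatial Recurrent neurons per subnetwork (defaults 80
#'   and 100 as in the full architecture; tests use smaller nets).
#' @param frac_exc_reward,frac_exc_spatial Excitatory fractions.
#' @param variant Model variant.
#' @param seed Weight-initialization seed.
#' @param arena_size Side of the square arena, cm.
#' @param dt Integration step, s.
#' @return A `gs_stsp_net` list.
#' @export
build_network <- function(n_reward = 80, n_spatial = 100,
                          frac_exc_reward = 0.8, frac_exc_spatial = 0.9,
                          variant = c("full", "no_stsp", "no_cross"),
                          seed = 1, arena_size = 60, dt = 0.01) {
  variant <- match.arg(variant)
  set.seed(seed)
  n <- n_reward + n_spatial
  is_reward <- c(rep(TRUE, n_reward), rep(FALSE, n_spatial))
  n_exc_r <- round(frac_exc_reward * n_reward)
  n_exc_s <- round(frac_exc_spatial * n_spatial)
  is_exc <- c(rep(TRUE, n_exc_r), rep(FALSE, n_reward - n_exc_r),
              rep(TRUE, n_exc_s), rep(FALSE, n_spatial - n_exc_s))
  # recurrent mask: within-subnet all-to-all (no self); cross-subnet E->E
  same <- outer(is_reward, is_reward, "==")
  mask <- same
  if (variant != "no_cross")
    mask <- mask | (!same & outer(rep(TRUE, n), is_exc, function(a, b) b) &
                      matrix(is_exc, n, n))
  diag(mask) <- FALSE
  # mask[i, j]: connection j -> i
  cross <- !same & mask
  sgn <- matrix(rep(ifelse(is_exc, 1, -1), each = n), n, n)
  W <- matrix(rnorm(n * n, sd = 0.25 / sqrt(n)), n, n)
  W <- abs(W) * sgn * mask
  # input mask: 4 reward features -> reward subnet, 10 place -> spatial
  n_in <- 14
  in_mask <- matrix(FALSE, n, n_in)
  in_mask[is_reward, 1:4] <- TRUE
  in_mask[!is_reward, 5:14] <- TRUE
  W_in <- matrix(rnorm(n * n_in, sd = 0.3), n, n_in) * in_mask
  W_out <- matrix(rnorm(2 * sum(is_exc), sd = 0.05), 2, sum(is_exc))
  # per-synapse STSP class: facilitating cross-subnet E->E, depressing
  # within-subnet; encoded per (post, pre) entry
  fac <- stsp_params("facilitating"); dep <- stsp_params("depressing")
  tau_x <- ifelse(cross, fac$tau_x, dep$tau_x)
  tau_u <- ifelse(cross, fac$tau_u, dep$tau_u)
  Umat <- ifelse(cross, fac$U, dep$U)
  # place-input basis: 10 Gaussian bumps on a fixed grid
  gx <- c(0.2, 0.5, 0.8, 0.2, 0.5, 0.8, 0.2, 0.5, 0.8, 0.5) * arena_size
  gy <- c(0.2, 0.2, 0.2, 0.5, 0.5, 0.5, 0.8, 0.8, 0.8, 0.35) * arena_size
  structure(list(
    n = n, n_reward = n_reward, n_spatial = n_spatial,
    is_reward = is_reward, is_exc = is_exc, variant = variant,
    mask = mask, in_mask = in_mask,
    W = W, W_in = W_in, W_out = W_out,
    tau_x = tau_x, tau_u = tau_u, Umat = Umat,
    arena_size = arena_size, dt = dt,
    place_centers = cbind(gx, gy), place_sigma = arena_size / 4,
    r_max = 100, v_max = 50
  ), class = "gs_stsp_net")
}

encode_inputs <- function(net, pos, goal, goal_radius = 5) {
  d <- sqrt(sum((pos - goal)^2))
  reward <- c(goal[1] / net$arena_size, goal[2] / net$arena_size,
              exp(-d / 20), as.numeric(d <= goal_radius))
  place <- exp(-rowSums(sweep(net$place_centers, 2, pos)^2) /
                 (2 * net$place_sigma^2))
  c(reward, place)
}

#' Run one navigation episode
#'
#' The agent starts at a corner of the arena; at each step the recurrent
#' rates follow `rates = f(W (x u rates) + W_in inputs)` with per-synapse STSP
#' efficacies (frozen at rest for the `no_stsp` variant), the readout gives
#' the x/y velocity, and the position integrates it (clipped to the
#' arena). The episode ends on entering the goal radius or at timeout.
#'
#' @param net A `gs_stsp_net`.
#' @param goal Goal position, cm.
#' @param start Start position, cm.
#' @param T_steps Maximum steps.
#' @param goal_radius Goal radius, cm.
#' @param record Keep per-step state for gradient computation.
#' @return List with `path`, `time_to_goal` (s; timeout flagged via
#'   `reached`), `efficiency` (straight-line / path length), and recorded
#'   state when requested.
#' @export
run_episode <- function(net, goal, start = c(5, 5), T_steps = 150,
                        goal_radius = 5, record = FALSE) {
  n <- net$n; dt <- net$dt
  r <- numeric(n)
  x <- matrix(1, n, n) * 1  # per-synapse resource; rows post, cols pre
  u <- net$Umat * 1
  frozen <- net$variant == "no_stsp"
  pos <- start
  path <- matrix(NA_real_, T_steps + 1, 2); path[1, ] <- pos
  if (record) {
    rec <- list(r = matrix(0, n, T_steps), z = matrix(0, n, T_steps),
                pre = matrix(0, n, T_steps), inp = matrix(0, 14, T_steps),
                vraw = matrix(0, 2, T_steps))
  }
  reached <- FALSE; steps_used <- T_steps
  exc <- which(net$is_exc)
  for (tt in seq_len(T_steps)) {
    inp <- encode_inputs(net, pos, goal, goal_radius)
    eff <- if (frozen) net$Umat else x * u
    pre <- r  # presynaptic rates entering this step
    z <- as.numeric((net$W * eff) %*% pre) + as.numeric(net$W_in %*% inp)
    r <- rate_nl(z, net$r_max)
    v_raw <- as.numeric(net$W_out %*% r[exc])
    v <- net$v_max * tanh(v_raw / net$v_max)  # bounded running speed
    pos <- pmin(pmax(pos + dt * v, 0), net$arena_size)
    path[tt + 1, ] <- pos
    if (record) {
      rec$r[, tt] <- r; rec$z[, tt] <- z; rec$pre[, tt] <- pre
      rec$inp[, tt] <- inp; rec$vraw[, tt] <- v_raw
      if (tt == 1) rec$eff <- array(0, c(n, n, T_steps))
      rec$eff[, , tt] <- eff
    }
    if (!frozen) {
      rr <- matrix(rep(r, each = n), n, n, byrow = TRUE)  # pre rates by col
      x <- x + dt * ((1 - x) / net$tau_x - u * x * rr)
      u <- u + dt * ((net$Umat - u) / net$tau_u + net$Umat * (1 - u) * rr)
      x <- pmin(pmax(x, 0), 1); u <- pmin(pmax(u, 0), 1)
    }
    if (!reached && sqrt(sum((pos - goal)^2)) <= goal_radius) {
      reached <- TRUE; steps_used <- tt
      break
    }
  }
  path <- path[seq_len(steps_used + 1), , drop = FALSE]
  plen <- sum(sqrt(rowSums(diff(path)^2)))
  straight <- sqrt(sum((path[1, ] - goal)^2))
  out <- list(path = path, reached = reached,
              time_to_goal = steps_used * dt,
              efficiency = if (plen > 0) min(1, straight / plen) else NA_real_,
              steps = steps_used)
  if (record) out$rec <- rec
  out
}

# loss: mean squared distance to goal over the episode (normalized by the
# arena size) plus saturation penalties on rates and the raw readout
# drive. The penalties keep the network out of the flat region of its
# nonlinearities, where gradients vanish and adaptation stalls.
episode_loss <- function(path, goal, rates, vraw, net,
                         lambda_r = 0.01, lambda_v = 0.01) {
  d2 <- rowSums(sweep(path[-1, , drop = FALSE], 2, goal)^2)
  mean(d2) / net$arena_size^2 +
    lambda_r * mean((rates / net$r_max)^2) +
    lambda_v * mean((vraw / net$v_max)^2)
}

# Backpropagation through the episode. The STSP efficacy trajectories and
# the position-dependence of the inputs are treated as given (recorded in
# the forward pass); gradients flow through the rate recursion, the
# readout and the position integral.
episode_gradients <- function(net, ep, goal, lambda_r = 0.01,
                              lambda_v = 0.01) {
  rec <- ep$rec
  T_used <- ep$steps
  n <- net$n; dt <- net$dt
  exc <- which(net$is_exc)
  path <- ep$path
  # adjoint of position: suffix sums of the per-step loss gradient
  gp <- 2 * sweep(path[-1, , drop = FALSE], 2, goal) /
    (T_used * net$arena_size^2)
  P <- apply(gp[T_used:1, , drop = FALSE], 2, cumsum)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  P <- P[T_used:1, , drop = FALSE]
  gW <- matrix(0, n, n); gWin <- matrix(0, n, 14)
  gWout <- matrix(0, 2, length(exc))
  delta_next <- numeric(n)  # dL/dz_{t+1}
  for (tt in T_used:1) {
    # dL/dv_raw: position adjoint through the bounded-velocity tanh plus
    # the readout saturation penalty
    dv <- dt * P[tt, ] * (1 - tanh(rec$vraw[, tt] / net$v_max)^2) +
      2 * lambda_v * rec$vraw[, tt] / (T_used * 2 * net$v_max^2)
    dr <- numeric(n)
    dr[exc] <- as.numeric(t(net$W_out) %*% dv)
    if (tt < T_used) {
      Weff_next <- net$W * rec$eff[, , tt + 1]
      dr <- dr + as.numeric(t(Weff_next) %*% delta_next)
    }
    dr <- dr + 2 * lambda_r * rec$r[, tt] / (T_used * n * net$r_max^2)
    delta <- dr * rate_nl_grad(rec$z[, tt], net$r_max)
    gWout <- gWout + dv %*% t(rec$r[exc, tt])
    gW <- gW + (delta %*% t(rec$pre[, tt])) * rec$eff[, , tt]
    gWin <- gWin + delta %*% t(rec$inp[, tt])
    delta_next <- delta
  }
  list(W = gW * net$mask, W_in = gWin * net$in_mask, W_out = gWout)
}

clip_by_norm <- function(g, max_norm = 1) {
  nrm <- sqrt(sum(unlist(g)^2))
  if (nrm > max_norm) g <- lapply(g, function(m) m * max_norm / nrm)
  g
}

#' Train the network on a goal with Adam
#'
#' Gradient of the integrated distance-to-goal loss (plus a small rate
#' penalty), masked by the predefined connectivity structure and clipped by
#' norm before each Adam update. The Dale sign constraint and the
#' connectivity mask are re-imposed after every step, so masked entries
#' stay exactly zero throughout training.
#'
#' @param net A `gs_stsp_net`.
#' @param goal Goal position.
#' @param n_episodes Training episodes.
#' @param start Episode start position.
#' @param lr Adam learning rate.
#' @param T_steps Episode length.
#' @param eval_every Run a held-out evaluation episode after every this
#'   many training episodes (0 disables evaluation).
#' @param stop_on_success Stop training at the first evaluation episode
#'   that reaches the goal.
#' @return The trained network, with attributes `loss_history`,
#'   `eval_times` (per-evaluation time to goal) and
#'   `episodes_to_criterion` (first episode count whose evaluation reached
#'   the goal; `n_episodes + 1` when never reached or not evaluated).
#' @export
train_network <- function(net, goal, n_episodes = 60, start = c(5, 5),
                          lr = 0.02, T_steps = 250, eval_every = 0,
                          stop_on_success = FALSE) {
  adam <- attr(net, "adam")
  if (is.null(adam))
    adam <- list(m = list(W = net$W * 0, W_in = net$W_in * 0,
                          W_out = net$W_out * 0),
                 v = list(W = net$W * 0, W_in = net$W_in * 0,
                          W_out = net$W_out * 0),
                 b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 0)
  losses <- numeric(0)
  eval_times <- numeric(0)
  crit <- n_episodes + 1L
  sgn <- matrix(rep(ifelse(net$is_exc, 1, -1), each = net$n),
                net$n, net$n)
  for (epn in seq_len(n_episodes)) {
    ep <- run_episode(net, goal, start, T_steps, record = TRUE)
    loss <- episode_loss(ep$path, goal, ep$rec$r[, seq_len(ep$steps)],
                         ep$rec$vraw[, seq_len(ep$steps)], net)
    if (!is.finite(loss)) stop("training diverged (non-finite loss)")
    losses <- c(losses, loss)
    g <- clip_by_norm(episode_gradients(net, ep, goal))
    adam$t <- adam$t + 1
    for (nm in names(g)) {
      adam$m[[nm]] <- adam$b1 * adam$m[[nm]] + (1 - adam$b1) * g[[nm]]
      adam$v[[nm]] <- adam$b2 * adam$v[[nm]] + (1 - adam$b2) * g[[nm]]^2
      mhat <- adam$m[[nm]] / (1 - adam$b1^adam$t)
      vhat <- adam$v[[nm]] / (1 - adam$b2^adam$t)
      net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + adam$eps)
    }
    # re-impose mask and Dale sign after the update
    net$W <- net$W * net$mask
    net$W <- ifelse(sgn > 0, pmax(net$W, 0), pmin(net$W, 0)) * net$mask
    net$W_in <- net$W_in * net$in_mask
    if (eval_every > 0 && epn %% eval_every == 0) {
      ev <- run_episode(net, goal, start, T_steps)
      eval_times <- c(eval_times, ev$time_to_goal)
      if (ev$reached && crit > n_episodes) crit <- epn
      if (ev$reached && stop_on_success) break
    }
  }
  attr(net, "adam") <- adam
  attr(net, "loss_history") <- losses
  attr(net, "eval_times") <- eval_times
  attr(net, "episodes_to_criterion") <- crit
  net
}

#' Goal-switch flexibility experiment
#'
#' Trains a copy of `trained` (pre-trained on goal A) and a naive network
#' on a new goal B for matched episode budgets, and reports for each arm
#' the first episode at which the evaluated time-to-goal meets the
#' criterion (goal reached within the episode), plus final performance.
#'
#' @param trained Network pre-trained on the original goal.
#' @param naive Freshly initialized network of identical architecture.
#' @param new_goal The switched goal position.
#' @param n_episodes Adaptation budget per arm.
#' @param eval_every Evaluate after every k training episodes.
#' @param start Episode start.
#' @param T_steps Episode length.
#' @param lr Adaptation learning rate (identical for both arms).
#' @return List with `episodes_to_criterion` (named, per arm; budget + 1
#'   when never met) and the per-evaluation time-to-goal curves.
#' @export
goal_switch_experiment <- function(trained, naive, new_goal,
                                   n_episodes = 60, eval_every = 2,
                                   start = c(5, 5), T_steps = 250,
                                   lr = 0.005) {
  run_arm <- function(net, lr) {
    attr(net, "adam") <- NULL  # both arms start the optimizer cold
    net <- train_network(net, new_goal, n_episodes = n_episodes,
                         start = start, T_steps = T_steps, lr = lr,
                         eval_every = eval_every, stop_on_success = TRUE)
    list(episodes_to_criterion = attr(net, "episodes_to_criterion"),
         eval_times = attr(net, "eval_times"))
  }
  pre <- run_arm(trained, lr)
  nv <- run_arm(naive, lr)
  list(episodes_to_criterion = c(pretrained = pre$episodes_to_criterion,
                                 naive = nv$episodes_to_criterion),
       pretrained_curve = pre$eval_times, naive_curve = nv$eval_times)
}
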