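#' The candidate model set
#'
#' Ten learning models are considered, partitioned into a no-ToM family
#' (biased Nash `BN`, win-stay/lose-switch `WS`, reinforcement learning
#' `RL`, frequency tracking `0ToM`) and a ToM family (influence learning
#' `Inf` and recursive `1ToM` / `2ToM` belief updating, each in cooperative
#' and competitive variants). All models share the softmax decision rule and
#' differ only in how they form the prediction that feeds it.
#'
#' @return a data.frame with one row per model: `model_id`, `family`
#'   (`"tom"` or `"notom"`), `stance` (`"coop"`, `"comp"` or `NA`) and
#'   `sophistication` (rank used by between-group comparisons; cooperative
#'   and competitive variants are tied).
#' @export
tom_models <- function() {
  data.frame(
    model_id = c("BN", "WS", "RL", "0ToM",
                 "Inf-coop", "Inf-comp",
                 "1ToM-coop", "1ToM-comp",
                 "2ToM-coop", "2ToM-comp"),
    family = c(rep("notom", 4), rep("tom", 6)),
    stance = c(NA, NA, NA, NA, "coop", "comp", "coop", "comp", "coop", "comp"),
    sophistication = c(1, 2, 3, 4, 5, 5, 6, 6, 7, 7),
    stringsAsFactors = FALSE
  )
}

#' Canonical model identifiers, in registry order
#' @return character vector of the ten model ids.
#' @export
model_ids <- function() tom_models()$model_id

# default parameters (natural scale) for simulated agents. Temperatures of
# simulated belief-based agents are near-greedy (see the methods vignette);
# arena opponent algorithms override beta = 1 per protocol configuration.
default_agent_params <- function() {
  list(beta = 0.02, bias = 0, vol = 0.05, alpha = 0.5, eta = 0.7, lambda = 0.5)
}

#' Specify a learning agent
#'
#' @param model_id one of the ten canonical model identifiers listed by
#'   [tom_models()].
#' @param params named list of model parameters on their natural scale;
#'   unspecified entries take the package defaults. Recognised names:
#'   `beta` (temperature, > 0), `bias`, `vol` (volatility, > 0, used by
#'   `0ToM`/`1ToM`/`2ToM`), `alpha` (learning rate in \[0, 1\], `RL`),
#'   `eta` and `lambda` (influence learning).
#' @param role `"seeker"` or `"hider"`: fixes the agent's own payoff table
#'   in the hide-and-seek game.
#' @return an object of class `agent_spec`.
#' @export
agent_spec <- function(model_id, params = list(), role = c("seeker", "hider")) {
  role <- match.arg(role)
  models <- tom_models()
  if (!model_id %in% models$model_id)
    stop("unknown model_id: ", model_id)
  p <- utils::modifyList(default_agent_params(), params)
  if (p$beta <= 0) stop("'beta' must be positive")
  if (p$vol <= 0) stop("'vol' must be positive")
  if (p$alpha < 0 || p$alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (p$eta < 0 || p$eta > 1) stop("'eta' must lie in [0, 1]")
  if (p$lambda < 0) stop("'lambda' must be non-negative")
  structure(list(model_id = model_id, params = p, role = role),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat("<agent_spec>", x$model_id, "as", x$role, "\n")
  act <- active_params(x$model_id)
  cat(" ", paste(sprintf("%s = %g", act, unlist(x$params[act])),
                 collapse = ", "), "\n")
  invisible(x)
}

# parameters that actually enter each model's rule
active_params <- function(model_id) {
  switch(sub("-(coop|comp)$", "", model_id),
    "BN"   = "bias",
    "WS"   = c("beta", "bias"),
    "RL"   = c("alpha", "beta", "bias"),
    "0ToM" = c("vol", "beta", "bias"),
    "Inf"  = c("eta", "lambda", "beta", "bias"),
    "1ToM" = c("vol", "beta", "bias"),
    "2ToM" = c("vol", "beta", "bias"),
    stop("unknown model_id: ", model_id)
  )
}

model_stance <- function(model_id) {
  if (grepl("-coop$", model_id)) "coop"
  else if (grepl("-comp$", model_id)) "comp"
  else NA_character_
}

# engine configuration list for an agent spec
agent_cfg <- function(spec) {
  stopifnot(inherits(spec, "agent_spec"))
  base <- sub("-(coop|comp)$", "", spec$model_id)
  code <- switch(base, "BN" = 0L, "WS" = 1L, "RL" = 2L, "0ToM" = 3L,
                 "Inf" = 4L, "1ToM" = 5L, "2ToM" = 5L)
  level <- switch(base, "1ToM" = 1L, "2ToM" = 2L, 0L)
  stance <- model_stance(spec$model_id)
  u_own <- payoff_hide_and_seek(spec$role)
  u_oth <- presumed_opponent_table(u_own, if (is.na(stance)) "comp" else stance)
  p <- spec$params
  list(model = code, level = level,
       icomp = if (identical(stance, "coop")) 0L else 1L,
       beta = p$beta, bias = p$bias, vol = p$vol, alpha = p$alpha,
       eta = p$eta, lambda = p$lambda, u_own = u_own, u_oth = u_oth)
}

# ---------------------------------------------------------------------------
# Elementary learning rules (reference R implementations)
# ---------------------------------------------------------------------------

#' Belief state of a frequency-tracking (0-ToM) learner
#'
#' A 0-ToM learner models the opponent's probability of choosing option 1 as
#' `s(x_t)` where the log-odds `x_t` drifts with volatility `vol`. Its
#' posterior over `x_t` is Gaussian with mean `mu` and variance `sigma2`.
#'
#' @param mu posterior mean of the log-odds.
#' @param sigma2 posterior variance (> 0).
#' @param vol volatility of the hidden log-odds (>= 0); at `vol = 0` the
#'   update reduces to fictitious play (tracking the stationary choice
#'   frequency).
#' @return an object of class `tom0_belief`.
#' @export
tom0_belief <- function(mu = 0, sigma2 = 1, vol = 0.5) {
  stopifnot(sigma2 > 0, vol >= 0)
  structure(list(mu = mu, sigma2 = sigma2, vol = vol), class = "tom0_belief")
}

#' One 0-ToM belief update
#'
#' Assimilates one observed opponent action:
#' `sigma2' = 1 / (1 / (sigma2 + vol) + s(mu) (1 - s(mu)))` and
#' `mu' = mu + sigma2' * (a_op - s(mu))`.
#'
#' @param b a [tom0_belief()].
#' @param a_op observed opponent action (0 or 1; fractional values are
#'   accepted for the degenerate zero-innovation case).
#' @return the updated belief.
#' @export
tom0_update <- function(b, a_op) {
  stopifnot(inherits(b, "tom0_belief"))
  sm <- plogis(b$mu)
  s_new <- 1 / (1 / (b$sigma2 + b$vol) + sm * (1 - sm))
  b$mu <- b$mu + s_new * (a_op - sm)
  b$sigma2 <- s_new
  b
}

#' Predicted opponent choice probability of a 0-ToM belief
#'
#' `E[s(x)]` under the Gaussian posterior, via [sigmoid_mean()].
#'
#' @param b a [tom0_belief()].
#' @return probability that the opponent chooses option 1.
#' @export
tom0_predict <- function(b) {
  stopifnot(inherits(b, "tom0_belief"))
  sigmoid_mean(b$mu, b$sigma2)
}

#' Action values for value-based heuristics
#'
#' @param v numeric length-2 vector of option values `(V0, V1)`.
#' @param alpha learning rate in \[0, 1\] (used by the RL rule only).
#' @return an object of class `qvalues`.
#' @export
qvalues <- function(v = c(0, 0), alpha = 0.5) {
  stopifnot(length(v) == 2, alpha >= 0, alpha <= 1)
  structure(list(v = v, alpha = alpha), class = "qvalues")
}

#' Reinforcement-learning value update
#'
#' The chosen option moves towards the obtained reward in proportion to the
#' reward prediction error: `V' = V + alpha * (R - V)`; the unchosen value
#' is unchanged.
#'
#' @param q a [qvalues()] state.
#' @param a_self chosen action (0 or 1).
#' @param reward obtained reward.
#' @return the updated state.
#' @export
rl_update <- function(q, a_self, reward) {
  stopifnot(inherits(q, "qvalues"), a_self %in% c(0, 1))
  i <- a_self + 1
  q$v[i] <- q$v[i] + q$alpha * (reward - q$v[i])
  q
}

#' Win-stay/lose-switch value update
#'
#' The chosen option's value is set to the last reward and the unchosen
#' option's to its negative, so the agent repeats rewarded actions and
#' switches otherwise. Equivalent in choice behaviour to RL with
#' `alpha = 1` whenever the value differences share a sign.
#'
#' @inheritParams rl_update
#' @return the updated state.
#' @export
ws_update <- function(q, a_self, reward) {
  stopifnot(inherits(q, "qvalues"), a_self %in% c(0, 1))
  i <- a_self + 1
  q$v[i] <- reward
  q$v[3 - i] <- -reward
  q
}

#' State of an influence learner
#'
#' Influence learning tracks the opponent's choice probability with a delta
#' rule and adds a heuristic correction for how one's own actions shift
#' that probability — a precursor form of ToM that presumes the opponent's
#' covert (cooperative or competitive) intention without recursive beliefs.
#'
#' @param p_op current estimate of the opponent's probability of choosing
#'   option 1, strictly inside (0, 1).
#' @param eta prediction-error weight in \[0, 1\].
#' @param lam influence weight (>= 0); `lam = 0` gives a pure delta rule.
#' @param beta_inf temperature inside the adjustment term (defaults to the
#'   agent's policy temperature).
#' @param i_comp 1 for a competitive reading of the game, 0 cooperative.
#' @return an object of class `influence_state`.
#' @export
influence_state <- function(p_op = 0.5, eta = 0.7, lam = 0.5,
                            beta_inf = 0.02, i_comp = 1) {
  stopifnot(p_op > 0, p_op < 1, eta >= 0, eta <= 1, lam >= 0,
            beta_inf > 0, i_comp %in% c(0, 1))
  structure(list(p_op = p_op, eta = eta, lam = lam, beta_inf = beta_inf,
                 i_comp = i_comp), class = "influence_state")
}

#' One influence-learning update
#'
#' `p' = p + eta (a_op - p)
#'      - lam p (1 - p) (2 a_self + (2 I - 1) beta s^{-1}(p) + I)`
#' followed by clamping to `[1e-4, 1 - 1e-4]`. The grouping of the
#' adjustment term follows the source formulation verbatim; see the methods
#' vignette for a note on its sign conventions.
#'
#' @param st an [influence_state()].
#' @param a_self own action (0 or 1).
#' @param a_op opponent action (0 or 1).
#' @return the updated state.
#' @export
influence_update <- function(st, a_self, a_op) {
  stopifnot(inherits(st, "influence_state"))
  p <- st$p_op
  if (p <= 0 || p >= 1) stop("'p_op' must lie strictly inside (0, 1)")
  adj <- 2 * a_self + (2 * st$i_comp - 1) * st$beta_inf * qlogis(p) + st$i_comp
  p <- p + st$eta * (a_op - p) - st$lam * p * (1 - p) * adj
  st$p_op <- clamp_prob(p)
  st
}

# ---------------------------------------------------------------------------
# Recursive (k-ToM) beliefs
# ---------------------------------------------------------------------------

#' Belief state of a recursive k-ToM learner
#'
#' A k-ToM agent entertains every opponent sophistication level
#' `kappa < k`: a posterior `level_post` over levels and, per level, a
#' Gaussian belief (mean, covariance) over that opponent model's hidden
#' states (its log volatility and log temperature). The state also carries
#' replica simulations of each opponent model used to obtain the gradient of
#' the opponent's predicted choice log-odds by central finite differences.
#'
#' @param level recursion depth k (1 or 2).
#' @param vol the agent's prior volatility `sigma^k` (> 0).
#' @param stance `"comp"` or `"coop"`: the presumed opponent payoff table.
#' @param role own role in the hide-and-seek game.
#' @param level_post optional initial probability vector over opponent
#'   levels `0..k-1` (defaults to uniform).
#' @return an object of class `ktom_belief` with accessors `$level_post`,
#'   `$state_mean`, `$state_cov` and `$p_op` kept in sync after updates.
#' @export
ktom_belief <- function(level, vol = 0.5, stance = c("comp", "coop"),
                        role = c("seeker", "hider"), level_post = NULL) {
  stance <- match.arg(stance)
  role <- match.arg(role)
  stopifnot(level >= 1, level <= 2, vol > 0)
  state <- ktom_init_cpp(as.integer(level))
  if (!is.null(level_post)) {
    stopifnot(length(level_post) == level, all(level_post >= 0),
              abs(sum(level_post) - 1) < 1e-10)
    state[seq_len(level)] <- level_post
  }
  u_own <- payoff_hide_and_seek(role)
  b <- structure(list(level = as.integer(level), vol = vol, stance = stance,
                      role = role, u_own = u_own,
                      u_oth = presumed_opponent_table(u_own, stance),
                      state = state),
                 class = "ktom_belief")
  ktom_refresh(b)
}

ktom_refresh <- function(b) {
  parts <- ktom_parts_cpp(b$level, b$state, b$u_own, b$u_oth)
  b$level_post <- parts$level_post
  b$state_mean <- parts$state_mean
  b$state_cov <- parts$state_cov
  b$p_op_by_level <- parts$p_op_by_level
  b$p_op <- parts$p_op
  b
}

#' One k-ToM belief update
#'
#' Performs the full recursive update after a trial: Bayes rule on the
#' opponent-level posterior using each level's predicted probability of the
#' observed opponent action, a Laplace-style update of each level's hidden
#' state belief weighted by the level posterior, and propagation of the
#' simulated opponent models with the observed actions.
#'
#' @param b a [ktom_belief()].
#' @param a_self own action (0 or 1).
#' @param a_op observed opponent action (0 or 1).
#' @return the updated belief; `$p_op` holds the next-trial prediction.
#' @export
ktom_update <- function(b, a_self, a_op) {
  stopifnot(inherits(b, "ktom_belief"), a_self %in% c(0, 1), a_op %in% c(0, 1))
  b$state <- ktom_step_cpp(b$level, b$state, as.integer(a_self),
                           as.integer(a_op), b$vol, b$u_own, b$u_oth)
  ktom_refresh(b)
}

#' Next-trial opponent prediction of a k-ToM belief
#'
#' The level-marginal prediction `p_op = sum_kappa lambda_kappa p_op^kappa`.
#'
#' @param b a [ktom_belief()].
#' @return probability that the opponent chooses option 1.
#' @export
ktom_predict <- function(b) {
  stopifnot(inherits(b, "ktom_belief"))
  b$p_op
}

# ---------------------------------------------------------------------------
# Uniform observe -> act interface
# ---------------------------------------------------------------------------

#' Initialise an agent's internal state
#'
#' @param spec an [agent_spec()].
#' @return an opaque state object for [agent_step()].
#' @export
agent_init <- function(spec) {
  stopifnot(inherits(spec, "agent_spec"))
  list(a_self = integer(0), a_op = integer(0))
}

#' Advance an agent by one trial
#'
#' Updates the internal state with the previous trial's outcome (if any),
#' computes the current choice probability through the model's prediction,
#' the expected payoff difference and the softmax policy, and samples the
#' action by comparing `rng_draw` with that probability (action 1 iff
#' `rng_draw < p`). Deterministic given `rng_draw`.
#'
#' @param spec an [agent_spec()].
#' @param state state from [agent_init()] or a previous step.
#' @param last_a_self,last_a_op,last_reward outcome of the previous trial,
#'   or `NULL` on the first trial. The reward must equal the payoff table
#'   entry for the action pair.
#' @param rng_draw a uniform(0,1) draw.
#' @return a list with `action`, `prob` (the choice probability used) and
#'   the updated `state`.
#' @export
agent_step <- function(spec, state, last_a_self = NULL, last_a_op = NULL,
                       last_reward = NULL, rng_draw) {
  stopifnot(inherits(spec, "agent_spec"))
  if (!is.null(last_a_self)) {
    if (is.null(last_a_op)) stop("incomplete history: missing opponent action")
    u <- payoff_hide_and_seek(spec$role)
    if (!is.null(last_reward) &&
        abs(last_reward - u[last_a_self + 1, last_a_op + 1]) > 1e-12)
      stop("inconsistent history: reward incompatible with the action pair")
    state$a_self <- c(state$a_self, as.integer(last_a_self))
    state$a_op <- c(state$a_op, as.integer(last_a_op))
  }
  n <- length(state$a_self)
  probs <- replay_probs_cpp(agent_cfg(spec),
                            c(state$a_self, 0L), c(state$a_op, 0L))
  p <- probs[n + 1]
  list(action = as.integer(rng_draw < p), prob = p, state = state)
}

#' Replay a recorded history through an agent model
#'
#' Returns the agent's trial-by-trial probability of choosing option 1
#' just before each trial, given the recorded actions of both players.
#'
#' @param spec an [agent_spec()].
#' @param a_self,a_op recorded binary action sequences of equal length.
#' @return numeric vector of choice probabilities, one per trial.
#' @export
agent_replay <- function(spec, a_self, a_op) {
  stopifnot(inherits(spec, "agent_spec"), length(a_self) == length(a_op))
  replay_probs_cpp(agent_cfg(spec), as.integer(a_self), as.integer(a_op))
}
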