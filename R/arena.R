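#' Biased pseudo-random (RB) opponent sequence
#'
#' I.i.d. draws of the hiding hand with a 65% bias for the favoured hand,
#' the control opponent of the protocol.
#'
#' @param n number of trials (>= 1).
#' @param favoured the favoured hand (0 or 1); counterbalanced across
#'   sessions by the caller.
#' @param p_favoured bias towards the favoured hand (default 0.65).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return integer vector of hiding hands.
#' @export
generate_rb_sequence <- function(n, favoured = 1, p_favoured = 0.65,
                                 seed = NULL) {
  stopifnot(n >= 1, favoured %in% c(0, 1))
  with_seed(seed, {
    hit <- runif(n) < p_favoured
    as.integer(ifelse(hit, favoured, 1 - favoured))
  })
}

#' Session design of the experimental protocol
#'
#' @param n_sessions_per_condition sessions per opponent condition
#'   (default 4, for 12 sessions in total).
#' @param trials_per_session trials per session (default 60).
#' @param min_trials_keep sessions shorter than this are flagged excluded
#'   (default 20).
#' @param truncation_prob probability that a session is interrupted early;
#'   0 disables truncation.
#' @param condition_order optional explicit sequence of conditions across
#'   sessions; defaults to a counterbalanced (Latin-square) order determined
#'   by the individual index.
#' @return an object of class `protocol_design`.
#' @export
protocol_design <- function(n_sessions_per_condition = 4,
                            trials_per_session = 60,
                            min_trials_keep = 20,
                            truncation_prob = 0,
                            condition_order = NULL) {
  stopifnot(n_sessions_per_condition >= 1, trials_per_session >= 1,
            truncation_prob >= 0, truncation_prob < 1)
  structure(list(n_sessions_per_condition = n_sessions_per_condition,
                 trials_per_session = trials_per_session,
                 min_trials_keep = min_trials_keep,
                 truncation_prob = truncation_prob,
                 condition_order = condition_order),
            class = "protocol_design")
}

#' Reduced-scale protocol for simulation studies
#'
#' Three sessions per condition of 40 trials each; the scale used by the
#' packaged confusion and recovery harnesses.
#' @return a [protocol_design()].
#' @export
reduced_design <- function() {
  protocol_design(n_sessions_per_condition = 3, trials_per_session = 40)
}

conditions <- function() c("RB", "OTOM", "ITOM")

# the on-line opponent algorithm of a condition (hider role).
# sigma = 0.5 and beta = 1 are the protocol configuration defaults.
opponent_spec <- function(condition, vol = 0.5, beta = 1) {
  switch(condition,
    "OTOM" = agent_spec("0ToM", list(vol = vol, beta = beta, bias = 0),
                        role = "hider"),
    "ITOM" = agent_spec("1ToM-comp", list(vol = vol, beta = beta, bias = 0),
                        role = "hider"),
    stop("no model opponent for condition ", condition)
  )
}

#' Play one hide-and-seek session
#'
#' Runs the trial loop of one session: the opponent hides (a biased random
#' draw in `RB`, or an on-line competitive 0-ToM/1-ToM hider that hides
#' where it predicts the subject will not seek), the subject seeks, the
#' reward is assigned (1 iff the hands match) and both agents update.
#' Fully reproducible given `seed`.
#'
#' @param subject an [agent_spec()] for the seeker.
#' @param condition one of `"RB"`, `"OTOM"`, `"ITOM"`.
#' @param design a [protocol_design()].
#' @param seed integer seed.
#' @param session_index session number within the protocol.
#' @param day_gap time since the previous session (arbitrary units).
#' @param favoured favoured hand of the RB sequence for this session.
#' @param n_trials optional override of the session length.
#' @return a data.frame with columns `trial`, `a_self`, `a_op`, `reward`,
#'   `condition`, `session_index`, `day_gap`, `included`.
#' @export
play_session <- function(subject, condition, design = protocol_design(),
                         seed = NULL, session_index = 1L, day_gap = 1,
                         favoured = session_index %% 2, n_trials = NULL) {
  stopifnot(inherits(subject, "agent_spec"))
  if (!condition %in% conditions()) stop("unknown condition: ", condition)
  n <- n_trials %||% design$trials_per_session
  with_seed(seed, {
    if (condition == "RB") {
      a_op <- generate_rb_sequence(n, favoured = favoured)
      res <- play_vs_seq_cpp(agent_cfg(subject), a_op, runif(n))
      a_self <- res$a_self
    } else {
      opp <- opponent_spec(condition)
      g <- simulate_game_cpp(agent_cfg(subject), agent_cfg(opp), n,
                             runif(n), runif(n))
      a_self <- g$a_a
      a_op <- g$a_b
    }
    data.frame(trial = seq_len(n), a_self = a_self, a_op = a_op,
               reward = as.integer(a_self == a_op),
               condition = condition,
               session_index = as.integer(session_index),
               day_gap = day_gap,
               included = n >= design$min_trials_keep,
               stringsAsFactors = FALSE)
  })
}

# counterbalanced condition order: Latin-square rows cycled by individual
condition_order_for <- function(design, individual_index = 1L) {
  if (!is.null(design$condition_order)) return(design$condition_order)
  latin <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  row <- latin[((individual_index - 1L) %% 3L) + 1L, ]
  rep(conditions()[row], design$n_sessions_per_condition)
}

#' Run the full session protocol for one individual
#'
#' Plays `3 * n_sessions_per_condition` sessions with the condition order
#' counterbalanced across individuals (Latin square). If the design enables
#' truncation, interrupted sessions are cut short and those below
#' `min_trials_keep` trials are flagged excluded.
#'
#' @param subject an [agent_spec()] for the seeker.
#' @param design a [protocol_design()].
#' @param seed integer seed.
#' @param individual_index index used to counterbalance the condition order.
#' @return a data.frame of stacked session records.
#' @export
run_protocol <- function(subject, design = protocol_design(), seed = NULL,
                         individual_index = 1L) {
  ord <- condition_order_for(design, individual_index)
  n_sessions <- length(ord)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
    gaps <- sample(1:3, n_sessions, replace = TRUE)
    lens <- rep(design$trials_per_session, n_sessions)
    if (design$truncation_prob > 0) {
      cut <- runif(n_sessions) < design$truncation_prob
      lens[cut] <- pmax(5L, as.integer(runif(sum(cut)) *
                                         design$trials_per_session))
    }
    out <- lapply(seq_len(n_sessions), function(i) {
      play_session(subject, ord[i], design, seed = seeds[i],
                   session_index = i, day_gap = gaps[i],
                   n_trials = lens[i])
    })
    do.call(rbind, out)
  })
}

#' Per-condition performance of a set of sessions
#'
#' Mean reward per opponent condition over included trials, reported both
#' raw and net of chance (raw - 0.5). Sessions flagged excluded (shorter
#' than the design's minimum) are dropped; a condition with no included
#' session is flagged missing.
#'
#' @param sessions a session data.frame from [run_protocol()] or
#'   [play_session()].
#' @return a data.frame with columns `condition`, `raw`, `net`,
#'   `n_trials`, `missing`.
#' @export
score_performance <- function(sessions) {
  stopifnot(all(c("condition", "reward", "included") %in% names(sessions)))
  inc <- sessions[sessions$included, , drop = FALSE]
  out <- lapply(conditions(), function(cc) {
    x <- inc$reward[inc$condition == cc]
    if (length(x) == 0)
      return(data.frame(condition = cc, raw = NA_real_, net = NA_real_,
                        n_trials = 0L, missing = TRUE))
    data.frame(condition = cc, raw = mean(x), net = mean(x) - 0.5,
               n_trials = length(x), missing = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate one game between two model agents
#'
#' Simultaneous-move repeated game between two [agent_spec()] agents (one
#' seeker, one hider in the competitive game). Used by tournament-style
#' analyses.
#'
#' @param agent_a,agent_b the two agents.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return a data.frame with both players' actions and choice
#'   probabilities, plus `reward_a` under agent A's payoff table.
#' @export
play_game <- function(agent_a, agent_b, n_trials = 60, seed = NULL) {
  stopifnot(inherits(agent_a, "agent_spec"), inherits(agent_b, "agent_spec"))
  with_seed(seed, {
    g <- simulate_game_cpp(agent_cfg(agent_a), agent_cfg(agent_b),
                           n_trials, runif(n_trials), runif(n_trials))
    u <- payoff_hide_and_seek(agent_a$role)
    data.frame(trial = seq_len(n_trials), a_a = g$a_a, a_b = g$a_b,
               p_a = g$p_a, p_b = g$p_b,
               reward_a = u[cbind(g$a_a + 1, g$a_b + 1)])
  })
}
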