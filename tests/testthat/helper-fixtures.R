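# shared fixtures for the test suite (everything is generated in code)

# a short session data.frame from explicit action vectors
toy_session <- function(a_self, a_op, condition = "RB", session_index = 1L) {
  data.frame(trial = seq_along(a_self), a_self = as.integer(a_self),
             a_op = as.integer(a_op),
             reward = as.integer(a_self == a_op),
             condition = condition, session_index = session_index,
             day_gap = 1, included = TRUE, stringsAsFactors = FALSE)
}

# evidence matrix with named model columns from a plain matrix
named_em <- function(m) {
  colnames(m) <- model_ids()[seq_len(ncol(m))]
  rownames(m) <- paste0("id", seq_len(nrow(m)))
  m
}

# mean win rate of agent A against agent B over seeded games
mean_win <- function(spec_a, spec_b, n_games = 100, n_trials = 60,
                     seed0 = 1000) {
  mean(vapply(seq_len(n_games), function(i)
    mean(play_game(spec_a, spec_b, n_trials, seed = seed0 + i)$reward_a),
    numeric(1)))
}

# mean per-trial reward of a subject across seeded sessions of one condition
mean_perf <- function(subject, condition, n_games = 100, seed0 = 2000,
                      n_trials = NULL) {
  mean(vapply(seq_len(n_games), function(i)
    mean(play_session(subject, condition, seed = seed0 + i,
                      n_trials = n_trials)$reward), numeric(1)))
}
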