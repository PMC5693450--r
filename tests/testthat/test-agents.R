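test_that("0-ToM update matches the hand-evaluated recursion", {
  b <- tom0_update(tom0_belief(0, 1, vol = 0), 1)
  expect_equal(b$sigma2, 0.8, tolerance = 1e-12)
  expect_equal(b$mu, 0.4, tolerance = 1e-12)
  # zero innovation leaves the mean unchanged
  b2 <- tom0_update(tom0_belief(0.3, 1, vol = 0), plogis(0.3))
  expect_equal(b2$mu, 0.3, tolerance = 1e-12)
  # variance non-increasing when vol = 0
  b3 <- tom0_belief(0, 1, vol = 0)
  for (a in c(1, 0, 1, 1, 0)) {
    s_old <- b3$sigma2
    b3 <- tom0_update(b3, a)
    expect_lte(b3$sigma2, s_old)
  }
})

test_that("0-ToM with zero volatility reproduces fictitious play", {
  set.seed(11)
  for (f in c(0.3, 0.7)) {
    obs <- rbinom(1000, 1, f)
    b <- tom0_belief(0, 1, vol = 0)
    for (a in obs) b <- tom0_update(b, a)
    # converges to the empirical opponent frequency
    expect_lt(abs(tom0_predict(b) - mean(obs)), 0.02)
  }
})

test_that("value-based updates follow the RL and win-stay/lose-switch rules", {
  q <- rl_update(qvalues(c(0, 0), alpha = 0.5), a_self = 1, reward = 1)
  expect_equal(q$v, c(0, 0.5))
  # alpha = 0 freezes values
  q0 <- rl_update(qvalues(c(0.2, -0.1), alpha = 0), 0, 1)
  expect_equal(q0$v, c(0.2, -0.1))
  # WS: chosen <- R, unchosen <- -R
  expect_equal(ws_update(qvalues(), 0, 1)$v, c(1, -1))
  expect_equal(ws_update(qvalues(), 1, -1)$v, c(1, -1))
  # idempotent under repeated wins on the same option
  w1 <- ws_update(qvalues(), 1, 1)
  expect_equal(ws_update(w1, 1, 1)$v, w1$v)
  # RL(alpha = 1) and WS choice signs agree along a shared history
  set.seed(2)
  a <- rbinom(40, 1, 0.5); r <- ifelse(runif(40) < 0.6, 1, 0)
  qr <- qvalues(alpha = 1); qw <- qvalues()
  agree <- TRUE
  for (t in seq_along(a)) {
    qr <- rl_update(qr, a[t], r[t]); qw <- ws_update(qw, a[t], r[t])
    dr <- qr$v[2] - qr$v[1]; dw <- qw$v[2] - qw$v[1]
    if (dr * dw < 0) agree <- FALSE
  }
  expect_true(agree)
})

test_that("influence learning reduces to a delta rule and clamps", {
  st <- influence_state(p_op = 0.4, eta = 0, lam = 0)
  expect_equal(influence_update(st, 1, 1)$p_op, 0.4)
  st2 <- influence_state(p_op = 0.4, eta = 0.5, lam = 0)
  expect_equal(influence_update(st2, 0, 1)$p_op, 0.7)
  # at the clamp boundary the influence term vanishes with epsilon
  eps <- 1e-4
  st3 <- influence_state(p_op = eps, eta = 0, lam = 0.5, beta_inf = 1,
                         i_comp = 1)
  out <- influence_update(st3, 0, 0)
  expect_lt(abs(out$p_op - eps), 0.5 * eps * (1 - eps) *
              abs(2 * 0 + 1 * qlogis(eps) + 1) + 1e-12)
  expect_gte(out$p_op, eps)
})

test_that("k-ToM beliefs stay on the simplex with PD covariances", {
  set.seed(5)
  b <- ktom_belief(2, vol = 0.05, stance = "comp")
  for (t in 1:40) {
    b <- ktom_update(b, rbinom(1, 1, 0.5), rbinom(1, 1, 0.5))
    expect_equal(sum(b$level_post), 1, tolerance = 1e-10)
    expect_true(all(b$level_post >= 0))
    for (k in 1:2) {
      ev <- eigen(b$state_cov[[k]], symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev > 0))
    }
    expect_true(b$p_op > 0 && b$p_op < 1)
  }
})

test_that("a 2-ToM locked on level 0 nests the 1-ToM belief trajectory", {
  set.seed(6)
  a_self <- rbinom(30, 1, 0.5); a_op <- rbinom(30, 1, 0.5)
  b1 <- ktom_belief(1, vol = 0.05, stance = "comp")
  b2 <- ktom_belief(2, vol = 0.05, stance = "comp", level_post = c(1, 0))
  for (t in 1:30) {
    b1 <- ktom_update(b1, a_self[t], a_op[t])
    b2 <- ktom_update(b2, a_self[t], a_op[t])
    expect_equal(b2$level_post, c(1, 0), tolerance = 1e-12)
    expect_equal(b2$state_mean[[1]], b1$state_mean[[1]], tolerance = 1e-8)
    expect_equal(b2$state_cov[[1]], b1$state_cov[[1]], tolerance = 1e-8)
  }
})

test_that("flat level likelihoods leave the level posterior unchanged", {
  # before any asymmetric history, both levels predict identically from
  # symmetric initial beliefs, so the first update preserves uniformity
  b <- ktom_belief(2, vol = 0.05, stance = "comp")
  p0 <- tomassay:::ktom_parts_cpp(2, b$state, b$u_own, b$u_oth)$p_op_by_level
  expect_equal(p0[1], p0[2], tolerance = 1e-9)
  b <- ktom_update(b, 1, 0)
  expect_equal(b$level_post, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("agent_step is deterministic, checks history and composes the learning rules", {
  spec <- agent_spec("0ToM", list(vol = 0.3, beta = 0.5, bias = 0.1))
  # biased Nash: constant probability s(bias)
  bn <- agent_spec("BN", list(bias = 0))
  st <- agent_init(bn)
  s1 <- agent_step(bn, st, rng_draw = 0.4)
  expect_equal(s1$prob, 0.5)
  # inconsistent reward is rejected
  expect_error(agent_step(spec, agent_init(spec), 1, 0, last_reward = 1,
                          rng_draw = 0.5), "inconsistent")
  # identical draws give identical sequences
  run <- function() {
    st <- agent_init(spec); out <- integer(0)
    la <- NULL; lo <- NULL
    set.seed(9)
    for (t in 1:20) {
      stp <- agent_step(spec, st, la, lo, rng_draw = runif(1))
      st <- stp$state
      la <- stp$action; lo <- rbinom(1, 1, 0.5)
      out <- c(out, stp$action)
    }
    out
  }
  expect_identical(run(), run())
  # replay equals the explicit composition update -> dV -> softmax
  set.seed(10)
  a_self <- rbinom(25, 1, 0.5); a_op <- rbinom(25, 1, 0.6)
  p_engine <- agent_replay(spec, a_self, a_op)
  b <- tom0_belief(0, 1, vol = 0.3)
  u <- payoff_hide_and_seek("seeker")
  p_compose <- numeric(25)
  for (t in 1:25) {
    p_compose[t] <- softmax_policy(
      expected_value_difference(tom0_predict(b), u), beta = 0.5, bias = 0.1)
    b <- tom0_update(b, a_op[t])
  }
  expect_equal(p_engine, p_compose, tolerance = 1e-10)
})

test_that("influence-learning replay matches the composed R update rule", {
  set.seed(12)
  a_self <- rbinom(30, 1, 0.5); a_op <- rbinom(30, 1, 0.5)
  spec <- agent_spec("Inf-comp", list(eta = 0.6, lambda = 0.4, beta = 0.3,
                                      bias = -0.2))
  p_engine <- agent_replay(spec, a_self, a_op)
  st <- influence_state(0.5, eta = 0.6, lam = 0.4, beta_inf = 0.3, i_comp = 1)
  u <- payoff_hide_and_seek("seeker")
  p_compose <- numeric(30)
  for (t in 1:30) {
    p_compose[t] <- softmax_policy(
      expected_value_difference(st$p_op, u), beta = 0.3, bias = -0.2)
    st <- influence_update(st, a_self[t], a_op[t])
  }
  expect_equal(p_engine, p_compose, tolerance = 1e-10)
})

test_that("a 1-ToM observer recovers its 0-ToM opponent's transformed parameters", {
  n_rep <- 25L
  ok <- 0L
  truth <- log(c(0.5, 1)) # the opponent algorithm's (volatility, temperature)
  for (r in seq_len(n_rep)) {
    g <- play_game(agent_spec("1ToM-comp"),
                   agent_spec("0ToM", list(vol = 0.5, beta = 1),
                              role = "hider"), 300, seed = 6000 + r)
    b <- ktom_belief(1, vol = 0.05, stance = "comp", role = "seeker")
    for (t in 1:300) b <- ktom_update(b, g$a_a[t], g$a_b[t])
    err <- abs(b$state_mean[[1]] - truth)
    if (all(err <= 2 * sqrt(diag(b$state_cov[[1]])))) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.8)
})

test_that("tournament signs: influence learning beats 0-ToM and loses to 1-ToM", {
  w_inf_tom0 <- mean_win(agent_spec("Inf-comp"),
                         agent_spec("0ToM", role = "hider"), 100)
  w_inf_tom1 <- mean_win(agent_spec("Inf-comp"),
                         agent_spec("1ToM-comp", role = "hider"), 100,
                         seed0 = 1500)
  expect_gt(w_inf_tom0, 0.5)
  expect_lt(w_inf_tom1, 0.5)
})
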