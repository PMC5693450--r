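test_that("RB generator has the 65% bias, complement symmetry and seed dependence", {
  s <- generate_rb_sequence(1e4, favoured = 1, seed = 3)
  expect_gte(mean(s), 0.64); expect_lte(mean(s), 0.66)
  s0 <- generate_rb_sequence(500, favoured = 0, seed = 7)
  s1 <- generate_rb_sequence(500, favoured = 1, seed = 7)
  expect_identical(s0, 1L - s1)
  expect_false(identical(generate_rb_sequence(500, seed = 1),
                         generate_rb_sequence(500, seed = 2)))
})

test_that("sessions respect the game contingency and replay consistently", {
  s <- play_session(agent_spec("1ToM-coop"), "OTOM", seed = 21)
  expect_equal(nrow(s), 60)
  expect_identical(s$reward, as.integer(s$a_self == s$a_op))
  # replaying the recorded opponent log reproduces the subject's policy
  s2 <- play_session(agent_spec("0ToM", list(vol = 0.2)), "RB", seed = 22)
  p <- agent_replay(agent_spec("0ToM", list(vol = 0.2)), s2$a_self, s2$a_op)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  # identical seeds give identical sessions
  expect_identical(play_session(agent_spec("WS"), "ITOM", seed = 5),
                   play_session(agent_spec("WS"), "ITOM", seed = 5))
  expect_error(play_session(agent_spec("WS"), "bogus"), "condition")
})

test_that("a fixed favoured-hand policy earns the RB base rate; biased Nash is unexploitable", {
  # subject that always seeks hand 1 against RB favouring hand 1
  always1 <- agent_spec("BN", list(bias = 50))
  r <- unlist(lapply(1:5, function(i)
    play_session(always1, "RB", seed = 100 + i, n_trials = 2000,
                 favoured = 1)$reward))
  expect_lt(abs(mean(r) - 0.65), 0.015)
  # unbiased Nash sits at chance against an adaptive opponent
  r2 <- unlist(lapply(1:10, function(i)
    play_session(agent_spec("BN", list(bias = 0)), "OTOM", seed = 200 + i,
                 n_trials = 1000)$reward))
  se <- sqrt(0.25 / length(r2))
  expect_lt(abs(mean(r2) - 0.5), 3 * se)
})

test_that("the protocol is counterbalanced, truncation flags short sessions", {
  d <- protocol_design()
  tr <- run_protocol(agent_spec("RL"), d, seed = 31, individual_index = 2)
  tab <- table(unique(tr[c("session_index", "condition")])$condition)
  expect_equal(sort(unname(as.vector(tab))), c(4, 4, 4))
  expect_equal(length(unique(tr$session_index)), 12)
  expect_true(all(tr$included))
  expect_equal(unique(tabulate(tr$session_index)), 60)
  # different individuals get different (rotated) condition orders
  o1 <- unique(run_protocol(agent_spec("BN"), d, 1, 1)[c("session_index", "condition")])$condition
  o2 <- unique(run_protocol(agent_spec("BN"), d, 1, 2)[c("session_index", "condition")])$condition
  expect_false(identical(o1, o2))
  # a 15-trial session is flagged excluded
  s <- play_session(agent_spec("BN"), "RB", d, seed = 1, n_trials = 15)
  expect_false(any(s$included))
})

test_that("score_performance reports raw and net rates and flags missing conditions", {
  s_all <- toy_session(rep(1, 30), rep(1, 30))
  sc <- score_performance(s_all)
  expect_equal(sc$raw[sc$condition == "RB"], 1)
  expect_equal(sc$net[sc$condition == "RB"], 0.5)
  expect_true(all(sc$missing[sc$condition != "RB"]))
  alt <- toy_session(rep(c(1, 0), 30), rep(1, 60))
  sc2 <- score_performance(alt)
  expect_equal(sc2$raw[1], 0.5); expect_equal(sc2$net[1], 0)
})

test_that("simulated performance shows the non-mentalizing decrement pattern", {
  # 0-ToM cohort: RB > vs-0-ToM >= vs-1-ToM (graded decrement)
  p <- vapply(c("RB", "OTOM", "ITOM"), function(cc)
    mean_perf(agent_spec("0ToM"), cc, n_games = 50), numeric(1))
  expect_gt(p["RB"], p["OTOM"])
  expect_gte(p["OTOM"] + 0.02, p["ITOM"])
  expect_gt(p["RB"], 0.5)
})
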