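test_that("choice log-likelihood has its closed forms and composes with replay", {
  s60 <- toy_session(rbinom(60, 1, 0.5), rbinom(60, 1, 0.5))
  expect_equal(choice_log_likelihood("BN", c(bias = 0), s60), 60 * log(0.5))
  # single trial at a known probability
  spec <- agent_spec("0ToM")
  s1 <- toy_session(1, 0)
  expect_equal(choice_log_likelihood("0ToM",
                                     c(log_vol = log(0.05),
                                       log_beta = log(0.02), bias = 0), s1),
               log(0.5))
  # any model: likelihood equals the Bernoulli sum over replayed step probabilities
  set.seed(14)
  s <- toy_session(rbinom(40, 1, 0.5), rbinom(40, 1, 0.6))
  phi <- c(log_vol = log(0.3), log_beta = log(0.2), bias = 0.1)
  p <- agent_replay(params_to_spec <- agent_spec("1ToM-comp",
                                                 list(vol = 0.3, beta = 0.2,
                                                      bias = 0.1)),
                    s$a_self, s$a_op)
  p <- pmin(1 - 1e-4, pmax(1e-4, p))
  ll <- sum(s$a_self * log(p) + (1 - s$a_self) * log(1 - p))
  expect_equal(choice_log_likelihood("1ToM-comp", phi, s), ll,
               tolerance = 1e-10)
})

test_that("variational-Laplace fits are monotone in F, deterministic and order-invariant", {
  set.seed(15)
  tr <- run_protocol(agent_spec("RL", list(alpha = 0.7, beta = 0.1)),
                     reduced_design(), seed = 44)
  sess <- tr[tr$condition == "RB", ]
  f <- fit_condition("RL", sess)
  expect_true(all(diff(f$f_trace) >= -1e-6))
  expect_s3_class(f, "fit_result")
  ev <- eigen(f$post_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # determinism
  f2 <- fit_condition("RL", sess)
  expect_equal(f$free_energy, f2$free_energy, tolerance = 1e-12)
  # session order within a condition does not matter
  sess_rev <- sess[order(-sess$session_index, sess$trial), ]
  f3 <- fit_condition("RL", sess_rev)
  expect_equal(f$free_energy, f3$free_energy, tolerance = 1e-8)
})

test_that("a biased-Nash fit recovers the empirical choice rate", {
  set.seed(16)
  a <- rbinom(200, 1, 0.8)
  f <- fit_condition("BN", toy_session(a, rbinom(200, 1, 0.5)))
  expect_gt(f$post_mean[["bias"]], 0)
  expect_lt(abs(plogis(f$post_mean[["bias"]]) - 0.8), 0.05)
})

test_that("the Laplace evidence of a one-parameter model matches quadrature", {
  skip_if_not_installed("pracma")
  set.seed(17)
  a <- rbinom(30, 1, 0.7)
  s <- toy_session(a, rbinom(30, 1, 0.5))
  f <- fit_condition("BN", s)
  gh <- pracma::gaussHermite(80)
  v <- 10 # prior variance of the bias
  b <- sqrt(2 * v) * gh$x
  ll <- vapply(b, function(bb)
    sum(a * plogis(bb, log.p = TRUE) + (1 - a) * plogis(-bb, log.p = TRUE)),
    numeric(1))
  logz <- log(sum(gh$w / sqrt(pi) * exp(ll - max(ll)))) + max(ll)
  expect_lt(abs(f$free_energy - logz), 0.5)
})

test_that("parameter recovery from refit simulated data stays inside the posterior", {
  # data simulated at the fitted posterior mean, then refitted: the truth
  # should fall within 2 posterior SD in most replicates
  set.seed(18)
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    truth <- c(logit_alpha = rnorm(1, 0.5, 0.5), log_beta = log(0.1),
               bias = rnorm(1, 0, 0.2))
    spec <- agent_spec("RL", list(alpha = plogis(truth[1]),
                                  beta = exp(truth[2]), bias = truth[3]))
    tr <- run_protocol(spec, reduced_design(), seed = 500 + r)
    f <- fit_condition("RL", tr[tr$condition == "RB", ])
    sds <- sqrt(diag(f$post_cov))
    if (abs(f$post_mean[["logit_alpha"]] - truth[1]) <= 2 * sds[1])
      hits <- hits + 1L
  }
  expect_gte(hits, 0.7 * n_rep)
})

test_that("the evidence matrix is complete, deterministic and flags missing conditions", {
  set.seed(19)
  tr <- run_protocol(agent_spec("WS", list(beta = 0.05)), reduced_design(),
                     seed = 77)
  tr$individual_id <- "a"
  tr2 <- tr; tr2$individual_id <- "b"
  trials <- rbind(tr, tr2)
  em <- evidence_matrix(trials, models = c("BN", "WS", "RL"))
  expect_equal(dim(em), c(2, 3))
  expect_false(any(is.na(em)))
  expect_equal(unname(em["a", ]), unname(em["b", ]))
  expect_gt(em["a", "WS"], em["a", "BN"])
  # an individual missing a condition is excluded and flagged
  tr3 <- tr[tr$condition != "ITOM", ]
  tr3$individual_id <- "c"
  em2 <- evidence_matrix(rbind(tr, tr3), models = "BN")
  expect_identical(attr(em2, "excluded"), "c")
  expect_identical(rownames(em2), "a")
})
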