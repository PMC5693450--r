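# Model-free decomposition of choice sequences into self- and
# opponent-history kernels: Bayesian logistic regression with
# exponentially parameterised lag kernels.

#' Exponential Volterra kernels of a choice sequence
#'
#' @param omega0 choice bias (log-odds offset).
#' @param a_op,lam_op magnitude and decay of the opponent-history
#'   (imitation) kernel: weight at lag `tau` is `a_op * exp(-lam_op * tau)`.
#' @param a_self,lam_self magnitude and decay of the self-history
#'   (perseveration) kernel.
#' @param max_lag number of lags.
#' @return an object of class `volterra_kernels`.
#' @export
volterra_kernels <- function(omega0, a_op, lam_op, a_self, lam_self,
                             max_lag = 15) {
  stopifnot(lam_op >= 0, lam_self >= 0, max_lag >= 1)
  structure(list(omega0 = omega0, a_op = a_op, lam_op = lam_op,
                 a_self = a_self, lam_self = lam_self, max_lag = max_lag),
            class = "volterra_kernels")
}

#' @export
print.volterra_kernels <- function(x, ...) {
  cat(sprintf("<volterra_kernels> bias %.3f | op: A=%.3f lam=%.3f | self: A=%.3f lam=%.3f (max lag %d)\n",
              x$omega0, x$a_op, x$lam_op, x$a_self, x$lam_self, x$max_lag))
  invisible(x)
}

#' Expand an exponential kernel over its lags
#'
#' @param a magnitude.
#' @param lam decay (>= 0).
#' @param max_lag number of lags.
#' @return numeric vector `a * exp(-lam * (1:max_lag))`.
#' @export
expand_kernel <- function(a, lam, max_lag) a * exp(-lam * seq_len(max_lag))

# signed lag design matrix: column tau holds 2*a[t - tau] - 1 (0 before the
# history starts, so early trials use the available lags only)
lag_design <- function(a, max_lag) {
  n <- length(a)
  x <- matrix(0, n, max_lag)
  s <- 2 * a - 1
  for (tau in seq_len(max_lag)) {
    if (tau < n) x[(tau + 1):n, tau] <- s[1:(n - tau)]
  }
  x
}

volterra_logodds <- function(phi, x_op, x_self, max_lag) {
  w_op <- expand_kernel(phi[2], exp(phi[3]), max_lag)
  w_self <- expand_kernel(phi[4], exp(phi[5]), max_lag)
  phi[1] + as.vector(x_op %*% w_op + x_self %*% w_self)
}

#' Fit Volterra kernels to one session
#'
#' Laplace (MAP + Gaussian curvature) fit of the logistic model
#' `q_t = s(omega0 + sum_tau w_op_tau (2 a_op_{t-tau} - 1)
#'                 + sum_tau w_self_tau (2 a_self_{t-tau} - 1))`
#' with exponentially parameterised kernels `w_tau = A exp(-lam tau)`,
#' lags starting at `tau = 1`. Early trials use the available lags only.
#'
#' @param session a session data.frame with columns `a_self`, `a_op`, or a
#'   list with those elements.
#' @param max_lag number of lags (default 15, below 1% of kernel magnitude
#'   for decays above ~0.3).
#' @param prior list of prior means/variances for the transformed parameter
#'   vector `(omega0, a_op, log lam_op, a_self, log lam_self)`.
#' @return a [volterra_kernels()] object with extra fields `post_cov`
#'   (Laplace covariance), `logpost` and `n_trials`.
#' @export
fit_volterra <- function(session, max_lag = 15, prior = volterra_prior()) {
  a_self <- as.integer(session$a_self)
  a_op <- as.integer(session$a_op)
  n <- length(a_self)
  if (n <= max_lag + 5) stop("session too short for max_lag = ", max_lag)
  if (length(unique(a_self)) == 1)
    warning("constant choice sequence: bias-dominated fit")
  x_op <- lag_design(a_op, max_lag)
  x_self <- lag_design(a_self, max_lag)
  y <- a_self

  negj <- function(phi) {
    q <- clamp_prob(plogis(volterra_logodds(phi, x_op, x_self, max_lag)))
    -(sum(y * log(q) + (1 - y) * log(1 - q)) +
        sum(dnorm(phi, prior$mean, sqrt(prior$var), log = TRUE)))
  }
  starts <- list(prior$mean,
                 prior$mean + c(0, 0.5, 0, 0.5, 0),
                 prior$mean + c(0, -0.5, 0, 0.5, 0))
  fits <- lapply(starts, function(s)
    optim(s, negj, method = "BFGS", control = list(maxit = 300)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  H <- optimHess(best$par, negj)
  k <- volterra_kernels(best$par[1], best$par[2], exp(best$par[3]),
                        best$par[4], exp(best$par[5]), max_lag)
  k$post_cov <- hess_to_cov(-H)
  k$logpost <- -best$value
  k$n_trials <- n
  k
}

default_volterra_prior_means <- c(0, 0, log(0.5), 0, log(0.5))

#' Prior for the Volterra parameter vector
#'
#' @param mean,var prior means and variances of
#'   `(omega0, a_op, log lam_op, a_self, log lam_self)`.
#' @return a list with `mean` and `var`.
#' @export
volterra_prior <- function(mean = default_volterra_prior_means,
                           var = c(10, 3, 1, 3, 1)) {
  list(mean = mean, var = var)
}

#' Within-sample prediction accuracy of fitted kernels
#'
#' Fraction of trials where the fitted choice probability, thresholded at
#' 0.5, matches the subject's recorded action.
#'
#' @param kernels a fitted [volterra_kernels()] object.
#' @param session the session to score (typically the one that was fitted).
#' @return a proportion in \[0, 1\].
#' @export
volterra_accuracy <- function(kernels, session) {
  stopifnot(inherits(kernels, "volterra_kernels"))
  a_self <- as.integer(session$a_self)
  a_op <- as.integer(session$a_op)
  phi <- c(kernels$omega0, kernels$a_op, log(max(kernels$lam_op, 1e-12)),
           kernels$a_self, log(max(kernels$lam_self, 1e-12)))
  q <- plogis(volterra_logodds(phi, lag_design(a_op, kernels$max_lag),
                               lag_design(a_self, kernels$max_lag),
                               kernels$max_lag))
  mean((q > 0.5) == (a_self == 1))
}

#' Similarity between two kernel sets
#'
#' Pearson correlation between the concatenated lag-expanded kernels
#' (opponent kernel weights followed by self kernel weights).
#'
#' @param k1,k2 [volterra_kernels()] objects with identical `max_lag`.
#' @return the correlation, or `NA` with a warning for a zero-variance
#'   kernel pair.
#' @export
kernel_similarity <- function(k1, k2) {
  stopifnot(inherits(k1, "volterra_kernels"), inherits(k2, "volterra_kernels"),
            k1$max_lag == k2$max_lag)
  v1 <- c(expand_kernel(k1$a_op, k1$lam_op, k1$max_lag),
          expand_kernel(k1$a_self, k1$lam_self, k1$max_lag))
  v2 <- c(expand_kernel(k2$a_op, k2$lam_op, k2$max_lag),
          expand_kernel(k2$a_self, k2$lam_self, k2$max_lag))
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("zero-variance kernel: similarity undefined")
    return(NA_real_)
  }
  cor(v1, v2)
}

#' Volterra reducibility of recursive agents
#'
#' Simulates competitive 1-ToM and 2-ToM seekers over hide-and-seek games
#' against the three opponent algorithms, fits the exponential-kernel
#' logistic model to each game and averages the within-sample prediction
#' accuracy — the degree to which recursive belief updating is reducible to
#' a linear convolution of both players' action histories.
#'
#' @param models seeker models to simulate.
#' @param conds opponent conditions.
#' @param n_seeds seeded games per model x condition pairing.
#' @param n_trials trials per game.
#' @param seed master seed.
#' @param max_lag kernel lags.
#' @return a list with `mean_accuracy` (across all games) and `by_pair`
#'   (data.frame of per-pairing means).
#' @export
volterra_reducibility <- function(models = c("1ToM-comp", "2ToM-comp"),
                                  conds = c("RB", "OTOM", "ITOM"),
                                  n_seeds = 50, n_trials = 200, seed = 1,
                                  max_lag = 15) {
  seeds <- child_seeds(seed, length(models) * length(conds) * n_seeds)
  out <- expand.grid(model = models, condition = conds,
                     rep = seq_len(n_seeds), stringsAsFactors = FALSE)
  out$accuracy <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- play_session(agent_spec(out$model[i]), out$condition[i],
                      seed = seeds[i], n_trials = n_trials,
                      session_index = out$rep[i])
    k <- fit_volterra(s, max_lag = max_lag)
    out$accuracy[i] <- volterra_accuracy(k, s)
  }
  by_pair <- aggregate(accuracy ~ model + condition, data = out, FUN = mean)
  list(mean_accuracy = mean(out$accuracy), by_pair = by_pair, games = out)
}

#' Reference kernels of the optimal learning style per condition
#'
#' The optimal responder to each opponent condition (0-ToM against RB,
#' 1-ToM against 0-ToM, 2-ToM against 1-ToM, all competitive) is simulated
#' on long games and its choices decomposed; the averaged kernels serve as
#' the reference against which individual learning styles are compared.
#'
#' @param condition one of `"RB"`, `"OTOM"`, `"ITOM"`.
#' @param n_trials trials per simulated game.
#' @param n_games number of games averaged.
#' @param seed integer seed.
#' @param max_lag kernel lags.
#' @return a [volterra_kernels()] object (parameters averaged over games).
#' @export
reference_kernels <- function(condition, n_trials = 200, n_games = 10,
                              seed = 1, max_lag = 15) {
  optimal <- switch(condition,
    "RB" = agent_spec("0ToM", role = "seeker"),
    "OTOM" = agent_spec("1ToM-comp", role = "seeker"),
    "ITOM" = agent_spec("2ToM-comp", role = "seeker"),
    stop("unknown condition: ", condition))
  seeds <- child_seeds(seed, n_games)
  fits <- lapply(seq_len(n_games), function(i) {
    s <- play_session(optimal, condition,
                      design = protocol_design(trials_per_session = n_trials),
                      seed = seeds[i], session_index = i)
    fit_volterra(s, max_lag = max_lag)
  })
  volterra_kernels(
    mean(vapply(fits, `[[`, numeric(1), "omega0")),
    mean(vapply(fits, `[[`, numeric(1), "a_op")),
    mean(vapply(fits, `[[`, numeric(1), "lam_op")),
    mean(vapply(fits, `[[`, numeric(1), "a_self")),
    mean(vapply(fits, `[[`, numeric(1), "lam_self")),
    max_lag)
}
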