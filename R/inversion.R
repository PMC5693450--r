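# Model inversion: variational-Laplace fits of the candidate models to
# trial-by-trial choice sequences, and the per-individual evidence matrix.

# transformed parameterisation per model: positive parameters on log scale,
# rates on logit scale, bias on its natural scale.
model_param_table <- function(model_id) {
  base <- sub("-(coop|comp)$", "", model_id)
  tab <- switch(base,
    "BN"   = data.frame(name = "bias"),
    "WS"   = data.frame(name = c("log_beta", "bias")),
    "RL"   = data.frame(name = c("logit_alpha", "log_beta", "bias")),
    "0ToM" = data.frame(name = c("log_vol", "log_beta", "bias")),
    "Inf"  = data.frame(name = c("logit_eta", "log_lambda", "log_beta", "bias")),
    "1ToM" = data.frame(name = c("log_vol", "log_beta", "bias")),
    "2ToM" = data.frame(name = c("log_vol", "log_beta", "bias")),
    stop("unknown model_id: ", model_id)
  )
  tab$prior_mean <- 0
  tab$prior_var <- ifelse(tab$name == "bias", 10, 3)
  tab
}

#' Prior specification for a model's transformed parameters
#'
#' Weakly informative independent Gaussian priors: standard normal-like
#' `N(0, 3)` on log volatilities, log temperatures, log influence weights
#' and logit rates, and `N(0, 10)` on the choice bias. The biased-Nash
#' model is fitted on its bias alone (its temperature is non-identifiable
#' when the value difference is fixed at zero).
#'
#' @param model_id one of the canonical model identifiers.
#' @return a list with named numeric vectors `mean` and `var`.
#' @export
prior_spec <- function(model_id) {
  tab <- model_param_table(model_id)
  list(mean = setNames(tab$prior_mean, tab$name),
       var = setNames(tab$prior_var, tab$name))
}

# transformed parameter vector -> agent_spec (subject is the seeker)
params_to_spec <- function(model_id, phi) {
  p <- list()
  if ("log_beta" %in% names(phi)) p$beta <- exp(phi[["log_beta"]])
  if ("bias" %in% names(phi)) p$bias <- phi[["bias"]]
  if ("log_vol" %in% names(phi)) p$vol <- exp(phi[["log_vol"]])
  if ("logit_alpha" %in% names(phi)) p$alpha <- plogis(phi[["logit_alpha"]])
  if ("logit_eta" %in% names(phi)) p$eta <- plogis(phi[["logit_eta"]])
  if ("log_lambda" %in% names(phi)) p$lambda <- exp(phi[["log_lambda"]])
  agent_spec(model_id, p, role = "seeker")
}

# normalise session input into parallel lists of integer action vectors
split_sessions <- function(sessions) {
  if (is.data.frame(sessions)) {
    stopifnot(all(c("a_self", "a_op") %in% names(sessions)))
    if ("included" %in% names(sessions))
      sessions <- sessions[sessions$included, , drop = FALSE]
    key <- if ("session_index" %in% names(sessions))
      sessions$session_index else 1L
    sessions <- split(sessions, key)
  }
  list(a_self = lapply(sessions, function(s) as.integer(s$a_self)),
       a_op = lapply(sessions, function(s) as.integer(s$a_op)))
}

#' Choice log-likelihood of a model on recorded sessions
#'
#' Sum over trials of the Bernoulli log-probability of the subject's action
#' under the model's sequentially updated choice probability; the learner's
#' state resets at each session boundary. Probabilities are clamped to
#' `[1e-4, 1 - 1e-4]`.
#'
#' @param model_id one of the canonical model identifiers.
#' @param params named numeric vector of transformed parameters (see
#'   [prior_spec()] for the names).
#' @param sessions a session data.frame (split by `session_index`) or a
#'   list of data.frames with columns `a_self`, `a_op`.
#' @return the summed log-likelihood.
#' @export
choice_log_likelihood <- function(model_id, params, sessions) {
  ss <- split_sessions(sessions)
  spec <- params_to_spec(model_id, params)
  loglik_sessions_cpp(agent_cfg(spec), ss$a_self, ss$a_op)
}

#' Options for variational-Laplace fitting
#'
#' @param max_iter maximum Gauss-Newton outer iterations.
#' @param tol convergence tolerance on the free energy (nats).
#' @param n_starts number of fixed initialisations (prior mean plus
#'   deterministic perturbations).
#' @param h finite-difference step for gradients and Hessians.
#' @return a list of options.
#' @export
fit_options <- function(max_iter = 64, tol = 1e-3, n_starts = 4, h = 1e-3) {
  list(max_iter = max_iter, tol = tol, n_starts = n_starts, h = h)
}

# posterior covariance from a negative Hessian (PD-floored)
hess_to_cov <- function(H) {
  e <- eigen((-H + t(-H)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 1e-8)
  e$vectors %*% diag(1 / ev, nrow = length(ev)) %*% t(e$vectors)
}

# fixed sign patterns for the multi-start schedule
start_patterns <- function() {
  rbind(c(0, 0, 0, 0),
        c(1, 1, 1, 1),
        c(-1, 1, -1, 1),
        c(1, -1, 1, -1),
        c(-1, -1, -1, -1),
        c(1, 1, -1, -1))
}

#' Fit one model to the sessions of one opponent condition
#'
#' Variational-Laplace inversion: the Gaussian posterior over transformed
#' parameters is found by damped Gauss-Newton ascent on the log-joint, with
#' steps accepted only if the Laplace free energy does not decrease, so the
#' free energy is non-decreasing across outer iterations. Four fixed
#' initialisations (prior mean plus deterministic perturbations) guard
#' against the non-convex likelihoods of the recursive models; the best
#' free energy is kept. Parameters are constrained to be identical across
#' the sessions being fitted.
#'
#' @param model_id one of the canonical model identifiers.
#' @param sessions sessions of a single opponent condition (data.frame or
#'   list of data.frames).
#' @param prior a prior specification as from [prior_spec()].
#' @param opts options from [fit_options()].
#' @return an object of class `fit_result`: `post_mean`, `post_cov`,
#'   `free_energy`, `n_trials`, `converged`, `f_trace`.
#' @export
fit_condition <- function(model_id, sessions, prior = prior_spec(model_id),
                          opts = fit_options()) {
  ss <- split_sessions(sessions)
  if (length(ss$a_self) == 0) stop("no included sessions to fit")
  n_trials <- sum(lengths(ss$a_self))
  y <- unlist(ss$a_self)
  pnames <- names(prior$mean)
  d <- length(pnames)
  cfg0 <- agent_cfg(agent_spec(model_id, role = "seeker"))
  pm <- prior$mean
  pv <- prior$var

  # per-trial choice probabilities across the pooled sessions
  probs <- function(phi) {
    names(phi) <- pnames
    p <- params_to_spec(model_id, phi)$params
    cfg <- cfg0
    cfg$beta <- p$beta; cfg$bias <- p$bias; cfg$vol <- p$vol
    cfg$alpha <- p$alpha; cfg$eta <- p$eta; cfg$lambda <- p$lambda
    clamp_prob(unlist(Map(function(a, b) replay_probs_cpp(cfg, a, b),
                          ss$a_self, ss$a_op)))
  }
  loglik <- function(q) sum(y * log(q) + (1 - y) * log(1 - q))
  joint <- function(phi, q) loglik(q) +
    sum(dnorm(phi, pm, sqrt(pv), log = TRUE))

  # Gauss-Newton quantities: gradient of the log-joint and the expected
  # (Fisher) negative Hessian, which is positive definite by construction,
  # via finite differences of the per-trial choice log-odds
  gn <- function(phi, q) {
    G <- matrix(0, n_trials, d)
    x0 <- qlogis(q)
    for (i in seq_len(d)) {
      ei <- numeric(d); ei[i] <- opts$h
      G[, i] <- (qlogis(probs(phi + ei)) - qlogis(probs(phi - ei))) /
        (2 * opts$h)
    }
    w <- q * (1 - q)
    g <- as.vector(t(G) %*% (y - q)) - (phi - pm) / pv
    Hneg <- t(G * w) %*% G + diag(1 / pv, d)
    list(g = g, Hneg = Hneg)
  }
  fenergy <- function(phi, q, Hneg) {
    joint(phi, q) + d / 2 * log(2 * pi) -
      0.5 * determinant(Hneg, logarithm = TRUE)$modulus[1]
  }

  pat <- start_patterns()
  starts <- lapply(seq_len(min(opts$n_starts, nrow(pat))), function(i) {
    pm + 0.5 * sqrt(pv) * pat[i, seq_len(d)]
  })

  best <- NULL
  f_by_start <- numeric(0)
  for (x0 in starts) {
    x <- x0
    init <- tryCatch({
      q <- probs(x)
      cur <- gn(x, q)
      list(q = q, cur = cur, F = fenergy(x, q, cur$Hneg))
    }, error = function(e) NULL)
    if (is.null(init) || !is.finite(init$F)) next
    q <- init$q; cur <- init$cur; Fcur <- init$F
    damp <- 1e-2
    trace <- Fcur
    converged <- FALSE
    for (it in seq_len(opts$max_iter)) {
      accepted <- FALSE
      for (try in 1:10) {
        step <- tryCatch(solve(cur$Hneg + diag(damp, d), cur$g),
                         error = function(e) NULL)
        if (!is.null(step)) {
          cand <- x + as.vector(step)
          cc <- tryCatch({
            qc <- probs(cand)
            gnc <- gn(cand, qc)
            list(q = qc, gn = gnc, F = fenergy(cand, qc, gnc$Hneg))
          }, error = function(e) NULL)
          if (!is.null(cc) && all(is.finite(cc$q))) {
            qc <- cc$q; gnc <- cc$gn; Fc <- cc$F
            if (is.finite(Fc) && Fc >= Fcur - 1e-9) {
              dF <- Fc - Fcur
              x <- cand; q <- qc; cur <- gnc; Fcur <- Fc
              trace <- c(trace, Fcur)
              accepted <- TRUE
              if (dF < opts$tol && it >= 2) converged <- TRUE
              damp <- max(damp / 4, 1e-6)
              break
            }
          }
        }
        damp <- damp * 10
      }
      if (!accepted || converged || damp > 1e10) break
    }
    if (is.null(best) || Fcur > best$free_energy) {
      best <- list(post_mean = setNames(x, pnames),
                   post_cov = hess_to_cov(-cur$Hneg),
                   free_energy = Fcur, n_trials = n_trials,
                   converged = converged, f_trace = trace,
                   model_id = model_id)
    }
    # stop the multi-start schedule once two starts agree on the optimum
    f_by_start <- c(f_by_start, Fcur)
    if (sum(abs(f_by_start - best$free_energy) < 0.1) >= 2) break
  }
  class(best) <- "fit_result"
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model_id, "| F =", round(x$free_energy, 2),
      "| n =", x$n_trials, if (x$converged) "(converged)" else "(not converged)",
      "\n")
  print(round(rbind(mean = x$post_mean, sd = sqrt(diag(x$post_cov))), 3))
  invisible(x)
}

#' Per-individual, per-model log-evidence matrix
#'
#' For each individual and candidate model, each opponent condition is
#' fitted separately (parameters shared across sessions within a condition,
#' free across conditions) and the three Laplace free energies are summed.
#' Individuals missing an opponent condition are flagged and excluded.
#'
#' @param trials cohort trial log: a data.frame with columns
#'   `individual_id`, `condition`, `session_index`, `a_self`, `a_op` and
#'   optionally `included`.
#' @param models model identifiers to fit (default: all ten).
#' @param opts options from [fit_options()].
#' @param progress print one line per individual.
#' @return a numeric matrix (individuals x models) of summed free energies,
#'   with the ids of excluded individuals in `attr(, "excluded")`.
#' @export
evidence_matrix <- function(trials, models = model_ids(),
                            opts = fit_options(), progress = FALSE) {
  stopifnot(all(c("individual_id", "condition", "a_self", "a_op") %in%
                  names(trials)))
  if (!"included" %in% names(trials)) trials$included <- TRUE
  ids <- unique(trials$individual_id)
  ok <- vapply(ids, function(id) {
    sub <- trials[trials$individual_id == id & trials$included, ]
    all(conditions() %in% unique(sub$condition))
  }, logical(1))
  excluded <- ids[!ok]
  ids <- ids[ok]
  em <- matrix(NA_real_, length(ids), length(models),
               dimnames = list(ids, models))
  for (id in ids) {
    sub <- trials[trials$individual_id == id, ]
    percond <- lapply(conditions(), function(cc)
      sub[sub$condition == cc, , drop = FALSE])
    for (m in models) {
      em[id, m] <- sum(vapply(percond, function(sc)
        fit_condition(m, sc, opts = opts)$free_energy, numeric(1)))
    }
    if (progress) message("fitted ", id)
  }
  attr(em, "excluded") <- excluded
  em
}
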