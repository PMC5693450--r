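# Family-level within-subject inference and group-level random-effects
# Bayesian model selection.

#' Partition of the model set into ToM and no-ToM families
#'
#' @return a list with character vectors `tom` (influence learning and the
#'   recursive 1-/2-ToM models, six models) and `notom` (BN, WS, RL and
#'   0-ToM, four models).
#' @export
family_partition <- function() {
  m <- tom_models()
  list(tom = m$model_id[m$family == "tom"],
       notom = m$model_id[m$family == "notom"])
}

#' Within-subject posterior probability of a ToM-compatible learning style
#'
#' Normalises one individual's ten log-evidences into posterior model
#' probabilities and returns the mass on the ToM family. Under the default
#' uniform-over-models prior, equal evidences give `pToM = 0.6` (6 of the
#' 10 models are ToM-compatible); a uniform-over-families prior (each
#' family worth 1/2, split equally within family) is available instead.
#'
#' @param evidences named numeric vector of 10 finite log-evidences (one
#'   row of the evidence matrix).
#' @param partition a [family_partition()].
#' @param prior `"model"` (uniform over models, default) or `"family"`.
#' @return the posterior probability, in \[0, 1\]; invariant to adding a
#'   constant to all log-evidences.
#' @export
ptom <- function(evidences, partition = family_partition(),
                 prior = c("model", "family")) {
  prior <- match.arg(prior)
  stopifnot(!is.null(names(evidences)), all(is.finite(evidences)))
  ids <- c(partition$tom, partition$notom)
  stopifnot(all(ids %in% names(evidences)))
  le <- evidences[ids]
  lp <- if (prior == "model") rep(0, length(ids)) else
    ifelse(ids %in% partition$tom,
           log(0.5 / length(partition$tom)),
           log(0.5 / length(partition$notom)))
  w <- le + lp
  w <- exp(w - max(w))
  post <- w / sum(w)
  sum(post[ids %in% partition$tom])
}

#' Species-level pToM scores
#'
#' Per-individual family posteriors averaged across individuals within
#' species.
#'
#' @param em evidence matrix (individuals x models) with row names.
#' @param species character vector of species labels, one per row of `em`.
#' @param ... passed to [ptom()].
#' @return a data.frame with columns `species`, `ptom` (mean), `se` and `n`.
#' @export
ptom_by_species <- function(em, species, ...) {
  stopifnot(nrow(em) == length(species))
  pt <- apply(em, 1, ptom, ...)
  out <- do.call(rbind, lapply(split(pt, species), function(x) {
    data.frame(ptom = mean(x), se = sd(x) / sqrt(length(x)), n = length(x))
  }))
  data.frame(species = rownames(out), out, row.names = NULL)
}

dirichlet_sample <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

#' Random-effects Bayesian model selection
#'
#' Treats the generating model as a random effect across subjects and
#' estimates the population frequencies of the candidate models by a
#' variational Dirichlet-multinomial scheme: subject-wise model posteriors
#' and Dirichlet counts are iterated to convergence. Exceedance
#' probabilities are estimated by Monte-Carlo sampling of the Dirichlet
#' posterior; protected exceedance probabilities mix with the
#' equal-frequency null via the Bayesian omnibus risk.
#'
#' @param em evidence matrix (subjects x models) of log-evidences.
#' @param alpha0 symmetric Dirichlet prior count (default 1).
#' @param max_iter,tol iteration control for the variational scheme.
#' @param n_samp Monte-Carlo draws for exceedance probabilities.
#' @param seed seed for the exceedance sampling.
#' @return an object of class `bms_result`: `alpha` (Dirichlet posterior),
#'   `exp_freq`, `xp`, `pxp`, `bor`, `u` (subject-wise model posteriors),
#'   `free_energy`.
#' @export
rfx_bms <- function(em, alpha0 = 1, max_iter = 500, tol = 1e-8,
                    n_samp = 1e5, seed = 1) {
  stopifnot(is.matrix(em), nrow(em) >= 2, all(is.finite(em)))
  n <- nrow(em); k <- ncol(em)
  a0 <- rep(alpha0, k)
  alpha <- a0 + n / k
  u <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    elogr <- digamma(alpha) - digamma(sum(alpha))
    w <- sweep(em, 2, elogr, "+")
    w <- exp(w - apply(w, 1, max))
    u <- w / rowSums(w)
    alpha_new <- a0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
    if (it == max_iter) stop("RFX-BMS did not converge")
  }
  exp_freq <- alpha / sum(alpha)
  r <- with_seed(seed, dirichlet_sample(n_samp, alpha))
  win <- max.col(r)
  xp <- tabulate(win, nbins = k) / n_samp
  # free energy of the random-effects model and of the equal-frequency null
  elogr <- digamma(alpha) - digamma(sum(alpha))
  lu <- ifelse(u > 0, log(u), 0)
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * elogr)
  f1 <- sum(u * (em + matrix(elogr, n, k, byrow = TRUE) - lu)) - kl_dir
  f0 <- sum(apply(em, 1, function(l) {
    m <- max(l); m + log(mean(exp(l - m)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * xp + bor / k
  structure(list(alpha = setNames(alpha, colnames(em)),
                 exp_freq = setNames(exp_freq, colnames(em)),
                 xp = setNames(xp, colnames(em)),
                 pxp = setNames(pxp, colnames(em)),
                 bor = bor, u = u, free_energy = f1),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> Dirichlet posterior over model frequencies\n")
  print(round(rbind(exp_freq = x$exp_freq, xp = x$xp, pxp = x$pxp), 3))
  cat("Bayesian omnibus risk:", signif(x$bor, 3), "\n")
  invisible(x)
}

#' Between-group comparison of learning-style sophistication
#'
#' Fits independent random-effects Dirichlet posteriors to two groups and
#' returns the Monte-Carlo posterior probability that group A's
#' frequency-weighted mean sophistication rank exceeds group B's.
#'
#' @param em_a,em_b evidence matrices of the two (disjoint) groups, with
#'   identical model columns.
#' @param score named numeric vector mapping model ids to sophistication
#'   ranks; defaults to the ordering BN < WS < RL < 0ToM < Inf < 1ToM <
#'   2ToM with cooperative/competitive variants tied.
#' @param alpha0 Dirichlet prior count.
#' @param n_samp Monte-Carlo draws.
#' @param seed seed for the sampling.
#' @return the posterior probability, in (0, 1).
#' @export
between_group_bms <- function(em_a, em_b, score = sophistication_rank(),
                              alpha0 = 1, n_samp = 1e5, seed = 1) {
  stopifnot(identical(colnames(em_a), colnames(em_b)))
  stopifnot(all(colnames(em_a) %in% names(score)))
  s <- score[colnames(em_a)]
  ba <- rfx_bms(em_a, alpha0 = alpha0, n_samp = 2, seed = seed)
  bb <- rfx_bms(em_b, alpha0 = alpha0, n_samp = 2, seed = seed)
  with_seed(seed, {
    ra <- dirichlet_sample(n_samp, ba$alpha)
    rb <- dirichlet_sample(n_samp, bb$alpha)
    mean(ra %*% s > rb %*% s)
  })
}

#' Default sophistication ranking of the model set
#'
#' @return named numeric vector of ranks (cooperative and competitive
#'   variants tied).
#' @export
sophistication_rank <- function() {
  m <- tom_models()
  setNames(m$sophistication, m$model_id)
}
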