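#' @useDynLib tomassay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm lm.fit anova coef vcov pnorm pf pt cor cor.test optim
#'   optimHess plogis qlogis rbinom runif rnorm rgamma sd aggregate
#'   setNames residuals as.formula qnorm dnorm model.matrix
#' @importFrom utils read.csv head
NULL

# probability clamp used wherever a probability is inverted or enters a
# likelihood; matches the engine's constant
.P_EPS <- 1e-4

# logistic-probit moment matching factor for E[s(x)] under a Gaussian
.A_ES <- 3 / pi^2

sigmoid <- function(x) plogis(x)

#' Posterior mean of a sigmoid-transformed Gaussian variable
#'
#' Approximates `E[s(x)]` for `x ~ N(mu, sigma2)` by the moment-matched
#' closed form `s(mu / sqrt(1 + a * sigma2))` with `a = 3 / pi^2`.
#'
#' @param mu mean of the Gaussian.
#' @param sigma2 variance of the Gaussian (non-negative).
#' @return a probability.
#' @export
sigmoid_mean <- function(mu, sigma2) {
  plogis(mu / sqrt(1 + .A_ES * pmax(sigma2, 0)))
}

clamp_prob <- function(p, eps = .P_EPS) pmin(1 - eps, pmax(eps, p))

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds from one master seed (kept below 2^31)
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
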