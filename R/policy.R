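#' Payoff tables for the dyadic hide-and-seek game
#'
#' Utilities are indexed as `u[a_self + 1, a_op + 1]` with binary actions
#' coding the two hands. The seeker is rewarded when both players pick the
#' same hand, the hider when they differ; the two tables are anti-symmetric,
#' which makes the game strictly competitive. The seeker table satisfies
#' `U(1,1) - U(0,1) = U(0,0) - U(1,0) = 1`, so the expected payoff
#' difference reduces to `2 * p_op - 1`.
#'
#' @param role `"seeker"` (wants to match) or `"hider"` (wants to mismatch).
#' @return a 2x2 numeric matrix.
#' @export
payoff_hide_and_seek <- function(role = c("seeker", "hider")) {
  role <- match.arg(role)
  u <- diag(2)
  if (role == "hider") u <- 1 - u
  dimnames(u) <- list(a_self = c("0", "1"), a_op = c("0", "1"))
  u
}

# presumed opponent table given an agent's own table and its reading of the
# interaction: cooperative partners share my interest (symmetric game),
# competitive ones hold the anti-symmetric counterpart.
presumed_opponent_table <- function(u_own, stance = c("comp", "coop")) {
  stance <- match.arg(stance)
  u <- t(u_own)
  if (stance == "comp") u <- max(u_own) + min(u_own) - u
  dimnames(u) <- list(a_self = c("0", "1"), a_op = c("0", "1"))
  u
}

#' Softmax (logistic) decision policy
#'
#' Maps an expected payoff difference to the probability of choosing
#' option 1: `P(a_self = 1) = s(dv / beta + bias)` with `s` the logistic
#' function. Output is strictly increasing in `dv` and in `bias`, and lies
#' in (0, 1).
#'
#' @param dv expected payoff difference between options 1 and 0.
#' @param beta behavioural temperature (> 0); small values give near-greedy
#'   choices, large values near-random ones.
#' @param bias log-odds offset in favour of option 1.
#' @return probability of choosing option 1.
#' @export
softmax_policy <- function(dv, beta = 1, bias = 0) {
  if (any(!is.finite(dv))) stop("'dv' must be finite")
  if (!is.numeric(beta) || any(beta <= 0)) stop("'beta' must be positive")
  plogis(dv / beta + bias)
}

#' Expected payoff difference given a prediction of the opponent
#'
#' Computes `dV = p_op * (U(1,1) - U(0,1)) + (1 - p_op) * (U(1,0) - U(0,0))`,
#' the difference in expected utility between choosing option 1 and option 0
#' when the opponent plays option 1 with probability `p_op`.
#'
#' @param p_op probability that the opponent chooses option 1, in \[0, 1\].
#' @param u 2x2 payoff table indexed `u[a_self + 1, a_op + 1]`.
#' @return the expected payoff difference.
#' @export
expected_value_difference <- function(p_op, u) {
  if (any(p_op < 0 | p_op > 1)) stop("'p_op' must lie in [0, 1]")
  stopifnot(is.matrix(u), all(dim(u) == c(2, 2)))
  p_op * (u[2, 2] - u[1, 2]) + (1 - p_op) * (u[2, 1] - u[1, 1])
}
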