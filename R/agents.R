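## Generative choice agents for the task simulator. Each agent is a plain
## parameter list (kind + params); the simulator drives it through
## newAgentState / agentChoose / updateAgentState.

#' Generative agents for the matching task
#'
#' * `randomAgent(pA)`: chooses object A with fixed probability.
#' * `historyAgent(rewardWeights, choiceWeights, bias)`: log-odds of choosing
#'   A are a weighted sum of the last `N` reward differences and choice
#'   differences — the same functional form as the history logistic model
#'   fitted by [fitHistoryWeights()], so its weights are recoverable by that
#'   fit.
#' * `logisticAgent(rewardWeights, choiceWeights, beta0, betaValue, betaRisk)`:
#'   computes per-object value (weighted mean of reward and choice history)
#'   and subjective risk (weighted variance of reward history) with the given
#'   fixed weights, maps them to left/right through the cue position, and
#'   chooses left with probability
#'   `plogis(beta0 + betaValue * dValue + betaRisk * dRisk)`. A positive
#'   `betaRisk` makes the agent risk seeking. The first `N` trials use an
#'   uninformed 0.5 policy.
#' * `rlAgent(alpha, tau, variant, stack)`: Rescorla-Wagner learner with
#'   softmax over the two object values. `variant = "standard"` updates the
#'   chosen option only; `"stack"` additionally lets the unchosen option's
#'   value accumulate toward the reward ceiling at rate `stack` (mimicking
#'   baited-reward availability growth); `"reversal"` updates the unchosen
#'   option toward the opposite outcome.
#'
#' @param pA probability of choosing A (random agent).
#' @param rewardWeights,choiceWeights numeric weight vectors over lags 1..N.
#' @param bias,beta0 intercepts (log-odds scale).
#' @param betaValue,betaRisk sensitivity to value and risk differences.
#' @param alpha learning rate in \[0, 1\].
#' @param tau softmax inverse temperature.
#' @param variant `"standard"`, `"stack"` or `"reversal"`.
#' @param stack stack rate in \[0, 1\] (stack variant only).
#' @return an agent object (list with class `"Agent"`)
#' @name agents
NULL

#' @rdname agents
#' @export
randomAgent <- function(pA = 0.5) {
  structure(list(kind = "random", pA = pA), class = "Agent")
}

#' @rdname agents
#' @export
historyAgent <- function(rewardWeights, choiceWeights, bias = 0) {
  stopifnot(length(rewardWeights) == length(choiceWeights))
  structure(list(kind = "history", wr = rewardWeights, wc = choiceWeights,
                 bias = bias, N = length(rewardWeights)), class = "Agent")
}

#' @rdname agents
#' @export
logisticAgent <- function(rewardWeights, choiceWeights = rep(0, length(rewardWeights)),
                          beta0 = 0, betaValue = 20, betaRisk = 6) {
  stopifnot(length(rewardWeights) == length(choiceWeights))
  structure(list(kind = "logistic", wr = rewardWeights, wc = choiceWeights,
                 b0 = beta0, b1 = betaValue, b2 = betaRisk,
                 N = length(rewardWeights)), class = "Agent")
}

#' @rdname agents
#' @export
rlAgent <- function(alpha = 0.3, tau = 5,
                    variant = c("standard", "stack", "reversal"), stack = 0.1) {
  variant <- match.arg(variant)
  stopifnot(alpha >= 0, alpha <= 1, tau > 0, stack >= 0, stack <= 1)
  structure(list(kind = paste0("rl-", variant), variant = variant,
                 alpha = alpha, tau = tau, stack = stack), class = "Agent")
}

newAgentState <- function(agent) {
  switch(agent$kind,
    random = list(t = 0L),
    history = ,
    logistic = list(t = 0L,
                    RA = numeric(agent$N), RB = numeric(agent$N),
                    CA = numeric(agent$N), CB = numeric(agent$N)),
    list(t = 0L, q = c(A = 0.5, B = 0.5)))  # rl-*
}

## Weighted mean value and weighted variance risk over a lag buffer
## (index 1 = previous trial).
historyValueRisk <- function(R, C, wr, wc) {
  N <- length(wr)
  value <- (sum(wr * R) + sum(wc * C)) / N
  risk <- sum(wr * (R - mean(R))^2) / (N - 1)
  c(value = value, risk = risk)
}

agentChoose <- function(agent, st, posA) {
  pA <- switch(agent$kind,
    random = agent$pA,
    history = {
      if (st$t < agent$N) 0.5
      else plogis(sum(agent$wr * (st$RA - st$RB)) +
                  sum(agent$wc * (st$CA - st$CB)) + agent$bias)
    },
    logistic = {
      if (st$t < agent$N) 0.5
      else {
        a <- historyValueRisk(st$RA, st$CA, agent$wr, agent$wc)
        b <- historyValueRisk(st$RB, st$CB, agent$wr, agent$wc)
        dV <- a["value"] - b["value"]; dR <- a["risk"] - b["risk"]
        if (posA == "L") {
          pL <- plogis(agent$b0 + agent$b1 * dV + agent$b2 * dR)
          pL
        } else {
          pL <- plogis(agent$b0 - agent$b1 * dV - agent$b2 * dR)
          1 - pL
        }
      }
    },
    plogis(agent$tau * (st$q["A"] - st$q["B"])))  # rl-*
  if (runif(1) < pA) "A" else "B"
}

updateAgentState <- function(agent, st, choice, action, reward) {
  st$t <- st$t + 1L
  if (agent$kind %in% c("history", "logistic")) {
    shift <- function(buf, v) c(v, buf[-length(buf)])
    chA <- as.numeric(choice == "A")
    st$RA <- shift(st$RA, reward * chA)
    st$RB <- shift(st$RB, reward * (1 - chA))
    st$CA <- shift(st$CA, chA)
    st$CB <- shift(st$CB, 1 - chA)
  } else if (startsWith(agent$kind, "rl")) {
    ch <- choice; un <- if (ch == "A") "B" else "A"
    st$q[ch] <- st$q[ch] + agent$alpha * (reward - st$q[ch])
    if (agent$variant == "stack")
      st$q[un] <- st$q[un] + agent$stack * (1 - st$q[un])
    else if (agent$variant == "reversal")
      st$q[un] <- st$q[un] + agent$alpha * ((1 - reward) - st$q[un])
  }
  st
}
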