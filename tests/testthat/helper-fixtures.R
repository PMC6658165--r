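## Shared fixtures, built in code at test time.

suppressPackageStartupMessages(library(SummarizedExperiment))

expDecayWeights <- function(a = 1.5, rate = 2, N = 10) a * exp(-(1:N) / rate)

## standard generative agents used across tests
riskSeekingAgent <- function(betaRisk = 6)
  logisticAgent(expDecayWeights(1.5), expDecayWeights(0.8),
                beta0 = 0, betaValue = 20, betaRisk = betaRisk)

## a session with weights, decision variables and action-domain weights
fittedSession <- function(nTrials = 400, seed = 1,
                          agent = riskSeekingAgent()) {
  s <- simulateSession(taskConfig(), agent, nTrials = nTrials, seed = seed)
  w <- suppressWarnings(fitHistoryWeights(buildHistoryMatrix(s)))
  wa <- suppressWarnings(fitHistoryWeights(buildHistoryMatrix(s, domain = "action")))
  dv <- decisionVariables(s, w, wa)
  list(session = s, weights = w, actionWeights = wa, dv = dv)
}

## hand-built session from explicit choice/reward vectors (single block,
## base probabilities nominal; inst_p/baited fields filled consistently)
toySession <- function(choice, reward, pos_A = NULL) {
  n <- length(choice)
  if (is.null(pos_A)) pos_A <- rep(c("L", "R"), length.out = n)
  action <- ifelse((choice == "A") == (pos_A == "L"), "L", "R")
  nUnA <- nUnB <- integer(n); na <- nb <- 0L
  for (i in seq_len(n)) {
    nUnA[i] <- na; nUnB[i] <- nb
    if (choice[i] == "A") { na <- 0L; nb <- nb + 1L }
    else { nb <- 0L; na <- na + 1L }
  }
  tr <- data.frame(
    trial = seq_len(n), block_id = 1L, base_p_A = 0.3, base_p_B = 0.3,
    n_unchosen_A = nUnA, n_unchosen_B = nUnB,
    inst_p_A = scheduledProbability(0.3, nUnA),
    inst_p_B = scheduledProbability(0.3, nUnB),
    baited_A = as.integer(choice == "A" & reward == 1),
    baited_B = as.integer(choice == "B" & reward == 1),
    pos_A = pos_A, choice = choice, action = action,
    reward = as.integer(reward),
    t_fix_on = 500, t_cue_on = 4000, t_tgt_fix = 4500, t_cue_off = 6000,
    t_outcome = 7000, stringsAsFactors = FALSE)
  new("Session", trials = tr, config = unclass(taskConfig()),
      agentId = "toy")
}

## brute-force loop oracles for the weighted history statistics
oracleValue <- function(R, C, wr, wc, i) {
  N <- length(wr)
  (sum(vapply(1:N, function(j) wr[j] * R[i - j], 0)) +
     sum(vapply(1:N, function(j) wc[j] * C[i - j], 0))) / N
}
oracleRisk <- function(R, wr, i) {
  N <- length(wr)
  m <- mean(vapply(1:N, function(j) R[i - j], 0))
  sum(vapply(1:N, function(j) wr[j] * (R[i - j] - m)^2, 0)) / (N - 1)
}
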