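test_that("scheduled probability follows the baited-schedule closed form", {
  expect_equal(scheduledProbability(0.05, 0), 0.05)
  expect_equal(scheduledProbability(0.5, 1), 0.75)
  expect_equal(scheduledProbability(0.2, 2), 0.488)
  ## monotone nondecreasing in n, equal to P0 at n = 0
  for (P0 in c(0.05, 0.3, 0.55)) {
    p <- scheduledProbability(P0, 0:20)
    expect_equal(p[1], P0)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p <= 1))
  }
  expect_error(scheduledProbability(0, 1))
  expect_error(scheduledProbability(1.2, 1))
  expect_error(scheduledProbability(0.5, -1))
})

test_that("objective risk equals the enumerated two-outcome variance", {
  ## brute-force oracle: var = sum_k p_k (m_k - EV)^2 over outcomes {0, m}
  enumVar <- function(p, m) {
    ev <- p * m
    p * (m - ev)^2 + (1 - p) * (0 - ev)^2
  }
  for (p in seq(0, 1, by = 0.05))
    expect_equal(objectiveRisk(p, 0.7), enumVar(p, 0.7), tolerance = 1e-15)
  expect_equal(objectiveRisk(0, 0.7), 0)
  expect_equal(objectiveRisk(1, 0.7), 0)
  expect_equal(objectiveRisk(0.3, 0.7), objectiveRisk(0.7, 0.7))
  expect_equal(objectiveRisk(0.3, 0.7), 0.1029)
  expect_error(objectiveRisk(-0.1, 0.7))
  expect_error(objectiveRisk(0.5, 0))
})

test_that("session simulation respects the trial-record invariants", {
  s <- simulateSession(taskConfig(), randomAgent(), nTrials = 1000, seed = 3)
  tr <- trials(s)
  expect_equal(tr$inst_p_A,
               1 - (1 - tr$base_p_A)^(tr$n_unchosen_A + 1))
  ## reward implies the chosen object was baited
  ch <- tr$choice
  baitedChosen <- ifelse(ch == "A", tr$baited_A, tr$baited_B)
  expect_true(all(tr$reward <= baitedChosen))
  expect_equal(tr$reward, baitedChosen)
  ## action consistent with (choice, cue position)
  expect_equal(tr$action,
               ifelse((ch == "A") == (tr$pos_A == "L"), "L", "R"))
  ## base probabilities sum to the configured constant
  expect_equal(tr$base_p_A + tr$base_p_B, rep(0.6, nrow(tr)))
})

test_that("cue positions are counterbalanced", {
  s <- simulateSession(taskConfig(), randomAgent(), nTrials = 2500, seed = 9)
  expect_lt(abs(mean(trials(s)$pos_A == "L") - 0.5), 0.02)
})

test_that("identical seed, config and agent give identical sessions", {
  a <- simulateSession(taskConfig(), randomAgent(), nTrials = 300, seed = 11)
  b <- simulateSession(taskConfig(), randomAgent(), nTrials = 300, seed = 11)
  expect_identical(trials(a), trials(b))
})

test_that("always choosing one object yields its base reward rate", {
  cfg <- taskConfig(baseProbPairs = cbind(0.3, 0.3))
  s <- simulateSession(cfg, randomAgent(pA = 1), nTrials = 4000, seed = 2)
  rate <- mean(trials(s)$reward)
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / 4000))
})

test_that("bait availability after n unchosen trials matches the closed form", {
  cfg <- taskConfig(baseProbPairs = cbind(0.3, 0.3))
  s <- simulateSession(cfg, randomAgent(), nTrials = 8000, seed = 5)
  tr <- trials(s)
  for (n in 0:3) {
    i <- tr$n_unchosen_B == n
    pred <- scheduledProbability(0.3, n)
    se <- sqrt(pred * (1 - pred) / sum(i))
    expect_lt(abs(mean(tr$baited_B[i]) - pred), 3 * se)
  }
})

test_that("risk-seeking logistic agent prefers the riskier equal-value side", {
  ## with equal values and higher risk left, P(left) > 0.5 by construction
  ag <- riskSeekingAgent(betaRisk = 2)
  s <- simulateSession(taskConfig(), ag, nTrials = 3000, seed = 13)
  w <- weightSet(expDecayWeights(1.5), expDecayWeights(0.8), domain = "object")
  dv <- decisionVariables(s, w)
  ok <- !is.na(dv$dRiskLR) & abs(dv$dValueLR) < quantile(abs(dv$dValueLR),
                                                         0.2, na.rm = TRUE)
  pL <- mean(trials(s)$action[ok & dv$dRiskLR > 0] == "L")
  expect_gt(pL, 0.5)
})

test_that("invalid agent output is a contract error", {
  bad <- structure(list(kind = "random", pA = 0.5), class = "Agent")
  ## break the agent by monkey-patching its kind to something unhandled
  bad$kind <- "bogus"
  expect_error(simulateSession(taskConfig(), bad, nTrials = 5, seed = 1))
})

test_that("task config validates its invariants", {
  expect_error(taskConfig(baseProbPairs = cbind(0.7, 0.1), probSum = 0.8),
               "0.05")
  expect_error(taskConfig(baseProbPairs = cbind(0.3, 0.4)), "probSum")
  cfg <- taskConfig()
  expect_equal(nrow(cfg$epochs), 11L)
  expect_true(all(cfg$epochs$duration == 500))
})
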