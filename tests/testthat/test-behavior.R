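test_that("history design matrix matches hand enumeration on a toy session", {
  choice <- c("A","A","B","A","B","B","A","B","A","A","B","A","A","B","A")
  reward <- c(1, 0, 1, 1, 0, 1, 0, 0, 1, 1, 1, 0, 1, 0, 0)
  s <- toySession(choice, reward)
  hm <- buildHistoryMatrix(s, N = 3, domain = "object")
  expect_equal(ncol(hm$X), 2 * 3 + 1)
  expect_equal(hm$trials, 4:15)
  RA <- as.numeric(choice == "A") * reward
  RB <- as.numeric(choice == "B") * reward
  CA <- as.numeric(choice == "A"); CB <- 1 - CA
  for (r in seq_along(hm$trials)) {
    i <- hm$trials[r]
    for (j in 1:3) {
      expect_equal(unname(hm$X[r, paste0("Rdiff", j)]), RA[i-j] - RB[i-j])
      expect_equal(unname(hm$X[r, paste0("Cdiff", j)]), CA[i-j] - CB[i-j])
    }
    expect_equal(hm$y[r], CA[i])
  }
  ## A chosen unrewarded: reward diff 0, choice diff +1
  expect_equal(RA[2] - RB[2], 0)
  expect_equal(CA[2] - CB[2], 1)
})

test_that("degenerate history columns are dropped with a warning", {
  s <- toySession(rep("A", 30), rbinom(30, 1, 0.5))
  hm <- buildHistoryMatrix(s, N = 3)
  expect_warning(w <- fitHistoryWeights(hm), "degenerate")
  expect_true(all(is.finite(rewardWeights(w))))
})

test_that("weighted value and risk match the loop oracles on random windows", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60
    choice <- sample(c("A", "B"), n, replace = TRUE)
    reward <- rbinom(n, 1, 0.5)
    s <- toySession(choice, reward)
    wr <- rnorm(10, 0.5, 0.4); wc <- rnorm(10, 0.2, 0.3)
    w <- weightSet(wr, wc, domain = "object")
    val <- objectValue(s, w, "reward_and_choice")
    rsk <- subjectiveRisk(s, w)
    RA <- as.numeric(choice == "A") * reward
    CA <- as.numeric(choice == "A")
    for (i in c(11, 25, n)) {
      expect_equal(val$valueA[i], oracleValue(RA, CA, wr, wc, i),
                   tolerance = 1e-12)
      expect_equal(rsk$riskA[i], oracleRisk(RA, wr, i), tolerance = 1e-12)
    }
    expect_true(all(is.na(val$valueA[1:10])))
  }
})

test_that("value and risk arithmetic on simple windows", {
  ## 2 rewards from A in the last 10 trials, unit weights -> value 0.2
  choice <- c(rep("A", 10), "B")
  reward <- c(1, 1, rep(0, 8), 0)
  s <- toySession(choice, reward)
  w <- weightSet(rep(1, 10), rep(0, 10), domain = "object")
  expect_equal(objectValue(s, w, "reward_only")$valueA[11], 0.2)
  ## exactly 1 reward in 10, unit weights -> risk ((0.9)^2 + 9 (0.1)^2)/9 = 0.1
  choice2 <- c(rep("A", 10), "B")
  reward2 <- c(1, rep(0, 9), 0)
  s2 <- toySession(choice2, reward2)
  expect_equal(subjectiveRisk(s2, w)$riskA[11], 0.1)
  ## all-identical rewards -> zero risk
  s3 <- toySession(rep("A", 11), rep(1, 11))
  expect_equal(subjectiveRisk(s3, w)$riskA[11], 0)
  ## no rewards and no choices of A in window -> value 0
  s4 <- toySession(c(rep("B", 10), "A"), rep(0, 11))
  expect_equal(objectValue(s4, weightSet(rep(1, 10), rep(1, 10)),
                           "reward_and_choice")$valueA[11], 0)
})

test_that("utility is the fitted-weight combination of value and risk", {
  fx <- fittedSession(nTrials = 200, seed = 4)
  dv <- utility(fx$dv, c(value = 2, risk = 3))
  i <- which(!is.na(dv$ObjectValueA))[1]
  expect_equal(dv$UtilityA[i],
               2 * dv$ObjectValueA[i] + 3 * dv$ObjectRiskA[i])
  ## risk weight 0 -> utility proportional to value
  dv0 <- utility(fx$dv, c(value = 2, risk = 0))
  expect_equal(dv0$UtilityB, 2 * dv0$ObjectValueB)
  ## equal values, higher risk on A, positive risk weight -> U_A > U_B
  j <- which(!is.na(dv$ObjectRiskA) & dv$ObjectRiskA > dv$ObjectRiskB)[1]
  dvEq <- fx$dv
  dvEq$ObjectValueA[j] <- dvEq$ObjectValueB[j]
  u <- utility(dvEq, c(value = 2, risk = 3))
  expect_gt(u$UtilityA[j], u$UtilityB[j])
})

test_that("random agent yields null history weights", {
  s <- simulateSession(taskConfig(), randomAgent(), nTrials = 4000, seed = 21)
  w <- fitHistoryWeights(buildHistoryMatrix(s))
  z <- abs(rewardWeights(w) / w@se$reward)
  expect_true(all(z < 3.5))
  expect_lt(mean(w@diagnostics$significant, na.rm = TRUE), 0.2)
})

test_that("generative history weights are recovered with decay ordering", {
  wr <- expDecayWeights(1.5); wc <- expDecayWeights(0.8)
  s <- simulateSession(taskConfig(), historyAgent(wr, wc),
                       nTrials = 8000, seed = 22)
  w <- fitHistoryWeights(buildHistoryMatrix(s))
  ## 3.5 SE per coefficient keeps the familywise error over the 21
  ## simultaneous comparisons near 1%
  expect_true(all(abs(rewardWeights(w) - wr) < 3.5 * w@se$reward))
  expect_true(all(abs(choiceWeights(w) - wc) < 3.5 * w@se$choice))
  ## decay ordering preserved across well-separated lags
  est <- rewardWeights(w)
  expect_true(est[1] > est[3] && est[2] > est[5] && est[1] > est[10])
})

test_that("history weights are stable across session halves", {
  s <- simulateSession(taskConfig(), historyAgent(expDecayWeights(1.5),
                                                  expDecayWeights(0.8)),
                       nTrials = 8000, seed = 23)
  hm <- buildHistoryMatrix(s)
  half <- floor(length(s) / 2)
  sub <- function(keep) list(X = hm$X[keep, ], y = hm$y[keep],
                             trials = hm$trials[keep], N = hm$N,
                             domain = hm$domain)
  w1 <- fitHistoryWeights(sub(hm$trials <= half))
  w2 <- fitHistoryWeights(sub(hm$trials > half))
  pooledSe <- sqrt(w1@se$reward^2 + w2@se$reward^2)
  expect_true(all(abs(rewardWeights(w1) - rewardWeights(w2)) < 3 * pooledSe))
})

test_that("choice-model risk coefficient tracks the generative risk attitude", {
  wr <- expDecayWeights(1.5); wc <- expDecayWeights(0.8)
  trueW <- weightSet(wr, wc, domain = "object")
  ## risk seeker
  sPlus <- simulateSession(taskConfig(), riskSeekingAgent(6),
                           nTrials = 10000, seed = 31)
  fPlus <- fitChoiceModel(decisionVariables(sPlus, trueW), sPlus)
  expect_gt(fPlus$coef[["dRisk"]], 0)
  ## risk averse: sign flips
  sMinus <- simulateSession(taskConfig(), riskSeekingAgent(-6),
                            nTrials = 10000, seed = 31)
  fMinus <- fitChoiceModel(decisionVariables(sMinus, trueW), sMinus)
  expect_lt(fMinus$coef[["dRisk"]], 0)
  ## value-only agent: value strongly positive, risk near zero
  s0 <- simulateSession(taskConfig(), riskSeekingAgent(0),
                        nTrials = 8000, seed = 32)
  f0 <- fitChoiceModel(decisionVariables(s0, trueW), s0)
  expect_gt(f0$coef[["dValue"]] / f0$se[["dValue"]], 5)
  expect_lt(abs(f0$coef[["dRisk"]] / f0$se[["dRisk"]]), 3)
})

test_that("minimal-value-difference subset still detects the risk influence", {
  trueW <- weightSet(expDecayWeights(1.5), expDecayWeights(0.8),
                     domain = "object")
  s <- simulateSession(taskConfig(), riskSeekingAgent(6),
                       nTrials = 8000, seed = 33)
  dv <- decisionVariables(s, trueW)
  f <- fitChoiceModel(dv, s, subset = "minValue")
  expect_lte(f$n, ceiling(0.11 * sum(!is.na(dv$dValueLR))))
  expect_gt(f$coef[["dRisk"]], 0)
})
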