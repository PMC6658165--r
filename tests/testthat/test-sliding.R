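test_that("run-length helpers implement the strict criterion", {
  x <- c(F, T, T, T, F, T, T, T, T, T, T, T, F)
  expect_equal(matchRisk:::maxRun(x), 7L)
  expect_equal(matchRisk:::firstRunStart(x, 6), 6L)
  expect_true(is.na(matchRisk:::firstRunStart(x, 7)))
  ## a blip of exactly the criterion length does not qualify
  y <- c(rep(TRUE, 6), rep(FALSE, 10))
  expect_true(is.na(matchRisk:::firstRunStart(y, 6)))
  ## two qualifying runs: latency from the first
  z <- c(rep(F, 3), rep(T, 8), rep(F, 4), rep(T, 9))
  expect_equal(matchRisk:::firstRunStart(z, 6), 4L)
})

test_that("window counts equal a direct binning oracle", {
  set.seed(71)
  spikes <- lapply(1:15, function(i) sort(runif(40, 0, 3000)))
  ev <- rep(500, 15)
  starts <- seq(-500, 1300, 25)
  got <- matchRisk:::windowCounts(spikes, ev, starts, 200)
  for (i in c(1, 7, 15)) for (k in c(1, 20, length(starts))) {
    rel <- spikes[[i]] - 500
    expect_equal(got[i, k], sum(rel >= starts[k] & rel < starts[k] + 200))
  }
})

test_that("designed sub-epoch tuning yields a covering significant run", {
  fx <- fittedSession(nTrials = 300, seed = 72)
  cfg <- list(list(n = 4, label = "risk", variables = "ObjectRiskA",
                   gain = 10, randomSign = FALSE,
                   window = list(event = "t_fix_on", t0 = 300, t1 = 800)))
  ec <- simulateSpikes(fx$session, fx$dv, makePopulation(cfg, seed = 73),
                       seed = 74, spikeTimes = TRUE)
  sw <- slidingWindowRegression(ec, "eq11", range = c(-500, 1500))
  codedAll <- vapply(sw$results, function(r) r$coded[["ObjectRiskA"]],
                     logical(1))
  expect_gte(sum(codedAll), 3)
  ## the first qualifying run starts near the designed onset
  lat <- codingLatency(sw, "ObjectRiskA")
  l <- lat$latency[codedAll, "ObjectRiskA"]
  expect_true(all(l > 0 - 250 & l < 800, na.rm = TRUE))
})

test_that("constant-rate neurons pass no sliding criterion", {
  fx <- fittedSession(nTrials = 250, seed = 75)
  ec <- simulateSpikes(fx$session, fx$dv,
                       list(neuronSpec(1, 12), neuronSpec(2, 18)),
                       seed = 76, spikeTimes = TRUE)
  sw <- slidingWindowRegression(ec, "eq11")
  expect_false(any(vapply(sw$results, function(r) any(r$coded), logical(1))))
})

test_that("trial shuffling calibrates the consecutive-window criterion", {
  fx <- fittedSession(nTrials = 300, seed = 77)
  cfg <- list(list(n = 15, label = "risk", variables = "ObjectRiskA",
                   gain = 8, window = list(event = "t_fix_on",
                                           t0 = 0, t1 = 1000)))
  ec <- simulateSpikes(fx$session, fx$dv, makePopulation(cfg, seed = 78),
                       seed = 79, spikeTimes = TRUE)
  cal <- slidingShuffleCalibration(ec, "eq11", nShuffles = 2, seed = 80)
  expect_lt(cal$fracByTerm[["ObjectRiskA"]], 0.15)
  ## the same neurons unshuffled are coded
  sw <- slidingWindowRegression(ec, "eq11")
  expect_gt(mean(vapply(sw$results, function(r) r$coded[["ObjectRiskA"]],
                        logical(1))), 0.7)
})

test_that("joint-coding statistics detect forced co-tuning", {
  set.seed(81)
  ## independent coding: no association expected
  a <- rbinom(120, 1, 0.4) == 1
  b <- rbinom(120, 1, 0.35) == 1
  jcInd <- jointCodingStats(cbind(risk = a, value = b))
  expect_gt(jcInd$pairs$p[1], 0.001)
  ## forced co-tuning: same neurons code both
  co <- rbinom(120, 1, 0.4) == 1
  noisy <- co & rbinom(120, 1, 0.9) == 1
  jcCo <- jointCodingStats(cbind(risk = co, value = noisy))
  expect_lt(jcCo$pairs$p[1], 1e-6)
  expect_gt(jcCo$pairs$nJoint[1], jcCo$pairs$expectedJoint[1])
  ## sign-matched co-tuning gives a positive cross-coefficient slope
  coefs <- cbind(risk = rnorm(120), value = rnorm(120))
  coefs[co, "value"] <- coefs[co, "risk"] * 0.8 + rnorm(sum(co), 0, 0.3)
  jcSign <- jointCodingStats(cbind(risk = co, value = co), coefs = coefs)
  expect_gt(jcSign$coefRegression$slope[1], 0)
  expect_lt(jcSign$coefRegression$p[1], 0.01)
  ## joint vs pure proportions
  expect_true(all(c("nJoint", "nPure", "z", "p") %in%
                    names(jcInd$jointVsPure)))
})
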