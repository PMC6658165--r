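test_that("population specs honour the requested class counts", {
  cfg <- list(
    list(n = 47, label = "objRisk", variables = "ObjectRiskA", gain = 6),
    list(n = 5, label = "untuned", variables = NULL, gain = 0))
  specs <- makePopulation(cfg, seed = 1)
  expect_length(specs, 52)
  hasRisk <- vapply(specs, function(sp)
    !is.null(sp$tuning) && any(sp$tuning$variable == "ObjectRiskA" &
                                 sp$tuning$gain != 0), logical(1))
  expect_equal(sum(hasRisk), 47L)
  man <- attr(specs, "manifest")
  expect_equal(sum(man$class == "objRisk"), 47L)
  ## all-untuned config: empty gain maps
  specs0 <- makePopulation(list(list(n = 4, variables = NULL)), seed = 1)
  expect_true(all(vapply(specs0, function(sp) is.null(sp$tuning), logical(1))))
})

test_that("population construction is seed-deterministic", {
  cfg <- defaultPopulationConfig(nPerClass = 3)
  a <- makePopulation(cfg, seed = 7)
  b <- makePopulation(cfg, seed = 7)
  expect_identical(a, b)
})

test_that("untuned Poisson neurons have the configured rate and Fano ~ 1", {
  fx <- fittedSession(nTrials = 800, seed = 8)
  specs <- list(neuronSpec(1, baseline = 10))
  ec <- simulateSpikes(fx$session, fx$dv, specs, seed = 9)
  x <- assay(ec, "Cue")[1, ]
  expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / 800))
  expect_lt(abs(var(x) / mean(x) - 1), 0.25)
})

test_that("count regression slope matches the designed gain", {
  ## expected slope of counts on the z-scored variable = gain * 0.5 s
  fx <- fittedSession(nTrials = 1000, seed = 10)
  tun <- data.frame(variable = "ObjectRiskA", gain = 6,
                    epochs = "Cue")
  ec <- simulateSpikes(fx$session, fx$dv,
                       list(neuronSpec(1, 20, tun)), seed = 11)
  z <- fx$dv$ObjectRiskA
  z <- (z - mean(z, na.rm = TRUE)) / sd(z, na.rm = TRUE)
  ok <- !is.na(z)
  f <- lm(assay(ec, "Cue")[1, ok] ~ z[ok])
  slope <- coef(f)[2]
  se <- summary(f)$coefficients[2, 2]
  expect_lt(abs(slope - 3), 3 * se)
})

test_that("spike simulation is seed-deterministic", {
  fx <- fittedSession(nTrials = 150, seed = 12)
  specs <- makePopulation(defaultPopulationConfig(nPerClass = 1), seed = 2)
  a <- simulateSpikes(fx$session, fx$dv, specs, seed = 13, spikeTimes = TRUE)
  b <- simulateSpikes(fx$session, fx$dv, specs, seed = 13, spikeTimes = TRUE)
  expect_identical(assays(a), assays(b))
  expect_identical(spikeTimes(a), spikeTimes(b))
})

test_that("spike-time stream and epoch counts are mutually consistent", {
  fx <- fittedSession(nTrials = 100, seed = 14)
  tun <- data.frame(variable = "ObjectRiskA", gain = 5, epochs = "Cue,PreCue")
  ec <- simulateSpikes(fx$session, fx$dv, list(neuronSpec(1, 15, tun)),
                       seed = 15, spikeTimes = TRUE)
  st <- spikeTimes(ec)[[1]]
  ev <- metadata(ec)$eventTimes
  oracle <- countEpochs(st, ev)
  for (e in epochNames(ec))
    expect_equal(unname(assay(ec, e)[1, ]), unname(oracle[, e]))
})

test_that("epoch counting matches a brute-force binning oracle", {
  set.seed(16)
  nT <- 20
  ev <- data.frame(t_fix_on = rep(500, nT), t_cue_on = runif(nT, 3600, 4400),
                   t_tgt_fix = runif(nT, 4600, 5000),
                   t_cue_off = runif(nT, 6000, 7000),
                   t_outcome = runif(nT, 7500, 8200))
  spikes <- lapply(seq_len(nT), function(i) sort(runif(60, 0, 9000)))
  got <- countEpochs(spikes, ev)
  et <- epochTable()
  for (i in seq_len(nT)) for (k in seq_len(nrow(et))) {
    t0 <- ev[i, et$event[k]] + et$offset[k]
    expect_equal(unname(got[i, k]),
                 sum(spikes[[i]] >= t0 & spikes[[i]] < t0 + 500))
  }
  ## single spike just after fixation onset lands in Fix only
  one <- c(list(601), lapply(2:nT, function(i) numeric(0)))
  g1 <- countEpochs(one, ev)
  expect_equal(unname(g1[1, "Fix"]), 1L)
  expect_equal(sum(g1[1, ]), 1L)
})

test_that("designed latency windows produce ordered sliding-window peaks", {
  fx <- fittedSession(nTrials = 300, seed = 17)
  cfg <- list(
    list(n = 6, label = "hist", variables = "LastRewardChoice", gain = 8,
         window = list(event = "t_fix_on", t0 = 0, t1 = 500)),
    list(n = 6, label = "risk", variables = "ObjectRiskA", gain = 8,
         window = list(event = "t_fix_on", t0 = 500, t1 = 1000)))
  specs <- makePopulation(cfg, seed = 18)
  ec <- simulateSpikes(fx$session, fx$dv, specs, seed = 19, spikeTimes = TRUE)
  sw <- slidingWindowRegression(ec, "eq11", range = c(-500, 1500))
  lat <- codingLatency(sw, c("LastRewardChoice", "ObjectRiskA"))
  mh <- median(lat$latency[1:6, "LastRewardChoice"], na.rm = TRUE)
  mr <- median(lat$latency[7:12, "ObjectRiskA"], na.rm = TRUE)
  expect_lt(mh, mr)
})
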