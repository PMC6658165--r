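## Single-response regression battery on synthetic populations with known
## ground truth.

regFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- fittedSession(nTrials = 500, seed = 51)
    cfg <- list(
      list(n = 3, label = "riskA", variables = "ObjectRiskA", gain = 8,
           epochs = "Cue", evoked = 8, randomSign = FALSE),
      list(n = 3, label = "choice", variables = "ObjectChoice", gain = 8,
           epochs = "Cue", evoked = 8, randomSign = FALSE),
      list(n = 4, label = "untuned", variables = NULL, evoked = 8,
           epochs = "Cue"))
    specs <- makePopulation(cfg, seed = 52)
    ec <- simulateSpikes(fx$session, fx$dv, specs, seed = 53)
    cache <<- list(fx = fx, ec = ec,
                   dv = as.data.frame(colData(ec)))
    cache
  }
})

test_that("task-relatedness screening separates evoked from flat responses", {
  f <- regFixture()
  rel <- taskRelatedness(f$ec)
  ## all neurons have an evoked Cue response
  expect_true(all(rel$related[, "Cue"]))
  ## control epoch always admitted
  expect_true(all(rel$related[, "PreFix"]))
  ## flat epochs (no evoked bump) are mostly not flagged
  expect_lt(mean(rel$related[, "Outc2"]), 0.3)
  ## identical rates: a constant neuron is nowhere task-related
  ecFlat <- simulateSpikes(f$fx$session, f$fx$dv,
                           list(neuronSpec(1, 12)), seed = 54)
  relFlat <- taskRelatedness(ecFlat)
  expect_false(any(relFlat$related[1, setdiff(colnames(relFlat$related),
                                              "PreFix")]))
})

test_that("response regression recovers the tuned variable specifically", {
  f <- regFixture()
  y <- assay(f$ec, "Cue")[1, ]  # riskA neuron, positive gain
  fit <- fitResponseRegression(y, f$dv, "eq10")
  co <- fit$coef
  expect_true(fit$codesRisk)
  expect_lt(co$p[co$term == "ObjectRiskA"], 0.001)
  expect_gt(co$beta[co$term == "ObjectRiskA"], 0)
  ## standardized-beta identity b * s_x / s_y on every coefficient
  rt <- regressorTable(f$dv, "eq10")
  yy <- y[rt$rows] / 0.5
  for (tm in colnames(rt$X)) {
    expect_equal(co$stdBeta[co$term == tm],
                 co$beta[co$term == tm] * sd(rt$X[, tm]) / sd(yy),
                 tolerance = 1e-12)
  }
  ## partial R^2 equals its definitional ratio for one regressor
  Xfull <- cbind(1, rt$X)
  sseF <- sum(lm.fit(Xfull, yy)$residuals^2)
  Xr <- Xfull[, colnames(Xfull) != "ObjectRiskA"]
  sseR <- sum(lm.fit(Xr, yy)$residuals^2)
  expect_equal(co$partialR2[co$term == "ObjectRiskA"],
               (sseR - sseF) / sseR, tolerance = 1e-10)
})

test_that("angle classification follows the documented segment rule", {
  expect_equal(classifyAngle(1, 0)$category, "riskA")
  expect_equal(classifyAngle(1, 0)$angle, 0)
  expect_equal(classifyAngle(-1, 0)$category, "riskA")
  expect_equal(classifyAngle(0, 1)$category, "riskB")
  expect_equal(classifyAngle(1, 1)$category, "riskSum")
  expect_equal(classifyAngle(1, 1)$angle, 45)
  expect_equal(classifyAngle(-1, -1)$category, "riskSum")
  expect_equal(classifyAngle(1, -1)$category, "riskDifference")
  expect_equal(classifyAngle(1, -1)$angle, 315)
  expect_equal(classifyAngle(-1, 1)$category, "riskDifference")
  ## boundary 22.5 degrees belongs to the 45-degree segment (half-open rule)
  b <- tan(22.5 * pi / 180)
  expect_equal(classifyAngle(1, b)$category, "riskSum")
  ## zero vector unclassifiable
  expect_equal(classifyAngle(0, 0)$category, "unclassifiable")
})

test_that("angle classification flags tuned responses and skips untuned", {
  f <- regFixture()
  dv <- f$dv
  acTuned <- angleClassification(assay(f$ec, "Cue")[1, ] / 0.5,
                                 dv$ObjectRiskA, dv$ObjectRiskB)
  expect_true(acTuned$significant)
  expect_equal(acTuned$category, "riskA")
  acFlat <- angleClassification(rnorm(nrow(dv), 10), dv$ObjectRiskA,
                                dv$ObjectRiskB, alpha = 1e-6)
  expect_equal(acFlat$category, "none")
})

test_that("stepwise regression retains the driving variable and drops noise", {
  f <- regFixture()
  swTuned <- stepwiseRegression(assay(f$ec, "Cue")[1, ], f$dv, "eq13")
  expect_true("ObjectRiskA" %in% swTuned$retained)
  swFlat <- stepwiseRegression(assay(f$ec, "Cue")[7, ], f$dv, "eq13")
  expect_lte(length(swFlat$retained), 2)
})

test_that("partial F test detects choice dependence only where designed", {
  f <- regFixture()
  pfChoice <- partialFTest(assay(f$ec, "Cue")[4, ], f$dv, "eq10",
                           "ObjectChoice")
  expect_lt(pfChoice$p, 0.01)
  pfRisk <- partialFTest(assay(f$ec, "Cue")[1, ], f$dv, "eq10",
                         "ObjectChoice")
  expect_gt(pfRisk$p, 0.001)
  expect_gte(pfRisk$F, 0)
})

test_that("dependent-proportions z test behaves at the extremes", {
  x <- c(rep(TRUE, 30), rep(FALSE, 10))
  expect_equal(zTestDependentProportions(x, x)$p, 1)
  y <- rep(FALSE, 40)
  r <- zTestDependentProportions(x, y)
  expect_lt(r$p, 1e-6)
  expect_gt(r$z, 0)
})

test_that("non-stationarity controls curb drift-driven false positives", {
  fx <- fittedSession(nTrials = 500, seed = 55)
  drifting <- list(
    list(n = 12, label = "drift", variables = NULL, evoked = 6,
         epochs = "Cue", driftPhi = 0.98, driftSd = 0.25))
  ec <- simulateSpikes(fx$session, fx$dv, makePopulation(drifting, seed = 56),
                       seed = 57)
  ns <- nonstationarityControls(ec, "eq10", "Cue")
  expect_lte(mean(ns$codesRiskAR), mean(ns$codesRiskPlain))
  ## genuinely tuned neurons survive the AR control
  tuned <- list(list(n = 8, label = "riskA", variables = "ObjectRiskA",
                     gain = 8, epochs = "Cue", evoked = 6))
  ecT <- simulateSpikes(fx$session, fx$dv, makePopulation(tuned, seed = 58),
                        seed = 59)
  nsT <- nonstationarityControls(ecT, "eq10", "Cue")
  expect_gte(mean(nsT$codesRiskAR), 0.8)
  expect_gte(mean(nsT$codesRiskCtrl), 0.8)
  ## without drift the plain and AR pathways agree
  flat <- simulateSpikes(fx$session, fx$dv,
                         makePopulation(list(list(n = 6, variables = NULL,
                                                  evoked = 6, epochs = "Cue")),
                                        seed = 60), seed = 61)
  nsF <- nonstationarityControls(flat, "eq10", "Cue")
  expect_equal(nsF$codesRiskPlain, nsF$codesRiskAR, tolerance = 0.5)
})

test_that("population curves are single-peaked for risk and monotone for value", {
  fx <- fittedSession(nTrials = 1500, seed = 62)
  cfg <- list(
    list(n = 10, label = "risk", variables = "ObjectRiskA", gain = 8,
         epochs = "Cue", evoked = 6),
    list(n = 10, label = "value", variables = "ObjectValueA", gain = 8,
         epochs = "Cue", evoked = 6))
  ec <- simulateSpikes(fx$session, fx$dv, makePopulation(cfg, seed = 63),
                       seed = 64)
  ## risk-neuron activity over reward probability: non-monotone,
  ## single-peaked, with the peak strictly inside the range
  prob <- colData(ec)$TrueProbA
  pcR <- populationValueCurve(ec, prob, neurons = 1:10, epoch = "Cue",
                              signVar = "ObjectRiskA")
  peak <- which.max(pcR$activity)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(pcR))
  expect_gt(max(pcR$activity) - min(pcR$activity), 0.2)
  ## value neurons, sign-corrected on value: increasing over value bins
  val <- colData(ec)$ObjectValueA
  pcV <- populationValueCurve(ec, val, neurons = 11:20, epoch = "Cue",
                              signVar = "ObjectValueA")
  expect_gt(cor(pcV$bin, pcV$activity, method = "spearman"), 0.5)
  ## untuned population: flat near zero
  flat <- simulateSpikes(fx$session, fx$dv,
                         makePopulation(list(list(n = 6, variables = NULL)),
                                        seed = 65), seed = 66)
  pcF <- populationValueCurve(flat, prob, epoch = "Cue",
                              signVar = "TrueProbA",
                              signs = rep(1, 6))
  expect_lt(max(abs(pcF$activity)), 0.2)
})
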