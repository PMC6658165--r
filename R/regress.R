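## Single-neuron analysis battery: epoch counting, task-relatedness
## screening, the multiple-regression models over decision variables,
## angle classification, stepwise and partial-F tests, non-stationarity
## controls, and population summaries.

.modelTerms <- list(
  eq3 = c("ObjectChoice", "CuePosition", "Action", "TrueProbA", "TrueProbB",
          "TrueRiskA", "TrueRiskB"),
  eq10 = c("ObjectChoice", "CuePosition", "Action", "ObjectValueA",
           "ObjectValueB", "ObjectRiskA", "ObjectRiskB"),
  eq11 = c("ObjectChoice", "CuePosition", "Action", "ObjectValueA",
           "ObjectValueB", "ObjectRiskA", "ObjectRiskB", "LastReward",
           "LastChoice", "LastRewardChoice"),
  eq12 = c("ObjectChoice", "CuePosition", "Action", "ObjectValueA",
           "ObjectValueB", "ObjectRiskA", "ObjectRiskB", "LastReward",
           "LastChoice", "LastRewardChoice", "LastReward2", "LastChoice2",
           "LastRewardChoice2"),
  eq13 = c("ObjectChoice", "CuePosition", "Action", "ObjectValueA",
           "ObjectValueB", "ObjectRiskA", "ObjectRiskB", "TrueProbA",
           "TrueProbB", "TrueRiskA", "TrueRiskB"),
  eq14 = c("ObjectChoice", "CuePosition", "Action", "ActionValueL",
           "ActionValueR", "ActionRiskL", "ActionRiskR"),
  eq15 = c("ObjectChoice", "CuePosition", "Action", "ObjectValueA",
           "ObjectValueB", "ObjectRiskA", "ObjectRiskB", "ActionValueL",
           "ActionValueR", "ActionRiskL", "ActionRiskR"),
  utility = c("ObjectChoice", "CuePosition", "Action", "UtilityA", "UtilityB",
              "ObjectRiskA", "ObjectRiskB"))

.riskTerms <- list(
  eq3 = c("TrueRiskA", "TrueRiskB"), eq10 = c("ObjectRiskA", "ObjectRiskB"),
  eq11 = c("ObjectRiskA", "ObjectRiskB"), eq12 = c("ObjectRiskA", "ObjectRiskB"),
  eq13 = c("ObjectRiskA", "ObjectRiskB"), eq14 = c("ActionRiskL", "ActionRiskR"),
  eq15 = c("ObjectRiskA", "ObjectRiskB", "ActionRiskL", "ActionRiskR"),
  utility = c("ObjectRiskA", "ObjectRiskB"))

#' Regressor matrix for a neuronal response model
#'
#' Assembles the design matrix (without intercept) for one of the response
#' models: `eq3` (objective probability/risk), `eq10` (subjective
#' value/risk), `eq11` (+ last-trial history), `eq12` (+ two-back history),
#' `eq13` (subjective vs objective competition set), `eq14` (action
#' value/risk), `eq15` (object vs action competition set), `utility`
#' (utility regressors substituting value).
#'
#' @param dv decision-variable table (or `colData` of an
#'   [EpochCounts-class] coerced to data.frame)
#' @param model model id
#' @return list `X` (matrix), `rows` (row indices of `dv` used: complete
#'   cases only), `terms`, `riskTerms`
#' @export
regressorTable <- function(dv, model = "eq10") {
  if (!model %in% names(.modelTerms)) stop("unknown model: ", model)
  terms <- .modelTerms[[model]]
  miss <- setdiff(terms, names(dv))
  if (length(miss))
    stop("decision-variable table lacks columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(dv)[, terms, drop = FALSE])
  rows <- which(complete.cases(X))
  list(X = X[rows, , drop = FALSE], rows = rows, terms = terms,
       riskTerms = .riskTerms[[model]])
}

## OLS with per-coefficient t tests, standardized slopes (b * s_x / s_y),
## per-regressor partial R^2 and overall F.
olsStats <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  n <- nrow(Xi); p <- ncol(Xi)
  qrx <- qr(Xi)
  if (qrx$rank < p) {
    aliased <- colnames(Xi)[qrx$pivot[seq(qrx$rank + 1L, p)]]
  } else aliased <- character(0)
  beta <- qr.coef(qrx, y)
  res <- y - drop(Xi[, !colnames(Xi) %in% aliased, drop = FALSE] %*%
                    beta[!names(beta) %in% aliased])
  df <- n - qrx$rank
  sse <- sum(res^2)
  sigma2 <- sse / df
  XtXi <- tryCatch(chol2inv(qr.R(qrx)[seq_len(qrx$rank), seq_len(qrx$rank)]),
                   error = function(e) NULL)
  se <- rep(NA_real_, p); names(se) <- colnames(Xi)
  if (!is.null(XtXi))
    se[qrx$pivot[seq_len(qrx$rank)]] <- sqrt(pmax(diag(XtXi), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  sy <- sd(y)
  stdBeta <- beta
  stdBeta[1] <- NA
  for (j in seq(2L, p))
    stdBeta[j] <- beta[j] * sd(Xi[, j]) / sy
  ## partial R^2: (SSE_reduced - SSE_full) / SSE_reduced
  pr2 <- rep(NA_real_, p); names(pr2) <- colnames(Xi)
  for (j in seq(2L, p)) {
    if (colnames(Xi)[j] %in% aliased) next
    sseR <- sum(qr.resid(qr(Xi[, -j, drop = FALSE]), y)^2)
    pr2[j] <- if (sseR > 0) (sseR - sse) / sseR else NA_real_
  }
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  kEff <- qrx$rank - 1L
  Fstat <- if (kEff > 0 && sse > 0 && df > 0)
    ((sst - sse) / kEff) / (sse / df) else NA_real_
  Fp <- if (is.na(Fstat)) NA_real_ else pf(Fstat, kEff, df, lower.tail = FALSE)
  list(coef = data.frame(term = colnames(Xi), beta = unname(beta),
                         se = unname(se), t = unname(tval), p = unname(pval),
                         stdBeta = unname(stdBeta), partialR2 = unname(pr2),
                         row.names = NULL),
       sse = sse, df = df, r2 = r2, overallF = Fstat, overallP = Fp,
       n = n, aliased = aliased)
}

#' Count spikes in the 11 task epochs
#'
#' Bins event-aligned spike times into the canonical 500-ms epochs of
#' [epochTable()]. Trials missing an alignment event are dropped with a
#' message.
#'
#' @param spikes list of per-trial spike-time vectors (trial-relative ms)
#' @param eventTimes data.frame of per-trial event times (columns named as in
#'   [epochTable()]'s `event`)
#' @param epochs epoch table
#' @return trials x epochs integer matrix (NA rows for dropped trials)
#' @export
countEpochs <- function(spikes, eventTimes, epochs = epochTable()) {
  nT <- length(spikes)
  out <- matrix(NA_integer_, nT, nrow(epochs),
                dimnames = list(NULL, epochs$epoch))
  dropped <- 0L
  for (i in seq_len(nT)) {
    ev <- eventTimes[i, epochs$event]
    if (any(is.na(ev))) { dropped <- dropped + 1L; next }
    t0 <- as.numeric(ev) + epochs$offset
    t1 <- t0 + epochs$duration
    s <- spikes[[i]]
    out[i, ] <- vapply(seq_along(t0),
                       function(k) sum(s >= t0[k] & s < t1[k]), integer(1))
  }
  if (dropped) message(dropped, " trial(s) dropped for missing events")
  out
}

#' Task-relatedness screening against the pre-fixation control period
#'
#' Paired two-sided Wilcoxon signed-rank test of each epoch's counts against
#' the pre-fixation control counts of the same trials, per neuron, with
#' Bonferroni correction over the 10 non-control epochs (criterion
#' `p < alpha` after correction). The control period itself is always
#' admitted. Zero-variance differences count as non-significant.
#'
#' @param ec an [EpochCounts-class]
#' @param alpha significance threshold before Bonferroni division
#'   (default 0.005)
#' @param control control epoch name (default `"PreFix"`)
#' @return list: `related` (neurons x epochs logical), `p` (raw p-values),
#'   `taskRelatedNeuron` (any epoch related)
#' @export
taskRelatedness <- function(ec, alpha = 0.005, control = "PreFix") {
  eps <- epochNames(ec)
  stopifnot(control %in% eps)
  test <- setdiff(eps, control)
  nN <- nrow(ec)
  p <- matrix(NA_real_, nN, length(eps), dimnames = list(NULL, eps))
  ctrl <- assay(ec, control)
  for (e in test) {
    m <- assay(ec, e)
    for (j in seq_len(nN)) {
      d <- m[j, ] - ctrl[j, ]
      p[j, e] <- if (all(d == 0)) 1 else
        suppressWarnings(wilcox.test(m[j, ], ctrl[j, ], paired = TRUE)$p.value)
    }
  }
  related <- p < alpha / length(test)
  related[, control] <- TRUE
  list(related = related, p = p,
       taskRelatedNeuron = rowSums(related[, test, drop = FALSE],
                                   na.rm = TRUE) > 0)
}

#' Fit a neuronal response regression
#'
#' Ordinary least-squares fit of the trial-by-trial impulse rate of one
#' response (neuron x epoch) on the regressors of the requested model, with
#' two-sided t tests per coefficient, standardized slopes, per-regressor
#' partial R^2 and the overall F test. A response is classified as coding
#' (object or action) risk if at least one risk regressor is significant at
#' `alpha`.
#'
#' @param y numeric response: per-trial counts or rates
#' @param dv decision-variable table aligned to the trials of `y`
#' @param model model id (see [regressorTable()])
#' @param alpha per-coefficient significance level (default 0.05)
#' @param rate divide counts by the 0.5-s epoch duration (default TRUE)
#' @return list: `coef` table, `overallF`, `overallP`, `r2`, `n`,
#'   `codesRisk`, `significantRiskTerms`, `model`
#' @export
fitResponseRegression <- function(y, dv, model = "eq10", alpha = 0.05,
                                  rate = TRUE) {
  rt <- regressorTable(dv, model)
  yy <- y[rt$rows]
  if (rate) yy <- yy / 0.5
  st <- olsStats(rt$X, yy)
  if (length(st$aliased))
    warning("rank-deficient design; aliased: ",
            paste(st$aliased, collapse = ", "))
  rk <- st$coef[st$coef$term %in% rt$riskTerms, ]
  sig <- rk$term[!is.na(rk$p) & rk$p < alpha]
  st$codesRisk <- length(sig) > 0
  st$significantRiskTerms <- sig
  st$model <- model
  st$terms <- rt$terms
  st
}

#' Run a response model over all task-related responses of a population
#'
#' @param ec an [EpochCounts-class]
#' @param model model id
#' @param alpha per-coefficient significance level
#' @param onlyTaskRelated restrict to responses passing [taskRelatedness()]
#' @return data.frame, one row per (neuron, epoch, term), plus columns
#'   `overallP`, `codesRisk`
#' @export
analyzeResponses <- function(ec, model = "eq10", alpha = 0.05,
                             onlyTaskRelated = TRUE) {
  dv <- as.data.frame(colData(ec))
  rel <- if (onlyTaskRelated) taskRelatedness(ec)$related
         else matrix(TRUE, nrow(ec), length(epochNames(ec)),
                     dimnames = list(NULL, epochNames(ec)))
  out <- list()
  for (e in epochNames(ec)) {
    m <- assay(ec, e)
    for (j in which(rel[, e])) {
      f <- fitResponseRegression(m[j, ], dv, model, alpha)
      co <- f$coef
      co$neuron <- j; co$epoch <- e
      co$overallP <- f$overallP; co$codesRisk <- f$codesRisk
      out[[length(out) + 1L]] <- co
    }
  }
  do.call(rbind, out)
}

#' Classify a coefficient pair by polar angle
#'
#' Divides the (beta1, beta2) plane into eight 45-degree segments centred on
#' 0, 45, ..., 315 degrees (half-open: \[centre - 22.5, centre + 22.5)).
#' Segments toward 0/180 code the first option's risk, 90/270 the second
#' option's, 45/225 the risk sum, 135/315 the risk difference.
#'
#' @param b1,b2 coefficients of the two risk regressors
#' @param labels category labels for (first, sum, second, difference)
#' @return list `angle` (degrees in \[0, 360)) and `category`
#' @export
classifyAngle <- function(b1, b2,
                          labels = c("riskA", "riskSum", "riskB", "riskDifference")) {
  if (b1 == 0 && b2 == 0)
    return(list(angle = NA_real_, category = "unclassifiable"))
  ang <- (atan2(b2, b1) * 180 / pi) %% 360
  seg <- floor((ang + 22.5) / 45) %% 8
  list(angle = ang, category = labels[seg %% 4 + 1])
}

#' Angle-based classification of a risk response
#'
#' Fits the reduced two-regressor model `y ~ b0 + b1 risk1 + b2 risk2` and,
#' when the overall fit is significant (F test, `p < alpha`), classifies the
#' response by the polar angle of the two coefficients (see
#' [classifyAngle()]). This classification is axis-invariant: it does not
#' depend on whether the model is parameterized in per-option risks or in
#' risk sum and difference.
#'
#' @param y response (counts or rates)
#' @param risk1,risk2 the two risk regressors (e.g. object A and B risk)
#' @param alpha overall-fit significance level (default 0.05)
#' @param labels category labels, see [classifyAngle()]
#' @return list: `significant`, `overallP`, `b1`, `b2`, `angle`, `category`
#' @export
angleClassification <- function(y, risk1, risk2, alpha = 0.05,
                                labels = c("riskA", "riskSum", "riskB",
                                           "riskDifference")) {
  ok <- complete.cases(risk1, risk2, y)
  st <- olsStats(cbind(risk1 = risk1[ok], risk2 = risk2[ok]), y[ok])
  b1 <- st$coef$beta[2]; b2 <- st$coef$beta[3]
  sig <- !is.na(st$overallP) && st$overallP < alpha
  cl <- if (sig) classifyAngle(b1, b2, labels)
        else list(angle = NA_real_, category = "none")
  list(significant = sig, overallP = st$overallP, b1 = b1, b2 = b2,
       angle = cl$angle, category = cl$category)
}

#' Stepwise response regression
#'
#' Forward-entry (p <= `entryP`) / backward-removal (p >= `removeP`) stepwise
#' OLS starting from the intercept-only model, over the starting set of the
#' requested model (`eq13`: subjective vs objective object risk; `eq15`:
#' object vs action risk). Used to let correlated variables compete directly
#' for response variance.
#'
#' @param y response
#' @param dv decision-variable table
#' @param model starting-set id (default `"eq13"`)
#' @param entryP,removeP entry and removal thresholds (0.05 / 0.10)
#' @param rate divide counts by epoch duration
#' @return list: `retained` (character), `fit` (final [olsStats] output or
#'   NULL if empty), `model`
#' @export
stepwiseRegression <- function(y, dv, model = "eq13", entryP = 0.05,
                               removeP = 0.10, rate = TRUE) {
  rt <- regressorTable(dv, model)
  yy <- y[rt$rows]
  if (rate) yy <- yy / 0.5
  X <- rt$X
  current <- character(0)
  candidates <- colnames(X)
  repeat {
    changed <- FALSE
    ## forward step
    avail <- setdiff(candidates, current)
    if (length(avail)) {
      pvals <- vapply(avail, function(v) {
        st <- olsStats(X[, c(current, v), drop = FALSE], yy)
        st$coef$p[st$coef$term == v]
      }, numeric(1))
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) <= entryP) {
        current <- c(current, avail[which.min(pvals)])
        changed <- TRUE
      }
    }
    ## backward step
    if (length(current)) {
      st <- olsStats(X[, current, drop = FALSE], yy)
      pv <- setNames(st$coef$p[-1], st$coef$term[-1])
      worst <- names(which.max(pv))
      if (length(worst) && !is.na(pv[worst]) && pv[worst] >= removeP) {
        current <- setdiff(current, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- if (length(current)) olsStats(X[, current, drop = FALSE], yy) else NULL
  list(retained = current, fit = fit, model = model)
}

#' Partial F test for an added regressor
#'
#' Tests whether adding `term` (by default the object-choice regressor) to
#' the reduced model significantly improves the fit:
#' `F = (SSE_r - SSE_f) / (SSE_f / df_f)`.
#'
#' @param y response
#' @param dv decision-variable table
#' @param model full-model id containing `term`
#' @param term regressor to test (default `"ObjectChoice"`)
#' @param rate divide counts by epoch duration
#' @return list: `F`, `p`, `df1`, `df2`
#' @export
partialFTest <- function(y, dv, model = "eq10", term = "ObjectChoice",
                         rate = TRUE) {
  rt <- regressorTable(dv, model)
  stopifnot(term %in% colnames(rt$X))
  yy <- y[rt$rows]
  if (rate) yy <- yy / 0.5
  full <- olsStats(rt$X, yy)
  red <- olsStats(rt$X[, setdiff(colnames(rt$X), term), drop = FALSE], yy)
  Fv <- if (full$sse > 0) (red$sse - full$sse) / (full$sse / full$df) else 0
  Fv <- max(Fv, 0)
  list(F = Fv, p = pf(Fv, 1, full$df, lower.tail = FALSE),
       df1 = 1, df2 = full$df)
}

#' z test for dependent proportions
#'
#' McNemar-style normal approximation for comparing two proportions measured
#' on the same units (e.g. the fraction of responses coding risk with vs
#' without choice dependence): `z = (n10 - n01) / sqrt(n10 + n01)` where
#' `n10`/`n01` count discordant units.
#'
#' @param x,y logical vectors over the same units
#' @return list `z`, `p` (two-sided)
#' @export
zTestDependentProportions <- function(x, y) {
  n10 <- sum(x & !y); n01 <- sum(!x & y)
  if (n10 + n01 == 0) return(list(z = 0, p = 1))
  z <- (n10 - n01) / sqrt(n10 + n01)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Non-stationarity controls for a response model
#'
#' Two robustness variants of a response regression against slow activity
#' fluctuations: (i) adding a first-order autoregressive term (the
#' previous-trial rate in the same epoch; the first trial is dropped), and
#' (ii) subtracting the same-trial control-period rate from the response
#' before the regression (the control epoch itself is excluded from this
#' pathway).
#'
#' @param ec an [EpochCounts-class]
#' @param model model id (default `"eq10"`)
#' @param epoch epoch to analyse
#' @param alpha per-coefficient significance level
#' @param control control epoch name
#' @return data.frame per neuron: `codesRiskPlain`, `codesRiskAR`,
#'   `codesRiskCtrl` (NA for the control epoch itself)
#' @export
nonstationarityControls <- function(ec, model = "eq10", epoch = "Cue",
                                    alpha = 0.05, control = "PreFix") {
  dv <- as.data.frame(colData(ec))
  m <- assay(ec, epoch) / 0.5
  ctrl <- assay(ec, control) / 0.5
  nN <- nrow(ec)
  out <- data.frame(neuron = seq_len(nN), codesRiskPlain = NA,
                    codesRiskAR = NA, codesRiskCtrl = NA)
  rt <- regressorTable(dv, model)
  for (j in seq_len(nN)) {
    y <- m[j, ]
    out$codesRiskPlain[j] <-
      fitResponseRegression(y, dv, model, alpha, rate = FALSE)$codesRisk
    ## AR variant: previous-trial rate, same epoch
    ar <- c(NA, y[-length(y)])
    rows <- rt$rows[!is.na(ar[rt$rows])]
    Xa <- cbind(rt$X[match(rows, rt$rows), , drop = FALSE], ARterm = ar[rows])
    sta <- olsStats(Xa, y[rows])
    rk <- sta$coef[sta$coef$term %in% rt$riskTerms, ]
    out$codesRiskAR[j] <- any(!is.na(rk$p) & rk$p < alpha)
    ## control-subtraction variant
    if (epoch != control) {
      yc <- y - ctrl[j, ]
      out$codesRiskCtrl[j] <-
        fitResponseRegression(yc, dv, model, alpha, rate = FALSE)$codesRisk
    }
  }
  out
}

#' Population activity as a function of value bins
#'
#' z-scores each neuron's epoch rate against its control-period mean and SD,
#' sign-corrects neurons with a negative relationship to the reference
#' variable, and averages within equal-population value bins. Risk-tuned
#' populations produce the characteristic single-peaked (inverted-U) curve
#' over value; value-tuned populations a monotone one.
#'
#' @param ec an [EpochCounts-class]
#' @param value per-trial value covariate
#' @param neurons neuron indices to include
#' @param epoch epoch to analyse (default `"Cue"`)
#' @param nBins number of equal-population bins (default 7)
#' @param signs per-neuron sign corrections (+1/-1); default derived from
#'   each neuron's regression slope on the neuron's reference variable
#'   `signVar` in `colData`
#' @param signVar variable whose slope sign is used when `signs` is NULL
#' @param control control epoch
#' @return data.frame per bin: `bin`, `valueMid`, `activity`, `se`, `n`;
#'   empty bins flagged by `n = 0`
#' @export
populationValueCurve <- function(ec, value, neurons = seq_len(nrow(ec)),
                                 epoch = "Cue", nBins = 7L, signs = NULL,
                                 signVar = NULL, control = "PreFix") {
  m <- assay(ec, epoch); ctrl <- assay(ec, control)
  ok <- !is.na(value)
  z <- matrix(NA_real_, length(neurons), ncol(m))
  for (k in seq_along(neurons)) {
    j <- neurons[k]
    mu <- mean(ctrl[j, ]); sdv <- sd(ctrl[j, ])
    if (sdv == 0) sdv <- 1
    z[k, ] <- (m[j, ] - mu) / sdv
  }
  if (is.null(signs)) {
    sv <- if (is.null(signVar)) value else colData(ec)[[signVar]]
    signs <- vapply(seq_along(neurons), function(k) {
      b <- coef(lm(z[k, ok] ~ sv[ok]))[2]
      if (is.na(b) || b >= 0) 1 else -1
    }, numeric(1))
  }
  z <- z * signs
  v <- value[ok]
  ## equal-population bins via ranks (stable under heavy ties)
  bin <- cut(rank(v, ties.method = "first"), nBins, labels = FALSE)
  zz <- z[, ok, drop = FALSE]
  do.call(rbind, lapply(seq_len(max(bin)), function(b) {
    i <- which(bin == b)
    vals <- as.vector(zz[, i])
    data.frame(bin = b, valueMid = if (length(i)) median(v[i]) else NA,
               activity = if (length(i)) mean(vals) else NA_real_,
               se = if (length(i) > 1) sd(vals) / sqrt(length(vals)) else NA,
               n = length(i))
  }))
}

#' Risk-updating contrast: trial N vs N-1 around rewarded trials
#'
#' Splits trials by whether the reward on trial N-1 increased or decreased
#' the risk estimate on trial N, then compares the population's cue-period
#' activity on N against N-1 within each split (paired Wilcoxon across
#' neurons on z-scored, sign-corrected activity). Risk-tracking populations
#' show higher activity on N when risk rose and lower when it fell.
#'
#' @param ec an [EpochCounts-class]
#' @param riskVar name of the per-trial risk column in `colData` (default
#'   `"ObjectRiskA"`)
#' @param neurons neuron indices (e.g. significant risk neurons)
#' @param epoch epoch to analyse (default `"Cue"`)
#' @param signs per-neuron sign corrections; default from the slope of
#'   activity on `riskVar`
#' @param control control epoch for z-scoring
#' @param minTrials minimum trials per split (flagged if fewer)
#' @return list with elements `up` and `down`, each holding `meanN`,
#'   `meanN1`, `p` (paired Wilcoxon), `nTrials`, `ok`
#' @export
riskUpdatingAnalysis <- function(ec, riskVar = "ObjectRiskA",
                                 neurons = seq_len(nrow(ec)), epoch = "Cue",
                                 signs = NULL, control = "PreFix",
                                 minTrials = 5L) {
  dv <- as.data.frame(colData(ec))
  risk <- dv[[riskVar]]
  rew <- dv$reward
  if (is.null(rew)) stop("colData must carry a 'reward' column")
  T <- length(risk)
  Nidx <- which(seq_len(T) > 1 & c(NA, rew[-T]) == 1 &
                  !is.na(risk) & !is.na(c(NA, risk[-T])))
  dRisk <- risk[Nidx] - risk[Nidx - 1L]
  m <- assay(ec, epoch); ctrl <- assay(ec, control)
  z <- t(vapply(neurons, function(j) {
    sdv <- sd(ctrl[j, ]); if (sdv == 0) sdv <- 1
    (m[j, ] - mean(ctrl[j, ])) / sdv
  }, numeric(ncol(m))))
  if (is.null(signs)) {
    ok <- !is.na(risk)
    signs <- vapply(seq_along(neurons), function(k) {
      b <- coef(lm(z[k, ok] ~ risk[ok]))[2]
      if (is.na(b) || b >= 0) 1 else -1
    }, numeric(1))
  }
  z <- z * signs
  splitStats <- function(sel) {
    idx <- Nidx[sel]
    if (length(idx) < minTrials)
      return(list(meanN = NA, meanN1 = NA, p = NA, nTrials = length(idx),
                  ok = FALSE))
    aN <- rowMeans(z[, idx, drop = FALSE])
    aN1 <- rowMeans(z[, idx - 1L, drop = FALSE])
    list(meanN = mean(aN), meanN1 = mean(aN1),
         p = suppressWarnings(wilcox.test(aN, aN1, paired = TRUE)$p.value),
         nTrials = length(idx), ok = TRUE)
  }
  list(up = splitStats(dRisk > 0), down = splitStats(dRisk < 0),
       nNeurons = length(neurons))
}
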