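## Choice models: the value/risk logistic model, reinforcement-learning
## variants, the 11-model comparison, matching summaries, psychometrics.

## Logistic fit returning coefficients, SEs, p, log-likelihood.
logisticFit <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- fit$coefficients
  R <- qr.R(fit$qr)
  se <- sqrt(diag(chol2inv(R)))
  names(se) <- names(beta)
  p <- 2 * pnorm(-abs(beta / se))
  mu <- fit$fitted.values
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coef = beta, se = se, p = p, logLik = ll, k = ncol(X), n = length(y))
}

## map per-object columns to a left-minus-right difference via cue position
lrDelta <- function(dv, colA, colB) {
  ifelse(dv$CuePosition == 0, dv[[colA]] - dv[[colB]],
         dv[[colB]] - dv[[colA]])
}

#' Fit the value/risk choice model
#'
#' Logistic regression of the side choice (left vs right) on the left-right
#' object-value difference and object-risk difference plus an intercept
#' (side bias). A positive fitted risk coefficient indicates risk seeking.
#' Optionally restricts to the subset of trials with minimal absolute value
#' difference (lowest decile by default), the control in which any risk
#' influence cannot be a value artifact.
#'
#' @param dv decision-variable table from [decisionVariables()]
#' @param session a [Session-class]
#' @param trialSubset optional integer subset of trial indices to fit on
#' @param subset `"all"` (default) or `"minValue"`
#' @param minValueFrac fraction of trials in the minimal-value subset (0.1)
#' @return list with `coef` (`bias`, `dValue`, `dRisk`), `se`, `p`,
#'   `logLik`, `aic`, `bic`, `n`, and `sharedR2` (squared correlation between
#'   the value and risk regressors, a collinearity diagnostic)
#' @export
fitChoiceModel <- function(dv, session, trialSubset = NULL,
                           subset = c("all", "minValue"), minValueFrac = 0.1) {
  subset <- match.arg(subset)
  tr <- trials(session)
  ok <- complete.cases(dv[, c("dValueLR", "dRiskLR")])
  if (!is.null(trialSubset)) ok <- ok & dv$trial %in% trialSubset
  if (subset == "minValue") {
    thr <- quantile(abs(dv$dValueLR[ok]), minValueFrac, na.rm = TRUE)
    ok <- ok & abs(dv$dValueLR) <= thr
  }
  y <- as.numeric(tr$action == "L")[ok]
  X <- cbind(bias = 1, dValue = dv$dValueLR[ok], dRisk = dv$dRiskLR[ok])
  f <- logisticFit(X, y)
  f$aic <- -2 * f$logLik + 2 * f$k
  f$bic <- -2 * f$logLik + f$k * log(f$n)
  f$sharedR2 <- cor(X[, "dValue"], X[, "dRisk"])^2
  f$modelId <- "value_risk"
  f
}

.rlVariantCode <- c(standard = 0L, stack = 1L, reversal = 2L)

#' Fit a reinforcement-learning choice model
#'
#' Maximum-likelihood fit of a Rescorla-Wagner learner with softmax choice
#' over the two objects. Variants: `"standard"` updates the chosen option
#' only; `"stack"` adds a parameter letting the unchosen option's value
#' accumulate toward the reward ceiling (capturing baited-reward persistence);
#' `"reversal"` updates the unchosen option toward the opposite outcome.
#' Optimization uses box-constrained BFGS from a deterministic multi-start
#' grid; non-convergence of a start is tolerated and reported.
#'
#' @param session a [Session-class]
#' @param variant `"standard"`, `"stack"` or `"reversal"`
#' @param trialSubset optional trial indices entering the likelihood (value
#'   updates always run over the whole session)
#' @return list with `variant`, `alpha`, `tau`, `stack` (NA unless stack
#'   variant), `se`, `logLik`, `aic`, `bic`, `k`, `n`, `converged`
#' @export
fitRLModel <- function(session, variant = c("standard", "stack", "reversal"),
                       trialSubset = NULL) {
  variant <- match.arg(variant)
  tr <- trials(session)
  choiceB <- as.integer(tr$choice == "B")
  reward <- as.integer(tr$reward)
  mask <- if (is.null(trialSubset)) rep(TRUE, nrow(tr))
          else tr$trial %in% trialSubset
  vcode <- .rlVariantCode[[variant]]
  k <- if (variant == "stack") 3L else 2L
  lower <- c(1e-4, 0.01, 1e-4)[seq_len(k)]
  upper <- c(1, 100, 1)[seq_len(k)]
  starts <- expand.grid(alpha = c(0.1, 0.4, 0.8), tau = c(1, 5, 20))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(starts$alpha[s], starts$tau[s], 0.1)[seq_len(k)]
    o <- tryCatch(
      optim(par0, rlNegLogLik, method = "L-BFGS-B", lower = lower,
            upper = upper, choiceB = choiceB, reward = reward,
            variant = vcode, evalMask = mask),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("RL fit failed from all starts")
  h <- tryCatch(
    optim(best$par, rlNegLogLik, method = "L-BFGS-B", lower = lower,
          upper = upper, choiceB = choiceB, reward = reward, variant = vcode,
          evalMask = mask, hessian = TRUE)$hessian,
    error = function(e) NULL)
  se <- if (!is.null(h)) {
    v <- tryCatch(diag(solve(h)), error = function(e) rep(NA_real_, k))
    sqrt(pmax(v, 0))
  } else rep(NA_real_, k)
  n <- sum(mask); ll <- -best$value
  list(variant = variant, alpha = best$par[1], tau = best$par[2],
       stack = if (k == 3L) best$par[3] else NA_real_,
       se = setNames(se, c("alpha", "tau", "stack")[seq_len(k)]),
       logLik = ll, k = k, n = n,
       aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
       converged = best$convergence == 0)
}

.modelDescriptions <- c(
  "Value from reward history",
  "Value from reward history and risk",
  "Value from choice history",
  "Value from choice history and risk",
  "Value from reward and choice history",
  "Value from reward and choice history and risk",
  "Objective reward probabilities",
  "Objective reward probabilities and objective risk",
  "Reinforcement learning (RL)",
  "RL with stack parameter",
  "RL, reversal-learning variant")

#' Compare the eleven choice models
#'
#' Out-of-sample protocol: history weights are fitted on the first half of
#' the session; all candidate models are then fitted (or their parameters
#' estimated) on the second half, and compared by AIC and BIC normalized to
#' per-trial mean deviance scale (values of order 2). Models 1-8 are logistic
#' regressions of the side choice on left-right differences of: (1) reward
#' -history value, (2) + subjective risk, (3) choice-history value, (4) +
#' risk, (5) combined reward+choice value, (6) + risk, (7) objective
#' probability, (8) + objective risk. Models 9-11 are the RL variants of
#' [fitRLModel()].
#'
#' @param session a [Session-class]
#' @param N history length (default 10)
#' @return data.frame with one row per model (`model`, `description`, `k`,
#'   `logLik`, `aic`, `bic`, `best`); attribute `"weights"` holds the fitted
#'   [WeightSet-class]
#' @export
compareChoiceModels <- function(session, N = 10L) {
  T <- length(session)
  half <- floor(T / 2)
  hm <- buildHistoryMatrix(session, N, "object")
  inH1 <- hm$trials <= half
  hm1 <- list(X = hm$X[inH1, , drop = FALSE], y = hm$y[inH1],
              trials = hm$trials[inH1], N = N, domain = "object")
  w <- fitHistoryWeights(hm1)
  dv <- decisionVariables(session, w)
  tr <- trials(session)
  evalIdx <- which(dv$trial > half & complete.cases(
    dv[, c("ObjectValueA", "ObjectRiskA")]))
  y <- as.numeric(tr$action == "L")[evalIdx]
  d <- dv[evalIdx, ]
  reg <- list(
    dVr = lrDelta(d, "ObjectValueRA", "ObjectValueRB"),
    dVc = lrDelta(d, "ObjectValueCA", "ObjectValueCB"),
    dVrc = d$dValueLR,
    dRisk = d$dRiskLR,
    dP = lrDelta(d, "TrueProbA", "TrueProbB"),
    dTR = lrDelta(d, "TrueRiskA", "TrueRiskB"))
  specs <- list(c("dVr"), c("dVr", "dRisk"), c("dVc"), c("dVc", "dRisk"),
                c("dVrc"), c("dVrc", "dRisk"), c("dP"), c("dP", "dTR"))
  rows <- lapply(seq_along(specs), function(i) {
    X <- cbind(bias = 1, do.call(cbind, reg[specs[[i]]]))
    f <- logisticFit(X, y)
    data.frame(model = i, k = f$k, logLik = f$logLik)
  })
  evalTrials <- dv$trial[evalIdx]
  for (v in c("standard", "stack", "reversal")) {
    f <- fitRLModel(session, v, trialSubset = evalTrials)
    rows[[length(rows) + 1L]] <-
      data.frame(model = length(rows) + 1L, k = f$k, logLik = f$logLik)
  }
  out <- do.call(rbind, rows)
  n <- length(y)
  out$description <- .modelDescriptions
  out$aic <- (-2 * out$logLik + 2 * out$k) / n
  out$bic <- (-2 * out$logLik + out$k * log(n)) / n
  out$best <- out$aic == min(out$aic)
  out <- out[, c("model", "description", "k", "logLik", "aic", "bic", "best")]
  attr(out, "weights") <- w
  attr(out, "nEval") <- n
  out
}

#' Matching-behavior summaries
#'
#' Block-wise relationship between log choice ratio and log reward ratio
#' (linear regression, the matching-law slope), the cumulative-choice
#' trajectory, and a seven-trial sliding-window correlation between choice
#' and reward ratios aligned on block transitions. Zero counts are smoothed
#' with an additive 0.5 before taking ratios. Sessions in which one object is
#' never chosen yield an undefined slope, flagged via `degenerate`.
#'
#' @param session a [Session-class]
#' @param window sliding-window half-width support: the window spans 7 trials
#' @param offsets trial offsets around block transitions for the sliding
#'   correlation
#' @return list: `blocks` (per-block counts and log ratios), `slope`,
#'   `intercept`, `r2`, `degenerate`, `cumulative`, `transition`
#' @export
matchingAnalysis <- function(session, offsets = -20:40) {
  tr <- trials(session)
  chA <- as.numeric(tr$choice == "A")
  rwA <- as.numeric(tr$reward * chA)
  rwB <- as.numeric(tr$reward * (1 - chA))
  blocks <- split(seq_len(nrow(tr)), tr$block_id)
  bs <- do.call(rbind, lapply(names(blocks), function(b) {
    i <- blocks[[b]]
    data.frame(block = as.integer(b), nTrials = length(i),
               nA = sum(chA[i]), nB = sum(1 - chA[i]),
               rA = sum(rwA[i]), rB = sum(rwB[i]))
  }))
  bs$logChoice <- log((bs$nA + 0.5) / (bs$nB + 0.5))
  bs$logReward <- log((bs$rA + 0.5) / (bs$rB + 0.5))
  degenerate <- all(chA == 1) || all(chA == 0) || nrow(bs) < 2 ||
    var(bs$logReward) == 0
  if (degenerate) {
    slope <- intercept <- r2 <- NA_real_
  } else {
    f <- lm(logChoice ~ logReward, data = bs)
    slope <- unname(coef(f)[2]); intercept <- unname(coef(f)[1])
    r2 <- summary(f)$r.squared
  }
  cumulative <- data.frame(trial = tr$trial, block = tr$block_id,
                           cumA = cumsum(chA), cumB = cumsum(1 - chA))
  ## sliding matching coefficient around block transitions
  starts <- which(diff(tr$block_id) != 0) + 1L
  transition <- NULL
  if (length(starts) >= 3) {
    n <- nrow(tr)
    transition <- do.call(rbind, lapply(offsets, function(o) {
      ctr <- starts + o
      keep <- ctr - 3 >= 1 & ctr + 3 <= n
      if (sum(keep) < 3) return(NULL)
      lc <- lr <- numeric(sum(keep))
      for (k in seq_along(which(keep))) {
        i <- (ctr[keep][k] - 3):(ctr[keep][k] + 3)
        lc[k] <- log((sum(chA[i]) + 0.5) / (sum(1 - chA[i]) + 0.5))
        lr[k] <- log((sum(rwA[i]) + 0.5) / (sum(rwB[i]) + 0.5))
      }
      if (var(lc) == 0 || var(lr) == 0)
        return(data.frame(offset = o, r = NA_real_, p = NA_real_,
                          n = sum(keep)))
      ct <- cor.test(lc, lr)
      data.frame(offset = o, r = unname(ct$estimate), p = ct$p.value,
                 n = sum(keep))
    }))
  }
  list(blocks = bs, slope = slope, intercept = intercept, r2 = r2,
       degenerate = degenerate, cumulative = cumulative,
       transition = transition)
}

#' Choice psychometrics: value bins crossed with a risk median split
#'
#' Probability of choosing object A in bins of the A-minus-B value difference,
#' split at the median of the A-minus-B risk difference, with chi-squared
#' tests between the two risk levels within each value bin; plus marginal
#' psychometric curves of choice probability against value- and
#' risk-difference deciles.
#'
#' @param dv decision-variable table
#' @param session a [Session-class]
#' @param nBins number of value bins (default 4)
#' @return list: `table` (bin x risk-split choice probabilities and counts),
#'   `tests` (chi-squared per bin), `valueCurve`, `riskCurve`
#' @export
choicePsychometrics <- function(dv, session, nBins = 4L) {
  tr <- trials(session)
  dVal <- dv$ObjectValueA - dv$ObjectValueB
  dRsk <- dv$ObjectRiskA - dv$ObjectRiskB
  ok <- complete.cases(dVal, dRsk)
  dVal <- dVal[ok]; dRsk <- dRsk[ok]
  chA <- as.numeric(tr$choice == "A")[ok]
  br <- unique(quantile(dVal, seq(0, 1, length.out = nBins + 1)))
  bin <- cut(dVal, br, include.lowest = TRUE, labels = FALSE)
  hi <- dRsk > median(dRsk)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    do.call(rbind, lapply(c(FALSE, TRUE), function(h) {
      i <- bin == b & hi == h
      data.frame(valueBin = b, riskHigh = h, n = sum(i),
                 pChooseA = if (sum(i)) mean(chA[i]) else NA_real_)
    }))
  }))
  tests <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    if (length(unique(hi[i])) < 2 || sum(i) < 10)
      return(data.frame(valueBin = b, chi2 = NA_real_, p = NA_real_,
                        empty = TRUE))
    ct <- suppressWarnings(chisq.test(table(chA[i], hi[i])))
    data.frame(valueBin = b, chi2 = unname(ct$statistic),
               p = ct$p.value, empty = FALSE)
  }))
  curve <- function(x) {
    b <- cut(x, unique(quantile(x, seq(0, 1, 0.1))),
             include.lowest = TRUE, labels = FALSE)
    do.call(rbind, lapply(sort(unique(b)), function(d) {
      data.frame(decile = d, x = mean(x[b == d]), pChooseA = mean(chA[b == d]),
                 n = sum(b == d))
    }))
  }
  list(table = tab, tests = tests,
       valueCurve = curve(dVal), riskCurve = curve(dRsk))
}
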