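## History-weight estimation and construction of subjective decision
## variables (value, variance risk) from recency-weighted reward history.

## lagMatrix(x, N): rows are trials N+1..T, column j holds x[i - j].
lagMatrix <- function(x, N) {
  m <- embed(x, N + 1L)[, -1L, drop = FALSE]
  colnames(m) <- paste0("lag", seq_len(N))
  m
}

## Object- or action-referenced reward/choice indicator series for a session.
## RA is 1 only on trials where A was chosen AND rewarded.
indicatorSeries <- function(session, domain = c("object", "action")) {
  domain <- match.arg(domain)
  tr <- trials(session)
  first <- if (domain == "object") tr$choice == "A" else tr$action == "L"
  list(R1 = as.numeric(tr$reward * first),
       R2 = as.numeric(tr$reward * !first),
       C1 = as.numeric(first),
       C2 = as.numeric(!first))
}

#' Build the choice-history design matrix
#'
#' For each trial `i > N` the design holds `N` reward-difference regressors
#' `R1(i-j) - R2(i-j)` and `N` choice-difference regressors
#' `C1(i-j) - C2(i-j)` (`j = 1..N`), plus an intercept. In the object domain
#' the reference option is object A (reward indicator = chosen *and*
#' rewarded); in the action domain it is the leftward saccade. The response is
#' the indicator of choosing the reference option.
#'
#' @param session a [Session-class]
#' @param N number of past trials (default 10)
#' @param domain `"object"` or `"action"`
#' @return list with elements `X` (design incl. intercept), `y` (0/1
#'   response), `trials` (trial indices of the rows), `N`, `domain`
#' @export
buildHistoryMatrix <- function(session, N = 10L, domain = c("object", "action")) {
  domain <- match.arg(domain)
  if (length(session) <= N + 1L)
    stop("session too short for ", N, " history lags")
  s <- indicatorSeries(session, domain)
  Rd <- lagMatrix(s$R1 - s$R2, N)
  Cd <- lagMatrix(s$C1 - s$C2, N)
  colnames(Rd) <- paste0("Rdiff", seq_len(N))
  colnames(Cd) <- paste0("Cdiff", seq_len(N))
  idx <- (N + 1L):length(session)
  X <- cbind(`(Intercept)` = 1, Rd, Cd)
  list(X = X, y = s$C1[idx], trials = idx, N = N, domain = domain)
}

## Ridge-penalized logistic IRLS, used as a fallback when the unpenalized
## fit separates or fails to converge.
ridgeLogistic <- function(X, y, lambda = 1e-2, maxit = 50L) {
  p <- ncol(X); beta <- numeric(p)
  pen <- diag(lambda, p); pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta); mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    betaNew <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(betaNew - beta)) < 1e-8) { beta <- betaNew; break }
    beta <- betaNew
  }
  se <- sqrt(diag(solve(H)))
  list(beta = beta, se = se)
}

#' Fit history weights by logistic regression
#'
#' Maximum-likelihood logistic fit (binomial, logit link) of the choice
#' indicator on the reward- and choice-difference history regressors,
#' returning the recency weights for past rewards and past choices. Columns
#' with zero variance are dropped (weight 0) with a warning. Perfect
#' separation or non-convergence triggers a ridge-penalized refit, flagged in
#' the diagnostics.
#'
#' @param hm design list from [buildHistoryMatrix()]
#' @param alpha significance level used to flag significant weights
#'   (default 0.005)
#' @return a [WeightSet-class]; `diagnostics` holds per-weight p-values,
#'   significance flags, and fit status
#' @export
fitHistoryWeights <- function(hm, alpha = 0.005) {
  X <- hm$X; y <- hm$y
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, function(v) var(v) > 0))
  if (!all(keep)) {
    warning("dropping degenerate history columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xk <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(glm.fit(Xk, y, family = binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15)
  if (separated) {
    rf <- ridgeLogistic(Xk, y)
    beta <- rf$beta; se <- rf$se
  } else {
    beta <- fit$coefficients
    R <- qr.R(fit$qr)
    cov <- chol2inv(R)
    se <- sqrt(diag(cov))
  }
  full <- setNames(numeric(ncol(X)), colnames(X))
  fullSe <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  full[colnames(Xk)] <- beta
  fullSe[colnames(Xk)] <- se
  N <- hm$N
  rn <- paste0("Rdiff", seq_len(N)); cn <- paste0("Cdiff", seq_len(N))
  p <- 2 * pnorm(-abs(full / fullSe))
  weightSet(
    rewardWeights = full[rn], choiceWeights = full[cn],
    bias = full["(Intercept)"],
    se = list(reward = fullSe[rn], choice = fullSe[cn],
              bias = fullSe["(Intercept)"]),
    domain = hm$domain,
    diagnostics = list(p = p, significant = p < alpha, alpha = alpha,
                       separation = separated, nTrials = length(y)))
}

## Core weighted history statistics for trials N+1..T.
## value (reward_and_choice): [sum_j wr_j R(i-j) + sum_j wc_j C(i-j)] / N
## (single denominator); risk: sum_j wr_j (R(i-j) - mean)^2 / (N-1) with the
## unweighted window mean.
weightedHistoryStats <- function(R, C, wr, wc) {
  N <- length(wr)
  LR <- lagMatrix(R, N); LC <- lagMatrix(C, N)
  valueR <- drop(LR %*% wr) / N
  valueC <- drop(LC %*% wc) / N
  m <- rowMeans(LR)
  risk <- drop(((LR - m)^2) %*% wr) / (N - 1)
  list(valueR = valueR, valueC = valueC, value = valueR + valueC, risk = risk)
}

#' Per-trial object (or action) value from weighted history
#'
#' `variant = "reward_only"` returns the weighted mean of the last `N` reward
#' deliveries for each option; `"reward_and_choice"` adds the weighted choice
#' history, with a single denominator `N` over both sums. The first `N` trials
#' are burn-in and returned as `NA`.
#'
#' @param session a [Session-class]
#' @param weights a [WeightSet-class]
#' @param variant `"reward_and_choice"` (default) or `"reward_only"`
#' @return data.frame with per-trial values for both options (columns named
#'   by option: A/B in the object domain, L/R in the action domain)
#' @export
objectValue <- function(session, weights,
                        variant = c("reward_and_choice", "reward_only")) {
  variant <- match.arg(variant)
  s <- indicatorSeries(session, weights@domain)
  wr <- rewardWeights(weights)
  wc <- if (variant == "reward_and_choice") choiceWeights(weights)
        else rep(0, length(wr))
  st1 <- weightedHistoryStats(s$R1, s$C1, wr, wc)
  st2 <- weightedHistoryStats(s$R2, s$C2, wr, wc)
  N <- length(wr); T <- length(session)
  v1 <- v2 <- rep(NA_real_, T)
  v1[(N + 1):T] <- st1$value; v2[(N + 1):T] <- st2$value
  labs <- if (weights@domain == "object") c("A", "B") else c("L", "R")
  out <- data.frame(trial = seq_len(T), v1, v2)
  names(out)[2:3] <- paste0("value", labs)
  out
}

#' Per-trial subjective variance risk from weighted reward history
#'
#' The weighted variance of the last `N` reward deliveries for each option:
#' squared deviations of the option-referenced reward indicators from the
#' unweighted window mean, weighted by the reward recency weights and summed,
#' divided by `N - 1`. Burn-in trials are `NA`. Negative fitted weights are
#' used as-is, so rare negative risk values are possible and retained.
#'
#' @inheritParams objectValue
#' @return data.frame of per-trial risks for both options
#' @export
subjectiveRisk <- function(session, weights) {
  s <- indicatorSeries(session, weights@domain)
  wr <- rewardWeights(weights)
  st1 <- weightedHistoryStats(s$R1, s$C1, wr, wr)
  st2 <- weightedHistoryStats(s$R2, s$C2, wr, wr)
  N <- length(wr); T <- length(session)
  r1 <- r2 <- rep(NA_real_, T)
  r1[(N + 1):T] <- st1$risk; r2[(N + 1):T] <- st2$risk
  labs <- if (weights@domain == "object") c("A", "B") else c("L", "R")
  out <- data.frame(trial = seq_len(T), r1, r2)
  names(out)[2:3] <- paste0("risk", labs)
  out
}

#' Assemble the per-trial decision-variable table
#'
#' Combines objective (true) probabilities and risks from the task schedule
#' with subjective values and risks from the weighted histories, current-trial
#' codings (object choice 0 = A / 1 = B, cue position 0 = A-left / 1 =
#' A-right, action 0 = left / 1 = right), last-trial and two-back history
#' regressors, and left-right value/risk differences. Burn-in trials (first
#' `N`) carry `NA` in the history-derived columns.
#'
#' @param session a [Session-class]
#' @param objectWeights [WeightSet-class] in the object domain
#' @param actionWeights optional [WeightSet-class] in the action domain; when
#'   supplied, action values and action risks are included
#' @return data.frame, one row per trial
#' @export
decisionVariables <- function(session, objectWeights, actionWeights = NULL) {
  stopifnot(objectWeights@domain == "object")
  tr <- trials(session)
  T <- nrow(tr)
  m <- session@config$rewardMagnitude
  dv <- data.frame(
    trial = tr$trial,
    ObjectChoice = as.numeric(tr$choice == "B"),
    CuePosition = as.numeric(tr$pos_A == "R"),
    Action = as.numeric(tr$action == "R"),
    TrueProbA = tr$inst_p_A, TrueProbB = tr$inst_p_B,
    TrueRiskA = objectiveRisk(tr$inst_p_A, m),
    TrueRiskB = objectiveRisk(tr$inst_p_B, m))
  vr <- objectValue(session, objectWeights, "reward_only")
  vrc <- objectValue(session, objectWeights, "reward_and_choice")
  rk <- subjectiveRisk(session, objectWeights)
  dv$ObjectValueRA <- vr$valueA; dv$ObjectValueRB <- vr$valueB
  dv$ObjectValueA <- vrc$valueA; dv$ObjectValueB <- vrc$valueB
  dv$ObjectValueCA <- vrc$valueA - vr$valueA  # choice-history component
  dv$ObjectValueCB <- vrc$valueB - vr$valueB
  dv$ObjectRiskA <- rk$riskA; dv$ObjectRiskB <- rk$riskB
  if (!is.null(actionWeights)) {
    stopifnot(actionWeights@domain == "action")
    av <- objectValue(session, actionWeights, "reward_and_choice")
    ar <- subjectiveRisk(session, actionWeights)
    dv$ActionValueL <- av$valueL; dv$ActionValueR <- av$valueR
    dv$ActionRiskL <- ar$riskL; dv$ActionRiskR <- ar$riskR
  }
  lag1 <- function(x) c(NA, x[-T])
  dv$LastReward <- lag1(as.numeric(tr$reward))
  dv$LastChoice <- lag1(dv$ObjectChoice)
  dv$LastRewardChoice <- dv$LastReward * dv$LastChoice
  dv$LastReward2 <- lag1(dv$LastReward)
  dv$LastChoice2 <- lag1(dv$LastChoice)
  dv$LastRewardChoice2 <- dv$LastReward2 * dv$LastChoice2
  ## left-right differences through the cue position
  aLeft <- dv$CuePosition == 0
  dv$dValueLR <- ifelse(aLeft, dv$ObjectValueA - dv$ObjectValueB,
                        dv$ObjectValueB - dv$ObjectValueA)
  dv$dRiskLR <- ifelse(aLeft, dv$ObjectRiskA - dv$ObjectRiskB,
                       dv$ObjectRiskB - dv$ObjectRiskA)
  dv
}

#' Mean-variance utility per object
#'
#' Utility as the weighted sum of object value and object risk, with the
#' weights taken from a fitted choice model: `U = b1 * value + b2 * risk`.
#'
#' @param dv decision-variable table from [decisionVariables()]
#' @param fit a choice-model fit from [fitChoiceModel()], or a numeric vector
#'   `c(value = b1, risk = b2)`
#' @return `dv` with `UtilityA` and `UtilityB` columns added
#' @export
utility <- function(dv, fit) {
  b <- if (is.numeric(fit)) fit
       else c(value = unname(fit$coef["dValue"]), risk = unname(fit$coef["dRisk"]))
  dv$UtilityA <- b[["value"]] * dv$ObjectValueA + b[["risk"]] * dv$ObjectRiskA
  dv$UtilityB <- b[["value"]] * dv$ObjectValueB + b[["risk"]] * dv$ObjectRiskB
  dv
}
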