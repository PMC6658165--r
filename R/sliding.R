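## Sliding-window regression on event-aligned spike times, with the
## consecutive-windows significance criterion, shuffle calibration, coding
## latencies and joint-coding statistics.

## Count spikes of each trial in overlapping windows aligned to one event.
## Returns trials x windows matrix.
windowCounts <- function(spikes, eventTime, starts, width) {
  nT <- length(spikes)
  out <- matrix(0L, nT, length(starts))
  edges0 <- starts; edges1 <- starts + width
  for (i in seq_len(nT)) {
    s <- sort(spikes[[i]]) - eventTime[i]
    if (!length(s)) next
    out[i, ] <- findInterval(edges1 - 1e-9, s) - findInterval(edges0 - 1e-9, s)
  }
  out
}

## Vectorized OLS of many window responses on a fixed design: returns
## per-term beta and p matrices (terms x windows).
slidingOls <- function(X, Y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  B <- qr.coef(qrx, Y)
  R <- qr.resid(qrx, Y)
  df <- nrow(Xi) - qrx$rank
  rss <- colSums(R^2)
  XtXi <- chol2inv(qr.R(qrx))
  dXtXi <- diag(XtXi)[order(qrx$pivot)]
  se <- sqrt(outer(dXtXi, rss / df))
  tv <- B / se
  P <- 2 * pt(-abs(tv), df)
  list(beta = B, p = P, df = df)
}

## length of longest run of TRUE
maxRun <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

## first start index of the first run of TRUE longer than minRun
firstRunStart <- function(x, minRun) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths > minRun)
  if (length(hit)) starts[hit[1]] else NA_integer_
}

#' Sliding-window regression over event-aligned spike times
#'
#' Counts each neuron's spikes in 200-ms windows stepped by 25 ms along a
#' single alignment stream, regresses the per-window counts on the
#' regressors of the requested model (same design for all windows, so the
#' OLS is solved once for all windows jointly), and applies the
#' consecutive-windows criterion: a variable is coded when more than
#' `minRun` consecutive windows are individually significant at `alpha`.
#'
#' @param ec an [EpochCounts-class] carrying spike times
#' @param model model id (default `"eq11"`)
#' @param align alignment event column (default `"t_fix_on"`)
#' @param range time range around the event in ms (default `c(-500, 1000)`:
#'   windows stay inside the span of the trial that is guaranteed to lie
#'   within the fixation period)
#' @param width,step window width and step in ms (defaults 200 / 25)
#' @param alpha per-window significance level (default 0.05)
#' @param minRun run-length criterion: coded requires strictly more than
#'   this many consecutive significant windows (default 6)
#' @param neurons neuron indices (default all)
#' @return list: `starts` (window start times), `terms`, and per-neuron
#'   `results` (each with `beta`, `p` matrices terms x windows, `coded`
#'   logical per term, `maxRun` per term)
#' @export
slidingWindowRegression <- function(ec, model = "eq11", align = "t_fix_on",
                                    range = c(-500, 1000), width = 200,
                                    step = 25, alpha = 0.05, minRun = 6L,
                                    neurons = seq_len(nrow(ec))) {
  st <- spikeTimes(ec)
  if (is.null(st)) stop("EpochCounts carries no spike times")
  ev <- metadata(ec)$eventTimes
  stopifnot(align %in% names(ev))
  dv <- as.data.frame(colData(ec))
  rt <- regressorTable(dv, model)
  starts <- seq(range[1], range[2] - width, by = step)
  eventTime <- ev[[align]]
  results <- vector("list", length(neurons))
  for (k in seq_along(neurons)) {
    j <- neurons[k]
    Y <- windowCounts(st[[j]], eventTime, starts, width)[rt$rows, , drop = FALSE]
    keep <- colSums(Y) > 0
    fit <- slidingOls(rt$X, Y[, keep, drop = FALSE])
    p <- matrix(NA_real_, ncol(rt$X) + 1L, length(starts),
                dimnames = list(rownames(fit$p), NULL))
    beta <- p
    p[, keep] <- fit$p; beta[, keep] <- fit$beta
    sig <- p < alpha
    terms <- rownames(p)[-1]
    coded <- vapply(terms, function(tm) maxRun(sig[tm, ]) > minRun, logical(1))
    mr <- vapply(terms, function(tm) maxRun(sig[tm, ]), integer(1))
    results[[k]] <- list(neuron = j, beta = beta, p = p, coded = coded,
                         maxRun = mr)
  }
  list(starts = starts, width = width, terms = colnames(rt$X),
       alpha = alpha, minRun = minRun, results = results,
       rows = rt$rows, model = model, align = align)
}

#' Shuffle calibration of the sliding-window criterion
#'
#' Re-runs the sliding-window regression on trial-shuffled data (response
#' counts permuted across trials, breaking any relation to the regressors)
#' and reports the fraction of neuron-shuffles in which at least one
#' variable passes the consecutive-windows criterion. The criterion is
#' calibrated so that this fraction stays below five per cent.
#'
#' @inheritParams slidingWindowRegression
#' @param nShuffles shuffles per neuron (default 1)
#' @param seed integer seed for the permutations
#' @return list: `fracAny` (fraction of neuron-shuffles with any coded
#'   variable), `fracByTerm`, `passed` (neurons x shuffles logical)
#' @export
slidingShuffleCalibration <- function(ec, model = "eq11", align = "t_fix_on",
                                      range = c(-500, 1000), width = 200,
                                      step = 25, alpha = 0.05, minRun = 6L,
                                      neurons = seq_len(nrow(ec)),
                                      nShuffles = 1L, seed = NULL) {
  st <- spikeTimes(ec)
  if (is.null(st)) stop("EpochCounts carries no spike times")
  ev <- metadata(ec)$eventTimes
  dv <- as.data.frame(colData(ec))
  rt <- regressorTable(dv, model)
  starts <- seq(range[1], range[2] - width, by = step)
  eventTime <- ev[[align]]
  terms <- colnames(rt$X)
  withSeed(seed, {
    passed <- matrix(FALSE, length(neurons), nShuffles)
    byTerm <- setNames(numeric(length(terms)), terms)
    for (k in seq_along(neurons)) {
      j <- neurons[k]
      Y0 <- windowCounts(st[[j]], eventTime, starts, width)[rt$rows, , drop = FALSE]
      for (s in seq_len(nShuffles)) {
        Y <- Y0[sample(nrow(Y0)), , drop = FALSE]
        keep <- colSums(Y) > 0
        fit <- slidingOls(rt$X, Y[, keep, drop = FALSE])
        sig <- matrix(FALSE, length(terms) + 1L, length(starts))
        rownames(sig) <- rownames(fit$p)
        sig[, keep] <- fit$p < alpha
        codedTerm <- vapply(terms, function(tm) maxRun(sig[tm, ]) > minRun,
                            logical(1))
        byTerm <- byTerm + codedTerm
        passed[k, s] <- any(codedTerm)
      }
    }
    list(fracAny = mean(passed),
         fracByTerm = byTerm / (length(neurons) * nShuffles),
         passed = passed)
  })
}

#' Coding latencies from sliding-window results
#'
#' Latency of a variable in a neuron is the start time of the first window
#' run that satisfies the consecutive-windows criterion; neurons in which a
#' variable never qualifies have no latency. Also returns cumulative latency
#' curves (normalized to each variable's own maximum) and pairwise rank-sum
#' comparisons between variables.
#'
#' @param sw result of [slidingWindowRegression()]
#' @param terms variables to extract (default all model terms)
#' @return list: `latency` (neurons x terms, ms), `cumulative` (data.frame
#'   per term and time), `comparisons` (pairwise rank-sum tests)
#' @export
codingLatency <- function(sw, terms = NULL) {
  allTerms <- setdiff(sw$terms, "(Intercept)")
  if (is.null(terms)) terms <- allTerms
  lat <- matrix(NA_real_, length(sw$results), length(terms),
                dimnames = list(NULL, terms))
  for (k in seq_along(sw$results)) {
    p <- sw$results[[k]]$p
    for (tm in terms) {
      i <- firstRunStart(p[tm, ] < sw$alpha, sw$minRun)
      if (!is.na(i)) lat[k, tm] <- sw$starts[i]
    }
  }
  cum <- do.call(rbind, lapply(terms, function(tm) {
    l <- sort(lat[, tm])
    if (!length(l)) return(NULL)
    data.frame(term = tm, time = l,
               cumFraction = seq_along(l) / length(l))
  }))
  if (length(terms) < 2) {
    return(list(latency = lat, cumulative = cum, comparisons = NULL))
  }
  pairs <- t(combn(terms, 2))
  comparisons <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    a <- lat[, pairs[r, 1]]; b <- lat[, pairs[r, 2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3)
      return(data.frame(term1 = pairs[r, 1], term2 = pairs[r, 2],
                        median1 = NA, median2 = NA, p = NA))
    wt <- suppressWarnings(wilcox.test(a, b))
    data.frame(term1 = pairs[r, 1], term2 = pairs[r, 2],
               median1 = median(a), median2 = median(b), p = wt$p.value)
  }))
  list(latency = lat, cumulative = cum, comparisons = comparisons)
}

#' Joint-coding statistics over a population
#'
#' Tests whether pairs of variables are coded by the same neurons more or
#' less often than expected from independent coding (chi-squared test of the
#' 2x2 coding table; exact test when expected counts fall below 5), compares
#' joint vs pure coding proportions with the dependent-proportions z test,
#' and (optionally) regresses the signed coefficients of one variable on the
#' other across jointly coding neurons.
#'
#' @param coding neurons x variables logical matrix (e.g. sliding-window
#'   coded flags)
#' @param coefs optional neurons x variables matrix of signed coefficients
#'   for the jointly coding regression
#' @return list: `pairs` (per-pair chi-squared/exact p, joint counts,
#'   expected), `jointVsPure` (per variable), `coefRegression` (per pair,
#'   when `coefs` given)
#' @export
jointCodingStats <- function(coding, coefs = NULL) {
  vars <- colnames(coding)
  stopifnot(!is.null(vars))
  prs <- t(combn(vars, 2))
  pairRows <- lapply(seq_len(nrow(prs)), function(r) {
    a <- coding[, prs[r, 1]]; b <- coding[, prs[r, 2]]
    tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    exact <- any(expct < 5)
    p <- if (exact) fisher.test(tab)$p.value
         else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    chi2 <- if (exact) NA_real_
            else unname(suppressWarnings(chisq.test(tab, correct = FALSE)$statistic))
    data.frame(term1 = prs[r, 1], term2 = prs[r, 2],
               nJoint = sum(a & b), expectedJoint = expct["TRUE", "TRUE"],
               chi2 = chi2, p = p, exact = exact)
  })
  jvp <- lapply(vars, function(v) {
    coders <- coding[, v]
    others <- coding[, setdiff(vars, v), drop = FALSE]
    joint <- coders & rowSums(others) > 0
    pure <- coders & rowSums(others) == 0
    zt <- zTestDependentProportions(joint, pure)
    data.frame(term = v, nCoding = sum(coders), nJoint = sum(joint),
               nPure = sum(pure), z = zt$z, p = zt$p)
  })
  coefReg <- NULL
  if (!is.null(coefs)) {
    coefReg <- do.call(rbind, lapply(seq_len(nrow(prs)), function(r) {
      j <- coding[, prs[r, 1]] & coding[, prs[r, 2]]
      if (sum(j) < 4)
        return(data.frame(term1 = prs[r, 1], term2 = prs[r, 2],
                          slope = NA, p = NA, n = sum(j)))
      f <- summary(lm(coefs[j, prs[r, 2]] ~ coefs[j, prs[r, 1]]))
      data.frame(term1 = prs[r, 1], term2 = prs[r, 2],
                 slope = f$coefficients[2, 1], p = f$coefficients[2, 4],
                 n = sum(j))
    }))
  }
  list(pairs = do.call(rbind, pairRows), jointVsPure = do.call(rbind, jvp),
       coefRegression = coefReg)
}
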