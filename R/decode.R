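## Pseudo-population decoding of risk (and other variables) with linear SVM
## and nearest-neighbour classifiers, shuffle nulls, size curves and
## subset/control analyses.

## z-score epoch counts against the control period, per neuron
zScoreEpoch <- function(ec, epoch, control = "PreFix") {
  m <- assay(ec, epoch); ctrl <- assay(ec, control)
  mu <- rowMeans(ctrl)
  sdv <- apply(ctrl, 1, sd)
  sdv[sdv == 0] <- 1
  (m - mu) / sdv
}

#' Build a pseudo-population for two-group decoding
#'
#' Splits trials into low vs high groups of a per-trial variable (terciles
#' by default: lowest vs highest third by rank, stable under ties; or a
#' median split), z-scores each neuron's epoch counts against the control
#' period, and assembles the two trials x neurons matrices. Neurons with
#' fewer than `minTrials` usable trials in either group are excluded.
#'
#' @param ec an [EpochCounts-class]
#' @param variable grouping variable name in `colData`
#' @param epoch epoch to decode from (default `"PreCue"`)
#' @param split `"tercile"` (default) or `"median"`
#' @param minTrials minimum trials per group per neuron (default 8)
#' @param neurons candidate neuron indices (default all)
#' @param control control epoch for z-scoring
#' @return list: `low`, `high` (trials x neurons matrices), `neurons`
#'   (included indices), `variable`, `epoch`
#' @export
buildPseudoPopulation <- function(ec, variable, epoch = "PreCue",
                                  split = c("tercile", "median"),
                                  minTrials = 8L, neurons = seq_len(nrow(ec)),
                                  control = "PreFix") {
  split <- match.arg(split)
  x <- colData(ec)[[variable]]
  if (is.null(x)) stop("no such grouping variable: ", variable)
  ok <- which(!is.na(x))
  r <- rank(x[ok], ties.method = "first")
  if (split == "tercile") {
    terc <- ceiling(3 * r / length(r))
    lowIdx <- ok[terc == 1L]; highIdx <- ok[terc == 3L]
  } else {
    lowIdx <- ok[r <= length(r) / 2]; highIdx <- ok[r > length(r) / 2]
  }
  z <- zScoreEpoch(ec, epoch, control)
  keep <- neurons[vapply(neurons, function(j)
    sum(!is.na(z[j, lowIdx])) >= minTrials &&
      sum(!is.na(z[j, highIdx])) >= minTrials, logical(1))]
  if (!length(keep)) stop("no neurons satisfy the trial minimum")
  list(low = t(z[keep, lowIdx, drop = FALSE]),
       high = t(z[keep, highIdx, drop = FALSE]),
       neurons = keep, variable = variable, epoch = epoch, split = split)
}

## Leave-one-pair-out cross-validated accuracy: each fold holds out one
## trial from each group, keeping the training set exactly balanced (plain
## leave-one-out with balanced groups biases the null below chance because
## the left-out trial's own class is in the training minority).
looPairAccuracy <- function(Xl, Xh, classifier) {
  m <- nrow(Xl)
  X <- rbind(Xl, Xh)
  y <- rep(c("low", "high"), each = m)
  yf <- factor(y)
  correct <- logical(2 * m)
  for (i in seq_len(m)) {
    hold <- c(i, m + i)
    if (classifier == "nn") {
      Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
      for (h in hold) {
        d2 <- rowSums((Xtr - matrix(X[h, ], nrow(Xtr), ncol(Xtr),
                                    byrow = TRUE))^2)
        correct[h] <- ytr[which.min(d2)] == y[h]
      }
    } else {
      fit <- e1071::svm(X[-hold, , drop = FALSE], yf[-hold],
                        kernel = "linear", cost = 1, scale = FALSE)
      pred <- as.character(predict(fit, X[hold, , drop = FALSE]))
      correct[hold] <- pred == y[hold]
    }
  }
  mean(correct)
}

#' Decode group membership from a pseudo-population
#'
#' Leave-one-out cross-validated classification of low vs high group with a
#' linear maximum-margin classifier (`"svm"`, cost 1) or a single
#' nearest-neighbour (`"nn"`, Euclidean metric), averaged over random
#' within-group trial matchings (neurons' trials are independently permuted
#' within each group before assembly, mimicking non-simultaneous
#' recordings). Groups are balanced by down-sampling to the smaller group
#' (optionally capped at `maxPerGroup` for tractability); chance is 50%.
#'
#' @param pp pseudo-population from [buildPseudoPopulation()]
#' @param classifier `"svm"` (default) or `"nn"`
#' @param matchings number of random trial matchings (default 30)
#' @param maxPerGroup cap on trials per group (default 24)
#' @param seed integer seed
#' @return list: `accuracy` (% correct), `se` (over matchings),
#'   `perMatching`, `classifier`, `nNeurons`, `nPerGroup`
#' @export
decodePopulation <- function(pp, classifier = c("svm", "nn"), matchings = 30L,
                             maxPerGroup = 24L, seed = NULL) {
  classifier <- match.arg(classifier)
  m <- min(nrow(pp$low), nrow(pp$high), maxPerGroup)
  if (m < 2) stop("need at least 2 trials per group")
  nn <- ncol(pp$low)
  withSeed(seed, {
    acc <- vapply(seq_len(matchings), function(it) {
      lowRows <- sample(nrow(pp$low), m)
      highRows <- sample(nrow(pp$high), m)
      Xl <- pp$low[lowRows, , drop = FALSE]
      Xh <- pp$high[highRows, , drop = FALSE]
      ## within-group trial matching: permute each neuron independently
      for (j in seq_len(nn)) {
        Xl[, j] <- Xl[sample(m), j]
        Xh[, j] <- Xh[sample(m), j]
      }
      looPairAccuracy(Xl, Xh, classifier)
    }, numeric(1))
    list(accuracy = 100 * mean(acc),
         se = 100 * sd(acc) / sqrt(length(acc)),
         perMatching = 100 * acc, classifier = classifier,
         nNeurons = nn, nPerGroup = m)
  })
}

#' Shuffle-null decoding and significance
#'
#' Repeats the decoding with group labels randomly permuted (without
#' replacement) to obtain the chance distribution, and compares the real
#' per-matching accuracies against the null by rank-sum test.
#'
#' @param pp pseudo-population
#' @param real result of [decodePopulation()] on `pp`
#' @param nShuffles number of label permutations (default 500)
#' @param classifier,maxPerGroup,seed as in [decodePopulation()]
#' @return list: `nullMean`, `nullSd`, `nullAccuracies`, `p` (rank-sum of
#'   real vs null)
#' @export
decodeShuffleNull <- function(pp, real, nShuffles = 500L,
                              classifier = c("svm", "nn"), maxPerGroup = 24L,
                              seed = NULL) {
  classifier <- match.arg(classifier)
  m <- min(nrow(pp$low), nrow(pp$high), maxPerGroup)
  all <- rbind(pp$low, pp$high)
  withSeed(seed, {
    acc <- vapply(seq_len(nShuffles), function(s) {
      rows <- sample(nrow(all), 2 * m)
      X <- all[rows, , drop = FALSE]
      perm <- sample(2 * m)
      looPairAccuracy(X[perm[seq_len(m)], , drop = FALSE],
                      X[perm[m + seq_len(m)], , drop = FALSE], classifier)
    }, numeric(1))
    p <- suppressWarnings(
      wilcox.test(real$perMatching, 100 * acc)$p.value)
    list(nullMean = 100 * mean(acc), nullSd = 100 * sd(acc),
         nullAccuracies = 100 * acc, p = p)
  })
}

#' Decoding accuracy as a function of population size
#'
#' For each requested size, draws `draws` random neuron subsets, decodes,
#' and summarizes accuracy; reports a Spearman trend of accuracy over size.
#'
#' @param ec an [EpochCounts-class]
#' @param variable,epoch grouping variable and epoch
#' @param sizes neuron counts to test
#' @param draws random subsets per size (default 10)
#' @param classifier,matchings,maxPerGroup,seed decoding settings
#' @param neurons candidate neuron pool
#' @return list: `curve` (per size x draw), `summary` (mean/se per size),
#'   `trend` (Spearman rho and p)
#' @export
decodingCurves <- function(ec, variable, epoch = "PreCue",
                           sizes = c(2L, 5L, 10L, 20L), draws = 10L,
                           classifier = "svm", matchings = 10L,
                           maxPerGroup = 16L, neurons = seq_len(nrow(ec)),
                           seed = NULL) {
  withSeed(seed, {
    pp <- buildPseudoPopulation(ec, variable, epoch, neurons = neurons)
    pool <- seq_along(pp$neurons)
    rows <- list()
    for (sz in sizes) {
      if (sz > length(pool)) next
      for (d in seq_len(draws)) {
        sel <- sample(pool, sz)
        sub <- pp
        sub$low <- pp$low[, sel, drop = FALSE]
        sub$high <- pp$high[, sel, drop = FALSE]
        r <- decodePopulation(sub, classifier, matchings, maxPerGroup)
        rows[[length(rows) + 1L]] <-
          data.frame(size = sz, draw = d, accuracy = r$accuracy)
      }
    }
    curve <- do.call(rbind, rows)
    smry <- do.call(rbind, lapply(unique(curve$size), function(sz) {
      a <- curve$accuracy[curve$size == sz]
      data.frame(size = sz, accuracy = mean(a), se = sd(a) / sqrt(length(a)))
    }))
    tr <- suppressWarnings(cor.test(curve$size, curve$accuracy,
                                    method = "spearman"))
    list(curve = curve, summary = smry,
         trend = list(rho = unname(tr$estimate), p = tr$p.value))
  })
}

#' Subset and control decoding analyses
#'
#' Three control analyses: (i) `"subsetBeta"` — decode from many random
#' fixed-size neuron subsets and regress each subset's accuracy on its mean
#' absolute single-neuron standardized risk coefficient; (ii) `"cross"` —
#' decode a different variable than the one the neuron subset was selected
#' for (e.g. object-risk neurons decoding action risk); (iii)
#' `"controlConstant"` — decode within trial subsets holding a control
#' variable constant at each of its levels.
#'
#' @param ec an [EpochCounts-class]
#' @param variable grouping variable to decode
#' @param epoch epoch
#' @param what which control analysis
#' @param betas per-neuron |standardized beta| for `"subsetBeta"`
#' @param nSubsets,subsetSize subset sampling for `"subsetBeta"`
#' @param neurons neuron pool (for `"cross"`: the selected subset)
#' @param controlVariable `colData` column held constant for
#'   `"controlConstant"`
#' @param classifier,matchings,maxPerGroup,minTrials,seed decoding settings
#' @return analysis-specific list (see details of each branch)
#' @export
subsetControlDecoding <- function(ec, variable, epoch = "PreCue",
                                  what = c("subsetBeta", "cross",
                                           "controlConstant"),
                                  betas = NULL, nSubsets = 50L,
                                  subsetSize = 20L,
                                  neurons = seq_len(nrow(ec)),
                                  controlVariable = "CuePosition",
                                  classifier = "svm", matchings = 10L,
                                  maxPerGroup = 16L, minTrials = 8L,
                                  seed = NULL) {
  what <- match.arg(what)
  withSeed(seed, {
    if (what == "subsetBeta") {
      stopifnot(!is.null(betas), length(betas) >= max(neurons))
      pp <- buildPseudoPopulation(ec, variable, epoch, neurons = neurons,
                                  minTrials = minTrials)
      pool <- seq_along(pp$neurons)
      if (length(pool) < subsetSize) stop("population smaller than subsetSize")
      rows <- do.call(rbind, lapply(seq_len(nSubsets), function(s) {
        sel <- sample(pool, subsetSize)
        sub <- pp
        sub$low <- pp$low[, sel, drop = FALSE]
        sub$high <- pp$high[, sel, drop = FALSE]
        r <- decodePopulation(sub, classifier, matchings, maxPerGroup)
        data.frame(subset = s, accuracy = r$accuracy,
                   meanAbsBeta = mean(abs(betas[pp$neurons[sel]])))
      }))
      f <- summary(lm(accuracy ~ meanAbsBeta, data = rows))
      return(list(subsets = rows, slope = f$coefficients[2, 1],
                  p = f$coefficients[2, 4]))
    }
    if (what == "cross") {
      pp <- buildPseudoPopulation(ec, variable, epoch, neurons = neurons,
                                  minTrials = minTrials)
      return(decodePopulation(pp, classifier, matchings, maxPerGroup))
    }
    ## controlConstant
    ctrl <- colData(ec)[[controlVariable]]
    out <- list()
    for (lev in sort(unique(ctrl[!is.na(ctrl)]))) {
      sel <- which(!is.na(ctrl) & ctrl == lev)
      if (length(sel) < 2 * minTrials) next
      sub <- ec[, sel]
      r <- tryCatch({
        pp <- buildPseudoPopulation(sub, variable, epoch, neurons = neurons,
                                    minTrials = minTrials)
        decodePopulation(pp, classifier, matchings, maxPerGroup)
      }, error = function(e) NULL)
      if (!is.null(r)) out[[as.character(lev)]] <- r
    }
    out
  })
}
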