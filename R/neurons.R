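## Synthetic spiking populations: Poisson neurons with linear tuning to
## z-scored decision variables, epoch- or window-specific activation,
## optional slow baseline drift, and event-aligned spike times.

#' Specify one synthetic neuron
#'
#' A neuron has a baseline rate and a tuning table: each row gives a variable
#' (a column of the decision-variable table, or one of the session codings),
#' a gain in impulses/s per z-scored unit, and the time window in which the
#' tuning is active — either a set of task epochs or an explicit
#' event-anchored window. Per-epoch firing rate is
#' `baseline * drift + sum(gain * z(variable))` over active tunings, floored
#' at zero; epoch counts are Poisson with mean `rate * 0.5 s`.
#'
#' @param neuronId identifier
#' @param baseline baseline rate, impulses/s (> 0)
#' @param tuning data.frame with columns `variable`, `gain`, and either
#'   `epochs` (comma-separated epoch names) or `event`,`t0`,`t1` (ms relative
#'   to the event); NULL for an untuned neuron
#' @param driftPhi,driftSd AR(1) coefficient and innovation SD of a
#'   multiplicative log-scale baseline drift (0 = stationary)
#' @return list of class `NeuronSpec`
#' @export
neuronSpec <- function(neuronId, baseline = 10, tuning = NULL,
                       driftPhi = 0, driftSd = 0) {
  stopifnot(baseline > 0)
  if (!is.null(tuning)) {
    stopifnot(is.data.frame(tuning), all(c("variable", "gain") %in% names(tuning)))
    if (is.null(tuning$epochs)) tuning$epochs <- NA_character_
    if (is.null(tuning$event)) { tuning$event <- NA_character_; tuning$t0 <- NA; tuning$t1 <- NA }
    stopifnot(all(is.finite(tuning$gain)))
  }
  structure(list(neuronId = neuronId, baseline = baseline, tuning = tuning,
                 driftPhi = driftPhi, driftSd = driftSd),
            class = "NeuronSpec")
}

## Expand a tuning table into per-epoch gain contributions: for each tuning
## row and each epoch, the fraction of the epoch covered by the tuning
## window (1 for epoch-named tunings). Window tunings only overlap epochs
## anchored to the same event, keeping fractions trial-invariant.
expandTuning <- function(tuning, epochs = epochTable()) {
  if (is.null(tuning) || nrow(tuning) == 0L)
    return(data.frame(variable = character(0), gain = numeric(0),
                      epoch = character(0), frac = numeric(0)))
  out <- list()
  for (r in seq_len(nrow(tuning))) {
    if (!is.na(tuning$epochs[r])) {
      eps <- trimws(strsplit(tuning$epochs[r], ",")[[1]])
      bad <- setdiff(eps, epochs$epoch)
      if (length(bad)) stop("unknown epoch(s): ", paste(bad, collapse = ", "))
      out[[length(out) + 1L]] <- data.frame(
        variable = tuning$variable[r], gain = tuning$gain[r],
        epoch = eps, frac = 1)
    } else {
      same <- epochs[epochs$event == tuning$event[r], ]
      if (!nrow(same)) next
      lo <- pmax(same$offset, tuning$t0[r])
      hi <- pmin(same$offset + same$duration, tuning$t1[r])
      frac <- pmax(0, hi - lo) / same$duration
      keep <- frac > 0
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          variable = tuning$variable[r], gain = tuning$gain[r],
          epoch = same$epoch[keep], frac = frac[keep])
    }
  }
  do.call(rbind, out)
}

#' Build a synthetic population from class counts
#'
#' `config` is a list of class descriptors, each a list with `n` (number of
#' neurons), `variables` (character vector of tuned variables; empty or NULL
#' for untuned), `gain` (impulses/s per z unit), and optionally `epochs`
#' (comma-separated epoch names; default all epochs), `window` (list
#' `(event, t0, t1)` or per-variable list of such windows, for sub-epoch
#' latency designs), `baseline` (mean baseline, default 10), `randomSign`
#' (draw the tuning sign at random per neuron, default TRUE, reflecting that
#' risk is encoded with both positive and negative slopes), `driftPhi`,
#' `driftSd`.
#'
#' @param config list of class descriptors
#' @param seed integer seed (baselines and tuning signs are drawn)
#' @return list of `NeuronSpec`; attribute `"manifest"` is a data.frame with
#'   the ground-truth class and variables per neuron
#' @export
makePopulation <- function(config, seed = NULL) {
  withSeed(seed, {
    specs <- list(); man <- list(); id <- 0L
    allEpochs <- paste(epochTable()$epoch, collapse = ",")
    for (ci in seq_along(config)) {
      cl <- config[[ci]]
      n <- cl$n
      vars <- cl$variables
      if (is.null(vars)) vars <- character(0)
      for (i in seq_len(n)) {
        id <- id + 1L
        base <- if (is.null(cl$baseline)) 10 else cl$baseline
        base <- base * exp(rnorm(1, 0, 0.15))
        tuning <- NULL
        signs <- numeric(0)
        if (length(vars)) {
          randomSign <- if (is.null(cl$randomSign)) TRUE else cl$randomSign
          signs <- if (randomSign) sample(c(-1, 1), length(vars), replace = TRUE)
                   else rep(1, length(vars))
          if (!is.null(cl$signs)) signs <- cl$signs
          if (!is.null(cl$window)) {
            w <- cl$window
            if (!is.null(w$event)) w <- rep(list(w), length(vars))
            tuning <- data.frame(
              variable = vars, gain = cl$gain * signs,
              epochs = NA_character_,
              event = vapply(w, `[[`, "", "event"),
              t0 = vapply(w, `[[`, 0, "t0"),
              t1 = vapply(w, `[[`, 0, "t1"))
          } else {
            eps <- if (is.null(cl$epochs)) allEpochs else cl$epochs
            tuning <- data.frame(variable = vars, gain = cl$gain * signs,
                                 epochs = eps)
          }
        }
        if (!is.null(cl$evoked) && cl$evoked != 0) {
          eps <- if (!is.null(cl$evokedEpochs)) cl$evokedEpochs
                 else if (!is.null(cl$epochs)) cl$epochs else allEpochs
          evRow <- data.frame(variable = "(evoked)", gain = cl$evoked,
                              epochs = eps)
          if (!is.null(tuning) && is.null(tuning$event)) {
            tuning <- rbind(tuning, evRow)
          } else if (is.null(tuning)) {
            tuning <- evRow
          } else {
            evRow$event <- NA_character_; evRow$t0 <- NA; evRow$t1 <- NA
            tuning <- rbind(tuning, evRow)
          }
        }
        specs[[id]] <- neuronSpec(id, base, tuning,
          driftPhi = if (is.null(cl$driftPhi)) 0 else cl$driftPhi,
          driftSd = if (is.null(cl$driftSd)) 0 else cl$driftSd)
        man[[id]] <- data.frame(
          neuron = id,
          class = if (is.null(cl$label)) paste0("class", ci) else cl$label,
          variables = paste(vars, collapse = ";"),
          gains = paste(if (length(vars)) cl$gain * signs else numeric(0),
                        collapse = ";"),
          baseline = base)
      }
    }
    attr(specs, "manifest") <- do.call(rbind, man)
    specs
  })
}

#' Default synthetic population mirroring reported coding prevalences
#'
#' Loosely reproduces the mix observed in prefrontal recordings: roughly
#' half the population carries object-risk tuning and a similar fraction
#' action-risk tuning, with heavy joint coding of value, choice and history
#' variables, plus untuned neurons.
#'
#' @param nPerClass scale factor: neurons per tuning class (default 10)
#' @param gain tuning gain, impulses/s per z unit (default 6)
#' @return config list for [makePopulation()]
#' @export
defaultPopulationConfig <- function(nPerClass = 10L, gain = 6,
                                    epochs = "Fix,Fix2,PreCue,Cue,PostFix",
                                    evoked = 8) {
  tuned <- function(label, vars)
    list(n = nPerClass, label = label, variables = vars, gain = gain,
         epochs = epochs, evoked = evoked)
  list(
    tuned("objectRiskA", "ObjectRiskA"),
    tuned("objectRiskB", "ObjectRiskB"),
    tuned("actionRisk", "ActionRiskL"),
    tuned("value", "ObjectValueA"),
    tuned("riskValueJoint", c("ObjectRiskA", "ObjectValueA")),
    tuned("choice", "ObjectChoice"),
    tuned("history", "LastRewardChoice"),
    list(n = 2L * nPerClass, label = "untuned", variables = NULL, gain = 0,
         epochs = epochs, evoked = evoked))
}

## z-score a covariate vector across trials; NA (burn-in) contributes 0.
zCovariate <- function(x) {
  mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mu) / s
  z[is.na(z)] <- 0
  z
}

## per-trial multiplicative drift factor exp(d_t), d_t AR(1)
driftFactors <- function(n, phi, sdv) {
  if (sdv == 0) return(rep(1, n))
  d <- numeric(n)
  d[1] <- rnorm(1, 0, sdv / sqrt(max(1 - phi^2, 1e-6)))
  for (i in 2:n) d[i] <- phi * d[i - 1] + rnorm(1, 0, sdv)
  exp(d)
}

#' Simulate epoch spike counts (and optionally spike times)
#'
#' For each neuron, per-trial firing rates are assembled per epoch as
#' baseline (times slow drift if configured) plus the sum of active tuning
#' gains multiplied by the z-scored covariates, floored at zero; counts are
#' Poisson over the 500-ms epoch. With `spikeTimes = TRUE`, a piecewise
#' homogeneous Poisson spike-time stream is generated over the whole trial
#' (baseline rate between tuned windows) and epoch counts are re-derived by
#' binning that stream, so counts and times are mutually consistent.
#'
#' @param session a [Session-class]
#' @param dv decision-variable table aligned to the session trials
#' @param specs list of `NeuronSpec` from [makePopulation()]
#' @param seed integer seed
#' @param spikeTimes logical: also generate event-aligned spike times
#' @return an [EpochCounts-class]; `rowData` carries the population manifest,
#'   `colData` the decision variables and trial covariates
#' @export
simulateSpikes <- function(session, dv, specs, seed = NULL,
                           spikeTimes = FALSE) {
  epochs <- epochTable()
  tr <- trials(session)
  nT <- nrow(tr); nN <- length(specs)
  stopifnot(nrow(dv) == nT)
  ev <- tr[, intersect(unique(epochs$event), names(tr))]
  zcache <- new.env(parent = emptyenv())
  getZ <- function(v) {
    if (v == "(evoked)") return(rep(1, nT))
    if (!is.null(zcache[[v]])) return(zcache[[v]])
    if (!v %in% names(dv)) stop("unknown tuning variable: ", v)
    zcache[[v]] <- zCovariate(dv[[v]])
    zcache[[v]]
  }
  withSeed(seed, {
    counts <- lapply(epochs$epoch, function(e) matrix(0L, nN, nT))
    names(counts) <- epochs$epoch
    stList <- if (spikeTimes) vector("list", nN) else NULL
    floorWarn <- 0L
    for (j in seq_len(nN)) {
      sp <- specs[[j]]
      drift <- driftFactors(nT, sp$driftPhi, sp$driftSd)
      et <- expandTuning(sp$tuning, epochs)
      ## per-epoch rate matrix contributions
      rates <- matrix(rep(sp$baseline * drift, length(epochs$epoch)),
                      nrow = nT)
      colnames(rates) <- epochs$epoch
      if (nrow(et)) {
        for (r in seq_len(nrow(et)))
          rates[, et$epoch[r]] <- rates[, et$epoch[r]] +
            et$gain[r] * et$frac[r] * getZ(et$variable[r])
      }
      floorWarn <- floorWarn + sum(rates < 0)
      rates[rates < 0] <- 0
      if (!spikeTimes) {
        for (e in epochs$epoch)
          counts[[e]][j, ] <- rpois(nT, rates[, e] * 0.5)
      } else {
        st <- simulateSpikeStream(sp, tr, epochs, getZ, drift)
        stList[[j]] <- st
        for (ei in seq_len(nrow(epochs))) {
          e <- epochs$epoch[ei]
          t0 <- tr[[epochs$event[ei]]] + epochs$offset[ei]
          t1 <- t0 + epochs$duration[ei]
          counts[[e]][j, ] <- vapply(seq_len(nT), function(i)
            sum(st[[i]] >= t0[i] & st[[i]] < t1[i]), integer(1))
        }
      }
    }
    man <- attr(specs, "manifest")
    if (is.null(man)) man <- data.frame(neuron = seq_len(nN))
    ec <- EpochCounts(counts, trialData = cbind(dv, reward = tr$reward),
                      neuronData = man, spikeTimes = stList, eventTimes = ev)
    metadata(ec)$flooredRates <- floorWarn
    if (floorWarn > 0.1 * nN * nT * nrow(epochs))
      warning("rate floored at 0 in ", floorWarn,
              " neuron-epoch-trials; consider higher baselines")
    ec
  })
}

## Piecewise-homogeneous Poisson spike stream for one neuron over each trial.
## Segments: tuned windows (event-anchored) plus baseline elsewhere, from
## t = 0 to 1 s past outcome. Tuning rows with epoch names activate over the
## full epoch window; rows with explicit (event, t0, t1) use that window.
simulateSpikeStream <- function(sp, tr, epochs, getZ, drift) {
  nT <- nrow(tr)
  tEnd <- tr$t_outcome + 1000
  wins <- NULL
  tu <- sp$tuning
  if (!is.null(tu) && nrow(tu)) {
    rows <- list()
    for (r in seq_len(nrow(tu))) {
      if (!is.na(tu$epochs[r])) {
        eps <- trimws(strsplit(tu$epochs[r], ",")[[1]])
        ei <- match(eps, epochs$epoch)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = tu$variable[r], gain = tu$gain[r],
          event = epochs$event[ei], t0 = epochs$offset[ei],
          t1 = epochs$offset[ei] + epochs$duration[ei])
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = tu$variable[r], gain = tu$gain[r],
          event = tu$event[r], t0 = tu$t0[r], t1 = tu$t1[r])
      }
    }
    wins <- do.call(rbind, rows)
  }
  out <- vector("list", nT)
  zmat <- if (!is.null(wins))
    vapply(wins$variable, function(v) getZ(v), numeric(nT)) else NULL
  for (i in seq_len(nT)) {
    brk <- c(0, tEnd[i])
    if (!is.null(wins)) {
      a <- as.numeric(tr[i, wins$event])
      brk <- c(brk, a + wins$t0, a + wins$t1)
    }
    brk <- sort(unique(pmin(pmax(brk, 0), tEnd[i])))
    spikes <- numeric(0)
    for (s in seq_len(length(brk) - 1L)) {
      lo <- brk[s]; hi <- brk[s + 1L]
      if (hi <= lo) next
      rate <- sp$baseline * drift[i]
      if (!is.null(wins)) {
        a <- as.numeric(tr[i, wins$event])
        mid <- (lo + hi) / 2
        act <- mid >= a + wins$t0 & mid < a + wins$t1
        if (any(act))
          rate <- rate + sum(wins$gain[act] * zmat[i, act])
      }
      rate <- max(0, rate)
      k <- rpois(1, rate * (hi - lo) / 1000)
      if (k > 0) spikes <- c(spikes, runif(k, lo, hi))
    }
    out[[i]] <- sort(spikes)
  }
  out
}
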