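## Task engine: baited dynamic-probability matching task.

#' Canonical table of the 11 task epochs
#'
#' Eleven fixed 500-ms analysis windows per trial, each anchored to a trial
#' event: before fixation (the control period), early/late fixation, pre-cue,
#' cue, post-fixation (after the saccade acquires the target), before/after
#' cue offset, and pre/early/late outcome.
#'
#' @return data.frame with columns `epoch`, `event`, `offset` (ms relative to
#'   the anchoring event) and `duration` (ms).
#' @export
epochTable <- function() {
  data.frame(
    epoch = c("PreFix", "Fix", "Fix2", "PreCue", "Cue", "PostFix",
              "PreCueOff", "PostCueOff", "PreOutc", "Outc", "Outc2"),
    event = c("t_fix_on", "t_fix_on", "t_fix_on", "t_cue_on", "t_cue_on",
              "t_tgt_fix", "t_cue_off", "t_cue_off", "t_outcome",
              "t_outcome", "t_outcome"),
    offset = c(-500, 0, 500, -500, 0, 0, -500, 0, -500, 0, 500),
    duration = 500,
    stringsAsFactors = FALSE)
}

#' Task configuration for the baited matching task
#'
#' Base reward probabilities are set block-wise; within a block the two
#' objects' base probabilities sum to `probSum` so that only relative
#' probability varies. Reward, once assigned (baited), persists until the
#' object is chosen, so instantaneous probability grows with the number of
#' consecutively unchosen trials (see [scheduledProbability()]).
#'
#' @param baseProbPairs optional matrix/data.frame of (P0_A, P0_B) pairs, one
#'   per block. Default: all pairs on the 0.05 grid within `[0.05, probSum - 0.05]`.
#' @param probSum constant sum of the two base probabilities (default 0.6).
#' @param blockLengthRange integer range of block lengths in trials
#'   (default `c(50, 150)`).
#' @param nBlocks number of blocks (default 8).
#' @param rewardMagnitude juice volume in ml on rewarded trials (default 0.7).
#' @param epochs epoch table, see [epochTable()].
#' @return a validated list of class `TaskConfig`
#' @export
taskConfig <- function(baseProbPairs = NULL, probSum = 0.6,
                       blockLengthRange = c(50L, 150L), nBlocks = 8L,
                       rewardMagnitude = 0.7, epochs = epochTable()) {
  if (is.null(baseProbPairs)) {
    p <- seq(0.05, probSum - 0.05, by = 0.05)
    p <- p[p >= 0.05 - 1e-9 & (probSum - p) >= 0.05 - 1e-9]
    baseProbPairs <- cbind(P0_A = p, P0_B = probSum - p)
  }
  baseProbPairs <- as.matrix(baseProbPairs)
  if (ncol(baseProbPairs) != 2L)
    stop("baseProbPairs must have two columns (P0_A, P0_B)")
  if (any(abs(rowSums(baseProbPairs) - probSum) > 1e-8))
    stop("every base-probability pair must sum to probSum")
  if (any(baseProbPairs < 0.05 - 1e-9 | baseProbPairs > 0.55 + 1e-9))
    stop("base probabilities must lie in [0.05, 0.55]")
  stopifnot(length(blockLengthRange) == 2L,
            blockLengthRange[1] >= 1, blockLengthRange[2] >= blockLengthRange[1],
            nBlocks >= 1, rewardMagnitude > 0)
  structure(list(baseProbPairs = baseProbPairs, probSum = probSum,
                 blockLengthRange = as.integer(blockLengthRange),
                 nBlocks = as.integer(nBlocks),
                 rewardMagnitude = rewardMagnitude, epochs = epochs),
            class = "TaskConfig")
}

#' Instantaneous reward probability under the baited schedule
#'
#' With base probability `P0` and `n` consecutive trials on which the object
#' was not chosen, the probability that a reward is available is
#' `P = 1 - (1 - P0)^(n + 1)`: the complement of all `n + 1` independent
#' assignment draws failing, because an assigned reward persists until the
#' object is chosen.
#'
#' @param P0 base probability, in (0, 1].
#' @param n non-negative integer count of consecutive unchosen trials.
#' @return instantaneous probability, monotone nondecreasing in `n`
#' @examples
#' scheduledProbability(0.05, 0)   # 0.05, the schedule floor
#' scheduledProbability(0.5, 1)    # 0.75
#' @export
scheduledProbability <- function(P0, n) {
  if (any(!is.finite(P0)) || any(P0 <= 0) || any(P0 > 1))
    stop("P0 must lie in (0, 1]")
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop("n must be a non-negative integer")
  pmin(1, 1 - (1 - P0)^(n + 1))
}

#' Objective variance risk of a binary reward
#'
#' Risk as the statistical variance of the two-outcome reward distribution
#' (magnitude `m` with probability `p`, zero otherwise):
#' `var = p (1 - p) m^2`. Symmetric about `p = 0.5`, where it attains its
#' maximum `m^2 / 4` — the characteristic inverted-U over probability.
#'
#' @param p reward probability in \[0, 1\].
#' @param m reward magnitude (ml), positive.
#' @return variance in ml^2
#' @examples
#' objectiveRisk(0.5, 0.7)  # 0.1225, the maximum for 0.7 ml
#' @export
objectiveRisk <- function(p, m = 0.7) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("m must be positive")
  p * (1 - p) * m^2
}

## Run expr with a private, restorable RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Balanced pseudorandom cue positions: shuffled blocks of 4 (2 L, 2 R).
balancedPositions <- function(n) {
  blocks <- ceiling(n / 4)
  pos <- unlist(lapply(seq_len(blocks),
                       function(i) sample(c("L", "L", "R", "R"))))
  pos[seq_len(n)]
}

## Draw trial event times (ms, trial-relative) from the task's timing
## intervals. Fixation onset is fixed at 500 ms so that the control window
## (PreFix) starts at 0.
drawEventTimes <- function(n) {
  t_fix_on <- rep(500, n)
  alert_on <- t_fix_on + runif(n, 1000, 2000)
  alert_off <- alert_on + runif(n, 700, 1000)
  t_cue_on <- alert_off + runif(n, 1400, 2000)
  t_tgt_fix <- t_cue_on + runif(n, 250, 750)
  t_cue_off <- t_tgt_fix + runif(n, 1000, 2000)
  t_outcome <- t_cue_off + runif(n, 700, 1200)
  data.frame(t_fix_on = t_fix_on, t_cue_on = round(t_cue_on),
             t_tgt_fix = round(t_tgt_fix), t_cue_off = round(t_cue_off),
             t_outcome = round(t_outcome))
}

#' Simulate one session of the baited matching task
#'
#' Implements reward assignment as a bait-and-persist state machine: on every
#' trial each unbaited object becomes baited with its base probability; a bait
#' persists until the object is chosen; choosing a baited object delivers the
#' reward and clears the bait. The closed-form schedule of
#' [scheduledProbability()] emerges as the marginal availability after `n`
#' unchosen trials. Base probabilities change block-wise; block lengths are
#' drawn uniformly from the configured range; cue positions are
#' counterbalanced pseudorandomly.
#'
#' @param config a `TaskConfig`, see [taskConfig()].
#' @param agent an agent object, see [randomAgent()], [logisticAgent()],
#'   [historyAgent()], [rlAgent()].
#' @param nTrials optional total trial count; block lengths are drawn until it
#'   is reached (last block truncated). Default: `nBlocks` drawn blocks.
#' @param seed integer seed; identical seed, config and agent give an
#'   identical session.
#' @return a [Session-class] object
#' @export
simulateSession <- function(config = taskConfig(), agent = randomAgent(),
                            nTrials = NULL, seed = NULL) {
  stopifnot(inherits(config, "TaskConfig"))
  withSeed(seed, {
    ## block structure
    blen <- integer(0); bpair <- integer(0); lastPair <- 0L
    npairs <- nrow(config$baseProbPairs)
    total <- 0L; b <- 0L
    repeat {
      b <- b + 1L
      len <- sample(seq(config$blockLengthRange[1], config$blockLengthRange[2]), 1L)
      pair <- sample(npairs, 1L)
      while (npairs > 1L && pair == lastPair) pair <- sample(npairs, 1L)
      lastPair <- pair
      blen <- c(blen, len); bpair <- c(bpair, pair); total <- total + len
      if (is.null(nTrials)) { if (b >= config$nBlocks) break }
      else if (total >= nTrials) break
    }
    n <- if (is.null(nTrials)) total else as.integer(nTrials)
    block_id <- rep(seq_along(blen), blen)[seq_len(n)]
    P0A <- config$baseProbPairs[bpair, 1][block_id]
    P0B <- config$baseProbPairs[bpair, 2][block_id]

    pos_A <- balancedPositions(n)
    ev <- drawEventTimes(n)

    st <- newAgentState(agent)
    baited <- c(A = FALSE, B = FALSE)
    nUn <- c(A = 0L, B = 0L)
    nUnA <- nUnB <- baitA <- baitB <- rewardV <- integer(n)
    choiceV <- actionV <- character(n)
    for (i in seq_len(n)) {
      ## bait draws (unbaited objects only)
      if (!baited["A"]) baited["A"] <- runif(1) < P0A[i]
      if (!baited["B"]) baited["B"] <- runif(1) < P0B[i]
      nUnA[i] <- nUn[["A"]]; nUnB[i] <- nUn[["B"]]
      baitA[i] <- as.integer(baited[["A"]])
      baitB[i] <- as.integer(baited[["B"]])

      ch <- agentChoose(agent, st, posA = pos_A[i])
      if (!is.character(ch) || !ch %in% c("A", "B"))
        stop("agent returned an invalid choice (must be 'A' or 'B')")
      choiceV[i] <- ch
      actionV[i] <- if ((ch == "A") == (pos_A[i] == "L")) "L" else "R"
      rew <- as.integer(baited[[ch]])
      rewardV[i] <- rew

      ## state updates
      baited[ch] <- FALSE
      nUn[ch] <- 0L
      other <- if (ch == "A") "B" else "A"
      nUn[other] <- nUn[other] + 1L
      st <- updateAgentState(agent, st, choice = ch,
                             action = actionV[i], reward = rew)
    }
    out <- data.frame(
      trial = seq_len(n), block_id = block_id, base_p_A = P0A, base_p_B = P0B,
      n_unchosen_A = nUnA, n_unchosen_B = nUnB,
      inst_p_A = scheduledProbability(P0A, nUnA),
      inst_p_B = scheduledProbability(P0B, nUnB),
      baited_A = baitA, baited_B = baitB, pos_A = pos_A,
      choice = choiceV, action = actionV, reward = rewardV,
      stringsAsFactors = FALSE)
    new("Session", trials = cbind(out, ev), config = unclass(config),
        agentId = agent$kind)
  })
}
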