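## Central S4 containers: Session (behavioral trials), WeightSet (fitted
## history weights), EpochCounts (spike counts in the 11 task epochs, on top
## of SummarizedExperiment).

#' Session: one simulated (or imported) behavioral session
#'
#' Ordered trial records of a single session of the baited matching task:
#' per-trial base and instantaneous reward probabilities, baiting state,
#' cue position, object choice, saccade action, reward, and event times.
#'
#' @slot trials data.frame with one row per trial (see [simulateSession()]
#'   for the column contract).
#' @slot config list of task parameters as produced by [taskConfig()].
#' @slot agentId character scalar identifying the generating agent.
#' @export
setClass("Session",
  representation(trials = "data.frame", config = "list", agentId = "character"))

setValidity("Session", function(object) {
  tr <- object@trials
  msgs <- character(0)
  req <- c("trial", "block_id", "base_p_A", "base_p_B", "n_unchosen_A",
           "n_unchosen_B", "inst_p_A", "inst_p_B", "baited_A", "baited_B",
           "pos_A", "choice", "action", "reward")
  miss <- setdiff(req, names(tr))
  if (length(miss))
    msgs <- c(msgs, paste("missing trial columns:", paste(miss, collapse = ", ")))
  if (nrow(tr) && !identical(tr$trial, seq_len(nrow(tr))))
    msgs <- c(msgs, "trial indices must be contiguous from 1")
  if (nrow(tr) && !all(tr$choice %in% c("A", "B")))
    msgs <- c(msgs, "choice must be 'A' or 'B'")
  if (nrow(tr) && !all(tr$action %in% c("L", "R")))
    msgs <- c(msgs, "action must be 'L' or 'R'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Session number of trials
#' @param x,object a `Session`
#' @export
setMethod("length", "Session", function(x) nrow(x@trials))

#' Extract the trial table of a Session
#' @param x a `Session`
#' @return data.frame of trials
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname trials
#' @export
setMethod("trials", "Session", function(x) x@trials)

#' Extract the task configuration of a Session
#' @param x a `Session`
#' @export
setGeneric("sessionConfig", function(x) standardGeneric("sessionConfig"))

#' @rdname sessionConfig
#' @export
setMethod("sessionConfig", "Session", function(x) x@config)

setMethod("show", "Session", function(object) {
  tr <- object@trials
  cat("Session of", nrow(tr), "trials,", length(unique(tr$block_id)),
      "blocks (agent:", object@agentId, ")\n")
  cat("  reward rate:", round(mean(tr$reward), 3),
      " choice A:", round(mean(tr$choice == "A"), 3), "\n")
})

#' WeightSet: fitted history weights from the choice-history logistic model
#'
#' Holds the recency weights for past rewards and past choices (one weight per
#' lag, `j = 1..N`) together with the bias term, as estimated by
#' [fitHistoryWeights()]. `domain` records whether the weights refer to object
#' choices (A vs B) or action choices (left vs right).
#'
#' @slot rewardWeights numeric, length `N`: weights of past reward deliveries.
#' @slot choiceWeights numeric, length `N`: weights of past choices.
#' @slot bias numeric scalar intercept.
#' @slot se list with numeric elements `reward`, `choice`, `bias`.
#' @slot domain `"object"` or `"action"`.
#' @slot diagnostics list (convergence, separation flag, n trials).
#' @export
setClass("WeightSet",
  representation(rewardWeights = "numeric", choiceWeights = "numeric",
                 bias = "numeric", se = "list", domain = "character",
                 diagnostics = "list"))

setValidity("WeightSet", function(object) {
  msgs <- character(0)
  if (length(object@rewardWeights) != length(object@choiceWeights))
    msgs <- c(msgs, "reward and choice weights must have equal length")
  if (!all(is.finite(object@rewardWeights)) ||
      !all(is.finite(object@choiceWeights)) || !is.finite(object@bias))
    msgs <- c(msgs, "weights must be finite")
  if (!object@domain %in% c("object", "action"))
    msgs <- c(msgs, "domain must be 'object' or 'action'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a WeightSet from raw weight vectors
#'
#' @param rewardWeights,choiceWeights numeric weight vectors (lag 1..N).
#' @param bias intercept, default 0.
#' @param se optional list of standard errors (`reward`, `choice`, `bias`).
#' @param domain `"object"` (default) or `"action"`.
#' @param diagnostics optional list of fit diagnostics.
#' @return a [WeightSet-class] object
#' @export
weightSet <- function(rewardWeights, choiceWeights = rep(0, length(rewardWeights)),
                      bias = 0, se = list(), domain = "object",
                      diagnostics = list()) {
  new("WeightSet", rewardWeights = as.numeric(rewardWeights),
      choiceWeights = as.numeric(choiceWeights), bias = as.numeric(bias),
      se = se, domain = domain, diagnostics = diagnostics)
}

#' @describeIn WeightSet number of lags N
#' @param x,object a `WeightSet`
#' @export
setMethod("length", "WeightSet", function(x) length(x@rewardWeights))

#' Accessors for WeightSet components
#' @param x a `WeightSet`
#' @export
setGeneric("rewardWeights", function(x) standardGeneric("rewardWeights"))
#' @rdname rewardWeights
#' @export
setMethod("rewardWeights", "WeightSet", function(x) x@rewardWeights)

#' @rdname rewardWeights
#' @export
setGeneric("choiceWeights", function(x) standardGeneric("choiceWeights"))
#' @rdname rewardWeights
#' @export
setMethod("choiceWeights", "WeightSet", function(x) x@choiceWeights)

#' @rdname rewardWeights
#' @export
setGeneric("biasWeight", function(x) standardGeneric("biasWeight"))
#' @rdname rewardWeights
#' @export
setMethod("biasWeight", "WeightSet", function(x) x@bias)

setMethod("show", "WeightSet", function(object) {
  cat("WeightSet (", object@domain, " domain), N = ",
      length(object@rewardWeights), " lags\n", sep = "")
  cat("  reward weights: ", paste(round(object@rewardWeights, 3), collapse = " "), "\n")
  cat("  choice weights: ", paste(round(object@choiceWeights, 3), collapse = " "), "\n")
  cat("  bias: ", round(object@bias, 3), "\n")
})

#' EpochCounts: spike counts per neuron, trial and task epoch
#'
#' Extends [SummarizedExperiment::SummarizedExperiment-class]: one assay per
#' task epoch (each a neurons x trials integer matrix), `colData` carrying the
#' per-trial covariates (decision variables, choices, event times), and
#' `rowData` carrying per-neuron metadata (ground-truth tuning where the data
#' are synthetic). Optional event-aligned spike times live in
#' `metadata(x)$spikeTimes` (a list: one element per neuron, each a list of
#' per-trial spike-time vectors in trial-relative ms).
#'
#' @export
setClass("EpochCounts", contains = "SummarizedExperiment")

#' Construct an EpochCounts object
#'
#' @param counts named list of neurons x trials count matrices, one per epoch,
#'   in canonical epoch order (see [epochTable()]).
#' @param trialData data.frame / DataFrame of per-trial covariates.
#' @param neuronData optional data.frame of per-neuron metadata.
#' @param spikeTimes optional list of per-neuron, per-trial spike-time vectors.
#' @param eventTimes optional data.frame of per-trial event times (ms).
#' @return an [EpochCounts-class] object
#' @export
EpochCounts <- function(counts, trialData, neuronData = NULL,
                        spikeTimes = NULL, eventTimes = NULL) {
  stopifnot(is.list(counts), length(counts) >= 1L)
  nn <- nrow(counts[[1L]])
  if (is.null(neuronData))
    neuronData <- data.frame(neuron = seq_len(nn))
  se <- SummarizedExperiment(
    assays = counts,
    colData = DataFrame(trialData),
    rowData = DataFrame(neuronData))
  obj <- new("EpochCounts", se)
  metadata(obj)$spikeTimes <- spikeTimes
  metadata(obj)$eventTimes <- eventTimes
  obj
}

setValidity("EpochCounts", function(object) {
  a <- assays(object)
  if (length(a) == 0L) return("at least one epoch assay required")
  bad <- vapply(a, function(m) any(m < 0, na.rm = TRUE), logical(1))
  if (any(bad)) return("spike counts must be non-negative")
  TRUE
})

#' Epoch names stored in an EpochCounts object
#' @param x an `EpochCounts`
#' @export
setGeneric("epochNames", function(x) standardGeneric("epochNames"))
#' @rdname epochNames
#' @export
setMethod("epochNames", "EpochCounts", function(x) assayNames(x))

#' Spike times stored in an EpochCounts object (or NULL)
#' @param x an `EpochCounts`
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname spikeTimes
#' @export
setMethod("spikeTimes", "EpochCounts", function(x) metadata(x)$spikeTimes)

setMethod("show", "EpochCounts", function(object) {
  cat("EpochCounts:", nrow(object), "neurons x", ncol(object), "trials,",
      length(assays(object)), "epochs\n")
  cat("  epochs:", paste(assayNames(object), collapse = ", "), "\n")
  if (!is.null(metadata(object)$spikeTimes))
    cat("  event-aligned spike times present\n")
})
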