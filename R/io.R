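## File I/O (session CSV, epoch-count CSV, weight JSON) and end-to-end
## pipeline orchestration.

.sessionCols <- c("trial", "block_id", "base_p_A", "base_p_B",
                  "n_unchosen_A", "n_unchosen_B", "inst_p_A", "inst_p_B",
                  "baited_A", "baited_B", "pos_A", "choice", "action",
                  "reward", "t_fix_on", "t_cue_on", "t_tgt_fix",
                  "t_cue_off", "t_outcome")

#' Write / read a session as CSV
#'
#' One row per trial; booleans encoded 0/1; header required. Reading
#' validates the schema and reports the offending column and row on
#' malformed values.
#'
#' @param session a [Session-class]
#' @param path file path
#' @return `readSessionCsv` returns a [Session-class] (with an empty config
#'   carrying only the reward magnitude attribute used downstream)
#' @export
writeSessionCsv <- function(session, path) {
  write.csv(trials(session)[, .sessionCols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname writeSessionCsv
#' @param rewardMagnitude reward volume used for objective risk (default 0.7)
#' @export
readSessionCsv <- function(path, rewardMagnitude = 0.7) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.sessionCols, names(tr))
  if (length(miss))
    stop("session file lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("baited_A", "baited_B", "reward")) {
    bad <- which(!tr[[col]] %in% c(0L, 1L))
    if (length(bad))
      stop("malformed boolean in column '", col, "', row ", bad[1])
  }
  for (col in c("choice")) {
    bad <- which(!tr[[col]] %in% c("A", "B"))
    if (length(bad))
      stop("malformed value in column 'choice', row ", bad[1])
  }
  cfg <- taskConfig(rewardMagnitude = rewardMagnitude)
  new("Session", trials = tr, config = unclass(cfg), agentId = "file")
}

#' Write / read epoch counts in long CSV format
#'
#' Long format `neuron,trial,epoch,count`.
#'
#' @param ec an [EpochCounts-class]
#' @param path file path
#' @export
writeCountsCsv <- function(ec, path) {
  eps <- epochNames(ec)
  rows <- lapply(eps, function(e) {
    m <- assay(ec, e)
    data.frame(neuron = rep(seq_len(nrow(m)), ncol(m)),
               trial = rep(seq_len(ncol(m)), each = nrow(m)),
               epoch = e, count = as.vector(m))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCountsCsv
#' @param trialData optional per-trial covariates to attach as `colData`
#' @export
readCountsCsv <- function(path, trialData = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("neuron", "trial", "epoch", "count"), names(d))
  if (length(miss))
    stop("counts file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(d$count) | d$count < 0 | d$count != floor(d$count))
  if (length(bad))
    stop("malformed count in row ", bad[1])
  eps <- unique(d$epoch)
  nN <- max(d$neuron); nT <- max(d$trial)
  counts <- lapply(eps, function(e) {
    m <- matrix(0L, nN, nT)
    sub <- d[d$epoch == e, ]
    m[cbind(sub$neuron, sub$trial)] <- sub$count
    m
  })
  names(counts) <- eps
  if (is.null(trialData)) trialData <- data.frame(trial = seq_len(nT))
  EpochCounts(counts, trialData = trialData)
}

#' Write / read a WeightSet as JSON
#'
#' @param w a [WeightSet-class]
#' @param path file path
#' @export
writeWeightsJson <- function(w, path) {
  jsonlite::write_json(
    list(domain = w@domain, rewardWeights = rewardWeights(w),
         choiceWeights = choiceWeights(w), bias = biasWeight(w)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeWeightsJson
#' @export
readWeightsJson <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  weightSet(d$rewardWeights, d$choiceWeights, d$bias, domain = d$domain)
}

#' Pipeline configuration
#'
#' Bundles the settings of every pipeline stage with per-stage seeds derived
#' from a single root seed.
#'
#' @param seed root seed; per-stage seeds are derived deterministically
#' @param nTrials session length (default 600)
#' @param agent generative agent (default a risk-seeking logistic agent with
#'   exponentially decaying weights)
#' @param task task configuration
#' @param population population config for [makePopulation()]
#' @param spikeTimes generate spike times and run sliding-window analyses
#' @param decoding run decoding analyses
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(seed = 1L, nTrials = 600L,
                           agent = logisticAgent(1.5 * exp(-(1:10) / 2),
                                                 0.8 * exp(-(1:10) / 2),
                                                 betaValue = 20, betaRisk = 6),
                           task = taskConfig(),
                           population = defaultPopulationConfig(),
                           spikeTimes = FALSE, decoding = TRUE) {
  stageSeeds <- seed * 1000L + c(session = 1L, population = 2L, spikes = 3L,
                                 analysis = 4L, decode = 5L)
  structure(list(seed = seed, stageSeeds = stageSeeds, nTrials = nTrials,
                 agent = agent, task = task, population = population,
                 spikeTimes = spikeTimes, decoding = decoding),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a session, fits history weights (object and action domains),
#' builds decision variables, fits and compares choice models, simulates a
#' spiking population, runs the epoch-regression battery and (optionally)
#' decoding, and returns a report bundle. With `outDir` set, persists the
#' session, decision variables, weights, counts and summary tables.
#'
#' @param config a `PipelineConfig`
#' @param outDir optional output directory
#' @return list: `session`, `weights`, `actionWeights`, `dv`, `choiceFit`,
#'   `modelComparison`, `matching`, `counts`, `taskRelated`, `riskSummary`,
#'   `decoding` (when enabled), `manifest`
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  ss <- config$stageSeeds
  session <- simulateSession(config$task, config$agent,
                             nTrials = config$nTrials, seed = ss[["session"]])
  w <- fitHistoryWeights(buildHistoryMatrix(session, domain = "object"))
  wAct <- fitHistoryWeights(buildHistoryMatrix(session, domain = "action"))
  dv <- decisionVariables(session, w, wAct)
  choiceFit <- fitChoiceModel(dv, session)
  dv <- utility(dv, choiceFit)
  comparison <- compareChoiceModels(session)
  matching <- matchingAnalysis(session)
  specs <- makePopulation(config$population, seed = ss[["population"]])
  ec <- simulateSpikes(session, dv, specs, seed = ss[["spikes"]],
                       spikeTimes = config$spikeTimes)
  rel <- taskRelatedness(ec)
  res <- analyzeResponses(ec, "eq10")
  riskNeurons <- sort(unique(res$neuron[res$codesRisk]))
  riskSummary <- list(
    nNeurons = nrow(ec),
    nTaskRelated = sum(rel$taskRelatedNeuron),
    nRiskNeurons = length(riskNeurons),
    riskNeurons = riskNeurons)
  decodingRes <- NULL
  if (config$decoding) {
    pp <- buildPseudoPopulation(ec, "ObjectRiskA", "PreCue")
    real <- decodePopulation(pp, "svm", matchings = 10L,
                             seed = ss[["decode"]])
    decodingRes <- list(objectRiskA = real)
  }
  report <- list(session = session, weights = w, actionWeights = wAct,
                 dv = dv, choiceFit = choiceFit, modelComparison = comparison,
                 matching = matching, counts = ec, taskRelated = rel,
                 responses = res, riskSummary = riskSummary,
                 decoding = decodingRes,
                 manifest = attr(specs, "manifest"))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSessionCsv(session, file.path(outDir, "session.csv"))
    write.csv(dv, file.path(outDir, "decision_variables.csv"),
              row.names = FALSE)
    writeWeightsJson(w, file.path(outDir, "weights_object.json"))
    writeWeightsJson(wAct, file.path(outDir, "weights_action.json"))
    writeCountsCsv(ec, file.path(outDir, "epoch_counts.csv"))
    write.csv(comparison, file.path(outDir, "model_comparison.csv"),
              row.names = FALSE)
  }
  report
}
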