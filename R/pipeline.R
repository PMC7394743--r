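#' Participant-flow arithmetic
#'
#' Applies named exclusion counts to the number of eligible participants and
#' returns the flow ledger. The analyzed count is eligible minus the sum of
#' exclusions; negative intermediate counts are an error.
#'
#' @param eligible number of eligible participants.
#' @param exclusions named integer vector of exclusion counts by reason.
#' @return a data.frame with one row per stage (\code{eligible}, one per
#'   exclusion reason, \code{analyzed}) and columns \code{stage},
#'   \code{count}, \code{remaining}.
#' @examples
#' participantFlow(554, c(discontinued_fmri = 17,
#'                        insufficient_quality = 251,
#'                        missing_clinical = 64))
#' @export
participantFlow <- function(eligible, exclusions = integer()) {
  stopifnot(eligible >= 0, all(exclusions >= 0))
  remaining <- eligible - cumsum(c(0, as.numeric(exclusions)))
  if (any(remaining < 0)) stop("exclusions exceed eligible participants")
  data.frame(
    stage = c("eligible", names(exclusions), "analyzed"),
    count = c(eligible, as.integer(exclusions),
              eligible - sum(exclusions)),
    remaining = c(remaining, eligible - sum(exclusions))
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> denoise -> connectivity -> MST -> group models
#' under one seed: generates each subject's series and motion trace, applies
#' the temporal denoising chain with its gates, computes the five network
#' outcomes for every subject that passes, fits the per-risk-factor and
#' combined models, and accounts for every subject in a run manifest. A
#' subject failing a gate is excluded with a single primary reason, never
#' fatal.
#'
#' @param config a [simulationConfig()] object.
#' @param outDir optional directory; when given, writes
#'   \code{outcomes.csv}, \code{models.csv}, \code{flow.csv} and
#'   \code{manifest.json} with stable names.
#' @param regionSets region sets for the regional outcomes
#'   (default [powerRegionSets()]).
#' @param nDrop,fdThresholdMm,motionThresholdMm,minSeconds,lowHz,highHz
#'   denoising parameters passed to [denoiseSubject()].
#' @return a list: \code{manifest} (config echo, seed, per-subject gate
#'   records, counts), \code{outcomes} (data.frame of per-subject network
#'   outcomes merged with covariates), \code{models} (tidy results of
#'   [riskFactorModels()], \code{NULL} when no subject passed), \code{flow}
#'   (participant-flow table).
#' @export
runPipeline <- function(config, outDir = NULL,
                        regionSets = powerRegionSets(),
                        nDrop = 15L, fdThresholdMm = 0.2,
                        motionThresholdMm = 0.2, minSeconds = 240,
                        lowHz = 0.01, highHz = 0.08) {
  stopifnot(inherits(config, "SimulationConfig"))
  covariates <- genCovariates(config)
  base <- genBaseCorrelation(config)
  z <- .standardize(covariates[[config$plantedCovariate]])
  n <- config$nSubjects
  gateRecords <- vector("list", n)
  outcomeRows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- covariates$id[i]
    sub <- genSubjectTimeseries(base, z[i], config,
                                seed = .deriveSeed(config$seed, 1000L + i))
    mot <- genMotionTrace(config, seed = .deriveSeed(config$seed, 2000L + i))
    den <- denoiseSubject(sub$series, mot$motion, tissue = sub$tissue,
                          nDrop = nDrop, fdThresholdMm = fdThresholdMm,
                          motionThresholdMm = motionThresholdMm,
                          minSeconds = minSeconds,
                          lowHz = lowHz, highHz = highHz)
    gateRecords[[i]] <- list(id = id, pass = den$qc$pass,
                             reason = den$qc$reason,
                             nCensored = den$qc$nCensored,
                             retainedSeconds = den$qc$retainedSeconds)
    if (den$qc$pass) {
      outcomeRows[[i]] <- cbind(covariates[i, , drop = FALSE],
                                networkOutcomes(den$series, regionSets))
    }
  }
  outcomes <- do.call(rbind, outcomeRows)
  reasons <- vapply(gateRecords,
                    function(g) if (g$pass) NA_character_ else g$reason,
                    character(1))
  exclusions <- table(factor(reasons[!is.na(reasons)]))
  flow <- participantFlow(n, stats::setNames(as.integer(exclusions),
                                             names(exclusions)))
  models <- NULL
  analyzed <- sum(vapply(gateRecords, `[[`, logical(1), "pass"))
  if (!is.null(outcomes) && nrow(outcomes) > 12L) {
    models <- riskFactorModels(outcomes)
  }
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    version = as.character(utils::packageVersion("mstfc")),
    subjects = gateRecords,
    counts = list(eligible = n, excluded = n - analyzed,
                  analyzed = analyzed),
    statsStage = if (is.null(models))
      "skipped: too few analyzable subjects" else "fitted"
  )
  res <- list(manifest = manifest, outcomes = outcomes, models = models,
              flow = flow)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(outcomes)) {
      utils::write.csv(outcomes, file.path(outDir, "outcomes.csv"),
                       row.names = FALSE)
    }
    if (!is.null(models)) {
      utils::write.csv(models, file.path(outDir, "models.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(flow, file.path(outDir, "flow.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Participant-flow ledger from a run manifest
#'
#' Recounts the per-subject gate records of a [runPipeline()] manifest into a
#' table of exclusion reasons, and checks the manifest invariant
#' analyzed + sum(exclusions) = eligible.
#'
#' @param manifest the \code{manifest} element of a [runPipeline()] result.
#' @return a data.frame as returned by [participantFlow()].
#' @export
flowLedger <- function(manifest) {
  reasons <- vapply(manifest$subjects,
                    function(g) if (isTRUE(g$pass)) NA_character_
                    else g$reason, character(1))
  excl <- table(factor(reasons[!is.na(reasons)]))
  flow <- participantFlow(manifest$counts$eligible,
                          stats::setNames(as.integer(excl), names(excl)))
  analyzed <- flow$count[flow$stage == "analyzed"]
  if (analyzed != manifest$counts$analyzed) {
    stop("manifest invariant violated: analyzed != eligible - exclusions")
  }
  flow
}
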