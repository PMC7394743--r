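#' One replicate of the planted-effect study
#'
#' Simulates a cohort with a planted standardized effect of age on
#' connectivity scaling, computes each subject's global MST strength through
#' the connectivity and spanning-tree stages, and fits the adjusted linear
#' model of strength on age (covariates: center, gender, IQ). This is the
#' package's calibration harness: generation feeds the analysis directly,
#' without the temporal-denoising stage, because the clean generation path
#' contains no artefacts for it to remove (denoising is validated
#' separately).
#'
#' @param seed replicate seed.
#' @param nSubjects cohort size (default 222).
#' @param gamma planted standardized effect (default 0.18; 0 gives a null
#'   cohort).
#' @param nRegions parcellation size for the simulation (default 60; the
#'   spanning-tree statistics behave identically at reduced node count and
#'   the replicate cost drops sharply).
#' @param nVolumes volumes per subject (default 238).
#' @param base optional precomputed base [ConnectivityMatrix-class] (shared
#'   across replicates for speed).
#' @return a list: \code{beta} (standardized coefficient of age on
#'   strength), \code{p} (its two-sided p-value), \code{n}.
#' @export
plantedEffectStudy <- function(seed, nSubjects = 222L, gamma = 0.18,
                               nRegions = 60L, nVolumes = 238L,
                               base = NULL) {
  config <- simulationConfig(nSubjects = nSubjects, nRegions = nRegions,
                             nVolumes = nVolumes,
                             plantedGamma = gamma,
                             tissueConfound = FALSE, motionSpikeProb = 0,
                             seed = seed)
  if (is.null(base)) base <- genBaseCorrelation(config)
  covariates <- genCovariates(config)
  z <- .standardize(covariates[[config$plantedCovariate]])
  baseM <- connValues(base)
  p <- nrow(baseM)
  strength <- numeric(nSubjects)
  for (i in seq_len(nSubjects)) {
    # same draws as genSubjectTimeseries, without the S4 container overhead
    set.seed(.deriveSeed(seed, 1000L + i))
    modulator <- gamma * z[i] + sqrt(1 - gamma^2) * stats::rnorm(1)
    target <- .subjectTargetCorrelation(baseM, modulator, config$fcModSd)
    ch <- tryCatch(chol(target), error = function(e) {
      chol(.repairPSD(target, tol = Inf) + diag(1e-10, p))
    })
    x <- matrix(stats::rnorm(nVolumes * p), nVolumes, p) %*% ch
    strength[i] <- mean(.kruskalCore(stats::cor(x))$weight)
  }
  d <- cbind(covariates, strength = strength)
  fit <- fitOutcomeModel(d, "strength", "age")
  co <- fit$coefficients[fit$coefficients$term == "age", ]
  list(beta = co$beta_std, p = co$p, n = fit$n)
}

#' Replicate the planted-effect study across seeds
#'
#' Runs [plantedEffectStudy()] over \code{nSeeds} replicate seeds derived
#' from a master seed and summarizes recovery of the planted effect.
#'
#' @param nSeeds number of replicates.
#' @param masterSeed master seed from which replicate seeds are derived.
#' @param alpha test level for the rejection rate (default 0.05).
#' @inheritParams plantedEffectStudy
#' @return a list: \code{meanBeta}, \code{positiveRate} (share of replicates
#'   with beta > 0), \code{rejectionRate} (share with p < alpha),
#'   \code{betas}, \code{ps}.
#' @export
recoveryStudy <- function(nSeeds = 100L, masterSeed = 1L, gamma = 0.18,
                          nSubjects = 222L, nRegions = 60L,
                          nVolumes = 238L, alpha = 0.05) {
  cfg <- simulationConfig(nSubjects = nSubjects, nRegions = nRegions,
                          nVolumes = nVolumes, plantedGamma = gamma,
                          tissueConfound = FALSE, motionSpikeProb = 0,
                          seed = masterSeed)
  base <- genBaseCorrelation(cfg)
  betas <- numeric(nSeeds)
  ps <- numeric(nSeeds)
  for (k in seq_len(nSeeds)) {
    rep <- plantedEffectStudy(.deriveSeed(masterSeed, 5000L + k),
                              nSubjects = nSubjects, gamma = gamma,
                              nRegions = nRegions, nVolumes = nVolumes,
                              base = base)
    betas[k] <- rep$beta
    ps[k] <- rep$p
  }
  list(meanBeta = mean(betas), positiveRate = mean(betas > 0),
       rejectionRate = mean(ps < alpha), betas = betas, ps = ps)
}
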