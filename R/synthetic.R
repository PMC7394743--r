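#' Simulation configuration for a synthetic resting-state cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults emulate
#' the acquisition and cohort actually analysed: 264 Power regions, 238
#' volumes at TR = 2 s, and covariate marginals matching the included-sample
#' demographics (age 71.2 +/- 4.9 truncated at 65, IQ 105 +/- 12.2,
#' MMSE 28.7 +/- 1.4 with a floor of 24, Barthel 98.4 +/- 4.8, 63% male,
#' 30% Berlin, 5% alcohol misuse, 5% depression, 24% TIA/stroke history,
#' 86% ASA-unhealthy).
#'
#' The planted effect ties a covariate to connectivity: each subject's
#' off-diagonal correlations are scaled by \code{1 + fcModSd * x} where the
#' unit-variance modulator \code{x = gamma * z + sqrt(1 - gamma^2) * eta}
#' mixes the subject's standardized covariate value \code{z} with independent
#' noise \code{eta}. The standardized slope of the connectivity scaling on the
#' covariate is therefore exactly \code{gamma}, so a downstream regression of
#' global MST strength on the covariate recovers \code{gamma} as its
#' standardized coefficient (up to sampling attenuation).
#'
#' @param nSubjects number of subjects to simulate.
#' @param nRegions number of parcellation regions (default 264).
#' @param nVolumes number of acquired volumes (default 238).
#' @param trSeconds repetition time in seconds (default 2).
#' @param nModules number of blocks in the block-structured base correlation
#'   (default 12, roughly the number of canonical resting-state networks).
#' @param withinBlockR correlation within a block, in [0, 1) (default 0.5).
#' @param betweenBlockR correlation between blocks, in [0, withinBlockR)
#'   (default 0.1).
#' @param plantedCovariate covariate name whose standardized value drives the
#'   connectivity modulator (default \code{"age"}).
#' @param plantedGamma standardized slope of the connectivity scaling on the
#'   planted covariate, in [0, 1) (default 0 = null cohort).
#' @param fcModSd amplitude of the subject-level connectivity modulation
#'   (default 0.1: subjects differ by ~10\% in overall coupling, a typical
#'   scale of inter-individual connectivity variability).
#' @param motionSpikeProb per-volume probability of a motion spike
#'   (default 0.05).
#' @param tissueConfound logical; add shared low-frequency WM/CSF/global
#'   confound signals to all regions (default TRUE).
#' @param confoundSd amplitude (SD) of each tissue confound relative to the
#'   unit-variance neural signal (default 0.5).
#' @param ageMean,ageSd,ageMin age distribution (years), truncated below at
#'   the inclusion minimum.
#' @param iqMean,iqSd premorbid IQ distribution.
#' @param mmseMean,mmseSd,mmseMin MMSE distribution; scores below
#'   \code{mmseMin} are excluded by design (cognitive-impairment screen),
#'   ceiling 30.
#' @param barthelMean,barthelSd Barthel Index distribution, clamped to
#'   [0, 100].
#' @param pMale,pBerlin,pAlcohol,pDepression,pTiaStroke,pAsaUnhealthy
#'   prevalences of the binary covariates.
#' @param seed integer RNG seed for the whole cohort.
#' @return a list of class \code{"SimulationConfig"}.
#' @examples
#' cfg <- simulationConfig(nSubjects = 10, nRegions = 20, nModules = 4,
#'                         seed = 1)
#' cov <- genCovariates(cfg)
#' summary(cov$age)
#' @export
simulationConfig <- function(nSubjects,
                             nRegions = 264L,
                             nVolumes = 238L,
                             trSeconds = 2,
                             nModules = 12L,
                             withinBlockR = 0.5,
                             betweenBlockR = 0.1,
                             plantedCovariate = "age",
                             plantedGamma = 0,
                             fcModSd = 0.1,
                             motionSpikeProb = 0.05,
                             tissueConfound = TRUE,
                             confoundSd = 0.5,
                             ageMean = 71.2, ageSd = 4.9, ageMin = 65,
                             iqMean = 105, iqSd = 12.2,
                             mmseMean = 28.7, mmseSd = 1.4, mmseMin = 24,
                             barthelMean = 98.4, barthelSd = 4.8,
                             pMale = 0.63, pBerlin = 0.30,
                             pAlcohol = 0.05, pDepression = 0.05,
                             pTiaStroke = 0.24, pAsaUnhealthy = 0.86,
                             seed = 1L) {
  stopifnot(nSubjects >= 1, nRegions >= 2, nVolumes >= 2, trSeconds > 0)
  if (nModules < 1L || nModules > nRegions) {
    stop("'nModules' must divide the regions into non-empty blocks")
  }
  if (!(withinBlockR >= 0 && withinBlockR < 1) ||
      !(betweenBlockR >= 0 && betweenBlockR < 1)) {
    stop("block correlations must lie in [0, 1)")
  }
  if (withinBlockR < betweenBlockR) {
    stop("'withinBlockR' must be >= 'betweenBlockR'")
  }
  if (plantedGamma < 0 || plantedGamma >= 1) {
    stop("'plantedGamma' must lie in [0, 1)")
  }
  if (motionSpikeProb < 0 || motionSpikeProb > 1) {
    stop("'motionSpikeProb' must be a probability")
  }
  cfg <- list(
    nSubjects = as.integer(nSubjects), nRegions = as.integer(nRegions),
    nVolumes = as.integer(nVolumes), trSeconds = trSeconds,
    nModules = as.integer(nModules), withinBlockR = withinBlockR,
    betweenBlockR = betweenBlockR, plantedCovariate = plantedCovariate,
    plantedGamma = plantedGamma, fcModSd = fcModSd,
    motionSpikeProb = motionSpikeProb, tissueConfound = tissueConfound,
    confoundSd = confoundSd,
    ageMean = ageMean, ageSd = ageSd, ageMin = ageMin,
    iqMean = iqMean, iqSd = iqSd,
    mmseMean = mmseMean, mmseSd = mmseSd, mmseMin = mmseMin,
    barthelMean = barthelMean, barthelSd = barthelSd,
    pMale = pMale, pBerlin = pBerlin, pAlcohol = pAlcohol,
    pDepression = pDepression, pTiaStroke = pTiaStroke,
    pAsaUnhealthy = pAsaUnhealthy,
    seed = as.integer(seed)
  )
  class(cfg) <- "SimulationConfig"
  cfg
}

# Deterministic per-purpose subseed (Lehmer step keeps it inside 32-bit ints).
.deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k)) %% 2147483629)
}

# Truncated-normal draws by rejection; degenerate sd = 0 allowed when the
# point mass respects the bounds.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("'sd' must be non-negative")
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("impossible truncation bounds: mean outside [lower, upper] with sd = 0")
    }
    return(rep(mean, n))
  }
  if (lower >= upper) stop("impossible truncation bounds")
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort covariate table
#'
#' Draws one row per subject with the demographic and risk-factor covariates
#' used by the group-level models: study center, gender, age, premorbid IQ,
#' alcohol misuse, MMSE, depression, Barthel Index, TIA/stroke history and
#' ASA physical-status dichotomy. Marginals follow the configuration;
#' continuous scores are truncated to their admissible ranges (age at the
#' inclusion minimum, MMSE at the cognitive screen floor, Barthel at
#' [0, 100]).
#'
#' @param config a [simulationConfig()] object.
#' @return a data.frame with one row per subject and columns
#'   \code{id, center, gender, age, iq, alcohol_misuse, mmse, depression,
#'   barthel, tia_stroke, asa_unhealthy}. Binary variables are 0/1 integers
#'   (\code{center}: 1 = Berlin; \code{gender}: 1 = male).
#' @export
genCovariates <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$nSubjects
  set.seed(.deriveSeed(config$seed, 101L))
  data.frame(
    id = sprintf("S%04d", seq_len(n)),
    center = as.integer(stats::runif(n) < config$pBerlin),
    gender = as.integer(stats::runif(n) < config$pMale),
    age = .rtruncnorm(n, config$ageMean, config$ageSd, lower = config$ageMin),
    iq = .rtruncnorm(n, config$iqMean, config$iqSd),
    alcohol_misuse = as.integer(stats::runif(n) < config$pAlcohol),
    mmse = as.integer(round(.rtruncnorm(n, config$mmseMean, config$mmseSd,
                                        lower = config$mmseMin - 0.49,
                                        upper = 30.49))),
    depression = as.integer(stats::runif(n) < config$pDepression),
    barthel = as.integer(round(.rtruncnorm(n, config$barthelMean,
                                           config$barthelSd,
                                           lower = -0.49, upper = 100.49))),
    tia_stroke = as.integer(stats::runif(n) < config$pTiaStroke),
    asa_unhealthy = as.integer(stats::runif(n) < config$pAsaUnhealthy),
    stringsAsFactors = FALSE
  )
}

#' Block-structured base correlation matrix
#'
#' Builds the cohort-level target correlation: regions are split into
#' \code{nModules} contiguous blocks as equal in size as possible, entries are
#' \code{withinBlockR} inside a block and \code{betweenBlockR} across blocks,
#' diagonal 1. The result is checked for positive semidefiniteness and
#' repaired by eigenvalue clipping if numerically indefinite.
#'
#' @param config a [simulationConfig()] object.
#' @return a [ConnectivityMatrix-class] holding the base correlation.
#' @export
genBaseCorrelation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  p <- config$nRegions
  block <- sort(rep_len(seq_len(config$nModules), p))
  m <- matrix(config$betweenBlockR, p, p)
  same <- outer(block, block, "==")
  m[same] <- config$withinBlockR
  diag(m) <- 1
  m <- .repairPSD(m)
  connectivityMatrix(m)
}

# Clip negative eigenvalues at 0, rebuild, rescale to unit diagonal.
# Errors if the matrix is too far from PSD to be a credible correlation
# target (smallest eigenvalue < -1e-8 relative to the largest).
.repairPSD <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) >= 0) return(m)
  if (min(lam) < -tol * max(abs(lam), 1)) {
    stop("matrix is not positive semidefinite and cannot be safely repaired")
  }
  lam[lam < 0] <- 0
  m2 <- ev$vectors %*% (lam * t(ev$vectors))
  m2 <- stats::cov2cor(m2)
  (m2 + t(m2)) / 2
}

# Subject-specific target correlation: off-diagonals scaled by (1 + c*x).
# Errors if the scaling pushes any |r| to 1 or beyond.
.subjectTargetCorrelation <- function(base, modulator, fcModSd) {
  f <- 1 + fcModSd * modulator
  m <- base * f
  diag(m) <- 1
  off <- m[upper.tri(m)]
  if (any(abs(off) >= 1)) {
    stop("connectivity scaling pushes |r| >= 1; reduce 'fcModSd' or block correlations")
  }
  m
}

#' Generate one subject's BOLD ROI time series
#'
#' Samples \code{nVolumes} volumes from a zero-mean multivariate normal whose
#' correlation is the base matrix with off-diagonals multiplied by
#' \code{1 + fcModSd * x}, where \code{x} is the subject's unit-variance
#' connectivity modulator (see [simulationConfig()]). The scaled matrix is
#' re-repaired to positive semidefiniteness before sampling. When
#' \code{config$tissueConfound} is TRUE, three shared low-frequency nuisance
#' signals (white matter, CSF, global) are added to every region with a
#' per-subject gain, giving the 36-parameter regression real structure to
#' remove.
#'
#' @param base a [ConnectivityMatrix-class] from [genBaseCorrelation()].
#' @param zCov the subject's standardized planted-covariate value.
#' @param config a [simulationConfig()] object.
#' @param seed integer seed for this subject's draws.
#' @param modulator optional precomputed unit-variance modulator x; when NULL
#'   it is drawn as \code{gamma * zCov + sqrt(1 - gamma^2) * eta}.
#' @return a list with elements \code{series} (an [RoiTimeSeries-class]),
#'   \code{tissue} (volumes x 3 matrix of WM/CSF/global signals, all zero when
#'   confounds are disabled), \code{modulator} (the x used) and \code{target}
#'   (the subject's target correlation matrix).
#' @export
genSubjectTimeseries <- function(base, zCov, config, seed,
                                 modulator = NULL) {
  stopifnot(inherits(config, "SimulationConfig"),
            is(base, "ConnectivityMatrix"))
  set.seed(seed)
  g <- config$plantedGamma
  if (is.null(modulator)) {
    modulator <- g * zCov + sqrt(1 - g^2) * stats::rnorm(1)
  }
  target <- .subjectTargetCorrelation(connValues(base), modulator,
                                      config$fcModSd)
  p <- nrow(target)
  tt <- config$nVolumes
  # fast path: a successful Cholesky proves positive definiteness; only
  # indefinite targets go through the eigenvalue-clipping repair
  ch <- tryCatch(chol(target), error = function(e) NULL)
  if (is.null(ch)) {
    target <- .repairPSD(target, tol = Inf)  # clip indefiniteness silently
    ch <- chol(target + diag(1e-10, p))
  }
  z <- matrix(stats::rnorm(tt * p), tt, p)
  values <- t(z %*% ch)  # regions x volumes
  tissue <- matrix(0, tt, 3L,
                   dimnames = list(NULL, c("wm", "csf", "global")))
  if (isTRUE(config$tissueConfound)) {
    tsec <- (seq_len(tt) - 1L) * config$trSeconds
    for (k in 1:3) {
      f1 <- stats::runif(1, 0.01, 0.05)
      f2 <- stats::runif(1, 0.01, 0.05)
      ph <- stats::runif(2, 0, 2 * pi)
      raw <- sin(2 * pi * f1 * tsec + ph[1]) + sin(2 * pi * f2 * tsec + ph[2])
      tissue[, k] <- config$confoundSd * raw / stats::sd(raw)
    }
    gain <- stats::runif(1, 0.5, 1.5)
    values <- values + gain * matrix(rowSums(tissue), p, tt, byrow = TRUE)
  }
  list(series = roiTimeSeries(values, trSeconds = config$trSeconds),
       tissue = tissue, modulator = modulator, target = target)
}

#' Generate a synthetic motion trace
#'
#' Produces six rigid-body parameter columns per volume: a smooth
#' low-amplitude drift (bounded random-walk increments) plus, at spike
#' volumes, persistent translation jumps of 0.4-0.8 mm. By construction the
#' framewise displacement is below 0.2 mm at every non-spike volume and above
#' 0.2 mm at every spike volume, so motion scrubbing can be verified exactly.
#'
#' @param config a [simulationConfig()] object (uses \code{nVolumes} and
#'   \code{motionSpikeProb}).
#' @param seed integer seed for this subject's motion draws.
#' @return a list with \code{motion} (a [MotionRecord-class]) and
#'   \code{spikeVolumes} (integer indices, volumes 2..T, where spikes were
#'   planted).
#' @export
genMotionTrace <- function(config, seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  tt <- config$nVolumes
  if (tt < 2L) stop("need at least 2 volumes for a motion trace")
  set.seed(seed)
  # drift increments: |FD| <= 3*0.02 + 50*3*0.0003 = 0.105 mm < 0.2 mm
  dRot <- matrix(stats::runif(3L * tt, -3e-4, 3e-4), tt, 3L)
  dTrans <- matrix(stats::runif(3L * tt, -0.02, 0.02), tt, 3L)
  dRot[1L, ] <- 0; dTrans[1L, ] <- 0
  spikes <- which(stats::runif(tt) < config$motionSpikeProb)
  spikes <- spikes[spikes >= 2L]
  if (length(spikes)) {
    axis <- sample(1:3, length(spikes), replace = TRUE)
    jump <- stats::runif(length(spikes), 0.4, 0.8) *
      sample(c(-1, 1), length(spikes), replace = TRUE)
    for (k in seq_along(spikes)) {
      dTrans[spikes[k], axis[k]] <- dTrans[spikes[k], axis[k]] + jump[k]
    }
  }
  params <- cbind(apply(dRot, 2, cumsum), apply(dTrans, 2, cumsum))
  colnames(params) <- c("rot_x", "rot_y", "rot_z",
                        "trans_x", "trans_y", "trans_z")
  list(motion = motionRecord(params), spikeVolumes = spikes)
}

#' Simulate a full synthetic cohort
#'
#' Generates covariates, the base correlation, and per-subject BOLD series
#' and motion traces under one seed. Optionally writes the cohort to disk in
#' the package's interchange formats: per-subject series TSV (regions x
#' volumes, row labels = region index), motion TSV (volumes x 6, documented
#' header), a covariates CSV and a JSON manifest echoing the configuration.
#'
#' @param config a [simulationConfig()] object.
#' @param dir optional output directory; created if missing.
#' @return a list with \code{covariates} (data.frame), \code{base}
#'   (ConnectivityMatrix) and \code{subjects} (per-subject lists as returned
#'   by [genSubjectTimeseries()] plus \code{motion} and \code{spikeVolumes}).
#' @export
simulateCohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  covariates <- genCovariates(config)
  base <- genBaseCorrelation(config)
  zAll <- .standardize(covariates[[config$plantedCovariate]])
  subjects <- vector("list", config$nSubjects)
  for (i in seq_len(config$nSubjects)) {
    sub <- genSubjectTimeseries(base, zAll[i], config,
                                seed = .deriveSeed(config$seed, 1000L + i))
    mot <- genMotionTrace(config, seed = .deriveSeed(config$seed, 2000L + i))
    subjects[[i]] <- c(sub, mot)
  }
  names(subjects) <- covariates$id
  res <- list(covariates = covariates, base = base, subjects = subjects,
              config = config)
  if (!is.null(dir)) writeCohort(res, dir)
  res
}

.standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
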