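#' Framewise displacement from rigid-body parameters
#'
#' Power-style framewise displacement: for each volume transition, the sum of
#' absolute backward differences of the three translations (mm) plus
#' \code{headRadiusMm} times the sum of absolute backward differences of the
#' three rotations (radians), converting rotation angles to arc length on a
#' sphere of the given radius. The first volume has no predecessor and is
#' assigned FD = 0.
#'
#' @param motion a [MotionRecord-class] or a volumes x 6 parameter matrix
#'   (3 rotations in radians, then 3 translations in mm).
#' @param headRadiusMm sphere radius for the rotation terms; 50 mm by
#'   convention.
#' @return numeric FD trace in mm, one value per volume.
#' @examples
#' p <- matrix(0, 5, 6)
#' p[3:5, 4] <- 0.1   # a 0.1 mm translation step at volume 3
#' computeFD(p)       # 0 0 0.1 0 0
#' @export
computeFD <- function(motion, headRadiusMm = 50) {
  params <- if (is(motion, "MotionRecord")) motionParams(motion) else motion
  if (!is.matrix(params) || ncol(params) != 6L) {
    stop("motion parameters must form a volumes x 6 matrix")
  }
  if (nrow(params) < 2L) stop("need at least 2 volumes to compute FD")
  if (any(!is.finite(params))) stop("motion parameters must be finite")
  d <- abs(diff(params))
  fd <- headRadiusMm * rowSums(d[, 1:3, drop = FALSE]) +
    rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Delete initial volumes
#'
#' Removes the first \code{nDrop} volumes from the series (values and
#' retention mask) and, when supplied, from the paired motion record (with FD
#' recomputed on the remaining volumes) and tissue-signal matrix. Initial
#' volumes are discarded to let magnetization reach steady state.
#'
#' @param series an [RoiTimeSeries-class].
#' @param nDrop number of leading volumes to delete (default 15).
#' @param motion optional paired [MotionRecord-class].
#' @param tissue optional volumes x k matrix of tissue signals.
#' @return the trimmed [RoiTimeSeries-class], or a list
#'   \code{(series, motion, tissue)} when \code{motion} or \code{tissue} is
#'   supplied.
#' @export
dropInitialVolumes <- function(series, nDrop = 15L, motion = NULL,
                               tissue = NULL) {
  stopifnot(is(series, "RoiTimeSeries"))
  tt <- nVolumes(series)
  if (tt <= nDrop) {
    stop("subject invalid: series has ", tt,
         " volumes, cannot drop ", nDrop)
  }
  keep <- (nDrop + 1L):tt
  out <- roiTimeSeries(seriesValues(series)[, keep, drop = FALSE],
                       trSeconds = trSeconds(series),
                       retainedMask = retainedMask(series)[keep],
                       regionIds = regionIds(series))
  if (is.null(motion) && is.null(tissue)) return(out)
  res <- list(series = out)
  if (!is.null(motion)) {
    res$motion <- motionRecord(motionParams(motion)[keep, , drop = FALSE],
                               meanRelDisplacement = meanRelDisplacement(motion))
  }
  if (!is.null(tissue)) res$tissue <- tissue[keep, , drop = FALSE]
  res
}

#' Censor high-motion volumes
#'
#' Marks as censored every volume whose framewise displacement exceeds the
#' threshold (strictly: a volume at exactly the threshold is retained). Only
#' the retention mask changes; signal values are untouched.
#'
#' @param series an [RoiTimeSeries-class].
#' @param fd numeric FD trace, one value per volume.
#' @param thresholdMm censoring threshold in mm (default 0.2).
#' @return the series with its retention mask set to \code{fd <= thresholdMm}.
#' @export
censorVolumes <- function(series, fd, thresholdMm = 0.2) {
  stopifnot(is(series, "RoiTimeSeries"))
  if (length(fd) != nVolumes(series)) {
    stop("'fd' length must equal the number of volumes")
  }
  roiTimeSeries(seriesValues(series), trSeconds = trSeconds(series),
                retainedMask = !(fd > thresholdMm),
                regionIds = regionIds(series))
}

#' Subject-level motion exclusion gate
#'
#' A subject is excluded when their mean relative displacement exceeds the
#' threshold (strictly greater: exactly 0.2 mm is retained). The realignment
#' tool's mean relative displacement is used when recorded on the
#' [MotionRecord-class]; otherwise mean framewise displacement serves as a
#' proxy, flagged as such in the result.
#'
#' @param motion a [MotionRecord-class], or \code{NULL} when motion data are
#'   missing (fails with reason \code{"missing_motion"}).
#' @param thresholdMm exclusion threshold in mm (default 0.2).
#' @return a list: \code{pass} (logical), \code{metric} (mm, \code{NA} when
#'   missing), \code{source} (\code{"mean_rel_displacement"},
#'   \code{"mean_fd_proxy"} or \code{"missing_motion"}).
#' @export
subjectMotionGate <- function(motion, thresholdMm = 0.2) {
  if (is.null(motion)) {
    return(list(pass = FALSE, metric = NA_real_, source = "missing_motion"))
  }
  stopifnot(is(motion, "MotionRecord"))
  mrd <- meanRelDisplacement(motion)
  if (!is.na(mrd)) {
    list(pass = !(mrd > thresholdMm), metric = mrd,
         source = "mean_rel_displacement")
  } else {
    m <- mean(fdTrace(motion))
    list(pass = !(m > thresholdMm), metric = m, source = "mean_fd_proxy")
  }
}

#' Build the 36-parameter nuisance design
#'
#' Nine base regressors (six rigid-body motion parameters plus white-matter,
#' CSF and global mean signals), their temporal derivatives (backward
#' differences with first element 0), and the elementwise squares of all
#' eighteen: 36 columns in total.
#'
#' @param motion a [MotionRecord-class] (or volumes x 6 parameter matrix).
#' @param wm,csf,globalSig numeric tissue mean signals, same length as the
#'   motion record.
#' @return a volumes x 36 matrix with descriptive column names. A warning is
#'   raised when a base column is all zero (the design is then
#'   rank-deficient).
#' @export
build36pDesign <- function(motion, wm, csf, globalSig) {
  params <- if (is(motion, "MotionRecord")) motionParams(motion) else motion
  tt <- nrow(params)
  if (length(wm) != tt || length(csf) != tt || length(globalSig) != tt) {
    stop("tissue signals must have one value per volume")
  }
  base <- cbind(params, wm = wm, csf = csf, global = globalSig)
  colnames(base) <- c(colnames(params) %||%
                        c("rot_x", "rot_y", "rot_z",
                          "trans_x", "trans_y", "trans_z"),
                      "wm", "csf", "global")
  if (any(apply(base, 2, function(col) all(col == 0)))) {
    warning("all-zero base regressor(s): nuisance design is rank-deficient")
  }
  deriv <- rbind(0, diff(base))
  colnames(deriv) <- paste0("d_", colnames(base))
  firstOrder <- cbind(base, deriv)
  squares <- firstOrder^2
  colnames(squares) <- paste0("sq_", colnames(firstOrder))
  design <- cbind(firstOrder, squares)
  stopifnot(ncol(design) == 36L)
  design
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regress nuisance signals out of every region
#'
#' Replaces each region's time series by its ordinary-least-squares residual
#' against the nuisance design (an intercept is appended internally, so the
#' output is also mean-centred). Residuals are orthogonal to every design
#' column. Rank-deficient designs are handled by the pivoted QR projection,
#' with a warning.
#'
#' @param series an [RoiTimeSeries-class]; the full (uncensored) series is
#'   used.
#' @param design volumes x k nuisance matrix, e.g. from [build36pDesign()].
#' @return the series with residualized values; mask and metadata unchanged.
#' @export
nuisanceRegress <- function(series, design) {
  stopifnot(is(series, "RoiTimeSeries"))
  if (nrow(design) != nVolumes(series)) {
    stop("design rows must equal the number of volumes")
  }
  x <- cbind(intercept = 1, design)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    warning("nuisance design is rank-deficient (rank ", qrx$rank, " of ",
            ncol(x), "); projecting onto its column space")
  }
  resid <- t(qr.resid(qrx, t(seriesValues(series))))
  roiTimeSeries(resid, trSeconds = trSeconds(series),
                retainedMask = retainedMask(series),
                regionIds = regionIds(series))
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of order
#' \code{order} to every region. Each series is mean-centred before
#' filtering; the pass band retains at least 90\% of a sinusoid's amplitude
#' and frequencies at twice the upper cut or beyond are attenuated by at
#' least 90\%.
#'
#' @param series an [RoiTimeSeries-class] with known TR.
#' @param lowHz,highHz band edges in Hz (defaults 0.01 and 0.08, the
#'   conventional BOLD fluctuation band).
#' @param order Butterworth order per pass (default 2; the forward-backward
#'   application doubles the effective order).
#' @return the filtered series; mask and metadata unchanged.
#' @export
bandpass <- function(series, lowHz = 0.01, highHz = 0.08, order = 2L) {
  stopifnot(is(series, "RoiTimeSeries"))
  nyq <- 1 / (2 * trSeconds(series))
  if (!(lowHz > 0 && highHz > lowHz && highHz < nyq)) {
    stop("band edges must satisfy 0 < lowHz < highHz < Nyquist = ",
         format(nyq), " Hz")
  }
  bf <- signal::butter(order, W = c(lowHz, highHz) / nyq, type = "pass")
  v <- seriesValues(series)
  v <- v - rowMeans(v)
  filtered <- t(apply(v, 1, function(row) signal::filtfilt(bf, row)))
  roiTimeSeries(filtered, trSeconds = trSeconds(series),
                retainedMask = retainedMask(series),
                regionIds = regionIds(series))
}

#' Minimum-duration gate
#'
#' A subject is excluded when the retained data (retained volumes times TR)
#' amount to less than \code{minSeconds} (strictly less: exactly 240 s
#' passes).
#'
#' @param series an [RoiTimeSeries-class] with its final retention mask.
#' @param minSeconds required duration (default 240 s).
#' @return a list: \code{pass} (logical), \code{retainedSeconds}.
#' @export
durationGate <- function(series, minSeconds = 240) {
  stopifnot(is(series, "RoiTimeSeries"))
  secs <- retainedSeconds(series)
  list(pass = !(secs < minSeconds), retainedSeconds = secs)
}

#' Denoise one subject end to end
#'
#' Runs the temporal denoising chain in a fixed, logged order: delete initial
#' volumes, compute framewise displacement, subject-level motion gate,
#' 36-parameter nuisance regression on the full series, zero-phase band-pass
#' on the full series, volume censoring, minimum-duration gate. Regression
#' and filtering operate on the full (uncensored) series because filtering an
#' irregularly sampled series is ill-defined; set \code{censorFirst = TRUE}
#' to censor before regression and filtering instead (the censored values are
#' then zeroed-out residuals of the retained fit).
#'
#' @param series an [RoiTimeSeries-class] (raw, all volumes).
#' @param motion a paired [MotionRecord-class].
#' @param tissue volumes x 3 matrix of WM/CSF/global signals (zeros give the
#'   design no tissue structure but keep its shape).
#' @param nDrop initial volumes to delete (default 15).
#' @param fdThresholdMm censoring threshold (default 0.2 mm).
#' @param motionThresholdMm subject-gate threshold (default 0.2 mm).
#' @param minSeconds duration-gate threshold (default 240 s).
#' @param lowHz,highHz band-pass edges (defaults 0.01, 0.08 Hz).
#' @param censorFirst censor before regression/filtering (default FALSE).
#' @return a list: \code{series} (denoised, censored), \code{motion}
#'   (trimmed), \code{fd} (post-trim FD trace), \code{qc} (named list with
#'   the gate outcomes, censored-volume count, retained seconds, and
#'   \code{pass} plus a \code{reason} code when excluded).
#' @export
denoiseSubject <- function(series, motion, tissue = NULL, nDrop = 15L,
                           fdThresholdMm = 0.2, motionThresholdMm = 0.2,
                           minSeconds = 240, lowHz = 0.01, highHz = 0.08,
                           censorFirst = FALSE) {
  stopifnot(is(series, "RoiTimeSeries"))
  if (nVolumes(series) <= nDrop) {
    return(list(series = NULL, motion = motion, fd = NULL,
                qc = list(pass = FALSE, reason = "too_few_volumes",
                          nCensored = NA_integer_,
                          retainedSeconds = NA_real_)))
  }
  if (is.null(tissue)) {
    tissue <- matrix(0, nVolumes(series), 3L,
                     dimnames = list(NULL, c("wm", "csf", "global")))
  }
  trimmed <- dropInitialVolumes(series, nDrop, motion = motion,
                                tissue = tissue)
  series <- trimmed$series; motion <- trimmed$motion; tissue <- trimmed$tissue
  fd <- fdTrace(motion)
  gate <- subjectMotionGate(motion, motionThresholdMm)
  if (!gate$pass) {
    return(list(series = series, motion = motion, fd = fd,
                qc = list(pass = FALSE, reason = "motion_gate",
                          motionMetric = gate$metric,
                          motionSource = gate$source,
                          nCensored = NA_integer_,
                          retainedSeconds = NA_real_)))
  }
  if (censorFirst) {
    series <- censorVolumes(series, fd, fdThresholdMm)
    keep <- retainedMask(series)
    sub <- roiTimeSeries(seriesValues(series)[, keep, drop = FALSE],
                         trSeconds = trSeconds(series),
                         regionIds = regionIds(series))
    sub <- nuisanceRegress(sub, build36pDesign(
      motionParams(motion)[keep, , drop = FALSE],
      tissue[keep, 1], tissue[keep, 2], tissue[keep, 3]))
    sub <- bandpass(sub, lowHz, highHz)
    v <- seriesValues(series); v[] <- 0; v[, keep] <- seriesValues(sub)
    series <- roiTimeSeries(v, trSeconds = trSeconds(series),
                            retainedMask = keep,
                            regionIds = regionIds(series))
  } else {
    design <- build36pDesign(motion, tissue[, 1], tissue[, 2], tissue[, 3])
    series <- nuisanceRegress(series, design)
    series <- bandpass(series, lowHz, highHz)
    series <- censorVolumes(series, fd, fdThresholdMm)
  }
  dur <- durationGate(series, minSeconds)
  qc <- list(pass = dur$pass,
             reason = if (dur$pass) NA_character_ else "duration_gate",
             motionMetric = gate$metric, motionSource = gate$source,
             nCensored = sum(!retainedMask(series)),
             retainedSeconds = dur$retainedSeconds)
  list(series = series, motion = motion, fd = fd, qc = qc)
}
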