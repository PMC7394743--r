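#' Log-transform selected cohort variables
#'
#' Replaces each listed variable by the natural log of (value + offset),
#' leaving everything else untouched. Intended for non-normally distributed
#' covariates or outcomes ahead of linear modelling.
#'
#' @param data a data.frame.
#' @param vars character vector of column names to transform (empty = no-op).
#' @param offsets named numeric offsets per variable (default 0 for each).
#' @return the data.frame with the listed columns transformed.
#' @export
logTransform <- function(data, vars = character(), offsets = NULL) {
  stopifnot(is.data.frame(data), all(vars %in% names(data)))
  for (v in vars) {
    off <- if (!is.null(offsets) && v %in% names(offsets)) offsets[[v]] else 0
    x <- data[[v]] + off
    if (any(x <= 0, na.rm = TRUE)) {
      stop("non-positive value(s) in '", v, "' after offset ", off,
           "; cannot log-transform")
    }
    data[[v]] <- log(x)
  }
  data
}

#' Normality screen for model variables
#'
#' Shapiro-Wilk test per variable; flags variables whose distribution departs
#' from normality at the given level as candidates for log transformation.
#' Purely advisory: nothing is transformed.
#'
#' @param data a data.frame.
#' @param vars column names to screen (default: all numeric columns).
#' @param alpha screening level (default 0.05).
#' @return data.frame with \code{variable}, \code{shapiro_p},
#'   \code{recommend_log}.
#' @export
normalityScreen <- function(data, vars = NULL, alpha = 0.05) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  p <- vapply(vars, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(unique(x)) < 3L || length(x) < 3L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  data.frame(variable = vars, shapiro_p = p,
             recommend_log = !is.na(p) & p < alpha)
}

#' Linear model of a network outcome on risk factors
#'
#' Ordinary least squares of one outcome on the determinant(s) plus the
#' adjustment covariates, on complete cases, with an intercept. Coefficients
#' are reported as standardized betas (raw slope times SD(predictor) /
#' SD(outcome); binary predictors on the same convention), alongside the
#' model's adjusted R-squared and overall F test.
#'
#' @param data data.frame containing the outcome and all predictors (e.g. the
#'   cohort covariates merged with the per-subject network outcomes).
#' @param outcome outcome column name.
#' @param determinants character vector of determinant column names.
#' @param adjusters adjustment covariates; defaults to center, age, gender
#'   and IQ, with age dropped automatically when it is a determinant.
#' @return a list of class \code{"ModelResult"}: \code{outcome},
#'   \code{coefficients} (data.frame: term, beta_std, estimate, p),
#'   \code{adjustedR2}, \code{r2}, \code{fStatistic}, \code{df1}, \code{df2},
#'   \code{fP}, \code{n}.
#' @examples
#' d <- data.frame(y = rnorm(50), age = rnorm(50, 70, 5),
#'                 center = rbinom(50, 1, 0.3), gender = rbinom(50, 1, 0.6),
#'                 iq = rnorm(50, 105, 12))
#' fitOutcomeModel(d, "y", "age")
#' @export
fitOutcomeModel <- function(data, outcome, determinants,
                            adjusters = c("center", "age", "gender", "iq")) {
  adjusters <- setdiff(adjusters, determinants)
  predictors <- c(determinants, adjusters)
  cols <- c(outcome, predictors)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 1L) {
    stop("too few complete cases (", n, ") for ", length(predictors),
         " predictors")
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients[-1L, , drop = FALSE]  # drop intercept
  sdY <- stats::sd(d[[outcome]])
  sdX <- vapply(predictors, function(v) stats::sd(d[[v]]), numeric(1))
  res <- list(
    outcome = outcome,
    determinants = determinants,
    coefficients = data.frame(
      term = rownames(ct),
      beta_std = ct[, "Estimate"] * sdX[rownames(ct)] / sdY,
      estimate = ct[, "Estimate"],
      p = ct[, "Pr(>|t|)"],
      row.names = NULL
    ),
    adjustedR2 = sm$adj.r.squared,
    r2 = sm$r.squared,
    fStatistic = unname(sm$fstatistic["value"]),
    df1 = unname(sm$fstatistic["numdf"]),
    df2 = unname(sm$fstatistic["dendf"]),
    fP = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                   sm$fstatistic["dendf"], lower.tail = FALSE),
    n = n
  )
  class(res) <- "ModelResult"
  res
}

#' @export
print.ModelResult <- function(x, ...) {
  cat("Linear model:", x$outcome, "~",
      paste(x$coefficients$term, collapse = " + "), "\n")
  cat(sprintf("  n = %d, adj. R2 = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$n, x$adjustedR2, x$df1, x$df2, x$fStatistic, x$fP))
  det <- x$coefficients[x$coefficients$term %in% x$determinants, ]
  for (k in seq_len(nrow(det))) {
    cat(sprintf("  %s: beta = %.3f, p = %.4g\n",
                det$term[k], det$beta_std[k], det$p[k]))
  }
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up adjustment: with the p-values sorted ascending, the
#' adjusted value at rank i is the minimum over ranks j >= i of
#' m * p(j) / j, capped at 1. Rejections are adjusted p strictly below the
#' target rate.
#'
#' @param p numeric p-values in [0, 1].
#' @param q FDR level for the rejection flags (default 0.05).
#' @return a list: \code{adjusted} (same order as input), \code{reject}
#'   (logical).
#' @examples
#' bhFDR(c(0.004, 0.03, 0.04, 0.8))
#' @export
bhFDR <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adjSorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  adjSorted <- pmin(adjSorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adjSorted
  list(adjusted = adjusted, reject = adjusted < q)
}

#' Extreme-quintile contrast
#'
#' Exploratory contrast of a network outcome between the lowest and highest
#' quintiles of a continuous risk indicator. Quintile cuts use the
#' linear-interpolation percentile rule (R's default, type 7) at the 20th and
#' 80th percentiles; boundary values fall in the extreme groups inclusively.
#' The groups are compared by a two-sample t-test.
#'
#' @param data data.frame with the variable and outcome columns.
#' @param variable continuous risk-indicator column name.
#' @param outcome outcome column name.
#' @param welch use the unequal-variance t-test (default TRUE).
#' @return a list: \code{t}, \code{p}, \code{df}, \code{nLow}, \code{nHigh},
#'   \code{cutLow}, \code{cutHigh}.
#' @export
extremeQuintileTest <- function(data, variable, outcome, welch = TRUE) {
  stopifnot(all(c(variable, outcome) %in% names(data)))
  d <- data[stats::complete.cases(data[c(variable, outcome)]), ]
  x <- d[[variable]]
  qs <- stats::quantile(x, c(0.2, 0.8), type = 7, names = FALSE)
  low <- d[[outcome]][x <= qs[1]]
  high <- d[[outcome]][x >= qs[2]]
  if (length(low) < 2L || length(high) < 2L) {
    stop("degenerate quintile group(s): lowest n = ", length(low),
         ", highest n = ", length(high))
  }
  if (stats::sd(low) == 0 && stats::sd(high) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1,
               parameter = c(df = length(low) + length(high) - 2))
  } else {
    tt <- stats::t.test(high, low, var.equal = !welch)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), nLow = length(low),
       nHigh = length(high), cutLow = qs[1], cutHigh = qs[2])
}

#' Two-sample t-test from summary statistics
#'
#' Computes the t statistic directly from (mean, SD, n) pairs, as needed when
#' only published summary statistics are available. The default is Welch's
#' unequal-variance form
#' t = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b) with
#' Welch-Satterthwaite degrees of freedom; the pooled-variance Student form
#' is available by flag. Two degenerate zero-variance groups with equal
#' means give t = 0.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summary statistics.
#' @param method \code{"welch"} (default) or \code{"pooled"}.
#' @return a list: \code{t}, \code{df}, \code{p}.
#' @examples
#' summaryTTest(72.1, 5.0, 554, 71.2, 4.9, 222)$t  # 2.30
#' @export
summaryTTest <- function(meanA, sdA, nA, meanB, sdB, nB,
                         method = c("welch", "pooled")) {
  method <- match.arg(method)
  stopifnot(sdA >= 0, sdB >= 0, nA >= 2, nB >= 2)
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB) {
      return(list(t = 0, df = nA + nB - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  if (method == "welch") {
    vA <- sdA^2 / nA; vB <- sdB^2 / nB
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  } else {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  }
  t <- (meanA - meanB) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Chi-square test of independence on a 2x2 contingency table, with optional
#' Yates continuity correction. All margins must be positive.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return a list: \code{statistic}, \code{p}, \code{df}.
#' @export
chi2Test2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("'counts' must be 2x2")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin in the 2x2 table")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Fit the per-risk-factor and combined outcome models
#'
#' Reproduces the group-level analysis layout: for each network outcome, one
#' linear model per individual risk factor (adjusted for center, age when not
#' the determinant, gender and IQ) plus one model with all risk factors
#' combined (adjusted for center, gender and IQ). Within each determinant,
#' p-values are FDR-corrected across the family of outcomes by the
#' Benjamini-Hochberg step-up.
#'
#' @param data cohort covariates merged with per-subject outcomes, one row
#'   per analyzable subject.
#' @param outcomes outcome column names (default the five network outcomes).
#' @param riskFactors determinant column names (default the seven
#'   predisposing risk factors).
#' @param adjusters adjustment covariates (default center, age, gender, IQ).
#' @return a tidy data.frame with columns \code{model}
#'   (\code{"individual"} or \code{"combined"}), \code{outcome},
#'   \code{determinant}, \code{adjustedR2}, \code{beta}, \code{p},
#'   \code{fdrP}, \code{significant}.
#' @export
riskFactorModels <- function(data,
                             outcomes = c("strength", "diameter",
                                          "leaf_fraction", "pcc_dlpfc_left",
                                          "pcc_dlpfc_right"),
                             riskFactors = c("age", "alcohol_misuse", "mmse",
                                             "depression", "barthel",
                                             "tia_stroke", "asa_unhealthy"),
                             adjusters = c("center", "age", "gender", "iq")) {
  outcomes <- outcomes[outcomes %in% names(data) &
                         vapply(outcomes, function(o)
                           !all(is.na(data[[o]])), logical(1))]
  rows <- list()
  for (rf in riskFactors) {
    for (oc in outcomes) {
      fit <- fitOutcomeModel(data, oc, rf, adjusters)
      co <- fit$coefficients[fit$coefficients$term == rf, ]
      rows[[length(rows) + 1L]] <- data.frame(
        model = "individual", outcome = oc, determinant = rf,
        adjustedR2 = fit$adjustedR2, beta = co$beta_std, p = co$p)
    }
  }
  for (oc in outcomes) {
    fit <- fitOutcomeModel(data, oc, riskFactors,
                           adjusters = setdiff(adjusters, "age"))
    for (rf in riskFactors) {
      co <- fit$coefficients[fit$coefficients$term == rf, ]
      rows[[length(rows) + 1L]] <- data.frame(
        model = "combined", outcome = oc, determinant = rf,
        adjustedR2 = fit$adjustedR2, beta = co$beta_std, p = co$p)
    }
  }
  tab <- do.call(rbind, rows)
  tab$fdrP <- NA_real_
  for (mdl in unique(tab$model)) {
    for (rf in unique(tab$determinant)) {
      sel <- tab$model == mdl & tab$determinant == rf
      tab$fdrP[sel] <- bhFDR(tab$p[sel])$adjusted
    }
  }
  tab$significant <- tab$fdrP < 0.05
  rownames(tab) <- NULL
  tab
}
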