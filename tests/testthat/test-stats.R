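test_that("log transform targets only the listed variables", {
  d <- data.frame(a = c(1, exp(1)), b = c(2, 3))
  expect_identical(logTransform(d, character()), d)
  out <- logTransform(d, "a")
  expect_equal(out$a, c(0, 1))
  expect_identical(out$b, d$b)
  # offsets
  out2 <- logTransform(data.frame(a = c(0, 1)), "a", offsets = c(a = 1))
  expect_equal(out2$a, log(c(1, 2)))
  expect_error(logTransform(data.frame(a = c(0, 1)), "a"), "non-positive")
})

test_that("log transform normalizes lognormal samples", {
  passes <- vapply(1:50, function(s) {
    set.seed(400 + s)
    d <- data.frame(x = exp(rnorm(100, sd = 0.8)))
    shapiro.test(logTransform(d, "x")$x)$p.value >= 0.05
  }, logical(1))
  expect_gte(mean(passes), 0.9)
})

test_that("normality screen flags skewed variables only", {
  set.seed(5)
  d <- data.frame(normal = rnorm(200), skewed = exp(rnorm(200)))
  scr <- normalityScreen(d)
  expect_true(scr$recommend_log[scr$variable == "skewed"])
  expect_false(scr$recommend_log[scr$variable == "normal"])
})

test_that("outcome regressed on itself is a perfect fit", {
  set.seed(6)
  d <- data.frame(y = rnorm(40))
  d$x <- d$y
  fit <- suppressWarnings(  # lm warns about the exact fit
    fitOutcomeModel(d, "y", "x", adjusters = character()))
  expect_equal(fit$coefficients$beta_std, 1, tolerance = 1e-12)
  expect_equal(fit$adjustedR2, 1, tolerance = 1e-12)
})

test_that("standardized beta is invariant to affine rescaling", {
  set.seed(7)
  d <- data.frame(age = rnorm(100, 70, 5), center = rbinom(100, 1, 0.3),
                  gender = rbinom(100, 1, 0.6), iq = rnorm(100, 105, 12))
  d$y <- 0.3 * scale(d$age) + rnorm(100)
  f1 <- fitOutcomeModel(d, "y", "age")
  d2 <- d
  d2$age <- (d$age - 70) / 5 * 13 + 200   # affine predictor rescale
  d2$y <- d$y * 40 - 7                    # affine outcome rescale
  f2 <- fitOutcomeModel(d2, "y", "age")
  expect_equal(f2$coefficients$beta_std, f1$coefficients$beta_std,
               tolerance = 1e-10)
  expect_equal(f2$coefficients$p, f1$coefficients$p, tolerance = 1e-10)
})

test_that("age drops out of the adjusters when it is the determinant", {
  set.seed(8)
  d <- data.frame(age = rnorm(60, 70, 5), center = rbinom(60, 1, 0.3),
                  gender = rbinom(60, 1, 0.6), iq = rnorm(60, 105, 12),
                  y = rnorm(60))
  fit <- fitOutcomeModel(d, "y", "age")
  expect_setequal(fit$coefficients$term, c("age", "center", "gender", "iq"))
  expect_equal(fit$df1, 4)
  expect_equal(fit$df2, 60 - 4 - 1)
})

test_that("collinear designs error with the aliased column named", {
  set.seed(9)
  d <- data.frame(a = rnorm(30))
  d$b <- 2 * d$a
  d$y <- rnorm(30)
  expect_error(fitOutcomeModel(d, "y", c("a", "b"),
                               adjusters = character()),
               "collinear.*b")
})

test_that("null simulations give uniform determinant p-values", {
  set.seed(30)
  ps <- vapply(1:1000, function(k) {
    d <- data.frame(age = rnorm(222, 71, 5), center = rbinom(222, 1, 0.3),
                    gender = rbinom(222, 1, 0.63),
                    iq = rnorm(222, 105, 12), y = rnorm(222))
    fit <- fitOutcomeModel(d, "y", "age")
    fit$coefficients$p[fit$coefficients$term == "age"]
  }, numeric(1))
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(mean(ps < 0.05), band[1])
  expect_lte(mean(ps < 0.05), band[2])
})

test_that("BH step-up matches the hand-worked examples", {
  r1 <- bhFDR(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r1$adjusted, rep(0.04, 4))
  expect_true(all(r1$reject))

  r2 <- bhFDR(c(0.004, 0.03, 0.04, 0.8))
  expect_equal(r2$adjusted, c(0.016, 0.0533333333, 0.0533333333, 0.8),
               tolerance = 1e-9)
  expect_equal(r2$reject, c(TRUE, FALSE, FALSE, FALSE))

  r3 <- bhFDR(0.5)
  expect_equal(r3$adjusted, 0.5)
  expect_error(bhFDR(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("BH adjusted values are monotone and match the oracle", {
  set.seed(31)
  for (rep in 1:100) {
    p <- runif(sample(1:50, 1))
    adj <- bhFDR(p)$adjusted
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("extreme quintile groups follow the percentile rule", {
  d <- data.frame(x = 1:10, y = 1:10)
  res <- extremeQuintileTest(d, "x", "y")
  expect_equal(res$nLow, 2)   # {1, 2} below the 20th percentile cut 2.8
  expect_equal(res$nHigh, 2)  # {9, 10} above the 80th percentile cut 8.2
  expect_equal(res$cutLow, 2.8)
  expect_equal(res$cutHigh, 8.2)
  # identical outcomes -> t = 0
  d2 <- data.frame(x = 1:10, y = rep(5, 10))
  expect_equal(extremeQuintileTest(d2, "x", "y")$t, 0)
})

test_that("extreme quintile t matches the textbook two-sample formula", {
  # x = 1..25: the 20th/80th percentile cuts are 5.8 and 20.2, so the
  # extreme groups are positions 1-5 and 21-25
  lowY <- c(0.42, 0.45, 0.40, 0.44, 0.41)
  highY <- c(0.47, 0.49, 0.46, 0.50, 0.48)
  set.seed(40)
  d <- data.frame(x = 1:25, y = c(lowY, rnorm(15, 0.45, 0.03), highY))
  res <- extremeQuintileTest(d, "x", "y")
  expect_equal(res$nLow, 5)
  expect_equal(res$nHigh, 5)
  # hand-computed Welch t
  se <- sqrt(var(highY) / 5 + var(lowY) / 5)
  expect_equal(res$t, (mean(highY) - mean(lowY)) / se, tolerance = 1e-12)
  # a tiny sample collapses an extreme group below 2 -> error
  d3 <- data.frame(x = 1:4, y = rnorm(4))
  expect_error(extremeQuintileTest(d3, "x", "y"), "degenerate")
})

test_that("summary t-test reproduces direct Welch and pooled t", {
  set.seed(32)
  a <- rnorm(40, 1, 2); b <- rnorm(25, 0, 1.5)
  sumT <- summaryTTest(mean(a), sd(a), 40, mean(b), sd(b), 25)
  direct <- t.test(a, b)
  expect_equal(sumT$t, unname(direct$statistic), tolerance = 1e-12)
  expect_equal(sumT$df, unname(direct$parameter), tolerance = 1e-12)
  expect_equal(sumT$p, direct$p.value, tolerance = 1e-12)
  sumP <- summaryTTest(mean(a), sd(a), 40, mean(b), sd(b), 25,
                       method = "pooled")
  directP <- t.test(a, b, var.equal = TRUE)
  expect_equal(sumP$t, unname(directP$statistic), tolerance = 1e-12)
  # degenerate equal groups
  expect_equal(summaryTTest(3, 0, 10, 3, 0, 10)$t, 0)
  expect_error(summaryTTest(3, 0, 10, 4, 0, 10), "undefined")
})

test_that("chi-square on 2x2 tables matches the by-hand formula", {
  expect_equal(chi2Test2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  # hand-computed expected counts: all margins 30, E = 15 everywhere
  res <- chi2Test2x2(rbind(c(20, 10), c(10, 20)))
  expect_equal(res$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # alcohol-misuse style table: tiny association; the shortcut formula
  # n(ad - bc)^2 / (row and column margin product) is the oracle
  res2 <- chi2Test2x2(rbind(c(25, 485), c(11, 211)))
  chiHand <- 732 * (25 * 211 - 485 * 11)^2 / (510 * 222 * 36 * 696)
  expect_equal(res2$statistic, chiHand, tolerance = 1e-12)
  expect_equal(res2$p, pchisq(chiHand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(chi2Test2x2(rbind(c(0, 0), c(5, 5))), "margin")
  expect_error(chi2Test2x2(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("risk-factor model table covers all factor/outcome/model cells", {
  set.seed(33)
  n <- 120
  d <- data.frame(
    age = rnorm(n, 71, 5), alcohol_misuse = rbinom(n, 1, 0.05),
    mmse = round(rnorm(n, 28.7, 1.4)), depression = rbinom(n, 1, 0.05),
    barthel = pmin(100, round(rnorm(n, 98, 5))),
    tia_stroke = rbinom(n, 1, 0.24), asa_unhealthy = rbinom(n, 1, 0.86),
    center = rbinom(n, 1, 0.3), gender = rbinom(n, 1, 0.63),
    iq = rnorm(n, 105, 12),
    strength = rnorm(n), diameter = rnorm(n), leaf_fraction = rnorm(n),
    pcc_dlpfc_left = rnorm(n), pcc_dlpfc_right = rnorm(n)
  )
  tab <- riskFactorModels(d)
  expect_equal(nrow(tab), 7 * 5 * 2)  # 7 factors x 5 outcomes x 2 models
  expect_setequal(unique(tab$model), c("individual", "combined"))
  # FDR family: the 5 outcomes within one determinant and model
  fam <- tab[tab$model == "individual" & tab$determinant == "age", ]
  expect_equal(fam$fdrP, bhFDR(fam$p)$adjusted, tolerance = 1e-12)
  expect_equal(tab$significant, tab$fdrP < 0.05)
})
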