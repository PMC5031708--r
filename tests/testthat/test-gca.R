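test_that("fitAr solves the least-squares autoregression", {
  set.seed(1)
  y <- rnorm(10000)
  f <- fitAr(y, 1)
  expect_lt(abs(f$ownCoef), 0.05)
  expect_equal(f$residVar, var(y), tolerance = 0.02)

  z <- generateVarSeries(matrix(0.6, 1, 1), 100000, seed = 2)
  f2 <- fitAr(as.numeric(z), 1)
  expect_equal(unname(f2$ownCoef), 0.6, tolerance = 0.01)

  # residuals orthogonal to every lagged predictor (normal equations)
  y3 <- rnorm(500)
  f3 <- fitAr(y3, 3)
  L <- embed(y3, 4)[, -1]
  expect_lt(max(abs(crossprod(cbind(1, L), f3$residuals))) / length(y3), 1e-10)

  expect_error(fitAr(rep(1, 100), 2), "degenerate|singular")
  expect_error(fitAr(rnorm(10), 3), "too short")
})

test_that("BIC selects the generating order", {
  expect_equal(selectOrderBic(rnorm(100), rnorm(100), pMax = 1), 1L)

  # bivariate VAR(2): order 2 recovered in >= 90% of replicates
  A1 <- matrix(c(0.3, 0.2, 0.2, 0.3), 2)
  A2 <- matrix(c(0.25, -0.3, 0.3, 0.25), 2)
  set.seed(5)
  hits <- vapply(1:100, function(r) {
    z <- generateVarSeries(list(A1, A2), 5000)
    selectOrderBic(z[, 1], z[, 2], pMax = 4) == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # independent white noise: smallest order wins in the majority
  set.seed(6)
  ones <- vapply(1:30, function(r)
    selectOrderBic(rnorm(1500), rnorm(1500), pMax = 4) == 1L, logical(1))
  expect_gt(mean(ones), 0.5)
})

test_that("grangerPair matches the closed form and its invariances", {
  set.seed(7)
  a <- rnorm(100000)
  b <- rnorm(100000)
  g0 <- grangerPair(a, b, 1)
  expect_lt(g0[["aToB"]], 0.001)
  expect_lt(g0[["bToA"]], 0.001)

  b2 <- 0.8 * c(0, a[-100000]) + rnorm(100000)
  g <- grangerPair(a, b2, 1)
  expect_equal(g[["aToB"]], log(1.64), tolerance = 0.01)
  expect_lt(g[["bToA"]], 0.005)

  # scale invariance of the variance ratio
  g2 <- grangerPair(a, b2 * 1000, 1)
  expect_equal(g2, g, tolerance = 1e-10)
})

test_that("grangerPair agrees with the brute-force normal equations", {
  set.seed(8)
  for (r in 1:10) {
    p <- sample(1:2, 1)
    n <- sample(30:50, 1)
    a <- rnorm(n)
    b <- 0.4 * c(rep(0, p), a[1:(n - p)]) + rnorm(n)
    expect_equal(unname(grangerPair(a, b, p)),
                 unname(pmax(0, oracleGranger(a, b, p))),
                 tolerance = 1e-10)
  }
})

test_that("causal maps are nonnegative, equivariant, and flag degeneracy", {
  set.seed(9)
  A <- matrix(0, 6, 6); diag(A) <- 0.3; A[2, 1] <- 0.8
  z <- generateVarSeries(A, 800, seed = 21)
  rec <- asPreprocessed(z)
  cm <- causalMap(rec, pMax = 3)
  w <- gcWeights(cm)
  expect_true(all(is.na(diag(w))))
  off <- w[row(w) != col(w)]
  expect_true(all(off >= 0))
  # the planted edge carries the largest weight
  expect_equal(which.max(w), which(row(w) == 1 & col(w) == 2)[1])

  # permutation equivariance
  perm <- c(4, 1, 6, 2, 5, 3)
  cmP <- causalMap(asPreprocessed(z[, perm]), pMax = 3)
  expect_equal(gcWeights(cmP), w[perm, perm], tolerance = 1e-10)
  expect_equal(gcOrders(cmP), gcOrders(cm)[perm, perm])

  # degenerate channel: incident edges NA, others intact
  z2 <- cbind(z[, 1:4], 0, z[, 6])
  expect_warning(cm2 <- causalMap(asPreprocessed(z2), pMax = 3),
                 "degenerate")
  w2 <- gcWeights(cm2)
  expect_true(all(is.na(w2[5, ])))
  expect_true(all(is.na(w2[, 5])))
  expect_false(anyNA(w2[c(1:4, 6), c(1:4, 6)][row(diag(5)) != col(diag(5))]))
})

test_that("null maps carry the small-sample log-ratio bias ~ p/T", {
  # under independence T_eff * G ~ chi-square(p), so E[G] ~ p / T_eff
  set.seed(10)
  z <- matrix(rnorm(2000 * 6), 2000, 6)
  cm <- causalMap(asPreprocessed(z), pMax = 3)
  w <- gcWeights(cm)
  o <- gcOrders(cm)
  tEff <- 2000 - 3
  off <- row(w) != col(w)
  expected <- mean(o[off]) / tEff
  se <- sqrt(2 * mean(o[off]) / sum(off)) / tEff
  expect_lt(abs(mean(w[off]) - expected), 3 * se)

  # and T_eff * G quantiles match the chi-square at the selected order
  g1 <- tEff * w[off][o[off] == 1]
  if (length(g1) > 10) {
    expect_equal(median(g1), qchisq(0.5, 1), tolerance = 0.5)
  }
})

test_that("causal maps round-trip through the edge-table format", {
  set.seed(11)
  z <- generateVarSeries(diag(0.3, 4), 400, seed = 3)
  cm <- causalMap(NirsRecording("p7", 9.5, "other", 10, z,
                                preprocessed = TRUE), pMax = 2)
  f <- tempfile(fileext = ".tsv")
  writeCausalMap(cm, f)
  back <- readCausalMap(f)
  expect_equal(gcWeights(back), gcWeights(cm))
  expect_equal(gcOrders(back), gcOrders(cm))
  expect_equal(participantId(back), "p7")
  expect_equal(condition(back), "other")
  expect_equal(ageYears(back), 9.5)
})

test_that("causalMap insists on preprocessed input", {
  raw <- NirsRecording("p1", 7, "own", 10, matrix(rnorm(400), 200, 2))
  expect_error(causalMap(raw, 2), "preprocessed")
})
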