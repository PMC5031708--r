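test_that("partial eta-squared follows F*df1/(F*df1 + df2)", {
  expect_lt(abs(partialEtaSq(10.572, 1, 122) - 0.0798), 5e-4)
  expect_lt(abs(partialEtaSq(12.15, 1, 122) - 0.0906), 5e-4)
  expect_equal(partialEtaSq(0, 1, 122), 0)
  expect_equal(round(partialEtaSq(88.72, 1, 122), 2), 0.42)
  expect_error(partialEtaSq(-1, 1, 10), "nonnegative")
})

test_that("the RM-ANOVA reduction matches an independent GLM oracle", {
  set.seed(1)
  for (r in 1:20) {
    N <- sample(8:20, 1)
    age <- runif(N, 3, 13)
    yo <- 0.02 * age + rnorm(N, sd = 0.3)
    yt <- 0.01 * age + rnorm(N, sd = 0.3)
    got <- rmAnovaAgeRace(yo, yt, age)
    want <- oracleRmAnova(yo, yt, age)
    expect_equal(got$F, unname(want[c("age", "race", "interaction")]),
                 tolerance = 1e-10)
    expect_equal(got$df2, rep(N - 2L, 3))
    expect_equal(got$eta2, got$F / (got$F + N - 2), tolerance = 1e-12)
  }
})

test_that("identical conditions give zero race and interaction F", {
  age <- runif(12, 3, 13)
  y <- rnorm(12)
  out <- rmAnovaAgeRace(y, y, age)
  expect_equal(out$F[out$effect == "race"], 0)
  expect_equal(out$F[out$effect == "interaction"], 0)

  expect_error(rmAnovaAgeRace(y[1:3], y[1:3], age[1:3]), "at least 4")
  expect_error(rmAnovaAgeRace(y, y, rep(5, 12)), "variance")
})

test_that("bootstrap averaging reduces to the plain eta2 and is seeded", {
  set.seed(2)
  age <- runif(30, 3, 13)
  yo <- rnorm(30); yt <- rnorm(30)

  full <- rmAnovaAgeRace(yo, yt, age)
  b1 <- bootstrapEffectSize(yo, yt, age, B = 1, frac = 1, seed = 3)
  expect_equal(unname(b1), full$eta2, tolerance = 1e-12)

  bA <- bootstrapEffectSize(yo, yt, age, B = 200, frac = 0.5, seed = 4)
  bB <- bootstrapEffectSize(yo, yt, age, B = 200, frac = 0.5, seed = 4)
  expect_identical(bA, bB)
  expect_true(all(bA >= 0 & bA <= 1))
})

test_that("bootstrap mean standard error shrinks like 1/sqrt(B)", {
  set.seed(5)
  age <- runif(124, 3.25, 13.49)
  yo <- rnorm(124); yt <- rnorm(124)
  sdAt <- function(B) sd(vapply(1:30, function(s)
    bootstrapEffectSize(yo, yt, age, B = B, frac = 0.5,
                        seed = 100 + s)[["interaction"]], numeric(1)))
  ratio <- sdAt(100) / sdAt(400)
  expect_gt(ratio, 1.35)  # ideal 2, generous Monte-Carlo band
  expect_lt(ratio, 3.0)
})

test_that("the sign-flip null matches full enumeration at N = 10", {
  # with frac = 1 every averaged replicate is exactly one flip's eta2,
  # so the sampled null must match the exact 2^10 enumeration
  set.seed(6)
  N <- 10
  age <- runif(N, 3, 13)
  yo <- rnorm(N); yt <- rnorm(N)
  D <- yo - yt
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
  exact <- apply(flips, 1, function(s) {
    f <- fnirsGCA:::.rmAnovaF(yo - (D - s * D) / 2 + 0,  # own with flipped D
                              yo - (D + s * D) / 2,
                              age)[["interaction"]]
    f / (f + N - 2)
  })
  pn <- permutationNull(yo, yt, age, B = 4000, frac = 1, seed = 7,
                        scheme = "averaged")
  for (q in c(0.5, 0.9, 0.95)) {
    expect_lt(abs(quantile(pn$null[, "interaction"], q) - quantile(exact, q)),
              0.02)
  }
})

test_that("permutation p-values behave at the extremes and monotonically", {
  set.seed(8)
  age <- runif(40, 3, 13)
  yo <- rnorm(40); yt <- rnorm(40)
  pn <- permutationNull(yo, yt, age, B = 200, frac = 0.5, seed = 9,
                        observed = c(age = 2, race = 2, interaction = 2))
  expect_equal(unname(pn$permP), rep(1 / 201, 3))

  null <- pn$null[, "interaction"]
  grid <- seq(0, 0.2, by = 0.01)
  pAt <- vapply(grid, function(o) (1 + sum(null >= o)) / (1 + length(null)),
                numeric(1))
  expect_true(all(diff(pAt) <= 0))

  expect_true(significanceDecision(max(null) + 1, null))
  expect_false(significanceDecision(median(null), null))
  expect_error(significanceDecision(1, numeric(0)), "nonempty")
})

test_that("swapping the condition labels flips nothing but signs", {
  set.seed(10)
  age <- runif(25, 3, 13)
  yo <- rnorm(25); yt <- rnorm(25)
  a <- rmAnovaAgeRace(yo, yt, age)
  b <- rmAnovaAgeRace(yt, yo, age)
  expect_equal(a$F, b$F, tolerance = 1e-12)  # two-sided effects
  expect_equal(nore(yo, yt), -nore(yt, yo))
})

test_that("NORE and Pearson helpers compute what they say", {
  expect_equal(nore(c(0.5, 0.2), c(0.2, 0.2)), c(0.3, 0))

  x <- 1:10
  expect_equal(unname(pearsonR(x, 2 * x + 1)[["r"]]), 1)

  set.seed(11)
  y <- rnorm(50)
  x2 <- rnorm(50)
  yOrth <- residuals(lm(y ~ x2))
  expect_lt(abs(pearsonR(x2, yOrth)[["r"]]), 1e-10)

  x3 <- c(1, 2, 4, 7, 9); y3 <- c(2, 1, 5, 4, 8)
  manual <- sum((x3 - mean(x3)) * (y3 - mean(y3))) /
    sqrt(sum((x3 - mean(x3))^2) * sum((y3 - mean(y3))^2))
  expect_equal(unname(pearsonR(x3, y3)[["r"]]), manual, tolerance = 1e-12)
})

test_that("behavioral accuracy ANOVA finds a planted pure age effect", {
  set.seed(12)
  Fs <- replicate(30, {
    N <- 60
    age <- runif(N, 3.25, 13.49)
    acc <- pmin(1, pmax(0, 0.35 + 0.03 * age))
    rec <- data.frame(age = age,
                      accOwn = pmin(1, pmax(0, acc + rnorm(N, sd = 0.08))),
                      accOther = pmin(1, pmax(0, acc + rnorm(N, sd = 0.08))))
    behavioralAnova(rec)$F
  })
  expect_gt(min(Fs[1, ]), 10)            # age effect everywhere
  expect_lt(abs(mean(Fs[2, ]) - 1), 0.6) # race F ~ 1 under the null
  expect_lt(abs(mean(Fs[3, ]) - 1), 0.6) # interaction F ~ 1 under the null

  rec <- data.frame(age = runif(10, 3, 13), accOwn = rep(0.5, 10),
                    accOther = rep(0.5, 10))
  out <- behavioralAnova(rec)
  expect_equal(out$F[2:3], c(0, 0))
  expect_error(behavioralAnova(data.frame(age = 1:5, accOwn = 2,
                                          accOther = 0.5)), "\\[0, 1\\]")
})

test_that("post-hoc t-tests match the textbook formulas", {
  set.seed(13)
  age <- runif(20, 3, 13)
  y <- rnorm(20)
  out0 <- posthocTtests(y, y, age)
  expect_equal(out0$t[1:2], c(0, 0))

  yo <- rnorm(20); yt <- rnorm(20)
  out <- posthocTtests(yo, yt, age, split = median(age))
  young <- age <= median(age)
  d <- (yo - yt)[young]
  tPaired <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$t[out$contrast == "paired_younger"], tPaired,
               tolerance = 1e-10)
  n1 <- sum(young); n2 <- sum(!young)
  sp2 <- ((n1 - 1) * var(yo[young]) + (n2 - 1) * var(yo[!young])) / (n1 + n2 - 2)
  tTwo <- (mean(yo[young]) - mean(yo[!young])) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(out$t[out$contrast == "twosample_own"], tTwo,
               tolerance = 1e-10)
})

test_that("edge inference and the cohort driver agree", {
  set.seed(14)
  N <- 40; nch <- 3
  age <- runif(N, 3.25, 13.49)
  own <- array(rnorm(nch * nch * N), c(nch, nch, N))
  other <- array(rnorm(nch * nch * N), c(nch, nch, N))
  for (k in 1:N) { diag(own[, , k]) <- NA; diag(other[, , k]) <- NA }

  st <- cohortEdgeStats(own, other, age, Bboot = 100, Bperm = 100,
                        seed = 15)
  expect_equal(nrow(st), nch * (nch - 1))
  one <- edgeInference(own[1, 2, ], other[1, 2, ], age, Bboot = 100,
                       Bperm = 100, seed = 15)
  row <- st[st$from == 1 & st$to == 2, names(one)]
  rownames(row) <- NULL
  expect_equal(row, one, tolerance = 1e-12)

  prov <- attr(st, "provenance")
  expect_equal(prov$scheme, "averaged")
  expect_match(prov$ageNull, "permuted")
})
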