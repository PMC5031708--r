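test_that("generateVarSeries is deterministic and respects independence", {
  A0 <- matrix(0, 2, 2)
  z1 <- generateVarSeries(A0, 5000, seed = 4)
  z2 <- generateVarSeries(A0, 5000, seed = 4)
  expect_identical(z1, z2)

  # zero coupling: cross-correlations at small lags stay at sampling error
  for (lag in 0:3) {
    cc <- cor(z1[1:(5000 - lag), 1], z1[(1 + lag):5000, 2])
    expect_lt(abs(cc), 0.05)
  }
})

test_that("a lag-1 coupling of 0.8 gives the stationary variance 1.64", {
  A <- rbind(c(0, 0), c(0.8, 0))  # channel 1 drives channel 2
  z <- generateVarSeries(A, 100000, seed = 9)
  expect_equal(var(z[, 2]), 1.64, tolerance = 0.03)
  expect_equal(var(z[, 1]), 1.00, tolerance = 0.03)
})

test_that("non-stationary and undersized configurations are rejected", {
  expect_error(generateVarSeries(matrix(1.05, 1, 1), 1000),
               "non-stationary")
  expect_error(generateVarSeries(matrix(0.5, 1, 1), 8), "nSamples")
})

test_that("planted couplings realize the age/condition formula", {
  e <- plantedEdge(1, 2, base = 0.1, ageSlope = 0.01, condOffset = 0.05,
                   interSlope = 0.02)
  expect_equal(fnirsGCA:::.realizedCoupling(e, 10, "other"), 0.1 + 0.1)
  expect_equal(fnirsGCA:::.realizedCoupling(e, 10, "own"),
               0.1 + 0.1 + 0.05 + 0.2)
  expect_error(plantedEdge(3, 3), "distinct")
})

test_that("generateCohort emits the designed cohort layout", {
  cfg <- synthConfig(nParticipants = 5, nChannels = 6, seed = 2)
  coh <- generateCohort(cfg)
  recs <- recordings(coh)
  expect_length(recs, 10L)
  expect_equal(sum(vapply(recs, condition, character(1)) == "own"), 5L)

  ages <- cohortAges(coh)
  expect_true(all(ages >= 3.25 & ages <= 13.49))

  # 20 trials x 13 s x 10 Hz + 2 x 2 s padding
  expect_equal(nrow(recordingData(recs[[1]])), 2640L)
  expect_equal(ncol(recordingData(recs[[1]])), 6L)
  expect_length(trialOnsets(recs[[1]]), 20L)
  expect_equal(trialOnsets(recs[[1]])[1], 21L)

  # pure-null config carries an empty but well-formed truth ledger
  expect_equal(nrow(groundTruth(coh)), 0L)
  expect_true(all(c("from", "to", "base", "interSlope") %in%
                    names(groundTruth(coh))))

  # regeneration under the same master seed is identical
  coh2 <- generateCohort(cfg)
  expect_identical(recordingData(recs[[3]]),
                   recordingData(recordings(coh2)[[3]]))
})

test_that("participant-level nuisance is shared between conditions", {
  # with innovations silenced the recording is pure drift, which must be
  # identical for the two conditions of one participant
  cfg <- synthConfig(nParticipants = 2, nChannels = 3, nTrials = 2,
                     innovationSd = 0, seed = 8)
  coh <- generateCohort(cfg)
  recs <- recordings(coh)
  expect_equal(recordingData(recs[[1]]), recordingData(recs[[2]]))
  # but differs across participants (random phases)
  expect_gt(max(abs(recordingData(recs[[1]]) - recordingData(recs[[3]]))), 0.01)
})

test_that("invalid cohort configurations error", {
  expect_error(synthConfig(nParticipants = 0), "positive integer")
  expect_error(synthConfig(ageRange = c(5, 2)), "increasing")
  expect_error(synthConfig(nParticipants = 3, ages = c(4, 5)), "length")
  expect_error(
    generateCohort(synthConfig(nParticipants = 2, nChannels = 2, ages = c(4, 20),
                               seed = 1)),
    "outside ageRange")
  # couplings that blow up anywhere in the cohort are rejected up front
  # (a reciprocal pair: spectral radius selfCoef + coupling >= 1)
  expect_error(
    generateCohort(synthConfig(nParticipants = 2, nChannels = 2,
                               planted = list(plantedEdge(1, 2, base = 0.6),
                                              plantedEdge(2, 1, base = 0.6)),
                               selfCoef = 0.5, seed = 1)),
    "non-stationary")
})

test_that("planted directed couplings are recovered with the right direction", {
  cfg <- synthConfig(nParticipants = 6, nChannels = 4,
                     planted = list(plantedEdge(1, 2, base = 0.6)),
                     seed = 3)
  coh <- generateCohort(cfg)
  maps <- cohortCausalMaps(coh, pMax = 10)
  w12 <- vapply(maps, function(m) gcWeights(m)[1, 2], numeric(1))
  w21 <- vapply(maps, function(m) gcWeights(m)[2, 1], numeric(1))
  expect_gt(median(w12), median(w21))
  expect_gt(median(w12), 0.05)
})

test_that("cohorts round-trip through the long-format text layout", {
  cfg <- synthConfig(nParticipants = 2, nChannels = 3, nTrials = 2,
                     planted = list(plantedEdge(1, 3, base = 0.4)), seed = 5)
  coh <- generateCohort(cfg)
  dir <- tempfile("cohort")
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_length(recordings(back), 4L)
  orig <- recordings(coh)[[1]]
  rest <- recordings(back)[[1]]
  expect_equal(recordingData(rest), unname(recordingData(orig)),
               tolerance = 1e-12)
  expect_equal(ageYears(rest), ageYears(orig))
  expect_equal(trialOnsets(rest), trialOnsets(orig))
  expect_equal(groundTruth(back)$from, groundTruth(coh)$from)
})
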