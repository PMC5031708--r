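# Synthetic cohort generator.
#
# Emulates the study design the downstream statistics expect: N
# participants with continuous ages, each measured under two task
# conditions (own- vs other-race faces), each recording a multichannel
# 10 Hz oxy-Hb series spanning 20 test trials (3 s stimulus + 10 s
# fixation) plus 2 s pre/post baseline padding. Directed couplings are
# planted as lag-specified VAR coefficients whose strength can depend on
# age, condition, and their interaction; physiological nuisance
# oscillations (cardiac, respiratory, Mayer waves) ride on top with
# participant-random phases shared between the two conditions.

#' Define a planted directed coupling
#'
#' The realized VAR coefficient for a participant of age \code{a} under
#' condition \code{cond} is
#' \deqn{c(a, cond) = base + ageSlope \cdot a + [cond = own]\,(condOffset + interSlope \cdot a).}
#' An \code{interSlope > 0} therefore plants an age-by-condition
#' interaction whose neural ORE (own minus other edge weight) grows with
#' age.
#'
#' @param from,to channel ids (source and target of the directed edge).
#' @param base baseline coupling coefficient (unitless VAR weight).
#' @param ageSlope coefficient change per year of age.
#' @param condOffset coefficient added in the own-race condition.
#' @param interSlope per-year coefficient added in the own-race condition.
#' @param lag the VAR lag at which the coupling is injected (default 1).
#' @return list of class \code{"plantedEdge"}.
#' @examples
#' plantedEdge(3, 7, base = 0.3, interSlope = 0.04)
#' @export
plantedEdge <- function(from, to, base = 0, ageSlope = 0, condOffset = 0,
                        interSlope = 0, lag = 1L) {
  if (!.isCount(from) || !.isCount(to) || from == to)
    stop("from and to must be distinct positive channel ids")
  if (!.isCount(lag))
    stop("lag must be a positive integer")
  structure(list(from = as.integer(from), to = as.integer(to),
                 base = base, ageSlope = ageSlope, condOffset = condOffset,
                 interSlope = interSlope, lag = as.integer(lag)),
            class = "plantedEdge")
}

.realizedCoupling <- function(edge, age, condition) {
  edge$base + edge$ageSlope * age +
    (condition == "own") * (edge$condOffset + edge$interSlope * age)
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the acquisition the package models: 124 children
#' with ages continuous on [3.25, 13.49] years, 46 channels sampled at
#' 10 Hz, a testing phase of 20 trials of 3 s stimulus + 10 s fixation,
#' and 2 s of pre/post baseline padding (2640 samples per condition).
#'
#' @param nParticipants number of participants (default 124).
#' @param ageRange numeric length-2, ages in years (default
#'   \code{c(3.25, 13.49)}).
#' @param ages optional explicit age vector (overrides random draws).
#' @param ageDist \code{"uniform"} (default; maximizes leverage for
#'   age-slope recovery) or \code{"truncnorm"} (mean 7.77, SD 2.80,
#'   truncated to \code{ageRange}, matching the cohort moments the
#'   design emulates).
#' @param nChannels number of montage channels (default 46).
#' @param fs sampling rate in Hz (default 10).
#' @param nTrials test trials per condition (default 20).
#' @param stimS,fixS stimulus and fixation durations in seconds
#'   (defaults 3 and 10).
#' @param padS pre/post baseline padding in seconds (default 2).
#' @param planted list of \code{\link{plantedEdge}} couplings (may be
#'   empty: a pure-null cohort).
#' @param selfCoef lag-1 autoregressive coefficient of every channel
#'   (default 0.3, giving mildly smooth hemodynamic-like series).
#' @param innovationSd innovation standard deviation, scalar or
#'   per-channel (default 1).
#' @param drift list of named components, each \code{c(amp=, freq=)} in
#'   signal units and Hz; defaults are cardiac (1.2 Hz), respiratory
#'   (0.3 Hz) and Mayer-wave (0.1 Hz) oscillations.
#' @param hrfSmoothing logical; convolve the generated series with the
#'   canonical HRF kernel to emulate hemodynamic blurring (default
#'   \code{FALSE}: the planted VAR is taken to live directly in the
#'   slow hemodynamic fluctuations).
#' @param seed master RNG seed (per-participant child streams are
#'   derived from it, so generation is order-independent).
#' @return list of class \code{"synthConfig"}.
#' @seealso \code{\link{generateCohort}}
#' @export
synthConfig <- function(nParticipants = 124L,
                        ageRange = c(3.25, 13.49),
                        ages = NULL,
                        ageDist = c("uniform", "truncnorm"),
                        nChannels = 46L,
                        fs = 10,
                        nTrials = 20L,
                        stimS = 3,
                        fixS = 10,
                        padS = 2,
                        planted = list(),
                        selfCoef = 0.3,
                        innovationSd = 1,
                        drift = list(cardiac = c(amp = 0.5, freq = 1.2),
                                     respiratory = c(amp = 0.5, freq = 0.3),
                                     mayer = c(amp = 0.8, freq = 0.1)),
                        hrfSmoothing = FALSE,
                        seed = NULL) {
  ageDist <- match.arg(ageDist)
  if (!.isCount(nParticipants))
    stop("nParticipants must be a positive integer")
  if (length(ageRange) != 2L || ageRange[1] >= ageRange[2] || any(ageRange <= 0))
    stop("ageRange must be an increasing positive pair")
  if (!is.null(ages) && length(ages) != nParticipants)
    stop("ages must have length nParticipants")
  if (!.isCount(nChannels) || nChannels < 2)
    stop("nChannels must be an integer >= 2")
  if (fs <= 0 || stimS <= 0 || fixS <= 0 || padS < 0 || !.isCount(nTrials))
    stop("durations must be positive and nTrials a positive integer")
  if (inherits(planted, "plantedEdge")) planted <- list(planted)
  ok <- vapply(planted, inherits, logical(1), what = "plantedEdge")
  if (length(planted) && !all(ok))
    stop("planted must be a list of plantedEdge objects")
  for (e in planted)
    if (e$from > nChannels || e$to > nChannels)
      stop("planted edge channel id exceeds nChannels")
  if (any(unlist(lapply(drift, function(d) d[["freq"]])) > fs / 2))
    stop("drift component frequency exceeds the Nyquist limit")
  structure(list(
    nParticipants = as.integer(nParticipants), ageRange = ageRange,
    ages = ages, ageDist = ageDist, nChannels = as.integer(nChannels),
    fs = fs, nTrials = as.integer(nTrials), stimS = stimS, fixS = fixS,
    padS = padS, planted = planted, selfCoef = selfCoef,
    innovationSd = innovationSd, drift = drift,
    hrfSmoothing = isTRUE(hrfSmoothing), seed = seed
  ), class = "synthConfig")
}

.nSamplesPerCondition <- function(config) {
  as.integer(round(config$nTrials * (config$stimS + config$fixS) * config$fs +
                     2 * config$padS * config$fs))
}

# Largest modulus eigenvalue of the VAR companion matrix.
.companionRadius <- function(coefList) {
  p <- length(coefList)
  n <- nrow(coefList[[1L]])
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p))
    comp[seq_len(n), (l - 1L) * n + seq_len(n)] <- coefList[[l]]
  if (p > 1L)
    comp[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Per-lag coefficient matrices (target row, source column) realized for
# one participant age and condition.
.varCoefMatrices <- function(config, age, condition) {
  maxLag <- max(1L, vapply(config$planted, `[[`, integer(1), "lag"))
  coefs <- replicate(maxLag, matrix(0, config$nChannels, config$nChannels),
                     simplify = FALSE)
  diag(coefs[[1L]]) <- config$selfCoef
  for (e in config$planted)
    coefs[[e$lag]][e$to, e$from] <- coefs[[e$lag]][e$to, e$from] +
      .realizedCoupling(e, age, condition)
  coefs
}

#' Simulate a stationary VAR time series
#'
#' Simulates \code{z[t, ] = sum_l coef[[l]] \%*\% z[t - l, ] + e[t, ]}
#' with Gaussian innovations, discarding a burn-in. Coefficient matrices
#' are indexed (target row, source column). A configuration whose
#' companion matrix has spectral radius >= 1 is rejected.
#'
#' @param coef a single matrix (lag 1) or list of per-lag matrices.
#' @param nSamples samples to return after burn-in.
#' @param innovationSd innovation SD, scalar or per-channel vector.
#' @param seed optional RNG seed (bit-identical output under the same
#'   seed; the caller's RNG state is restored).
#' @param burnin discarded leading samples (default 200).
#' @return numeric matrix \code{nSamples} x \code{nChannels}.
#' @examples
#' A <- rbind(c(0, 0), c(0.8, 0))  # channel 1 drives channel 2
#' z <- generateVarSeries(A, 1000, seed = 1)
#' @export
generateVarSeries <- function(coef, nSamples, innovationSd = 1, seed = NULL,
                              burnin = 200L) {
  if (is.matrix(coef)) coef <- list(coef)
  if (!length(coef) || !all(vapply(coef, is.matrix, logical(1))))
    stop("coef must be a matrix or list of matrices")
  n <- nrow(coef[[1L]])
  if (any(vapply(coef, function(m) !identical(dim(m), c(n, n)), logical(1))))
    stop("all coefficient matrices must be square of equal dimension")
  p <- length(coef)
  if (!.isCount(nSamples) || nSamples <= 10 * p)
    stop("nSamples must exceed 10 * order")
  rho <- .companionRadius(coef)
  if (rho >= 1)
    stop(sprintf("non-stationary VAR coefficients (spectral radius %.3f >= 1)",
                 rho))
  sdVec <- rep_len(innovationSd, n)
  if (any(sdVec < 0)) stop("innovationSd must be nonnegative")
  burnin <- max(as.integer(burnin), 200L)
  total <- nSamples + burnin
  .withSeed(seed, {
    e <- matrix(rnorm(total * n), total, n) %*% diag(sdVec, n)
    z <- matrix(0, total, n)
    for (t in (p + 1L):total) {
      acc <- e[t, ]
      for (l in seq_len(p))
        acc <- acc + coef[[l]] %*% z[t - l, ]
      z[t, ] <- acc
    }
    z[(burnin + 1L):total, , drop = FALSE]
  })
}

# Physiological oscillations: sum of sinusoids with per-channel phases.
.driftMatrix <- function(drift, phases, nSamples, fs, nChannels) {
  tt <- (seq_len(nSamples) - 1L) / fs
  D <- matrix(0, nSamples, nChannels)
  for (k in seq_along(drift)) {
    amp <- drift[[k]][["amp"]]
    freq <- drift[[k]][["freq"]]
    D <- D + amp * sin(outer(2 * pi * freq * tt, rep(1, nChannels)) +
                         matrix(phases[, k], nSamples, nChannels, byrow = TRUE))
  }
  D
}

#' Generate a synthetic two-condition cohort
#'
#' Draws participant ages, realizes the planted VAR couplings per
#' participant and condition, simulates both recordings, and adds the
#' physiological drift components (phases drawn once per participant and
#' shared across conditions). The planted-effect ledger is carried in
#' the returned object for recovery scoring.
#'
#' Stationarity is pre-checked at the extreme ages of the cohort for
#' both conditions; a configuration that is non-stationary for any
#' cohort member is rejected.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return a \linkS4class{NirsCohort} with \code{2 * nParticipants}
#'   recordings (conditions own/other per participant).
#' @examples
#' cfg <- synthConfig(nParticipants = 2, nChannels = 4, nTrials = 2,
#'                    seed = 1)
#' coh <- generateCohort(cfg)
#' length(recordings(coh))  # 4
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "synthConfig"))
    stop("config must come from synthConfig()")
  n <- config$nParticipants
  nSamples <- .nSamplesPerCondition(config)
  seeds <- .childSeeds(if (is.null(config$seed)) sample.int(1e9, 1) else config$seed,
                       n + 1L)
  ages <- config$ages
  if (is.null(ages)) {
    ages <- .withSeed(seeds[n + 1L], {
      if (config$ageDist == "uniform") {
        runif(n, config$ageRange[1], config$ageRange[2])
      } else {
        out <- numeric(0)
        while (length(out) < n) {
          cand <- rnorm(2L * n, mean = 7.77, sd = 2.80)
          out <- c(out, cand[cand >= config$ageRange[1] &
                               cand <= config$ageRange[2]])
        }
        out[seq_len(n)]
      }
    })
  }
  if (any(ages < config$ageRange[1] - 1e-9) ||
      any(ages > config$ageRange[2] + 1e-9))
    stop("explicit ages fall outside ageRange")

  # reject configurations that are non-stationary anywhere in the cohort
  for (a in range(ages)) for (cond in c("own", "other")) {
    rho <- .companionRadius(.varCoefMatrices(config, a, cond))
    if (rho >= 1)
      stop(sprintf(
        "planted couplings give a non-stationary VAR at age %.2f (%s): spectral radius %.3f",
        a, cond, rho))
  }

  onsets <- as.integer(round(config$padS * config$fs +
    (seq_len(config$nTrials) - 1L) * (config$stimS + config$fixS) * config$fs + 1L))
  kern <- if (config$hrfSmoothing) hrfKernel(config$fs) else NULL

  recs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    pid <- sprintf("p%03d", i)
    pair <- .withSeed(seeds[i], {
      phases <- matrix(runif(config$nChannels * length(config$drift),
                             0, 2 * pi),
                       config$nChannels, length(config$drift))
      drift <- .driftMatrix(config$drift, phases, nSamples, config$fs,
                            config$nChannels)
      lapply(c("own", "other"), function(cond) {
        z <- generateVarSeries(.varCoefMatrices(config, ages[i], cond),
                               nSamples, config$innovationSd, seed = NULL)
        if (!is.null(kern)) z <- .convolveReflect(z, kern)
        NirsRecording(pid, ages[i], cond, config$fs, z + drift,
                      trialOnsets = onsets)
      })
    })
    recs[[2L * i - 1L]] <- pair[[1L]]
    recs[[2L * i]] <- pair[[2L]]
  }

  truth <- if (length(config$planted)) {
    do.call(rbind, lapply(config$planted, function(e)
      data.frame(from = e$from, to = e$to, lag = e$lag, base = e$base,
                 ageSlope = e$ageSlope, condOffset = e$condOffset,
                 interSlope = e$interSlope)))
  } else {
    data.frame(from = integer(), to = integer(), lag = integer(),
               base = numeric(), ageSlope = numeric(),
               condOffset = numeric(), interSlope = numeric())
  }
  new("NirsCohort", recordings = recs, truth = truth,
      config = unclass(config))
}

#' Write / read a cohort as plain-text tables
#'
#' Each recording is written as a long-format TSV (time, channel, value)
#' plus a JSON sidecar carrying participant id, age, condition, sampling
#' rate, trial onsets and the preprocessing flag; cohort-level files
#' store the planted-coupling ledger and the generating configuration.
#'
#' @param cohort a \linkS4class{NirsCohort}.
#' @param dir output directory (created if needed).
#' @return \code{writeCohort}: \code{dir} invisibly; \code{readCohort}:
#'   a \linkS4class{NirsCohort}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in recordings(cohort)) {
    stem <- file.path(dir, paste0(participantId(rec), "_", condition(rec)))
    d <- recordingData(rec)
    long <- data.frame(
      time = rep((seq_len(nrow(d)) - 1L) / samplingRate(rec), ncol(d)),
      channel = rep(seq_len(ncol(d)), each = nrow(d)),
      value = as.vector(d))
    write.table(long, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    side <- list(participantId = participantId(rec), age = ageYears(rec),
                 condition = condition(rec), fs = samplingRate(rec),
                 trialOnsets = trialOnsets(rec),
                 preprocessed = isPreprocessed(rec))
    jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  write.table(groundTruth(cohort), file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- cohortConfig(cohort)
  cfg$planted <- lapply(cfg$planted, unclass)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  sides <- sort(list.files(dir, pattern = "^p.*\\.json$", full.names = TRUE))
  # mirror generator order: participants ascending, own before other
  pid <- sub("_(own|other)\\.json$", "", basename(sides))
  cond <- sub("^.*_(own|other)\\.json$", "\\1", basename(sides))
  sides <- sides[order(pid, match(cond, c("own", "other")))]
  recs <- lapply(sides, function(sf) {
    meta <- jsonlite::read_json(sf, simplifyVector = TRUE)
    long <- read.delim(sub("\\.json$", ".tsv", sf))
    nS <- length(unique(long$time))
    nC <- length(unique(long$channel))
    d <- matrix(long$value[order(long$channel, long$time)], nS, nC)
    NirsRecording(meta$participantId, meta$age, meta$condition, meta$fs, d,
                  trialOnsets = as.integer(meta$trialOnsets),
                  preprocessed = isTRUE(meta$preprocessed))
  })
  truth <- read.delim(file.path(dir, "truth.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  new("NirsCohort", recordings = recs, truth = truth,
      config = as.list(cfg))
}
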