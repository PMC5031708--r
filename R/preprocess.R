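# Oxy-Hb preprocessing chain: HRF-shaped low-pass smoothing, drift
# removal, and two-point baseline correction. The order is fixed
# (low-pass -> detrend -> baseline) and recorded in provenance; each
# step is strictly per-channel, so preprocessing commutes with channel
# permutation.

#' Canonical HRF smoothing kernel
#'
#' The canonical double-gamma hemodynamic response function (peak delay
#' 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot ratio
#' 6) sampled at \code{fs} and normalized to unit sum, for use as a
#' low-pass smoothing kernel. The positive lobe peaks at ~5 s (mode of
#' the shape-6, scale-1 gamma) and is followed by a single undershoot.
#'
#' @param fs sampling rate in Hz.
#' @param durationS kernel length in seconds; the default 32 s covers
#'   the undershoot.
#' @return numeric vector of \code{fs * durationS} weights summing to 1.
#' @examples
#' k <- hrfKernel(10)
#' length(k)        # 320
#' sum(k)           # 1
#' which.max(k) / 10  # ~5 s
#' @export
hrfKernel <- function(fs, durationS = 32) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!is.numeric(durationS) || length(durationS) != 1L || durationS <= 0)
    stop("durationS must be a single positive number")
  tt <- seq(0, by = 1 / fs, length.out = round(fs * durationS))
  h <- dgamma(tt, shape = 6, rate = 1) - dgamma(tt, shape = 16, rate = 1) / 6
  h / sum(h)
}

# Causal convolution with reflect padding at the onset: output has the
# input length and a constant input maps to itself (unit-sum kernel).
.convolveReflect <- function(x, kern) {
  onecol <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  L <- length(kern)
  if (n < 2L) stop("degenerate input: channel too short to filter")
  padIdx <- rev(rep_len(2:n, L))  # mirror without repeating the edge sample
  out <- apply(x, 2L, function(col) {
    xp <- c(col[padIdx], col)
    y <- stats::filter(xp, kern, method = "convolution", sides = 1)
    as.numeric(y[(L + 1L):(L + n)])
  })
  if (onecol) drop(out) else out
}

#' Low-pass filter a recording with the canonical HRF shape
#'
#' Convolves every channel with \code{\link{hrfKernel}}, reflect-padding
#' the onset so the output keeps the input length without a filter
#' transient. Being a unit-sum kernel, a constant channel is preserved
#' exactly; broadband noise is strongly attenuated above ~0.2 Hz, which
#' suppresses cardiac and respiratory oscillations.
#'
#' @param recording a \linkS4class{NirsRecording}.
#' @param durationS kernel duration in seconds (default 32).
#' @return the filtered \linkS4class{NirsRecording} (provenance updated).
#' @seealso \code{\link{preprocessRecording}}
#' @export
hrfLowpass <- function(recording, durationS = 32) {
  d <- recordingData(recording)
  if (!nrow(d) || !ncol(d)) stop("degenerate input: empty recording")
  kern <- hrfKernel(samplingRate(recording), durationS)
  recording@data <- .convolveReflect(d, kern)
  recording@provenance <- c(provenance(recording),
                            list(list(step = "hrf_lowpass",
                                      durationS = durationS)))
  recording
}

# Discrete-cosine high-pass: project out DCT-II basis functions with
# period longer than cutoffS (plus the constant), as in SPM's high-pass.
.dctDetrend <- function(x, fs, cutoffS) {
  n <- nrow(x)
  if (cutoffS >= n / fs)
    stop("detrend cutoff period must be shorter than the session")
  kMax <- floor(2 * (n / fs) / cutoffS)
  tt <- seq_len(n)
  X <- vapply(seq_len(kMax),
              function(k) cos(pi * k * (2 * tt - 1) / (2 * n)),
              numeric(n))
  X <- cbind(1, tt, X)  # mean + linear trend + slow cosines
  qx <- qr(X)
  x - qr.fitted(qx, x)
}

# Haar pyramid detrend with MDL-chosen depth: remove the approximation
# (scaling) coefficients at the decomposition level whose removal
# minimizes an MDL score rss-fit + k log(n); candidate levels are
# restricted to scales at least cutoffS seconds so genuine signal bands
# are never eligible.
.haarDetrendColumn <- function(col, fs, cutoffS) {
  n <- length(col)
  J <- ceiling(log2(n))
  m <- 2^J
  xp <- c(col, rev(col)[seq_len(m - n)])  # reflect-pad to a power of two
  # forward Haar transform, keeping per-level detail coefficients
  approx <- xp
  details <- vector("list", J)
  for (j in seq_len(J)) {
    even <- approx[seq(2, length(approx), 2)]
    odd  <- approx[seq(1, length(approx), 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    approx <- (odd + even) / sqrt(2)
  }
  # removing the approximation at level j kills scales >= 2^(j+1)
  # samples; allow two levels below the nominal cutoff scale because a
  # smooth drift leaks into finer dyadic bands (the MDL penalty is what
  # protects the signal from over-removal)
  jMin <- max(2L, floor(log2(max(2, cutoffS * fs))) - 2L)
  jCand <- seq(from = min(jMin, J), to = J)
  # reconstruct from the details only, zeroing the approximation at
  # level jCut (details of coarser levels are re-included)
  reconstruct <- function(jCut) {
    a <- rep(0, 2^(J - jCut))
    for (j in seq(from = jCut, to = 1L)) {
      d <- details[[j]]
      odd  <- (a + d) / sqrt(2)
      even <- (a - d) / sqrt(2)
      out <- numeric(2 * length(a))
      out[seq(1, length(out), 2)] <- odd
      out[seq(2, length(out), 2)] <- even
      a <- out
    }
    a[seq_len(n)]
  }
  best <- NULL
  bestScore <- Inf
  for (jCut in jCand) {
    cand <- reconstruct(jCut)
    k <- 2^(J - jCut)          # drift coefficients spent at this depth
    rss <- sum(cand^2)         # residual (detrended) energy
    score <- n / 2 * log(max(rss, 1e-300) / n) + k * log(n)
    if (score < bestScore) {
      bestScore <- score
      best <- cand
    }
  }
  best
}

#' Remove slow drift from a recording
#'
#' Default method \code{"dct_highpass"} projects out a discrete-cosine
#' basis of periods longer than \code{cutoffS} seconds (plus the mean),
#' the standard SPM-style high-pass. Method \code{"wavelet_mdl"} is a
#' wavelet-style alternative behind the same interface: a Haar pyramid
#' whose coarse (approximation) coefficients are removed at the depth
#' selected by a minimum-description-length score. Both leave channel
#' means at ~0.
#'
#' @param recording a \linkS4class{NirsRecording} (after
#'   \code{\link{hrfLowpass}} in the standard chain).
#' @param method \code{"dct_highpass"} (default) or \code{"wavelet_mdl"}.
#' @param cutoffS drift cutoff period in seconds (default 128).
#' @return the detrended \linkS4class{NirsRecording}.
#' @export
detrendRecording <- function(recording,
                             method = c("dct_highpass", "wavelet_mdl"),
                             cutoffS = 128) {
  method <- match.arg(method)
  d <- recordingData(recording)
  fs <- samplingRate(recording)
  if (cutoffS >= nrow(d) / fs)
    stop("detrend cutoff period must be shorter than the session")
  out <- switch(method,
    dct_highpass = .dctDetrend(d, fs, cutoffS),
    wavelet_mdl = apply(d, 2L, .haarDetrendColumn, fs = fs,
                        cutoffS = cutoffS))
  recording@data <- out
  recording@provenance <- c(provenance(recording),
                            list(list(step = "detrend", method = method,
                                      cutoffS = cutoffS)))
  recording
}

#' Two-point linear baseline correction
#'
#' Per channel, subtracts the straight line through the mean of the
#' pre-task baseline window and the mean of the post-task baseline
#' window (each \code{windowS} seconds, at the session edges). Both
#' window means of the output are 0 by construction.
#'
#' @param recording a \linkS4class{NirsRecording} whose session includes
#'   at least \code{windowS} seconds of pre- and post-task padding.
#' @param windowS baseline window length in seconds (default 2).
#' @return the corrected \linkS4class{NirsRecording}.
#' @export
baselineCorrect <- function(recording, windowS = 2) {
  d <- recordingData(recording)
  fs <- samplingRate(recording)
  w <- round(windowS * fs)
  n <- nrow(d)
  if (w < 1L || n < 2L * w)
    stop("recording lacks the pre/post baseline sections")
  preIdx <- seq_len(w)
  postIdx <- (n - w + 1L):n
  mPre <- colMeans(d[preIdx, , drop = FALSE])
  mPost <- colMeans(d[postIdx, , drop = FALSE])
  tPre <- mean(preIdx)
  tPost <- mean(postIdx)
  slope <- (mPost - mPre) / (tPost - tPre)
  tt <- seq_len(n)
  line <- outer(tt - tPre, slope) +
    matrix(mPre, n, ncol(d), byrow = TRUE)
  recording@data <- d - line
  recording@provenance <- c(provenance(recording),
                            list(list(step = "baseline_correct",
                                      windowS = windowS)))
  recording
}

#' Run the full preprocessing chain
#'
#' Applies, in the fixed order, HRF-shaped low-pass smoothing
#' (\code{\link{hrfLowpass}}), drift removal
#' (\code{\link{detrendRecording}}) and two-point baseline correction
#' (\code{\link{baselineCorrect}}), then marks the recording
#' preprocessed. Re-running on an already-preprocessed recording is an
#' error.
#'
#' @param recording a raw \linkS4class{NirsRecording}.
#' @param method detrending method, see \code{\link{detrendRecording}}.
#' @param cutoffS detrend cutoff period in seconds (default 128).
#' @param windowS baseline window in seconds (default 2).
#' @param hrfDurationS HRF kernel duration in seconds (default 32).
#' @return the preprocessed \linkS4class{NirsRecording}.
#' @examples
#' raw <- NirsRecording("p1", 7, "own", 10,
#'                      matrix(rnorm(4000), 2000, 2))
#' pp <- preprocessRecording(raw)
#' isPreprocessed(pp)
#' @export
preprocessRecording <- function(recording,
                                method = c("dct_highpass", "wavelet_mdl"),
                                cutoffS = 128, windowS = 2,
                                hrfDurationS = 32) {
  if (isPreprocessed(recording))
    stop("recording is already preprocessed; re-running is not allowed")
  rec <- hrfLowpass(recording, durationS = hrfDurationS)
  rec <- detrendRecording(rec, method = method, cutoffS = cutoffS)
  rec <- baselineCorrect(rec, windowS = windowS)
  rec@preprocessed <- TRUE
  validObject(rec)
  rec
}
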