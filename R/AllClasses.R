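# S4 classes and accessors shared across the package.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' NirsRecording: one participant x condition multichannel time series
#'
#' Container for a single fNIRS recording: a time-by-channel matrix of
#' oxy-hemoglobin concentration change, the participant's age, the task
#' condition, trial onset markers and a preprocessing provenance list.
#'
#' @slot participantId character participant identifier.
#' @slot age numeric age in years.
#' @slot condition either \code{"own"} or \code{"other"} (own-race vs
#'   other-race face task).
#' @slot fs sampling rate in Hz.
#' @slot data numeric matrix, rows are samples, columns are channels.
#' @slot trialOnsets integer sample indices of stimulus onsets.
#' @slot preprocessed logical; set by \code{\link{preprocessRecording}}.
#' @slot provenance list recording the preprocessing steps applied.
#'
#' @seealso \code{\link{NirsRecording}} (constructor),
#'   \code{\link{preprocessRecording}}, \code{\link{causalMap}}
#' @name NirsRecording-class
#' @aliases NirsRecording-class
#' @exportClass NirsRecording
setClass("NirsRecording",
  representation(
    participantId = "character",
    age           = "numeric",
    condition     = "character",
    fs            = "numeric",
    data          = "matrix",
    trialOnsets   = "integer",
    preprocessed  = "logical",
    provenance    = "list"
  ),
  prototype(
    participantId = "p0", age = NA_real_, condition = "own", fs = 10,
    data = matrix(numeric(0), 0, 0), trialOnsets = integer(),
    preprocessed = FALSE, provenance = list()
  )
)

setValidity("NirsRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!object@condition %in% c("own", "other"))
    msg <- c(msg, "condition must be 'own' or 'other'")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (isTRUE(object@preprocessed) && anyNA(object@data))
    msg <- c(msg, "preprocessed recordings must not contain missing values")
  if (length(object@trialOnsets) &&
      (min(object@trialOnsets) < 1L || max(object@trialOnsets) > nrow(object@data)))
    msg <- c(msg, "trialOnsets out of range")
  if (length(msg)) msg else TRUE
})

#' Construct a NirsRecording
#'
#' @param participantId character scalar.
#' @param age age in years.
#' @param condition \code{"own"} or \code{"other"}.
#' @param fs sampling rate (Hz).
#' @param data numeric time-by-channel matrix.
#' @param trialOnsets integer sample indices of stimulus onsets.
#' @param preprocessed logical flag.
#' @param provenance list of processing records.
#' @return A \linkS4class{NirsRecording}.
#' @examples
#' rec <- NirsRecording("p1", age = 6.5, condition = "own", fs = 10,
#'                      data = matrix(rnorm(200), 100, 2))
#' @export
NirsRecording <- function(participantId, age, condition, fs, data,
                          trialOnsets = integer(), preprocessed = FALSE,
                          provenance = list()) {
  new("NirsRecording",
      participantId = as.character(participantId), age = as.numeric(age),
      condition = match.arg(condition, c("own", "other")),
      fs = as.numeric(fs), data = as.matrix(data),
      trialOnsets = as.integer(trialOnsets),
      preprocessed = isTRUE(preprocessed), provenance = provenance)
}

#' @describeIn NirsRecording-class participant identifier
#' @param object,x an object of the documented class.
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
setMethod("participantId", "NirsRecording", function(object) object@participantId)

#' @describeIn NirsRecording-class task condition ("own"/"other")
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
setMethod("condition", "NirsRecording", function(object) object@condition)

#' @describeIn NirsRecording-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
setMethod("samplingRate", "NirsRecording", function(object) object@fs)

#' @describeIn NirsRecording-class time-by-channel data matrix
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))
setMethod("recordingData", "NirsRecording", function(object) object@data)

#' @describeIn NirsRecording-class trial onset sample indices
#' @export
setGeneric("trialOnsets", function(object) standardGeneric("trialOnsets"))
setMethod("trialOnsets", "NirsRecording", function(object) object@trialOnsets)

#' @describeIn NirsRecording-class has preprocessing been applied?
#' @export
setGeneric("isPreprocessed", function(object) standardGeneric("isPreprocessed"))
setMethod("isPreprocessed", "NirsRecording", function(object) object@preprocessed)

#' @describeIn NirsRecording-class provenance list of processing steps
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
setMethod("provenance", "NirsRecording", function(object) object@provenance)

#' @describeIn NirsRecording-class participant age in years
#' @export
setGeneric("ageYears", function(object) standardGeneric("ageYears"))
setMethod("ageYears", "NirsRecording", function(object) object@age)

setMethod("show", "NirsRecording", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "NirsRecording '%s' (%s condition, age %.2f y)\n  %d samples x %d channels at %g Hz, %d trials%s\n",
    object@participantId, object@condition, object@age,
    d[1], d[2], object@fs, length(object@trialOnsets),
    if (object@preprocessed) ", preprocessed" else ", raw"))
})

#' NirsCohort: a set of recordings with ground-truth metadata
#'
#' Holds the two-condition recordings of a (synthetic) cohort, the planted
#' coupling ledger used to generate them, and the generating configuration.
#'
#' @slot recordings list of \linkS4class{NirsRecording} (two per participant).
#' @slot truth data.frame of planted directed couplings
#'   (columns from, to, lag, base, ageSlope, condOffset, interSlope).
#' @slot config list, the \code{\link{synthConfig}} used.
#'
#' @seealso \code{\link{generateCohort}}
#' @name NirsCohort-class
#' @aliases NirsCohort-class
#' @exportClass NirsCohort
setClass("NirsCohort",
  representation(recordings = "list", truth = "data.frame", config = "list"))

setValidity("NirsCohort", function(object) {
  ok <- vapply(object@recordings, is, logical(1), class2 = "NirsRecording")
  if (!all(ok)) return("all recordings must be NirsRecording objects")
  TRUE
})

#' @describeIn NirsCohort-class list of recordings
#' @param object,x an object of the documented class.
#' @export
setGeneric("recordings", function(object) standardGeneric("recordings"))
setMethod("recordings", "NirsCohort", function(object) object@recordings)

#' @describeIn NirsCohort-class planted-coupling ground-truth ledger
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
setMethod("groundTruth", "NirsCohort", function(object) object@truth)

#' @describeIn NirsCohort-class generating configuration list
#' @export
setGeneric("cohortConfig", function(object) standardGeneric("cohortConfig"))
setMethod("cohortConfig", "NirsCohort", function(object) object@config)

#' @describeIn NirsCohort-class named vector of participant ages (years)
#' @export
setGeneric("cohortAges", function(object) standardGeneric("cohortAges"))
setMethod("cohortAges", "NirsCohort", function(object) {
  own <- Filter(function(r) condition(r) == "own", object@recordings)
  setNames(vapply(own, ageYears, numeric(1)),
           vapply(own, participantId, character(1)))
})

setMethod("show", "NirsCohort", function(object) {
  n <- length(object@recordings)
  cat(sprintf("NirsCohort: %d recordings (%d participants), %d planted coupling(s)\n",
              n, n %/% 2L, nrow(object@truth)))
})

#' CausalMap: pairwise Granger weights for one recording
#'
#' A square matrix of directed Granger causality magnitudes
#' G(i -> j) = ln(reduced/full residual variance) for every ordered channel
#' pair, with the BIC-selected model order per pair. The diagonal is
#' undefined and stored as \code{NA}.
#'
#' @slot participantId character.
#' @slot condition \code{"own"} or \code{"other"}.
#' @slot age numeric years.
#' @slot weights numeric matrix; entry (i, j) is G(i -> j), \code{NA} on
#'   the diagonal and on edges incident to degenerate channels.
#' @slot orders integer matrix of selected VAR orders (symmetric per pair).
#'
#' @seealso \code{\link{causalMap}}, \code{\link{grangerPair}}
#' @name CausalMap-class
#' @aliases CausalMap-class
#' @exportClass CausalMap
setClass("CausalMap",
  representation(
    participantId = "character",
    condition     = "character",
    age           = "numeric",
    weights       = "matrix",
    orders        = "matrix"
  ))

setValidity("CausalMap", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (nrow(w) && !all(is.na(diag(w)))) msg <- c(msg, "diagonal must be NA")
  off <- w[row(w) != col(w)]
  off <- off[!is.na(off)]
  if (length(off) && any(off < -1e-8))
    msg <- c(msg, "defined weights must be nonnegative")
  if (length(off) && any(!is.finite(off)))
    msg <- c(msg, "defined weights must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn CausalMap-class matrix of Granger weights, (i, j) = G(i->j)
#' @export
setGeneric("gcWeights", function(object) standardGeneric("gcWeights"))
setMethod("gcWeights", "CausalMap", function(object) object@weights)

#' @describeIn CausalMap-class matrix of BIC-selected orders per pair
#' @export
setGeneric("gcOrders", function(object) standardGeneric("gcOrders"))
setMethod("gcOrders", "CausalMap", function(object) object@orders)

setMethod("participantId", "CausalMap", function(object) object@participantId)
setMethod("condition", "CausalMap", function(object) object@condition)
setMethod("ageYears", "CausalMap", function(object) object@age)

setMethod("show", "CausalMap", function(object) {
  w <- object@weights
  off <- w[row(w) != col(w)]
  cat(sprintf(
    "CausalMap '%s' (%s): %d x %d channels, median weight %.4g, %d missing edge(s)\n",
    object@participantId, object@condition, nrow(w), ncol(w),
    median(off, na.rm = TRUE), sum(is.na(off))))
})

#' GCNetwork: a significant-edge directed network for one ANOVA effect
#'
#' The set of directed edges whose bootstrap-averaged effect size passed
#' the permutation top-5\% rule for one effect (age, race or
#' age-by-race interaction), each classified by cortical area pair and,
#' where applicable, by developmental trend subtype.
#'
#' @slot effect one of \code{"age"}, \code{"race"}, \code{"interaction"}.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{edgeClass}, \code{trend} and per-effect statistics.
#' @slot nChannels integer number of montage channels.
#'
#' @seealso \code{\link{assembleNetwork}}, \code{\link{exportGraph}}
#' @name GCNetwork-class
#' @aliases GCNetwork-class
#' @exportClass GCNetwork
setClass("GCNetwork",
  representation(effect = "character", edges = "data.frame",
                 nChannels = "integer"))

setValidity("GCNetwork", function(object) {
  if (!object@effect %in% c("age", "race", "interaction"))
    return("effect must be 'age', 'race' or 'interaction'")
  need <- c("from", "to", "edgeClass")
  if (nrow(object@edges) && !all(need %in% names(object@edges)))
    return("edges must carry from, to and edgeClass columns")
  TRUE
})

#' @describeIn GCNetwork-class data.frame of significant edges
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
setMethod("networkEdges", "GCNetwork", function(object) object@edges)

#' @describeIn GCNetwork-class edge counts by area-pair class
#' @export
setGeneric("networkCounts", function(object) standardGeneric("networkCounts"))
setMethod("networkCounts", "GCNetwork", function(object) {
  lv <- edgeClassLevels()
  cls <- factor(object@edges$edgeClass, levels = lv)
  table(cls)
})

#' @describeIn GCNetwork-class the ANOVA effect the network belongs to
#' @export
setGeneric("networkEffect", function(object) standardGeneric("networkEffect"))
setMethod("networkEffect", "GCNetwork", function(object) object@effect)

setMethod("show", "GCNetwork", function(object) {
  cnt <- networkCounts(object)
  cat(sprintf("GCNetwork (%s effect): %d significant edge(s)\n",
              object@effect, nrow(object@edges)))
  if (nrow(object@edges)) {
    for (k in names(cnt)) if (cnt[[k]] > 0)
      cat(sprintf("  %-28s %d\n", k, cnt[[k]]))
  }
})
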