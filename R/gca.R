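# Bivariate Granger causality per ordered channel pair.
#
# For channels A and B, each series is fitted with a reduced AR(p) model
# on its own lags and a full model augmented with the other channel's
# lags; the causality magnitude is the Geweke log variance ratio
#   G(B -> A) = ln( var(eps_A, reduced) / var(eps_BA, full) ) >= 0,
# with residual variances as maximum-likelihood (1/T_eff) estimates so
# the least-squares nesting inequality guarantees nonnegativity. The
# common order p per pair is chosen by the bivariate VAR BIC.

#' Fit an autoregressive model by least squares
#'
#' Fits \code{y[t] = a0 + sum a_i y[t-i] (+ sum b_i x[t-i]) + e[t]} by
#' ordinary least squares with an intercept. The residual variance is
#' the maximum-likelihood estimate (mean squared residual over the
#' effective sample), and \code{bic = T_eff log(rv) + k log(T_eff)} with
#' \code{k} the number of estimated coefficients.
#'
#' @param y numeric series (response).
#' @param p autoregressive order.
#' @param x optional conditioning series whose lags 1..p augment the
#'   model (the "full" model of a Granger pair).
#' @return list of class \code{"arFit"}: \code{order}, \code{intercept},
#'   \code{ownCoef}, \code{crossCoef}, \code{residuals},
#'   \code{residVar}, \code{nObs}, \code{bic}.
#' @examples
#' set.seed(1)
#' y <- as.numeric(arima.sim(list(ar = 0.6), 5000))
#' fitAr(y, 1)$ownCoef  # ~0.6
#' @export
fitAr <- function(y, p, x = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (!.isCount(p)) stop("p must be a positive integer")
  if (n <= 3 * p + 3) stop("series too short for order ", p)
  if (!is.null(x)) {
    x <- as.numeric(x)
    if (length(x) != n) stop("x must have the same length as y")
  }
  Y <- y[(p + 1L):n]
  L <- embed(y, p + 1L)[, -1L, drop = FALSE]
  X <- if (is.null(x)) cbind(1, L) else
    cbind(1, L, embed(x, p + 1L)[, -1L, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("degenerate input: singular lag design (constant series?)")
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  tEff <- length(Y)
  rv <- sum(res^2) / tEff
  if (!is.finite(rv) || rv < 0)
    stop("degenerate input: invalid residual variance")
  k <- ncol(X)
  structure(list(
    order = p,
    intercept = beta[1L],
    ownCoef = beta[2L:(p + 1L)],
    crossCoef = if (is.null(x)) NULL else beta[(p + 2L):(2L * p + 1L)],
    residuals = as.numeric(res),
    residVar = rv,
    nObs = tEff,
    bic = tEff * log(max(rv, .Machine$double.xmin)) + k * log(tEff)
  ), class = "arFit")
}

#' Select the common VAR order of a channel pair by BIC
#'
#' Fits the bivariate VAR(p) for p = 1..pMax on the common effective
#' sample (conditioning on \code{pMax} initial values so all candidates
#' see identical data) and returns the order minimizing
#' \code{T_eff log det(Sigma) + k log(T_eff)}, where Sigma is the ML
#' residual covariance and \code{k = 2(2p + 1)} the coefficient count.
#' Ties break toward the smaller order.
#'
#' @param a,b numeric series of equal length.
#' @param pMax largest candidate order (default 10, i.e. 1 s at 10 Hz).
#' @return the selected integer order.
#' @export
selectOrderBic <- function(a, b, pMax = 10L) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n) stop("series must have equal length")
  if (!.isCount(pMax)) stop("pMax must be a positive integer")
  if (n <= 3 * pMax + 3) stop("series too short for pMax = ", pMax)
  if (pMax == 1L) return(1L)
  idx <- (pMax + 1L):n
  Ya <- a[idx]; Yb <- b[idx]
  La <- embed(a, pMax + 1L)[, -1L, drop = FALSE]
  Lb <- embed(b, pMax + 1L)[, -1L, drop = FALSE]
  tEff <- length(idx)
  bic <- numeric(pMax)
  for (p in seq_len(pMax)) {
    X <- cbind(1, La[, seq_len(p), drop = FALSE],
               Lb[, seq_len(p), drop = FALSE])
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop("degenerate input: singular lag design")
    resA <- Ya - X %*% qr.coef(qx, Ya)
    resB <- Yb - X %*% qr.coef(qx, Yb)
    Sigma <- crossprod(cbind(resA, resB)) / tEff
    dS <- max(det(Sigma), .Machine$double.xmin)
    bic[p] <- tEff * log(dS) + 2 * (2 * p + 1) * log(tEff)
  }
  which.min(bic)  # first minimum = smallest order on ties
}

#' Pairwise Granger causality magnitudes
#'
#' Computes both directed magnitudes for a channel pair at a common
#' order: \code{G(a -> b) = ln(rv(b | own lags) / rv(b | own + a
#' lags))} and symmetrically \code{G(b -> a)}. Both are nonnegative by
#' least-squares nesting (ML variances, equal orders, common sample)
#' and invariant to rescaling either series.
#'
#' @param a,b numeric series of equal length.
#' @param p common autoregressive order.
#' @return named numeric vector \code{c(aToB =, bToA =)}.
#' @examples
#' set.seed(1)
#' a <- rnorm(5000); b <- 0.8 * c(0, a[-5000]) + rnorm(5000)
#' grangerPair(a, b, 1)  # aToB ~ ln(1.64), bToA ~ 0
#' @export
grangerPair <- function(a, b, p) {
  redA <- fitAr(a, p)
  fullA <- fitAr(a, p, b)
  redB <- fitAr(b, p)
  fullB <- fitAr(b, p, a)
  if (fullA$residVar <= 0 || fullB$residVar <= 0)
    stop("degenerate input: zero full-model residual variance")
  c(aToB = max(0, log(redB$residVar / fullB$residVar)),
    bToA = max(0, log(redA$residVar / fullA$residVar)))
}

# Fast all-pairs engine. Precomputes the intercept+all-lags cross-product
# matrices once per recording; every reduced/full fit then reduces to a
# small normal-equation solve on an index subset. All models condition on
# pMax initial samples so reduced/full pairs share the same rows and the
# nesting inequality holds exactly.
.causalMapCore <- function(Z, pMax) {
  n <- nrow(Z)
  nch <- ncol(Z)
  tEff <- n - pMax
  Y <- Z[(pMax + 1L):n, , drop = FALSE]
  L <- matrix(0, tEff, nch * pMax)
  for (ch in seq_len(nch))
    L[, (ch - 1L) * pMax + seq_len(pMax)] <-
      embed(Z[, ch], pMax + 1L)[, -1L, drop = FALSE]
  Xall <- cbind(1, L)
  G <- crossprod(Xall)
  C <- crossprod(Xall, Y)
  YtY <- crossprod(Y)
  lagCols <- function(ch, p) 1L + (ch - 1L) * pMax + seq_len(p)

  rssOf <- function(cols, target) {
    bt <- solve(G[cols, cols, drop = FALSE], C[cols, target])
    list(b = bt, rss = YtY[target, target] - sum(bt * C[cols, target]))
  }

  weights <- matrix(NA_real_, nch, nch)
  orders <- matrix(NA_integer_, nch, nch)
  logT <- log(tEff)
  for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch) {
    # order selection: bivariate VAR BIC on the common sample
    bic <- numeric(pMax)
    keepFull <- vector("list", pMax)
    for (p in seq_len(pMax)) {
      cols <- c(1L, lagCols(i, p), lagCols(j, p))
      fi <- rssOf(cols, i)
      fj <- rssOf(cols, j)
      # residual cross-covariance via the normal equations
      cij <- YtY[i, j] - sum(fj$b * C[cols, i])
      Sig <- matrix(c(fi$rss, cij, cij, fj$rss), 2L) / tEff
      dS <- max(det(Sig), .Machine$double.xmin)
      bic[p] <- tEff * log(dS) + 2 * (2 * p + 1) * logT
      keepFull[[p]] <- c(fullI = fi$rss, fullJ = fj$rss)
    }
    p <- which.min(bic)
    redI <- rssOf(c(1L, lagCols(i, p)), i)$rss
    redJ <- rssOf(c(1L, lagCols(j, p)), j)$rss
    fullI <- keepFull[[p]][["fullI"]]
    fullJ <- keepFull[[p]][["fullJ"]]
    if (fullI <= 0 || fullJ <= 0)
      stop("degenerate input: zero full-model residual variance")
    weights[i, j] <- max(0, log(redJ / fullJ))  # G(i -> j)
    weights[j, i] <- max(0, log(redI / fullI))  # G(j -> i)
    orders[i, j] <- orders[j, i] <- p
  }
  list(weights = weights, orders = orders)
}

#' Compute the causal map of a preprocessed recording
#'
#' For every ordered channel pair, selects the common order by bivariate
#' BIC and computes both directed Granger magnitudes on the full
#' preprocessed session series, yielding the weighted directed adjacency
#' matrix of the recording. Degenerate (near-constant) channels have
#' their incident edges set to \code{NA} with a warning.
#'
#' @param recording a preprocessed \linkS4class{NirsRecording}.
#' @param pMax largest candidate order (default 10; 1 s at 10 Hz).
#' @return a \linkS4class{CausalMap}.
#' @seealso \code{\link{grangerPair}}, \code{\link{selectOrderBic}}
#' @export
causalMap <- function(recording, pMax = 10L) {
  if (!is(recording, "NirsRecording"))
    stop("recording must be a NirsRecording")
  if (!isPreprocessed(recording))
    stop("causalMap expects a preprocessed recording; run preprocessRecording() first")
  Z <- recordingData(recording)
  if (!.isCount(pMax)) stop("pMax must be a positive integer")
  if (nrow(Z) <= 3 * pMax + 3) stop("recording too short for pMax = ", pMax)
  sds <- apply(Z, 2L, sd)
  degenerate <- which(!is.finite(sds) | sds < 1e-12)
  ok <- setdiff(seq_len(ncol(Z)), degenerate)
  weights <- matrix(NA_real_, ncol(Z), ncol(Z))
  orders <- matrix(NA_integer_, ncol(Z), ncol(Z))
  if (length(degenerate))
    warning("degenerate channel(s) ", paste(degenerate, collapse = ", "),
            ": incident edges set to NA")
  if (length(ok) >= 2L) {
    core <- .causalMapCore(Z[, ok, drop = FALSE], pMax)
    weights[ok, ok] <- core$weights
    orders[ok, ok] <- core$orders
  }
  diag(weights) <- NA_real_
  new("CausalMap", participantId = participantId(recording),
      condition = condition(recording), age = ageYears(recording),
      weights = weights, orders = orders)
}

#' Write / read a causal map as a delimited edge table
#'
#' The edge table carries one row per defined ordered pair (participant,
#' condition, from, to, weight, order); reading reconstructs the square
#' matrices, so a write/read round trip is the identity.
#'
#' @param map a \linkS4class{CausalMap}.
#' @param path output TSV path.
#' @param age participant age (read side; stored in the restored map).
#' @param nChannels matrix dimension on the read side (default: largest
#'   channel id present).
#' @return \code{writeCausalMap}: \code{path} invisibly;
#'   \code{readCausalMap}: a \linkS4class{CausalMap}.
#' @export
writeCausalMap <- function(map, path) {
  w <- gcWeights(map)
  o <- gcOrders(map)
  idx <- which(!is.na(w), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tab <- data.frame(
    participant = participantId(map), condition = condition(map),
    age = ageYears(map),
    from = idx[, 1L], to = idx[, 2L],
    weight = w[idx], order = o[idx])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCausalMap
#' @export
readCausalMap <- function(path, nChannels = NULL, age = NULL) {
  tab <- read.delim(path)
  nch <- if (is.null(nChannels)) max(tab$from, tab$to) else as.integer(nChannels)
  w <- matrix(NA_real_, nch, nch)
  o <- matrix(NA_integer_, nch, nch)
  w[cbind(tab$from, tab$to)] <- tab$weight
  o[cbind(tab$from, tab$to)] <- tab$order
  new("CausalMap", participantId = as.character(tab$participant[1L]),
      condition = as.character(tab$condition[1L]),
      age = if (is.null(age)) as.numeric(tab$age[1L]) else age,
      weights = w, orders = o)
}

#' Causal maps for every recording of a cohort
#'
#' Preprocesses (optionally) and maps each recording in turn.
#'
#' @param cohort a \linkS4class{NirsCohort}.
#' @param pMax largest candidate order per pair.
#' @param preprocess logical; run \code{\link{preprocessRecording}} on
#'   raw recordings first (default TRUE).
#' @param ... passed to \code{\link{preprocessRecording}}.
#' @return list of \linkS4class{CausalMap}, one per recording, in
#'   cohort order.
#' @export
cohortCausalMaps <- function(cohort, pMax = 10L, preprocess = TRUE, ...) {
  lapply(recordings(cohort), function(rec) {
    if (preprocess && !isPreprocessed(rec))
      rec <- preprocessRecording(rec, ...)
    causalMap(rec, pMax = pMax)
  })
}

#' Stack causal maps into a channel x channel x participant array
#'
#' @param maps list of \linkS4class{CausalMap} (one condition).
#' @return 3-D array with participant ids as the third dimnames.
#' @export
stackCausalMaps <- function(maps) {
  if (!length(maps)) stop("no maps to stack")
  nch <- nrow(gcWeights(maps[[1L]]))
  arr <- vapply(maps, gcWeights, matrix(0, nch, nch))
  dimnames(arr) <- list(NULL, NULL,
                        vapply(maps, participantId, character(1)))
  arr
}
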