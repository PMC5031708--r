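# Group-level inference per directed edge.
#
# The 2 (condition, within-participant) x 1 (age, continuous
# between-participant) repeated-measures ANOVA reduces exactly to two
# regressions on per-participant summary scores:
#   M = (own + other)/2 on centered age  -> age main effect (slope),
#   D = own - other     on centered age  -> race main effect (intercept)
#                                           and age x race interaction
#                                           (slope),
# each F with df (1, N - 2), which reproduces df = 122 at N = 124.
# Partial eta-squared for df1 = 1 is F / (F + df2).
#
# Edge-level significance follows the subsample-bootstrap scheme: the
# observed statistic is the mean partial eta-squared over B random 50%
# subsamples; the null is built by scrambling the two condition labels
# per participant (a fair-coin sign flip of D, the exchangeability-
# preserving scheme for paired data) and the decision is the strict
# top-5% rule on the permutation distribution. The age main effect is
# invariant to condition flips (participant means are unchanged), so
# its null permutes ages across participants instead; this deviation is
# recorded in the output provenance.

.EFFECTS <- c("age", "race", "interaction")

# Closed-form F statistics of the difference/mean-score reduction.
.rmAnovaF <- function(yOwn, yOther, age) {
  N <- length(age)
  xc <- age - mean(age)
  Sxx <- sum(xc^2)
  M <- (yOwn + yOther) / 2
  D <- yOwn - yOther
  df2 <- N - 2L
  bM <- sum(xc * M) / Sxx
  rssM <- sum((M - mean(M) - bM * xc)^2)
  aD <- mean(D)
  bD <- sum(xc * D) / Sxx
  rssD <- sum((D - aD - bD * xc)^2)
  fOf <- function(num, rss) {
    if (rss <= num * 1e-12 || rss <= 0) {
      if (num <= 1e-300) 0 else Inf
    } else {
      (num / rss) * df2
    }
  }
  c(age = fOf(bM^2 * Sxx, rssM),
    race = fOf(N * aD^2, rssD),
    interaction = fOf(bD^2 * Sxx, rssD))
}

#' Repeated-measures ANOVA: two-level condition by continuous age
#'
#' Tests the age main effect, the condition (face race) main effect and
#' their interaction for paired per-participant values under two
#' conditions, with age as a continuous between-participant covariate.
#' Implemented through the exact difference/mean-score reduction (see
#' the package vignette), giving every effect df (1, N - 2). Age is
#' mean-centered, so the race effect is evaluated at the cohort mean
#' age.
#'
#' @param yOwn,yOther numeric vectors of per-participant values under
#'   the own- and other-race conditions.
#' @param age numeric vector of ages in years (nonzero variance).
#' @return data.frame with one row per effect (\code{age}, \code{race},
#'   \code{interaction}): \code{F}, \code{df1}, \code{df2},
#'   \code{eta2} (partial), \code{p}.
#' @examples
#' set.seed(1)
#' age <- runif(20, 3, 13)
#' own <- 0.05 * age + rnorm(20, sd = 0.1)
#' oth <- 0.05 * age + rnorm(20, sd = 0.1)
#' rmAnovaAgeRace(own, oth, age)
#' @export
rmAnovaAgeRace <- function(yOwn, yOther, age) {
  N <- length(age)
  if (length(yOwn) != N || length(yOther) != N)
    stop("yOwn, yOther and age must have equal length")
  if (N < 4L) stop("at least 4 participants are required")
  if (var(age) <= 0) stop("age must have nonzero variance")
  if (anyNA(yOwn) || anyNA(yOther) || anyNA(age))
    stop("missing values are not allowed")
  Fv <- .rmAnovaF(yOwn, yOther, age)
  df2 <- N - 2L
  eta2 <- ifelse(is.infinite(Fv), 1, Fv / (Fv + df2))
  if (is.infinite(Fv[["race"]]) || is.infinite(Fv[["interaction"]]))
    warning("degenerate difference scores: zero residual variance")
  data.frame(effect = .EFFECTS, F = as.numeric(Fv), df1 = 1L, df2 = df2,
             eta2 = as.numeric(eta2),
             p = pf(as.numeric(Fv), 1, df2, lower.tail = FALSE),
             row.names = NULL)
}

#' Partial eta-squared from an F statistic
#'
#' \code{eta2 = F * df1 / (F * df1 + df2)}; for \code{df1 = 1} this is
#' \code{F / (F + df2)}.
#'
#' @param f F statistic (nonnegative).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta-squared in [0, 1]. Vectorized over \code{f}.
#' @examples
#' partialEtaSq(10.572, 1, 122)  # 0.0798
#' partialEtaSq(88.72, 1, 122)   # 0.42
#' @export
partialEtaSq <- function(f, df1 = 1, df2) {
  if (any(f < 0, na.rm = TRUE)) stop("F must be nonnegative")
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  f * df1 / (f * df1 + df2)
}

# Subsample index matrix (B x nSub), redrawing the rare degenerate
# subset (zero age variance), with a capped retry count.
.drawSubsets <- function(N, frac, B, age) {
  nSub <- floor(frac * N)
  if (nSub < 4L) stop("floor(frac * N) must be at least 4")
  idx <- matrix(0L, B, nSub)
  for (b in seq_len(B)) {
    for (tries in 1:100) {
      s <- sample.int(N, nSub)
      if (var(age[s]) > 0) break
      if (tries == 100L) stop("could not draw a subset with age variance")
    }
    idx[b, ] <- s
  }
  idx
}

# Shared per-cohort inference scaffolding: subset indicators, centered
# subset ages, sign-flip and age-permutation draws. Fixing the subset
# collection across the observed statistic and every permutation
# replicate makes the averaged-null scheme exactly exchangeable.
.inferencePrep <- function(age, Bboot, Bperm, frac, seed) {
  N <- length(age)
  .withSeed(seed, {
    idx <- .drawSubsets(N, frac, Bboot, age)
    nSub <- ncol(idx)
    W1 <- matrix(0, Bboot, N)
    W1[cbind(rep(seq_len(Bboot), nSub), as.vector(idx))] <- 1
    # centered ages within each subset (zero outside)
    W2 <- W1 * matrix(age, Bboot, N, byrow = TRUE)
    W2 <- W2 - (rowSums(W2) / nSub) * W1
    SxxB <- rowSums(W2^2)
    Sgn <- matrix(sample(c(-1, 1), N * Bperm, replace = TRUE), N, Bperm)
    agePerm <- vapply(seq_len(Bperm), function(r) sample(age), numeric(N))
    ageP <- unname(cbind(age, agePerm))
    list(N = N, nSub = nSub, W1 = W1, W2 = W2, SxxB = SxxB,
         Sgn = cbind(1, Sgn), ageP = ageP,
         SA = NULL, SA2 = NULL, Bboot = Bboot, Bperm = Bperm,
         frac = frac, seed = seed)
  })
}

.prepAgeCross <- function(prep) {
  prep$SA <- prep$W1 %*% prep$ageP
  prep$SA2 <- prep$W1 %*% prep$ageP^2
  prep
}

# eta2 = num / (num + RSS); guards 0/0 -> 0 and RSS ~ 0 with signal -> 1.
.etaFromParts <- function(num, rss) {
  tot <- num + pmax(rss, 0)
  eta <- num / tot
  eta[tot <= 0] <- 0
  eta
}

# Vectorized engine for one edge: returns bootstrap means (col 1 = real
# data) for all three effects across the sign-flip / age-permutation
# columns. Bperm columns of MC noise share the one fixed subset panel.
.edgeEngine <- function(yOwn, yOther, prep) {
  D <- yOwn - yOther
  M <- (yOwn + yOther) / 2
  nSub <- prep$nSub
  # race + interaction under sign flips of D
  DS <- prep$Sgn * D
  H1 <- prep$W1 %*% DS
  H2 <- prep$W2 %*% DS
  Q <- as.vector(prep$W1 %*% (D * D))
  numRace <- H1^2 / nSub
  numInt <- H2^2 / prep$SxxB
  rss <- Q - numRace - numInt
  etaRace <- .etaFromParts(numRace, rss)
  etaInt <- .etaFromParts(numInt, rss)
  # age effect on M under age permutations
  SM <- as.vector(prep$W1 %*% M)
  SM2 <- as.vector(prep$W1 %*% (M * M))
  WM <- prep$W1 * matrix(M, prep$Bboot, prep$N, byrow = TRUE)
  SxyM <- WM %*% prep$ageP
  Sxy <- SxyM - prep$SA * (SM / nSub)
  SxxP <- prep$SA2 - prep$SA^2 / nSub
  Syy <- SM2 - SM^2 / nSub
  numAge <- Sxy^2 / SxxP
  etaAge <- .etaFromParts(numAge, Syy - numAge)
  list(age = colMeans(etaAge), race = colMeans(etaRace),
       interaction = colMeans(etaInt))
}

#' Bootstrap-averaged partial eta-squared effect sizes
#'
#' Draws \code{B} random subsets of \code{floor(frac * N)} participants
#' without replacement, runs the repeated-measures ANOVA on each, and
#' returns the mean partial eta-squared per effect. Deterministic under
#' \code{seed}.
#'
#' @inheritParams rmAnovaAgeRace
#' @param B number of subsample repetitions (the reference analysis
#'   uses 10000).
#' @param frac subsample fraction (default 0.5).
#' @param seed RNG seed.
#' @return named numeric vector of averaged eta-squared for \code{age},
#'   \code{race} and \code{interaction}.
#' @export
bootstrapEffectSize <- function(yOwn, yOther, age, B = 10000L, frac = 0.5,
                                seed = NULL) {
  N <- length(age)
  if (length(yOwn) != N || length(yOther) != N)
    stop("yOwn, yOther and age must have equal length")
  if (!.isCount(B)) stop("B must be a positive integer")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  .withSeed(seed, {
    if (frac == 1) {
      # identity subsets: B repetitions of the full-sample eta2
      eta <- rmAnovaAgeRace(yOwn, yOther, age)$eta2
      return(setNames(eta, .EFFECTS))
    }
    idx <- .drawSubsets(N, frac, B, age)
    df2 <- ncol(idx) - 2L
    acc <- c(age = 0, race = 0, interaction = 0)
    for (b in seq_len(B)) {
      s <- idx[b, ]
      Fv <- .rmAnovaF(yOwn[s], yOther[s], age[s])
      acc <- acc + ifelse(is.infinite(Fv), 1, Fv / (Fv + df2))
    }
    acc / B
  })
}

#' Permutation null distribution of the edge-level effect sizes
#'
#' Builds the null by scrambling the own/other labels per participant
#' (fair-coin sign flip of the difference scores). Because participant
#' means are invariant to label flips, the age effect's null is built
#' by permuting ages across participants instead.
#'
#' Two schemes are available. \code{"averaged"} (default): every
#' permutation replicate is averaged over the same fixed collection of
#' \code{B} subsamples used for the observed statistic, making observed
#' and null draws exchangeable, so the top-5\% rule has its nominal 5\%
#' size. \code{"single"}: each replicate is a single flip + single
#' subsample eta-squared (the literal subsample-null reading; its null
#' spread includes subsampling noise the averaged observed statistic
#' does not have, giving a conservative test).
#'
#' @inheritParams bootstrapEffectSize
#' @param B permutation replicates (and, for \code{"averaged"}, the
#'   size of the shared subsample panel).
#' @param observed optional named vector of observed averaged effect
#'   sizes; when supplied, permutation p-values are returned.
#' @param scheme \code{"averaged"} or \code{"single"}; see Details.
#' @return list with \code{null} (B x 3 matrix of null effect sizes),
#'   \code{observed}, \code{permP} (add-one estimator
#'   \code{(1 + #\{null >= obs\}) / (1 + B)}) and \code{scheme}.
#' @export
permutationNull <- function(yOwn, yOther, age, B = 10000L, frac = 0.5,
                            seed = NULL, observed = NULL,
                            scheme = c("averaged", "single")) {
  scheme <- match.arg(scheme)
  N <- length(age)
  if (length(yOwn) != N || length(yOther) != N)
    stop("yOwn, yOther and age must have equal length")
  if (!.isCount(B)) stop("B must be a positive integer")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (scheme == "averaged") {
    prep <- .prepAgeCross(.inferencePrep(age, Bboot = B, Bperm = B,
                                         frac = frac, seed = seed))
    eng <- .edgeEngine(yOwn, yOther, prep)
    nullMat <- cbind(age = eng$age[-1L], race = eng$race[-1L],
                     interaction = eng$interaction[-1L])
    if (is.null(observed))
      observed <- c(age = eng$age[1L], race = eng$race[1L],
                    interaction = eng$interaction[1L])
  } else {
    nullMat <- .withSeed(seed, {
      nSub <- floor(frac * N)
      if (nSub < 4L) stop("floor(frac * N) must be at least 4")
      df2 <- nSub - 2L
      out <- matrix(0, B, 3L, dimnames = list(NULL, .EFFECTS))
      for (r in seq_len(B)) {
        flip <- sample(c(TRUE, FALSE), N, replace = TRUE)
        yo <- ifelse(flip, yOther, yOwn)
        yt <- ifelse(flip, yOwn, yOther)
        ageP <- sample(age)
        for (tries in 1:100) {
          s <- sample.int(N, nSub)
          if (var(age[s]) > 0 && var(ageP[s]) > 0) break
        }
        Fv <- .rmAnovaF(yo[s], yt[s], age[s])
        FvA <- .rmAnovaF(yOwn[s], yOther[s], ageP[s])
        eta <- ifelse(is.infinite(Fv), 1, Fv / (Fv + df2))
        etaA <- ifelse(is.infinite(FvA), 1, FvA / (FvA + df2))
        out[r, ] <- c(etaA[["age"]], eta[["race"]], eta[["interaction"]])
      }
      out
    })
  }
  permP <- NULL
  if (!is.null(observed)) {
    permP <- vapply(.EFFECTS, function(e)
      (1 + sum(nullMat[, e] >= observed[[e]])) / (1 + nrow(nullMat)),
      numeric(1))
  }
  list(null = nullMat, observed = observed, permP = permP, scheme = scheme)
}

#' Top-5\% significance decision
#'
#' An observed averaged effect size is called significant when it lies
#' in the top \code{alpha} tail of the permutation null: the add-one
#' permutation p-value \code{(1 + #\{null >= obs\}) / (1 + B)} is below
#' \code{alpha}.
#'
#' @param observed observed (bootstrap-averaged) effect size.
#' @param null numeric vector of null effect sizes.
#' @param alpha significance level (default 0.05).
#' @return logical.
#' @export
significanceDecision <- function(observed, null, alpha = 0.05) {
  if (!length(null)) stop("null distribution must be nonempty")
  (1 + sum(null >= observed)) / (1 + length(null)) < alpha
}

#' Neural other-race effect (NORE)
#'
#' Per-participant difference in effective connectivity intensity
#' between the own-race and other-race conditions.
#'
#' @param yOwn,yOther numeric vectors of equal length.
#' @return \code{yOwn - yOther}.
#' @export
nore <- function(yOwn, yOther) {
  if (length(yOwn) != length(yOther))
    stop("yOwn and yOther must have equal length")
  yOwn - yOther
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors (N >= 3, nonzero variance).
#' @return named vector \code{c(r =, p =)} from the t-based two-sided
#'   test.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations are required")
  if (var(x) <= 0 || var(y) <= 0) stop("x and y must have nonzero variance")
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Repeated-measures ANOVA on recognition accuracy
#'
#' Convenience wrapper applying \code{\link{rmAnovaAgeRace}} to a
#' behavioral table of per-participant recognition accuracies under the
#' two face-race conditions.
#'
#' @param records data.frame with columns \code{age}, \code{accOwn},
#'   \code{accOther} (accuracies in [0, 1]).
#' @return as \code{\link{rmAnovaAgeRace}}.
#' @export
behavioralAnova <- function(records) {
  need <- c("age", "accOwn", "accOther")
  if (!all(need %in% names(records)))
    stop("records must carry columns: ", paste(need, collapse = ", "))
  if (any(records$accOwn < 0 | records$accOwn > 1 |
            records$accOther < 0 | records$accOther > 1))
    stop("accuracies must lie in [0, 1]")
  rmAnovaAgeRace(records$accOwn, records$accOther, records$age)
}

#' Post-hoc t-tests for an interaction edge
#'
#' Splits the cohort at an age threshold (default: cohort median) and
#' reports the paired t-test own minus other within each age group and
#' the two-sample t-test younger minus older within each condition,
#' with two-sided p-values.
#'
#' @inheritParams rmAnovaAgeRace
#' @param split age threshold in years; participants with
#'   \code{age <= split} form the younger group. Default
#'   \code{median(age)}.
#' @return data.frame with rows \code{paired_younger},
#'   \code{paired_older}, \code{twosample_own}, \code{twosample_other}
#'   and columns \code{t}, \code{df}, \code{p}.
#' @export
posthocTtests <- function(yOwn, yOther, age, split = NULL) {
  if (is.null(split)) split <- median(age)
  young <- age <= split
  if (!any(young) || all(young))
    stop("age split leaves an empty group")
  pairT <- function(sel) {
    d <- yOwn[sel] - yOther[sel]
    if (sd(d) == 0)  # identical conditions: no paired difference
      return(c(t = 0, df = sum(sel) - 1, p = 1))
    tt <- t.test(yOwn[sel], yOther[sel], paired = TRUE)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  twoT <- function(y) {
    tt <- t.test(y[young], y[!young], var.equal = TRUE)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  out <- rbind(paired_younger = pairT(young),
               paired_older = pairT(!young),
               twosample_own = twoT(yOwn),
               twosample_other = twoT(yOther))
  data.frame(contrast = rownames(out), out, row.names = NULL)
}

#' Edge-level inference for one directed edge
#'
#' Runs the full per-edge decision procedure: full-sample ANOVA,
#' bootstrap-averaged effect sizes, permutation null, top-5\% decisions
#' and the NORE-age Pearson correlation.
#'
#' @inheritParams permutationNull
#' @param Bboot subsample repetitions for the observed averaged effect
#'   size.
#' @param Bperm permutation replicates.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame of edge statistics (see
#'   \code{\link{cohortEdgeStats}} for the column layout).
#' @export
edgeInference <- function(yOwn, yOther, age, Bboot = 10000L,
                          Bperm = 10000L, frac = 0.5, seed = NULL,
                          alpha = 0.05, scheme = c("averaged", "single")) {
  scheme <- match.arg(scheme)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (scheme == "averaged" && Bboot != Bperm)
    stop("the averaged scheme shares one panel: Bboot must equal Bperm")
  prep <- .prepAgeCross(.inferencePrep(age, Bboot, Bperm, frac, seed))
  .edgeInferenceRow(yOwn, yOther, age, prep, alpha, scheme)
}

# Shared per-edge worker (prep built once per cohort).
.edgeInferenceRow <- function(yOwn, yOther, age, prep, alpha, scheme) {
  full <- rmAnovaAgeRace(yOwn, yOther, age)
  if (scheme == "averaged") {
    eng <- .edgeEngine(yOwn, yOther, prep)
    boot <- vapply(eng, `[`, numeric(1), 1L)
    permP <- vapply(eng, function(v)
      (1 + sum(v[-1L] >= v[1L])) / length(v), numeric(1))
  } else {
    boot <- bootstrapEffectSize(yOwn, yOther, age, B = prep$Bboot,
                                frac = prep$frac, seed = prep$seed)
    pn <- permutationNull(yOwn, yOther, age, B = prep$Bperm,
                          frac = prep$frac,
                          seed = prep$seed + 1L, observed = boot,
                          scheme = "single")
    permP <- pn$permP
  }
  nr <- pearsonR(nore(yOwn, yOther), age)
  out <- data.frame(
    F_age = full$F[1L], eta2_age = full$eta2[1L],
    boot_age = boot[["age"]], permP_age = permP[["age"]],
    sig_age = permP[["age"]] < alpha,
    F_race = full$F[2L], eta2_race = full$eta2[2L],
    boot_race = boot[["race"]], permP_race = permP[["race"]],
    sig_race = permP[["race"]] < alpha,
    F_interaction = full$F[3L], eta2_interaction = full$eta2[3L],
    boot_interaction = boot[["interaction"]],
    permP_interaction = permP[["interaction"]],
    sig_interaction = permP[["interaction"]] < alpha,
    nore_r = nr[["r"]], nore_p = nr[["p"]])
  out
}

#' Edge statistics for a whole cohort of causal maps
#'
#' Applies the per-edge decision procedure to every ordered channel
#' pair of the stacked own/other causal-map arrays. All edges share the
#' same subsample panel, sign flips and age permutations, so results
#' are reproducible from one seed.
#'
#' @param own,other numeric arrays channel x channel x participant (see
#'   \code{\link{stackCausalMaps}}), participants aligned.
#' @param age numeric vector of participant ages, aligned with the
#'   third array dimension.
#' @param Bboot,Bperm,frac,seed,alpha,scheme as
#'   \code{\link{edgeInference}}.
#' @return data.frame with one row per defined ordered edge: columns
#'   \code{from}, \code{to}, \code{edgeClass}, the per-effect blocks
#'   \code{F_*}, \code{eta2_*}, \code{boot_*}, \code{permP_*},
#'   \code{sig_*} (for age, race, interaction), \code{nore_r},
#'   \code{nore_p}. The provenance attribute records B, frac, seed,
#'   alpha, scheme and the age-null deviation.
#' @export
cohortEdgeStats <- function(own, other, age, Bboot = 500L, Bperm = 500L,
                            frac = 0.5, seed = NULL, alpha = 0.05,
                            scheme = c("averaged", "single")) {
  scheme <- match.arg(scheme)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(length(dim(own)) == 3L, length(dim(other)) == 3L)
  nch <- dim(own)[1L]
  N <- dim(own)[3L]
  if (dim(other)[3L] != N || length(age) != N)
    stop("own, other and age must describe the same participants")
  if (scheme == "averaged" && Bboot != Bperm)
    stop("the averaged scheme shares one panel: Bboot must equal Bperm")
  if (is.null(seed)) seed <- sample.int(1e9, 1)
  prep <- .prepAgeCross(.inferencePrep(age, Bboot, Bperm, frac, seed))
  edges <- .allEdges(nch)
  rows <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]
    yOwn <- own[i, j, ]
    yOther <- other[i, j, ]
    if (anyNA(yOwn) || anyNA(yOther)) next
    rows[[k]] <- cbind(edges[k, , drop = FALSE],
                       .edgeInferenceRow(yOwn, yOther, age, prep, alpha,
                                         scheme))
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  out$edgeClass <- if (nch == 46L) classifyEdge(out$from, out$to)
                   else NA_character_
  attr(out, "provenance") <- list(
    Bboot = Bboot, Bperm = Bperm, frac = frac, seed = seed, alpha = alpha,
    scheme = scheme, nParticipants = N,
    ageNull = "ages permuted across participants (condition flips leave participant means unchanged)")
  out
}
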