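# Independent brute-force oracles used to cross-check the package's
# estimators, plus small fixture builders.

# lag matrix built by explicit shifting (deliberately not embed())
lagmat <- function(x, p) {
  n <- length(x)
  vapply(seq_len(p), function(l) x[(p + 1 - l):(n - l)], numeric(n - p))
}

# Granger magnitudes via explicit normal equations
oracleGranger <- function(a, b, p) {
  n <- length(a)
  rssNE <- function(y, X) {
    X <- cbind(1, X)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  Ya <- a[(p + 1):n]; Yb <- b[(p + 1):n]
  La <- lagmat(a, p); Lb <- lagmat(b, p)
  c(aToB = log(rssNE(Yb, Lb) / rssNE(Yb, cbind(Lb, La))),
    bToA = log(rssNE(Ya, La) / rssNE(Ya, cbind(La, Lb))))
}

# RM-ANOVA F statistics via R's lm on the difference/mean scores
oracleRmAnova <- function(yOwn, yOther, age) {
  xc <- age - mean(age)
  M <- (yOwn + yOther) / 2
  D <- yOwn - yOther
  sM <- summary(lm(M ~ xc))$coefficients
  sD <- summary(lm(D ~ xc))$coefficients
  c(age = sM["xc", "t value"]^2,
    race = sD["(Intercept)", "t value"]^2,
    interaction = sD["xc", "t value"]^2)
}

# a recording wrapper for matrices that are already analysis-ready
asPreprocessed <- function(data, fs = 10, age = 7, cond = "own",
                           pid = "p1") {
  NirsRecording(pid, age, cond, fs, data, preprocessed = TRUE)
}

# the planted-interaction recovery scenario frozen for this package:
# three directed couplings whose own-condition strength grows with age,
# scaled so recovered interaction effects resemble small effects
# typical of developmental connectivity work
recoveryPlanted <- function() {
  list(plantedEdge(1, 5, base = 0.2, interSlope = 0.007),
       plantedEdge(2, 8, base = 0.2, interSlope = 0.007),
       plantedEdge(9, 3, base = 0.2, interSlope = 0.007))
}
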