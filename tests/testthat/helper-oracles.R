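# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# Lower regularized incomplete gamma P(a, x) by series (x < a + 1) or
# continued fraction, giving an independent chi-square CDF:
# CDF_chi2(x, df) = P(df / 2, x / 2).
oracleGammaP <- function(a, x) {
  if (x <= 0) return(0)
  if (x < a + 1) {
    # series expansion
    term <- 1 / a
    s <- term
    n <- 0
    while (abs(term) > abs(s) * 1e-14 && n < 10000) {
      n <- n + 1
      term <- term * x / (a + n)
      s <- s + term
    }
    s * exp(-x + a * log(x) - lgamma(a))
  } else {
    # Lentz continued fraction for Q(a, x)
    tiny <- 1e-300
    b <- x + 1 - a
    c <- 1 / tiny
    d <- 1 / b
    h <- d
    for (i in 1:10000) {
      an <- -i * (i - a)
      b <- b + 2
      d <- an * d + b
      if (abs(d) < tiny) d <- tiny
      c <- b + an / c
      if (abs(c) < tiny) c <- tiny
      d <- 1 / d
      del <- d * c
      h <- h * del
      if (abs(del - 1) < 1e-14) break
    }
    q <- exp(-x + a * log(x) - lgamma(a)) * h
    1 - q
  }
}

oracleChisqCdf <- function(x, df)
  vapply(x, function(xx) oracleGammaP(df / 2, xx / 2), 0)

# Per-point Mahalanobis loop solving the linear system explicitly.
oracleMahalanobisSq <- function(features, labels, clusterId) {
  member <- labels == clusterId
  X <- features[member, , drop = FALSE]
  mu <- colMeans(X)
  S <- cov(X)
  apply(features, 1, function(x) {
    d <- x - mu
    as.numeric(d %*% solve(S, d))
  })
}

oracleLRatio <- function(features, labels, clusterId, df = ncol(features)) {
  md2 <- oracleMahalanobisSq(features, labels, clusterId)
  member <- labels == clusterId
  L <- sum(1 - oracleChisqCdf(md2[!member], df))
  list(L = L, LRatio = L / sum(member))
}

oracleIsolationDistance <- function(features, labels, clusterId) {
  md2 <- oracleMahalanobisSq(features, labels, clusterId)
  member <- labels == clusterId
  nonMember <- sort(md2[!member])
  if (length(nonMember) < sum(member)) return(NA_real_)
  nonMember[sum(member)]
}

# von Mises angles (degrees) by rejection sampling against a uniform
# proposal with the exact envelope exp(kappa * (cos(theta - mu) - 1)).
oracleVonMises <- function(n, muDeg, kappa, seed) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    cand <- runif(2 * n, 0, 360)
    u <- runif(2 * n)
    keep <- u < exp(kappa * (cos((cand - muDeg) * pi / 180) - 1))
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

circMeanDeg <- function(anglesDeg) {
  th <- anglesDeg * pi / 180
  (atan2(sum(sin(th)), sum(cos(th))) * 180 / pi) %% 360
}

# smallest absolute angular difference in degrees
angDiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

rmsOf <- function(x) sqrt(mean(x^2))
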