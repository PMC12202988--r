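# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (plain-R string handling, exhaustive enumeration,
# dbinom-based likelihoods).

revcompStr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

canonStr <- function(s) pmin(s, revcompStr(s))

# unordered, strand-insensitive key for a ref/alt context pair
pairKey <- function(refCtx, altCtx) {
  a <- canonStr(refCtx)
  b <- canonStr(altCtx)
  paste(pmin(a, b), pmax(a, b))
}

# precision of calls against planted truth
callPrecision <- function(calls, truth) {
  mean(pairKey(calls$ref_context, calls$alt_context) %in%
         pairKey(truth$ref_context, truth$alt_context))
}

# exhaustive maximum-weight matching over all subsets of edges
bruteMatching <- function(ia, ib, w) {
  m <- length(w)
  best <- -Inf
  for (mask in 0:(2^m - 1)) {
    take <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    v <- c(ia[take], ib[take])
    if (anyDuplicated(v)) next
    best <- max(best, sum(w[take]))
  }
  best
}

# per-site -2 log likelihood ratio via full dbinom densities (binomial
# coefficients cancel between numerator and denominator per sample)
lambdaOracle <- function(r, a) {
  mapply(function(r, a) {
    n <- r + a
    p1 <- r / n
    ps <- (r + 1) / (n + 2)
    num <- dbinom(r, n, ps, log = TRUE) + dbinom(1, 2, ps, log = TRUE)
    den <- dbinom(r, n, p1, log = TRUE) + dbinom(1, 2, 0.5, log = TRUE)
    -2 * (num - den)
  }, r, a)
}

# brute-force peak scan without early-stop rules (strict 3-point local max)
brutePeaks <- function(dense) {
  which(vapply(seq_along(dense), function(f) {
    f >= 2 && f < length(dense) &&
      dense[f - 1] < dense[f] && dense[f] > dense[f + 1]
  }, logical(1)))
}

# all k-length windows of a string
windowsOf <- function(s, k) {
  starts <- seq_len(nchar(s) - k + 1)
  substring(s, starts, starts + k - 1)
}

# small diploid fixture shared by stage-1/stage-2 tests
makeDiploidFixture <- function(len = 300000L, het = 0.01, seed = 101,
                               params = kmerParams()) {
  set.seed(seed)
  base <- sketchmer:::cpp_random_genome(as.integer(len))
  A <- simulateDiploid(NA, het, params, base = base)
  B <- simulateDiploid(NA, het, params, base = base)
  list(A = A, B = B, base = base)
}
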