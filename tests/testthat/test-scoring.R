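test_that("the genotype cutoff sits in the valley between het and hom clusters", {
  set.seed(41)
  # half the ratios near 0.5, half near 1.0: valley around 0.75
  ratios <- c(rnorm(5000, 0.5, 0.05), pmin(1, rnorm(5000, 0.98, 0.02)))
  v <- genotypeCutoff(ratios)
  # brute-force valley scan on the same 50-bin histogram
  bins <- pmin(floor(ratios * 50) + 1L, 50L)
  freq <- tabulate(bins, 50)
  centers <- (1:50 - 0.5) / 50
  elig <- centers >= 0.6 & centers <= 0.9
  expect_equal(min(freq[elig]), freq[which(centers == v)])
  expect_lt(abs(v - 0.75), 0.03)
  # permutation invariance
  expect_equal(genotypeCutoff(sample(ratios)), v)
  # degenerate input still returns a value in the search range
  allHet <- rnorm(5000, 0.5, 0.03)
  v2 <- genotypeCutoff(allHet)
  expect_gte(v2, 0.60)
  expect_lte(v2, 0.90)
  # too few sites falls back to 0.75 with a warning
  expect_warning(v3 <- genotypeCutoff(runif(50)), "0.75")
  expect_equal(v3, 0.75)
})

test_that("genotype labels follow the symmetric cutoff rule", {
  counts <- data.frame(site = 1:6,
                       ref = c(5L, 10L, 0L, 0L, 3L, 9L),
                       alt = c(5L, 0L, 8L, 0L, 2L, 3L))
  g <- callGenotypes(counts, cutoff = 0.75)
  expect_equal(g$label, c("het", "hom", "hom", "missing", "het", "hom"))
  # ratio exactly at the cutoff is homozygous (boundary decision)
  b <- callGenotypes(data.frame(site = 1L, ref = 3L, alt = 1L), cutoff = 0.75)
  expect_equal(b$label, "hom")
  expect_error(callGenotypes(counts, cutoff = 0.4))
})

test_that("relatedness score is Het/(Het+Hom) with analytic anchor cases", {
  mkSummary <- function(het, hom) {
    data.frame(label = c(rep("het", het), rep("hom", hom),
                         rep("missing", 3)))
  }
  expect_equal(relatednessScore(mkSummary(1000, 0)), 1.0)
  expect_equal(relatednessScore(mkSummary(500, 500)), 0.5)
  expect_error(relatednessScore(mkSummary(0, 0)), "no callable")
  set.seed(42)
  for (i in 1:20) {
    het <- sample(0:50, 1); hom <- sample(0:50, 1)
    if (het + hom == 0) next
    r <- relatednessScore(mkSummary(het, hom))
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("per-site lambda matches the independent dbinom oracle", {
  # identical counts on both samples cancel exactly
  expect_equal(likelihoodScore(data.frame(ref = 1L, alt = 1L))$lambdaBar, 0)
  # (2,0): -2 ln(0.75^2 * 0.75 * 0.25 / (1 * 0.25)) = -6 ln 0.75
  lam20 <- likelihoodScore(data.frame(ref = 2L, alt = 0L))$lambdaBar
  expect_equal(lam20, -6 * log(0.75), tolerance = 1e-12)
  expect_equal(lam20, lambdaOracle(2, 0), tolerance = 1e-12)
  expect_equal(lam20, 1.7261, tolerance = 1e-4)
  # random count pairs agree with the full-density oracle
  set.seed(43)
  r <- rpois(500, 8); a <- rpois(500, 8)
  keep <- r + a >= 2
  got <- likelihoodScore(data.frame(ref = r, alt = a))$lambda
  expect_equal(got, lambdaOracle(r[keep], a[keep]), tolerance = 1e-9)
})

test_that("lambda is non-negative and symmetric in (ref, alt)", {
  set.seed(44)
  r <- rpois(10000, 6); a <- rpois(10000, 6)
  keep <- r + a >= 2
  lamRA <- likelihoodScore(data.frame(ref = r, alt = a))$lambda
  lamAR <- likelihoodScore(data.frame(ref = a, alt = r))$lambda
  expect_true(all(lamRA >= 0))
  expect_equal(lamRA, lamAR, tolerance = 1e-12)
  expect_equal(length(lamRA), sum(keep))
})

test_that("effective sites require ref+alt >= 2", {
  counts <- data.frame(ref = c(1L, 1L, 0L, 2L, 0L),
                       alt = c(0L, 1L, 1L, 3L, 0L))
  lik <- likelihoodScore(counts)
  expect_equal(lik$N, 2L)  # (1,1) and (2,3) only
  noEff <- likelihoodScore(data.frame(ref = c(1L, 0L), alt = c(0L, 1L)))
  expect_equal(noEff$N, 0L)
  expect_true(is.na(noEff$lambdaBar))
})

test_that("classification applies the unreliability floor and the 0.63 bound", {
  p <- kmerParams()
  lowN <- list(lambdaBar = 0.01, N = 40L, lambda = numeric(40))
  rep1 <- classifyPair(1.0, lowN, p)
  expect_equal(rep1@verdict, "unreliable")
  expect_match(rep1@warnings, "effective sites")
  # any N < 50 is unreliable regardless of score
  for (N in c(0L, 10L, 49L))
    expect_equal(classifyPair(1, list(lambdaBar = 0, N = N), p)@verdict,
                 "unreliable")
  same <- classifyPair(1, list(lambdaBar = 0.3, N = 1000L), p)
  expect_equal(same@verdict, "same")
  diff <- classifyPair(0.5, list(lambdaBar = 1.4, N = 1000L), p)
  expect_equal(diff@verdict, "different")
  # boundary: exactly at the threshold counts as identical
  expect_equal(classifyPair(1, list(lambdaBar = 0.63, N = 100L), p)@verdict,
               "same")
  # the direction can be flipped for recalibration
  expect_equal(classifyPair(1, list(lambdaBar = 0.3, N = 100L), p,
                            flipDirection = TRUE)@verdict, "different")
  # report converts to a one-row data.frame
  df <- as.data.frame(same)
  expect_equal(df$verdict, "same")
  expect_equal(df$likelihood_score, 0.3)
})
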