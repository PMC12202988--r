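test_that("heterozygous k-mer extraction is an interval filter", {
  region <- new("HetRegion", lo = 6L, hi = 18L, hetPeak = 12L)
  tab <- new("KmerCountTable", code = c(10, 20, 30), count = c(1L, 6L, 19L),
             k = 21L, nWindows = 26)
  expect_equal(extractHetKmers(tab, region), 20)
  # empty result warns
  low <- new("HetRegion", lo = 2L, hi = 3L, hetPeak = 2L)
  tab2 <- new("KmerCountTable", code = c(1, 2), count = c(4L, 9L), k = 21L,
              nWindows = 13)
  expect_warning(out <- extractHetKmers(tab2, low), "no heterozygous")
  expect_equal(length(out), 0L)
  # idempotent: re-filtering the kept k-mers changes nothing
  kept <- extractHetKmers(tab, region)
  tab3 <- new("KmerCountTable", code = kept,
              count = tab@count[tab@code %in% kept], k = 21L,
              nWindows = sum(tab@count[tab@code %in% kept]))
  expect_equal(extractHetKmers(tab3, region), kept)
})

test_that("candidate pairing finds middle-base differences in either orientation", {
  p <- kmerParams(k = 5L)
  # plain middle-base difference
  pr <- findCandidatePairs(kmerCode(c("AACGT", "AATGT")), p)
  expect_equal(nrow(pr), 1L)
  expect_equal(substr(pr$orientedA, 3, 3) != substr(pr$orientedB, 3, 3), TRUE)
  # difference visible only after reverse complement: rc(ACATT) = AATGT
  pr2 <- findCandidatePairs(kmerCode(c("AACGT", "ACATT")), p)
  expect_equal(nrow(pr2), 1L)
  # difference at a non-middle position is not a pair
  expect_equal(nrow(findCandidatePairs(kmerCode(c("AACGT", "TACGT")), p)), 0L)
  # oriented forms differ at exactly the middle
  set.seed(12)
  s <- unique(vapply(1:300, function(i)
    paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = ""), ""))
  pr3 <- findCandidatePairs(kmerCode(s), kmerParams(k = 9L))
  if (nrow(pr3)) {
    d <- mapply(function(a, b) {
      which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, pr3$orientedA, pr3$orientedB)
    expect_true(all(unlist(d) == 5L))
  }
  # brute-force oracle: every het k-mer pair with a middle-difference
  # orientation is found, and nothing else
  oracle <- 0L
  cs <- canonStr(s)
  for (i in seq_along(s)) for (j in seq_along(s)) {
    if (cs[i] >= cs[j]) next
    hit <- any(vapply(c(cs[i], revcompStr(cs[i])), function(a)
      any(vapply(c(cs[j], revcompStr(cs[j])), function(b) {
        d <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
        length(d) == 1L && d == 5L
      }, logical(1))), logical(1)))
    oracle <- oracle + hit
  }
  expect_equal(nrow(pr3), oracle)
})

test_that("support length counts bidirectional unambiguous extension, capped at k", {
  p <- kmerParams(k = 5L)
  # two full 9 bp contexts differing at the center: all 5+5 windows het
  ref <- "ACGTAGGCA"
  alt <- "ACGTCGGCA"
  het <- kmerCode(c(windowsOf(ref, 5), windowsOf(alt, 5)))
  pr <- supportLength(findCandidatePairs(het, p), het, p)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$support, 5L)
  # contexts come back in the central k-mer's canonical orientation
  expect_setequal(canonStr(c(pr$ctxA, pr$ctxB)), canonStr(c(ref, alt)))
  # only the central pair present: no extension possible
  central <- kmerCode(c("GTAGG", "GTCGG"))
  pr1 <- supportLength(findCandidatePairs(central, p), central, p)
  expect_equal(pr1$support, 1L)
  # ambiguous extension (two right-extensions both succeed) stops the walk
  amb <- kmerCode(c("GTAGG", "GTCGG",
                    "TAGGA", "TCGGA",   # extension with A
                    "TAGGC", "TCGGC"))  # extension with C
  pr2 <- supportLength(findCandidatePairs(amb, p), amb, p)
  pr2 <- pr2[pr2$support == max(pr2$support), ]
  expect_equal(max(pr2$support), 1L)
})

test_that("support is invariant under reverse-complementing the context pair", {
  p <- kmerParams(k = 5L)
  ref <- "TTCGAAGCA"
  alt <- "TTCGCAGCA"
  het1 <- kmerCode(c(windowsOf(ref, 5), windowsOf(alt, 5)))
  het2 <- kmerCode(c(windowsOf(revcompStr(ref), 5),
                     windowsOf(revcompStr(alt), 5)))
  expect_identical(sort(het1), sort(het2))  # canonical codes are strandless
  s1 <- supportLength(findCandidatePairs(het1, p), het1, p)
  s2 <- supportLength(findCandidatePairs(het2, p), het2, p)
  expect_equal(s1$support, s2$support)
})

test_that("maximum-weight matching is optimal and deterministic", {
  mkPairs <- function(ia, ib, w)
    data.frame(codeA = pmin(ia, ib), codeB = pmax(ia, ib),
               orientedA = "", orientedB = "", support = w)
  # path a-b (3), b-c (2): the heavier edge wins
  sel <- maxWeightMatching(mkPairs(c(1, 2), c(2, 3), c(3L, 2L)))
  expect_equal(sel$support, 3L)
  expect_equal(c(sel$codeA, sel$codeB), c(1, 2))
  # two disjoint pairs: both kept
  sel2 <- maxWeightMatching(mkPairs(c(1, 3), c(2, 4), c(5L, 1L)))
  expect_equal(nrow(sel2), 2L)
  # triangle 3,3,2: one weight-3 edge, deterministically the first
  tri <- mkPairs(c(1, 1, 2), c(2, 3, 3), c(3L, 3L, 2L))
  sel3 <- maxWeightMatching(tri)
  expect_equal(sel3$support, 3L)
  expect_equal(c(sel3$codeA, sel3$codeB), c(1, 2))
  expect_identical(sel3, maxWeightMatching(tri))
  # random graphs <= 12 vertices: total weight equals brute-force optimum,
  # and no vertex is used twice
  set.seed(13)
  for (i in 1:40) {
    nv <- sample(4:12, 1)
    ne <- sample(3:min(10, nv * (nv - 1) / 2), 1)
    pairs <- unique(t(apply(matrix(sample(nv, 2 * ne, TRUE),
                                   ncol = 2), 1, sort)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (!nrow(pairs)) next
    w <- sample(1:21, nrow(pairs), TRUE)
    sel <- maxWeightMatching(mkPairs(pairs[, 1], pairs[, 2], w))
    expect_false(anyDuplicated(c(sel$codeA, sel$codeB)) > 0)
    expect_equal(sum(sel$support),
                 bruteMatching(pairs[, 1], pairs[, 2], w))
  }
})

test_that("stage-1 calling on a simulated diploid is precise and order-invariant", {
  p <- kmerParams()
  fx <- makeDiploidFixture(len = 200000L, het = 0.01, seed = 14)
  set.seed(15)
  reads <- simulateReads(fx$A, 10, 150L, 0.002)
  calls <- suppressWarnings(callSnps(reads, p))
  expect_gt(nrow(calls), 0L)
  expect_true(all(calls$support == 21L))
  expect_true(all(nchar(calls$ref_context) == 41L))
  # contexts differ exactly at the center
  d <- mapply(function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              calls$ref_context, calls$alt_context)
  expect_true(all(unlist(d) == 21L))
  expect_gte(callPrecision(calls, fx$A$truth), 0.90)
  # read order does not matter
  calls2 <- suppressWarnings(callSnps(rev(reads), p))
  expect_identical(calls, calls2)
})

test_that("a genome without heterozygosity yields no calls", {
  p <- kmerParams()
  set.seed(16)
  hom <- simulateDiploid(120000L, 0)
  expect_identical(hom$hap1, hom$hap2)
  reads <- simulateReads(hom, 10, 150L, 0.002)
  expect_error(suppressWarnings(callSnps(reads, p)), "no SNPs|no peak")
})
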