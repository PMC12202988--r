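test_that("canonicalization picks the smaller of a k-mer and its reverse complement", {
  expect_equal(canonicalKmer("AACGT"), "AACGT")  # revcomp ACGTT is larger
  expect_equal(canonicalKmer("ACGTT"), "AACGT")
  expect_equal(canonicalKmer("ACGT"), "ACGT")    # self-reverse-complementary
  expect_error(canonicalKmer("ACNGT"), "ambiguous")
  # property: canonical(s) == canonical(revcomp(s)) on random k-mers
  set.seed(1)
  s <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""), "")
  expect_equal(canonicalKmer(s), canonicalKmer(revcompStr(s)))
  expect_equal(canonicalKmer(s), canonStr(s))
  expect_equal(kmerCode(s), kmerCode(revcompStr(s)))
})

test_that("the 64-bit hash is invertible and injective", {
  set.seed(2)
  x <- c(0, 1, floor(runif(1e5) * 2^53))
  expect_identical(kmerUnhash(kmerHash(x)), sketchmer:::toHex64(x))
  # distinctness over the full 2^16 prefix of the domain
  h <- sketchmer:::cpp_hash_range(65536L)
  expect_equal(length(unique(h)), 65536L)
  # hex helpers round-trip values above 2^32
  big <- c(2^52, 2^40 + 12345)
  expect_equal(sketchmer:::fromHex64(sketchmer:::toHex64(big)), big)
})

test_that("k-mer counting covers every unambiguous window exactly once", {
  p <- kmerParams()
  set.seed(3)
  read <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  tab <- countKmers(read, p)
  expect_equal(tab@nWindows, 25 - 21 + 1)
  expect_equal(sum(tab@count), 5)
  # additivity: same read twice doubles every count
  tab2 <- countKmers(c(read, read), p)
  expect_equal(tab2@code, tab@code)
  expect_equal(tab2@count, 2L * tab@count)
  # a homopolymer collapses to one distinct k-mer
  polyA <- countKmers(strrep("A", 25), p)
  expect_equal(length(polyA@code), 1L)
  expect_equal(polyA@count, 5L)
  # ambiguous bases invalidate only the windows containing them
  withN <- countKmers(paste0(strrep("A", 21), "N", strrep("A", 21)), p)
  expect_equal(withN@nWindows, 2)
  expect_warning(empty <- countKmers(character(), p), "empty")
  expect_equal(length(empty@code), 0L)
})

test_that("counting is read-order independent", {
  p <- kmerParams()
  set.seed(4)
  reads <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
  t1 <- countKmers(reads, p)
  t2 <- countKmers(rev(reads), p)
  expect_identical(t1@code, t2@code)
  expect_identical(t1@count, t2@count)
})

test_that("counting agrees with a brute-force window scan", {
  p <- kmerParams(k = 7L)
  set.seed(5)
  reads <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), "")
  tab <- countKmers(reads, p)
  wins <- canonStr(unlist(lapply(reads, windowsOf, k = 7)))
  oracle <- table(wins)
  got <- setNames(tab@count, sketchmer:::cpp_decode(tab@code, 7L))
  expect_equal(sort(names(got)), sort(names(oracle)))
  expect_equal(as.integer(got[names(oracle)]), as.integer(oracle))
})

test_that("FASTA/FASTQ inputs (plain and gzipped) are counted identically", {
  p <- kmerParams()
  set.seed(6)
  reads <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""), "")
  fq <- tempfile(fileext = ".fq")
  fqgz <- tempfile(fileext = ".fq.gz")
  fa <- tempfile(fileext = ".fa")
  writeFastq(reads, fq)
  writeFastq(reads, fqgz)
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(reads), paste0("r", 1:20)), fa)
  ref <- countKmers(reads, p)
  for (f in c(fq, fqgz, fa)) {
    tab <- countKmers(f, p)
    expect_identical(tab@code, ref@code)
    expect_identical(tab@count, ref@count)
  }
})

test_that("histogram counts distinct k-mers per frequency and conserves mass", {
  p <- kmerParams()
  # {x:2, y:2, z:5} -> hist[2]=2, hist[5]=1
  tab <- new("KmerCountTable", code = c(1, 2, 3), count = c(2L, 2L, 5L),
             k = 21L, nWindows = 9)
  h <- buildHistogram(tab, p)
  expect_equal(h@freq, c(2L, 5L))
  expect_equal(h@n, c(2, 1))
  expect_equal(h@totalDistinct, 3)
  expect_equal(h@totalMass, 9)
  # empty table -> empty histogram
  h0 <- buildHistogram(new("KmerCountTable", code = numeric(),
                           count = integer(), k = 21L, nWindows = 0), p)
  expect_equal(length(h0@freq), 0L)
  # totals invariant on random tables (brute-force recount)
  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:50, 1)
    cnt <- sample(1:20, n, TRUE)
    tab <- new("KmerCountTable", code = sort(sample(1e6, n)),
               count = cnt, k = 21L, nWindows = sum(cnt))
    h <- buildHistogram(tab, p)
    expect_equal(h@totalDistinct, n)
    expect_equal(h@totalMass, sum(cnt))
    expect_equal(sum(h@freq * h@n), tab@nWindows)  # mass conservation
  }
})

test_that("histogram text format round-trips", {
  tab <- countKmers(c("ACGTACGTACGTACGTACGTACGTA",
                      "TTTTTTTTTTTTTTTTTTTTTTTTT"), kmerParams())
  h <- buildHistogram(tab)
  f <- tempfile()
  writeHistogram(h, f)
  h2 <- readHistogram(f, k = 21L)
  expect_equal(h2@freq, h@freq)
  expect_equal(h2@n, h@n)
  expect_equal(h2@totalMass, h@totalMass)
})
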