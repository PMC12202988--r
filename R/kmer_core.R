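#' @useDynLib sketchmer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats dbinom dnbinom dpois optim quantile rbinom rgeom rpois
#'   runif setNames
#' @importFrom utils read.table write.table head
NULL

#' Canonical k-mer table: counts of distinct canonical k-mers
#'
#' Produced by \code{\link{countKmers}}. Codes are the 2-bit packing
#' (A=0, C=1, G=2, T=3) of the canonical orientation (the lexicographically
#' smaller of a k-mer and its reverse complement under A<C<G<T), stored
#' sorted and unique.
#'
#' @slot code sorted numeric vector of canonical k-mer codes.
#' @slot count integer occurrence counts (all >= 1).
#' @slot k k-mer size.
#' @slot nWindows total number of unambiguous length-k windows consumed.
#' @exportClass KmerCountTable
setClass("KmerCountTable",
  representation(code = "numeric", count = "integer", k = "integer",
                 nWindows = "numeric"))

setValidity("KmerCountTable", function(object) {
  msg <- character()
  if (length(object@code) != length(object@count))
    msg <- c(msg, "code and count lengths differ")
  if (length(object@count) && any(object@count < 1L))
    msg <- c(msg, "all stored counts must be >= 1")
  if (is.unsorted(object@code, strictly = TRUE) && length(object@code) > 1L)
    msg <- c(msg, "codes must be sorted and unique")
  if (length(object@count) && sum(as.numeric(object@count)) != object@nWindows)
    msg <- c(msg, "total mass must equal the number of windows consumed")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerCountTable", function(object) {
  cat("KmerCountTable:", length(object@code), "distinct", object@k,
      "-mers over", format(object@nWindows, big.mark = ","), "windows\n")
})

#' K-mer abundance histogram
#'
#' Number of distinct k-mers per occurrence frequency, plus the derived
#' totals. The diploid k-mer spectrum shows a heterozygous peak near the
#' per-haplotype coverage and a homozygous peak near twice that.
#'
#' @slot freq integer occurrence frequencies (sorted, unique).
#' @slot n number of distinct k-mers at each frequency.
#' @slot totalDistinct sum of \code{n}.
#' @slot totalMass sum of \code{freq * n}.
#' @slot k k-mer size.
#' @exportClass KmerHistogram
setClass("KmerHistogram",
  representation(freq = "integer", n = "numeric", totalDistinct = "numeric",
                 totalMass = "numeric", k = "integer"))

setValidity("KmerHistogram", function(object) {
  msg <- character()
  if (length(object@freq) != length(object@n))
    msg <- c(msg, "freq and n lengths differ")
  if (length(object@n) && any(object@n < 0))
    msg <- c(msg, "entries must be >= 0")
  if (!isTRUE(all.equal(sum(object@n), object@totalDistinct)))
    msg <- c(msg, "totalDistinct must equal sum(n)")
  if (!isTRUE(all.equal(sum(object@freq * object@n), object@totalMass)))
    msg <- c(msg, "totalMass must equal sum(freq * n)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerHistogram", function(object) {
  cat("KmerHistogram:", length(object@freq), "frequencies,",
      format(object@totalDistinct, big.mark = ","), "distinct k-mers, mass",
      format(object@totalMass, big.mark = ","), "\n")
})

#' Canonicalize k-mer sequences
#'
#' Returns the lexicographically smaller of each sequence and its reverse
#' complement (A<C<G<T). Case-insensitive; sequences containing non-ACGT
#' characters are rejected.
#'
#' @param seq character vector of equal-length DNA strings.
#' @return character vector of canonical sequences.
#' @examples
#' canonicalKmer("AACGT")   # revcomp "ACGTT" is larger
#' @export
canonicalKmer <- function(seq) {
  k <- unique(nchar(seq))
  if (length(k) != 1L) stop("all sequences must share one length")
  res <- cpp_canonical(seq, as.integer(k))
  if (any(!res$ok))
    stop("ambiguous base in k-mer(s): ",
         paste(head(which(!res$ok), 3L), collapse = ", "))
  res$kmer
}

#' Numeric code of canonical k-mers
#'
#' @param seq character vector of equal-length DNA strings.
#' @return numeric vector of 2-bit packed canonical codes (exact for k <= 25).
#' @export
kmerCode <- function(seq) {
  k <- unique(nchar(seq))
  if (length(k) != 1L) stop("all sequences must share one length")
  res <- cpp_canonical(seq, as.integer(k))
  if (any(!res$ok))
    stop("ambiguous base in k-mer(s): ",
         paste(head(which(!res$ok), 3L), collapse = ", "))
  res$code
}

#' Invertible 64-bit hash
#'
#' A bijective mixer (xorshift-multiply finalizer) over the full 64-bit
#' domain, with \code{kmerUnhash} as its exact inverse. Values are exchanged
#' as 16-character lower-case hex strings so the full domain is representable.
#'
#' @param x numeric vector of non-negative integers below 2^53, or
#'   16-character hex strings.
#' @return character vector of hex-encoded hashed values.
#' @examples
#' kmerUnhash(kmerHash(12345)) == sketchmer:::toHex64(12345)
#' @export
kmerHash <- function(x) cpp_hash_hex(toHex64(x))

#' @rdname kmerHash
#' @export
kmerUnhash <- function(x) cpp_unhash_hex(toHex64(x))

toHex64 <- function(x) {
  if (is.character(x)) return(tolower(x))
  if (any(x < 0 | x >= 2^53)) stop("numeric input must be in [0, 2^53)")
  # sprintf %x needs integers; emit four exact 16-bit chunks
  out <- character(length(x))
  for (shift in c(2^48, 2^32, 2^16, 1)) {
    chunk <- floor(x / shift)
    x <- x - chunk * shift
    out <- paste0(out, sprintf("%04x", as.integer(chunk)))
  }
  out
}

fromHex64 <- function(h) {
  # parse in 16-bit chunks; strtoi overflows 32-bit values
  vapply(h, function(s) {
    chunks <- substring(s, c(1L, 5L, 9L, 13L), c(4L, 8L, 12L, 16L))
    sum(strtoi(chunks, 16L) * c(2^48, 2^32, 2^16, 1))
  }, numeric(1), USE.NAMES = FALSE)
}

# Read sequences from character vector, DNAStringSet or FASTA/FASTQ path(s)
# (plain or gzipped). Quality strings are ignored.
readSequences <- function(reads) {
  if (is(reads, "DNAStringSet")) return(as.character(reads))
  if (!is.character(reads)) stop("reads must be sequences or file paths")
  if (length(reads) && all(file.exists(reads)) &&
      !all(grepl("^[ACGTNacgtn]+$", reads))) {
    seqs <- unlist(lapply(reads, function(f) {
      fmt <- sniffFormat(f)
      x <- tryCatch(Biostrings::readDNAStringSet(f, format = fmt),
                    error = function(e)
                      stop("malformed ", fmt, " in '", f, "': ",
                           conditionMessage(e), call. = FALSE))
      as.character(x)
    }))
    return(unname(seqs))
  }
  reads
}

sniffFormat <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) return("fasta")
  if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Count canonical k-mers in sequencing reads
#'
#' Every length-k window free of ambiguous bases contributes one count to its
#' canonical k-mer. Input may be a character vector of sequences, a
#' \code{DNAStringSet}, or paths to FASTA/FASTQ files (optionally gzipped).
#'
#' @param reads sequences or file path(s).
#' @param params a \linkS4class{KmerParams} object.
#' @return a \linkS4class{KmerCountTable}.
#' @examples
#' tab <- countKmers(strrep("A", 25), kmerParams())
#' @export
countKmers <- function(reads, params = kmerParams()) {
  seqs <- readSequences(reads)
  if (!length(seqs)) {
    warning("empty input: returning an empty k-mer table")
    return(new("KmerCountTable", code = numeric(), count = integer(),
               k = params@k, nWindows = 0))
  }
  res <- cpp_count_kmers(seqs, params@k)
  new("KmerCountTable", code = res$code, count = res$count, k = params@k,
      nWindows = res$n_windows)
}

#' Build the k-mer abundance histogram
#'
#' @param table a \linkS4class{KmerCountTable}.
#' @param params a \linkS4class{KmerParams} object (unused beyond k).
#' @return a \linkS4class{KmerHistogram}.
#' @export
buildHistogram <- function(table, params = kmerParams()) {
  stopifnot(is(table, "KmerCountTable"))
  if (!length(table@count))
    return(new("KmerHistogram", freq = integer(), n = numeric(),
               totalDistinct = 0, totalMass = 0, k = table@k))
  tab <- tabulate(table@count)
  freq <- which(tab > 0L)
  n <- as.numeric(tab[freq])
  new("KmerHistogram", freq = as.integer(freq), n = n,
      totalDistinct = sum(n), totalMass = sum(freq * n), k = table@k)
}

#' Read or write the two-column histogram text format
#'
#' Plain whitespace-separated \code{frequency n_distinct} rows, one per
#' frequency, interoperable with the common k-mer-counter layout.
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param path file path.
#' @param k k-mer size to record on read.
#' @return \code{readHistogram} returns a \linkS4class{KmerHistogram};
#'   \code{writeHistogram} returns \code{path} invisibly.
#' @export
writeHistogram <- function(hist, path) {
  stopifnot(is(hist, "KmerHistogram"))
  write.table(data.frame(hist@freq, hist@n), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeHistogram
#' @export
readHistogram <- function(path, k = 21L) {
  df <- read.table(path, header = FALSE,
                   colClasses = c("integer", "numeric"))
  new("KmerHistogram", freq = df[[1]], n = df[[2]],
      totalDistinct = sum(df[[2]]), totalMass = sum(df[[1]] * df[[2]]),
      k = as.integer(k))
}
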