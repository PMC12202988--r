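#' Per-site k-mer counts of a query sample
#'
#' Stage-2 result of streaming a sample's reads over a sketch index: one
#' count per retained sketch k-mer (a "slot"), in the index row order.
#'
#' @slot counts data.frame with \code{site}, \code{allele}, \code{slot},
#'   \code{count}.
#' @slot sample sample label.
#' @slot nReads,nBases reads and bases consumed.
#' @slot earlyStopped whether the expected-coverage early stop triggered.
#' @slot k k-mer size.
#' @exportClass SiteCounts
setClass("SiteCounts",
  representation(counts = "data.frame", sample = "character",
                 nReads = "numeric", nBases = "numeric",
                 earlyStopped = "logical", k = "integer"))

setValidity("SiteCounts", function(object) {
  msg <- character()
  if (!all(c("site", "allele", "slot", "count") %in% names(object@counts)))
    msg <- c(msg, "counts must have site/allele/slot/count columns")
  else if (nrow(object@counts) && any(object@counts$count < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SiteCounts", function(object) {
  cat("SiteCounts for '", object@sample, "': ",
      length(unique(object@counts$site)), " sites, ",
      format(object@nReads, big.mark = ","), " reads",
      if (object@earlyStopped) " (early stop)", "\n", sep = "")
})

#' Index a sketch for counting
#'
#' Builds the lookup structure used by \code{\link{countSample}}: sketch
#' k-mer codes sorted for O(log n) membership (each code resolves to its
#' (site, allele, slot)).
#'
#' @param sketch a \linkS4class{VariantSketch}.
#' @return an opaque list index.
#' @export
indexSketch <- function(sketch) {
  stopifnot(is(sketch, "VariantSketch"))
  km <- sketch@kmers[order(sketch@kmers$code), , drop = FALSE]
  list(code = km$code, site = km$site, allele = km$allele, slot = km$slot,
       k = sketch@k)
}

#' Count a sample's k-mers against a sketch
#'
#' Decomposes the query reads into canonical k-mers and increments the
#' matching sketch slot for every hit. With \code{expectedCov} set, reads are
#' consumed in batches (default 100,000) and the stream stops once the mean
#' count over all sketch slots reaches \code{expectedCov}. Any sequencing
#' technology is acceptable here, including high-error long reads.
#'
#' @param reads sequences or FASTA/FASTQ path(s).
#' @param index from \code{\link{indexSketch}}.
#' @param params a \linkS4class{KmerParams} object.
#' @param expectedCov optional early-stop mean coverage.
#' @param sample sample label.
#' @param batchSize reads per early-stop check.
#' @return a \linkS4class{SiteCounts}.
#' @export
countSample <- function(reads, index, params = kmerParams(),
                        expectedCov = NULL, sample = "query",
                        batchSize = 100000L) {
  seqs <- readSequences(reads)
  if (params@k != index$k) stop("k mismatch between params and sketch index")
  hits <- integer(length(index$code))
  nReads <- 0; nBases <- 0; stopped <- FALSE
  if (!length(seqs)) {
    warning("empty input: all counts zero")
  } else {
    starts <- seq(1L, length(seqs), by = batchSize)
    for (s in starts) {
      batch <- seqs[s:min(s + batchSize - 1L, length(seqs))]
      res <- cpp_count_against(batch, index$code, index$k)
      hits <- hits + res$hits
      nReads <- nReads + length(batch)
      nBases <- nBases + res$n_bases
      if (!is.null(expectedCov) && mean(hits) >= expectedCov &&
          nReads < length(seqs)) {
        stopped <- TRUE
        break
      }
    }
  }
  new("SiteCounts",
      counts = data.frame(site = index$site, allele = index$allele,
                          slot = index$slot, count = hits,
                          stringsAsFactors = FALSE),
      sample = sample, nReads = nReads, nBases = nBases,
      earlyStopped = stopped, k = index$k)
}

#' Modal allele count at a site
#'
#' Collapses the positive per-k-mer counts observed for one allele into a
#' single depth estimate by taking their mode (rather than the maximum,
#' which inflates under sequencing error: counts 8, 9, 8, 7 give 8). Ties
#' break toward the smaller value; with no positive count the allele depth
#' is 0.
#'
#' @param counts integer vector of observed (positive) slot counts; zeros
#'   are discarded.
#' @return the modal count (integer scalar).
#' @examples
#' siteAlleleCount(c(8L, 9L, 8L, 7L))  # 8
#' @export
siteAlleleCount <- function(counts) {
  counts <- counts[counts > 0L]
  if (!length(counts)) return(0L)
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])  # which.max: first max = smaller value
}

#' Per-site ref/alt depth summary
#'
#' Applies \code{\link{siteAlleleCount}} to each (site, allele) slot vector.
#'
#' @param x a \linkS4class{SiteCounts}.
#' @return data.frame with \code{site}, \code{ref}, \code{alt} (modal
#'   depths), sorted by site.
#' @export
alleleCounts <- function(x) {
  stopifnot(is(x, "SiteCounts"))
  cnt <- x@counts
  agg <- function(a) {
    d <- cnt[cnt$allele == a, , drop = FALSE]
    v <- tapply(d$count, d$site, siteAlleleCount)
    data.frame(site = as.integer(names(v)), val = as.integer(v))
  }
  r <- agg("ref"); a <- agg("alt")
  sites <- sort(unique(cnt$site))
  data.frame(site = sites,
             ref = ifelse(is.na(match(sites, r$site)), 0L,
                          r$val[match(sites, r$site)]),
             alt = ifelse(is.na(match(sites, a$site)), 0L,
                          a$val[match(sites, a$site)]))
}

#' Write or read the per-site counts TSV
#'
#' @param counts data.frame from \code{\link{alleleCounts}} (columns
#'   \code{site}, \code{ref}, \code{alt}).
#' @param path file path.
#' @return \code{readCountsTsv} returns the data.frame; \code{writeCountsTsv}
#'   returns \code{path} invisibly.
#' @export
writeCountsTsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
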