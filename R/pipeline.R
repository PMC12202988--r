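#' Stage 1: build a variant sketch from low-error reads
#'
#' Orchestrates SNP calling (\code{\link{callSnps}}) and sketch construction
#' (\code{\link{buildSketch}}), optionally writing the sketch FASTA, its
#' sites sidecar and a genome-profile report. Stage 1 requires low-error
#' data (HiFi/Illumina-like); high-error long reads are only usable in
#' stage 2.
#'
#' @param reads sequences or FASTA/FASTQ path(s).
#' @param params a \linkS4class{KmerParams} object.
#' @param highHet is the species heterozygosity above ~1.2%?
#' @param individual provenance label for the sketch.
#' @param outPrefix optional path prefix; writes
#'   \code{<prefix>.sketch.fa(.sites.tsv)} and \code{<prefix>.profile.txt}.
#' @param verbose log progress to stderr.
#' @return a \linkS4class{VariantSketch} (invisibly when writing files),
#'   with the genome profile attached as attribute \code{"profile"}.
#' @export
buildVariantSketch <- function(reads, params = kmerParams(), highHet = FALSE,
                               individual = "sample", outPrefix = NULL,
                               verbose = FALSE) {
  tab <- countKmers(reads, params)
  hist <- buildHistogram(tab, params)
  peaks <- detectPeaks(hist, params)
  hp <- selectHetPeak(peaks, highHet = highHet, params = params)
  region <- hetRegion(hp, params)
  if (verbose)
    message("[sketch] het peak ", hp, ", region [", region@lo, ", ",
            region@hi, "]")
  profile <- fitGenomeProfile(hist, hp, params)
  calls <- callSnpsFromTable(tab, params, highHet = highHet,
                             verbose = verbose, region = region)
  if (verbose) message("[sketch] ", nrow(calls), " SNPs at full support")
  if (nrow(calls) < params@minSketchSites)
    warning(sprintf("only %d SNP sites called (< %d): sketch may be unstable",
                    nrow(calls), params@minSketchSites))
  sketch <- buildSketch(calls, params, individual = individual)
  attr(sketch, "profile") <- profile
  if (!is.null(outPrefix)) {
    writeSketch(sketch, paste0(outPrefix, ".sketch.fa"))
    capture <- utils::capture.output(show(profile))
    writeLines(capture, paste0(outPrefix, ".profile.txt"))
    return(invisible(sketch))
  }
  sketch
}

#' Stage 2: check query samples against a sketch
#'
#' Counts each sample's k-mers over the sketch, collapses slot vectors to
#' modal ref/alt depths, and scores identity/relatedness. Results from
#' multiple samples are independent, so processing order does not matter.
#'
#' @param sketch a \linkS4class{VariantSketch} or sketch FASTA path.
#' @param samples named list (or vector) of read inputs; names label the
#'   samples.
#' @param params a \linkS4class{KmerParams} object.
#' @param expectedCov optional early-stop coverage for counting.
#' @param threshold decision bound (default \code{params@identityThreshold}).
#' @param flipDirection see \code{\link{classifyPair}}.
#' @param out optional CSV path for the report.
#' @return data.frame with one row per sample: both scores, effective
#'   sites, verdict, warnings.
#' @export
checkSamples <- function(sketch, samples, params = kmerParams(),
                         expectedCov = NULL,
                         threshold = params@identityThreshold,
                         flipDirection = FALSE, out = NULL) {
  if (is.character(sketch)) sketch <- readSketch(sketch, k = params@k)
  stopifnot(is(sketch, "VariantSketch"))
  idx <- indexSketch(sketch)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  indiv <- paste(unique(sketch@sites$individual), collapse = "+")
  rows <- lapply(names(samples), function(nm) {
    sc <- countSample(samples[[nm]], idx, params, expectedCov = expectedCov,
                      sample = nm)
    counts <- alleleCounts(sc)
    rep <- scoreCounts(counts, params, sample = nm, individual = indiv,
                       threshold = threshold, flipDirection = flipDirection)
    as.data.frame(rep)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.csv(report, out, row.names = FALSE)
    return(invisible(report))
  }
  report
}
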