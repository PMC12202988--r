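#' Count-level simulation of sketch-site depths
#'
#' Emulates the count table a query produces over a variant sketch, without
#' simulating sequence: per site, depth d ~ Poisson(coverage). For the same
#' individual ("identical") every site splits ref ~ Binomial(d, P = 0.5),
#' alt = d - ref. For a first-degree relative half of the sites (chosen at
#' random) follow the binomial split and the other half place the full depth
#' on one randomly chosen allele, zero on the other — the relative is
#' homozygous there. Deterministic under \code{set.seed}.
#'
#' @param coverage mean site depth.
#' @param relationship "identical" or "first_degree".
#' @param nSites number of sketch sites (default 200000).
#' @param pHet binomial allele-split probability (default 0.5).
#' @return data.frame with \code{site}, \code{ref}, \code{alt}.
#' @examples
#' set.seed(1)
#' head(simulateSiteCounts(30, "identical", nSites = 10L))
#' @export
simulateSiteCounts <- function(coverage,
                               relationship = c("identical", "first_degree"),
                               nSites = 200000L, pHet = 0.5) {
  relationship <- match.arg(relationship)
  stopifnot(coverage >= 0)
  d <- rpois(nSites, coverage)
  if (relationship == "identical") {
    ref <- rbinom(nSites, d, pHet)
    alt <- d - ref
  } else {
    hetHalf <- sample.int(nSites) <= nSites / 2
    ref <- integer(nSites)
    alt <- integer(nSites)
    ref[hetHalf] <- rbinom(sum(hetHalf), d[hetHalf], pHet)
    alt[hetHalf] <- d[hetHalf] - ref[hetHalf]
    toRef <- runif(sum(!hetHalf)) < 0.5
    ref[!hetHalf] <- ifelse(toRef, d[!hetHalf], 0L)
    alt[!hetHalf] <- ifelse(toRef, 0L, d[!hetHalf])
  }
  data.frame(site = seq_len(nSites), ref = as.integer(ref),
             alt = as.integer(alt))
}

#' Coverage study of the likelihood score
#'
#' For each (coverage, relationship) cell, simulates \code{reps} independent
#' count tables, scores each with \code{\link{likelihoodScore}}, and records
#' the mean, 1st and 99th percentile of the score, plus the mean effective
#' site count. The separation between the identical and first-degree score
#' distributions widens with coverage; the decision bound (default 0.63)
#' sits between them from moderate coverage on.
#'
#' @param coverages vector of mean depths (default the 13-level grid 0.1-30).
#' @param relationships subset of c("identical", "first_degree").
#' @param reps replicates per cell (default 1000).
#' @param nSites sites per replicate (default 200000).
#' @param params a \linkS4class{KmerParams} object.
#' @param verbose log progress.
#' @return data.frame with columns \code{coverage}, \code{relationship},
#'   \code{mean}, \code{p1}, \code{p99}, \code{mean_n_effective}.
#' @export
runScoreStudy <- function(coverages = c(0.1, 0.2, 0.3, 0.5, 1, 2, 3, 4, 6,
                                        8, 10, 20, 30),
                          relationships = c("identical", "first_degree"),
                          reps = 1000L, nSites = 200000L,
                          params = kmerParams(), verbose = FALSE) {
  grid <- expand.grid(coverage = coverages, relationship = relationships,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cov <- grid$coverage[i]
    rel <- grid$relationship[i]
    if (verbose) message("[study] coverage ", cov, " ", rel)
    scores <- numeric(reps)
    neff <- numeric(reps)
    for (r in seq_len(reps)) {
      cnt <- simulateSiteCounts(cov, rel, nSites = nSites,
                                pHet = params@simPHet)
      lik <- likelihoodScore(cnt, params)
      scores[r] <- lik$lambdaBar
      neff[r] <- lik$N
    }
    ok <- is.finite(scores)
    data.frame(coverage = cov, relationship = rel,
               mean = mean(scores[ok]),
               p1 = quantile(scores[ok], 0.01, names = FALSE),
               p99 = quantile(scores[ok], 0.99, names = FALSE),
               mean_n_effective = mean(neff))
  })
  do.call(rbind, out)
}

#' Simulate a diploid genome with isolated heterozygous SNPs
#'
#' A uniform random A/C/G/T sequence (or a supplied base genome, so two
#' individuals can share one background) with heterozygous substitutions
#' placed by a renewal process: successive SNPs are separated by at least
#' 2k-1 bases, guaranteeing isolated SNPs with unique (2k-1)-length
#' contexts, while the geometric gap component is solved so the realized SNP
#' density equals \code{hetRate} despite the spacing constraint.
#'
#' @param genomeLen genome length in bases (ignored when \code{base} given).
#' @param hetRate per-base heterozygosity; must satisfy
#'   \code{1/hetRate >= 2k}, else the spacing is infeasible and an error is
#'   raised.
#' @param params a \linkS4class{KmerParams} object.
#' @param base optional background genome (character scalar).
#' @return list with \code{hap1}, \code{hap2} (character scalars) and
#'   \code{truth}: data.frame of \code{pos}, \code{ref_base},
#'   \code{alt_base}, \code{ref_context}, \code{alt_context}.
#' @export
simulateDiploid <- function(genomeLen, hetRate, params = kmerParams(),
                            base = NULL) {
  k <- params@k
  ctxLen <- 2L * k - 1L
  if (is.null(base)) {
    stopifnot(genomeLen >= 10L * ctxLen)
    base <- cpp_random_genome(as.integer(genomeLen))
  }
  L <- nchar(base)
  if (hetRate < 0 || hetRate > 0.05) stop("hetRate must be in [0, 0.05]")
  if (hetRate == 0) {
    return(list(hap1 = base, hap2 = base,
                truth = data.frame(pos = integer(), ref_base = character(),
                                   alt_base = character(),
                                   ref_context = character(),
                                   alt_context = character(),
                                   stringsAsFactors = FALSE)))
  }
  p <- 1 / (1 / hetRate - ctxLen)
  if (p <= 0 || p > 1)
    stop("infeasible spacing: hetRate ", hetRate,
         " incompatible with minimum SNP distance ", ctxLen)
  nDraw <- ceiling(L * hetRate * 1.5) + 50L
  gaps <- ctxLen + rgeom(nDraw, p) + 1L
  pos <- (k - 1L) + cumsum(gaps)
  while (length(pos) && pos[length(pos)] <= L - k + 1L) {
    gaps <- ctxLen + rgeom(nDraw, p) + 1L
    pos <- c(pos, pos[length(pos)] + cumsum(gaps))
  }
  pos <- pos[pos >= k & pos <= L - k + 1L]
  refb <- substring(base, pos, pos)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "", USE.NAMES = FALSE)
  hap2 <- strsplit(base, "", fixed = TRUE)[[1]]
  hap2[pos] <- altb
  hap2 <- paste(hap2, collapse = "")
  refCtx <- substring(base, pos - (k - 1L), pos + (k - 1L))
  altCtx <- substring(hap2, pos - (k - 1L), pos + (k - 1L))
  list(hap1 = base, hap2 = hap2,
       truth = data.frame(pos = pos, ref_base = refb, alt_base = altb,
                          ref_context = refCtx, alt_context = altCtx,
                          stringsAsFactors = FALSE))
}

#' Simulate whole-genome shotgun reads from a diploid
#'
#' Reads are drawn uniformly from both haplotypes and both strands, with
#' i.i.d. substitution errors; no indels (the downstream pipeline is exact
#' k-mer matching, and error handling is rate-based). Coverage is total
#' bases over the haploid length, so each haplotype receives about half the
#' nominal depth. The read count is exactly
#' \code{round(coverage * L / readLen)}. Deterministic under
#' \code{set.seed}.
#'
#' @param haps list with \code{hap1}, \code{hap2} (from
#'   \code{\link{simulateDiploid}}).
#' @param coverage total-base coverage of the haploid genome.
#' @param readLen read length.
#' @param errorRate per-base substitution rate in [0, 0.2].
#' @return character vector of reads.
#' @export
simulateReads <- function(haps, coverage, readLen = 150L, errorRate = 0) {
  stopifnot(coverage >= 0, errorRate >= 0, errorRate <= 0.2)
  L <- nchar(haps$hap1)
  nReads <- round(coverage * L / readLen)
  if (nReads == 0L) return(character())
  cpp_sim_reads(haps$hap1, haps$hap2, as.integer(nReads),
                as.integer(readLen), errorRate)
}

#' Write reads as FASTQ
#'
#' Fixed quality 'I' (Q40); read ids \code{read1..readN}.
#'
#' @param reads character vector of read sequences.
#' @param path output path (".gz" suffix compresses).
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- paste0("read", seq_along(reads))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
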