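#' Identity/relatedness score report
#'
#' @slot sample,individual the query sample and the sketch donor.
#' @slot relatedness Het/(Het+Hom) over callable sites (NA when no site is
#'   callable).
#' @slot likelihood mean per-site -2 log-likelihood ratio over effective
#'   sites (NA when there are none).
#' @slot nEffective number of effective sites (ref+alt >= 2).
#' @slot nSites number of sketch sites.
#' @slot verdict "same", "different" or "unreliable".
#' @slot warnings character vector of warnings.
#' @exportClass ScoreReport
setClass("ScoreReport",
  representation(sample = "character", individual = "character",
                 relatedness = "numeric", likelihood = "numeric",
                 nEffective = "integer", nSites = "integer",
                 verdict = "character", warnings = "character"))

setValidity("ScoreReport", function(object) {
  if (!object@verdict %in% c("same", "different", "unreliable"))
    return("verdict must be same/different/unreliable")
  TRUE
})

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport: ", object@sample, " vs ", object@individual, "\n",
      "  relatedness ", signif(object@relatedness, 4),
      " | likelihood ", signif(object@likelihood, 4),
      " | effective sites ", object@nEffective, "/", object@nSites, "\n",
      "  verdict: ", toupper(object@verdict), "\n", sep = "")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

#' @describeIn ScoreReport-class one-row data.frame view.
#' @param x a \linkS4class{ScoreReport}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @method as.data.frame ScoreReport
#' @export
as.data.frame.ScoreReport <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(sample = x@sample, sketch_individual = x@individual,
             n_sites = x@nSites, n_effective = x@nEffective,
             relatedness_score = x@relatedness, likelihood_score = x@likelihood,
             verdict = x@verdict,
             warnings = paste(x@warnings, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Genotype cutoff from the Ref/(Ref+Alt) spectrum
#'
#' Builds a 50-bin histogram of the per-site ratios on [0, 1] and returns
#' the bin center with the lowest frequency within the search window
#' (default [0.60, 0.90]) — the valley separating the heterozygous cluster
#' near 0.5 from the homozygous cluster near 1. Ties break toward the center
#' closest to 0.75, then toward the smaller center. With too few informative
#' sites the default cutoff 0.75 is returned with a warning.
#'
#' @param ratios numeric vector of ref/(ref+alt) values (sites with
#'   ref+alt >= 1).
#' @param searchLo,searchHi search window.
#' @param nBins number of histogram bins.
#' @param minSites minimum number of ratios required.
#' @return cutoff value in (0.5, 1).
#' @export
genotypeCutoff <- function(ratios, searchLo = 0.60, searchHi = 0.90,
                           nBins = 50L, minSites = 200L) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < minSites) {
    warning("fewer than ", minSites,
            " informative sites; falling back to cutoff 0.75")
    return(0.75)
  }
  bin <- pmin(floor(ratios * nBins) + 1L, nBins)
  freq <- tabulate(bin, nbins = nBins)
  centers <- (seq_len(nBins) - 0.5) / nBins
  elig <- which(centers >= searchLo & centers <= searchHi)
  cand <- elig[freq[elig] == min(freq[elig])]
  cand <- cand[order(abs(centers[cand] - 0.75), centers[cand])]
  centers[cand[1L]]
}

#' Classify sites as heterozygous or homozygous
#'
#' A covered site (ref+alt >= 1) is homozygous when its ratio is at or
#' beyond the cutoff on either side (\code{ratio >= v} or
#' \code{ratio <= 1-v}), heterozygous otherwise; uncovered sites are missing.
#'
#' @param counts data.frame with \code{site}, \code{ref}, \code{alt}
#'   (from \code{\link{alleleCounts}} or \code{\link{simulateSiteCounts}}).
#' @param cutoff from \code{\link{genotypeCutoff}}, in (0.5, 1).
#' @return \code{counts} with added \code{ratio} and \code{label}
#'   ("het"/"hom"/"missing").
#' @export
callGenotypes <- function(counts, cutoff = 0.75) {
  stopifnot(cutoff > 0.5, cutoff < 1)
  tot <- counts$ref + counts$alt
  ratio <- ifelse(tot >= 1L, counts$ref / tot, NA_real_)
  label <- ifelse(tot < 1L, "missing",
                  ifelse(ratio >= cutoff | ratio <= 1 - cutoff, "hom", "het"))
  counts$ratio <- ratio
  counts$label <- label
  counts
}

#' Relatedness score: Het / (Het + Hom)
#'
#' The sketch donor is heterozygous at every site by construction, so an
#' identical sample shares all heterozygous genotypes (score 1) and a
#' first-degree relative (parent-offspring or sibling) about half
#' (score 0.5). Homozygous sites are not in the sketch, so more distant
#' relationships are not resolvable.
#'
#' @param genotypes data.frame from \code{\link{callGenotypes}}.
#' @return score in [0, 1].
#' @export
relatednessScore <- function(genotypes) {
  het <- sum(genotypes$label == "het")
  hom <- sum(genotypes$label == "hom")
  if (het + hom == 0L) stop("no callable sites")
  het / (het + hom)
}

#' Mean log-likelihood-ratio identity score
#'
#' Per effective site (ref+alt >= 2) with query counts (r, a) and a
#' pseudo-sample fixed at (1, 1), compares the identity model (one shared
#' binomial allele-balance, pooled MLE (r+1)/(r+a+2)) against independence
#' (each sample at its own MLE; the pseudo-sample's is 1/2):
#' \deqn{\lambda = -2 [\log L^{(*)} - \log L^{(1)} - \log L^{(2)}]}
#' with binomial kernels \eqn{p^{ref}(1-p)^{alt}} (coefficients cancel),
#' natural logs. \eqn{\lambda \ge 0} always; identical samples give small
#' values, diverging genotypes large ones. The score is the mean over the N
#' effective sites.
#'
#' @param counts data.frame with \code{ref}, \code{alt}.
#' @param params a \linkS4class{KmerParams} object.
#' @return list with \code{lambdaBar} (NA when N = 0), \code{N}, and
#'   \code{lambda} (per-site values).
#' @export
likelihoodScore <- function(counts, params = kmerParams()) {
  eff <- counts$ref + counts$alt >= 2L
  r <- as.numeric(counts$ref[eff])
  a <- as.numeric(counts$alt[eff])
  lam <- lambdaSite(r, a)
  list(lambdaBar = if (length(lam)) mean(lam) else NA_real_,
       N = length(lam), lambda = lam)
}

# vectorized per-site -2 log LR; xlogy(0, 0) = 0
lambdaSite <- function(r, a) {
  n <- r + a
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ll1 <- xlogy(r, r / n) + xlogy(a, a / n)
  ll2 <- 2 * log(0.5)
  ps <- (r + 1) / (n + 2)
  lls <- (r + 1) * log(ps) + (a + 1) * log(1 - ps)
  pmax(0, -2 * (lls - ll1 - ll2))
}

#' Verdict on a sample/sketch pair
#'
#' Below \code{minEffectiveSites} effective sites (default 50) the result is
#' unreliable regardless of score. Otherwise the pair is called "same" when
#' the likelihood score sits on the identical side of the decision bound
#' (default 0.63; identical pairs score low under this kernel, so
#' \eqn{\bar\lambda \le} threshold, with \code{flipDirection} available to
#' recalibrate).
#'
#' @param relatedness relatedness score (may be NA).
#' @param likelihood list from \code{\link{likelihoodScore}}.
#' @param params a \linkS4class{KmerParams} object.
#' @param sample,individual labels.
#' @param nSites number of sketch sites.
#' @param threshold decision bound (default from \code{params}).
#' @param flipDirection call "same" above the threshold instead of below.
#' @return a \linkS4class{ScoreReport}.
#' @export
classifyPair <- function(relatedness, likelihood, params = kmerParams(),
                         sample = "query", individual = "sketch",
                         nSites = NA_integer_,
                         threshold = params@identityThreshold,
                         flipDirection = FALSE) {
  warns <- character()
  N <- likelihood$N
  if (N < params@minEffectiveSites) {
    warns <- c(warns, sprintf(
      "only %d effective sites (< %d): unreliable; reselect more SNP sites",
      N, params@minEffectiveSites))
    verdict <- "unreliable"
  } else {
    low <- likelihood$lambdaBar <= threshold
    verdict <- if (xor(low, flipDirection)) "same" else "different"
  }
  new("ScoreReport", sample = sample, individual = individual,
      relatedness = relatedness, likelihood = likelihood$lambdaBar,
      nEffective = as.integer(N), nSites = as.integer(nSites),
      verdict = verdict, warnings = warns)
}

#' Score a counts table end to end
#'
#' Convenience wrapper: genotype cutoff, genotype calls, both scores,
#' verdict.
#'
#' @param counts data.frame with \code{site}, \code{ref}, \code{alt}.
#' @param params a \linkS4class{KmerParams} object.
#' @param ... passed to \code{\link{classifyPair}}.
#' @return a \linkS4class{ScoreReport}.
#' @export
scoreCounts <- function(counts, params = kmerParams(), ...) {
  covered <- counts[counts$ref + counts$alt >= 1L, , drop = FALSE]
  rel <- NA_real_
  if (nrow(covered)) {
    v <- suppressWarnings(genotypeCutoff(covered$ref /
                                           (covered$ref + covered$alt)))
    geno <- callGenotypes(counts, v)
    rel <- tryCatch(relatednessScore(geno), error = function(e) NA_real_)
  }
  lik <- likelihoodScore(counts, params)
  classifyPair(rel, lik, params, nSites = nrow(counts), ...)
}
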