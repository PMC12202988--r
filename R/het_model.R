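#' Heterozygous frequency region of the k-mer spectrum
#'
#' @slot lo,hi inclusive frequency bounds.
#' @slot hetPeak the chosen heterozygous peak frequency.
#' @exportClass HetRegion
setClass("HetRegion",
  representation(lo = "integer", hi = "integer", hetPeak = "integer"))

setValidity("HetRegion", function(object) {
  if (object@lo < 2L || object@lo > object@hetPeak || object@hetPeak > object@hi)
    "need 2 <= lo <= hetPeak <= hi" else TRUE
})

setMethod("show", "HetRegion", function(object) {
  cat("HetRegion: [", object@lo, ",", object@hi, "] around het peak",
      object@hetPeak, "\n")
})

#' Rough genome profile from a two-negative-binomial spectrum fit
#'
#' @slot hetCoverage,homCoverage fitted component means (heterozygous k-mers
#'   occur at about half the homozygous coverage in a diploid).
#' @slot hetDispersion,homDispersion fitted NB size parameters.
#' @slot heterozygosityEstimate rough per-base heterozygosity fraction.
#' @slot genomeSizeEstimate rough haploid genome size in bases.
#' @slot fitOk whether the optimizer converged to a usable fit.
#' @slot message diagnostic message when \code{fitOk} is \code{FALSE}.
#' @exportClass GenomeProfile
setClass("GenomeProfile",
  representation(hetCoverage = "numeric", homCoverage = "numeric",
                 hetDispersion = "numeric", homDispersion = "numeric",
                 heterozygosityEstimate = "numeric",
                 genomeSizeEstimate = "numeric", fitOk = "logical",
                 message = "character"))

setMethod("show", "GenomeProfile", function(object) {
  if (!object@fitOk) {
    cat("GenomeProfile: fit failed (", object@message, ")\n")
    return(invisible(NULL))
  }
  cat("GenomeProfile:\n",
      " het coverage  ", signif(object@hetCoverage, 4), "\n",
      " hom coverage  ", signif(object@homCoverage, 4), "\n",
      " heterozygosity", signif(object@heterozygosityEstimate, 3), "\n",
      " genome size   ", format(round(object@genomeSizeEstimate),
                                big.mark = ","), "bp\n")
})

#' Detect peaks in the k-mer spectrum
#'
#' Scans the first \code{histMaxEntries} frequencies in increasing order and
#' reports a peak at every strict 3-point local maximum
#' (\code{n[f-1] < n[f] > n[f+1]}). The scan terminates early once the
#' cumulative k-mer mass reaches \code{histMassStop} of the total or once
#' \code{maxPeaks} peaks have been found, which suppresses noise peaks in the
#' long right tail. Frequency 1 (dominated by sequencing-error k-mers) counts
#' toward the mass but cannot itself be a peak.
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param params a \linkS4class{KmerParams} object.
#' @return data.frame with columns \code{freq} and \code{height} (possibly
#'   zero rows).
#' @export
detectPeaks <- function(hist, params = kmerParams()) {
  stopifnot(is(hist, "KmerHistogram"))
  if (!length(hist@freq)) return(data.frame(freq = integer(), height = numeric()))
  fmax <- min(params@histMaxEntries, max(hist@freq))
  dense <- numeric(fmax)
  keep <- hist@freq <= fmax
  dense[hist@freq[keep]] <- hist@n[keep]
  peaks_f <- integer()
  peaks_h <- numeric()
  mass <- 0
  for (f in seq_len(fmax)) {
    mass <- mass + f * dense[f]
    if (f >= 2L && f < fmax &&
        dense[f - 1L] < dense[f] && dense[f] > dense[f + 1L]) {
      peaks_f <- c(peaks_f, f)
      peaks_h <- c(peaks_h, dense[f])
    }
    if (length(peaks_f) >= params@maxPeaks) break
    if (mass >= params@histMassStop * hist@totalMass) break
  }
  data.frame(freq = peaks_f, height = peaks_h)
}

#' Choose the heterozygous peak
#'
#' With two peaks the first (lower-frequency) one is the heterozygous peak.
#' With a single peak the interpretation depends on the species: above a
#' heterozygosity of about 1.2% the heterozygous peak overtakes the homozygous
#' one, so a lone peak is heterozygous (\code{highHet = TRUE}); otherwise the
#' lone peak is homozygous and the heterozygous coverage is half of it
#' (clamped to >= 2).
#'
#' @param peaks data.frame from \code{\link{detectPeaks}}.
#' @param highHet logical: is the species' heterozygosity above
#'   \code{params@highHetCutoff}?
#' @param params a \linkS4class{KmerParams} object.
#' @return heterozygous peak frequency (integer).
#' @export
selectHetPeak <- function(peaks, highHet = FALSE, params = kmerParams()) {
  if (nrow(peaks) == 0L)
    stop("no peak detected; increase coverage or check data")
  if (nrow(peaks) >= 2L) return(as.integer(peaks$freq[1L]))
  f <- peaks$freq[1L]
  if (highHet) as.integer(f)
  else max(2L, as.integer(roundHalfUp(f / 2)))
}

#' Heterozygous region from the heterozygous peak
#'
#' \code{[max(minRegionLo, round(0.5 * peak)), round(1.5 * peak)]} with
#' half-away-from-zero rounding; the left clamp excludes error k-mers.
#'
#' @param hetPeak heterozygous peak frequency.
#' @param params a \linkS4class{KmerParams} object.
#' @return a \linkS4class{HetRegion}.
#' @examples
#' hetRegion(12L)   # [6, 18]
#' @export
hetRegion <- function(hetPeak, params = kmerParams()) {
  stopifnot(hetPeak >= 1)
  lo <- max(params@minRegionLo,
            as.integer(roundHalfUp(params@regionLoMult * hetPeak)))
  hi <- max(lo, as.integer(roundHalfUp(params@regionHiMult * hetPeak)))
  new("HetRegion", lo = lo, hi = hi,
      hetPeak = as.integer(max(lo, min(hi, hetPeak))))
}

#' Fit a two-negative-binomial mixture to the k-mer spectrum
#'
#' Least-squares fit (on the variance-stabilizing square-root scale) of
#' \code{A * [w NB(size1, mu1) + (1-w) NB(size2, mu2)]} to the distinct-k-mer
#' counts at frequencies at or above the heterozygous-region left bound,
#' excluding the error spike. The homozygous mean is constrained to twice the
#' heterozygous mean (the diploid expectation), which keeps the faint
#' heterozygous shoulder identifiable; amplitudes are profiled out by
#' weighted linear least squares. Yields a rough genome profile: homozygous
#' coverage,
#' genome size (mass / homCoverage) and heterozygosity
#' (het k-mers / (2k * genome size)).
#'
#' @param hist a \linkS4class{KmerHistogram}.
#' @param hetPeak heterozygous peak frequency.
#' @param params a \linkS4class{KmerParams} object.
#' @return a \linkS4class{GenomeProfile}; \code{fitOk = FALSE} (never an
#'   error) when the fit is degenerate.
#' @export
fitGenomeProfile <- function(hist, hetPeak, params = kmerParams()) {
  stopifnot(is(hist, "KmerHistogram"))
  fail <- function(msg) new("GenomeProfile", hetCoverage = NA_real_,
                            homCoverage = NA_real_, hetDispersion = NA_real_,
                            homDispersion = NA_real_,
                            heterozygosityEstimate = NA_real_,
                            genomeSizeEstimate = NA_real_, fitOk = FALSE,
                            message = msg)
  lo <- hetRegion(hetPeak, params)@lo
  keep <- hist@freq >= lo & hist@freq <= params@histMaxEntries
  f <- hist@freq[keep]
  y <- hist@n[keep]
  if (length(f) < 10L) return(fail("fewer than 10 informative frequencies"))
  # amplitudes are linear given the component shapes: profile them out with
  # Poisson-weighted least squares, and optimize only the shape parameters
  wgt <- 1 / (y + 1)
  amplitudes <- function(phi1, phi2) {
    a11 <- sum(wgt * phi1 * phi1); a12 <- sum(wgt * phi1 * phi2)
    a22 <- sum(wgt * phi2 * phi2)
    b1 <- sum(wgt * phi1 * y); b2 <- sum(wgt * phi2 * y)
    det <- a11 * a22 - a12 * a12
    c12 <- if (det > 0) c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det
           else c(0, b2 / a22)
    pmax(c12, 0)
  }
  # diploid constraint: the homozygous component sits at twice the
  # heterozygous coverage, which makes the faint het shoulder identifiable
  shapes <- function(par) {
    list(phi1 = dnbinom(f, size = exp(par[2]), mu = exp(par[1])),
         phi2 = dnbinom(f, size = exp(par[3]), mu = 2 * exp(par[1])))
  }
  obj <- function(par) {
    sh <- shapes(par)
    cc <- amplitudes(sh$phi1, sh$phi2)
    m <- cc[1] * sh$phi1 + cc[2] * sh$phi2
    sum(wgt * (y - m)^2)
  }
  init <- c(log(hetPeak), log(10), log(10))
  fit <- tryCatch({
    a <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
    optim(a$par, obj, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12))
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail("optimizer error"))
  mu1 <- exp(fit$par[1]); mu2 <- 2 * mu1
  s1 <- exp(fit$par[2]); s2 <- exp(fit$par[3])
  sh <- shapes(fit$par)
  cc <- amplitudes(sh$phi1, sh$phi2)
  if (!is.finite(mu1) || mu1 <= 0)
    return(fail("degenerate component means"))
  mass <- sum(f * y)
  G <- mass / mu2
  het <- min(1, max(0, cc[1] / (2 * hist@k * G)))
  new("GenomeProfile", hetCoverage = mu1, homCoverage = mu2,
      hetDispersion = s1, homDispersion = s2,
      heterozygosityEstimate = het, genomeSizeEstimate = G,
      fitOk = TRUE, message = "")
}

#' @importFrom stats plogis qlogis
NULL
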