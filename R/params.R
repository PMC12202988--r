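#' Tuning constants for sketch construction and scoring
#'
#' Holds every constant the two-stage pipeline depends on: the k-mer size, the
#' heterozygous-region rule, histogram scan limits, the support filter, the
#' effective-site and sketch-size floors, the identity threshold and the
#' count-level simulation defaults.
#'
#' @slot k odd k-mer size (default 21).
#' @slot regionLoMult,regionHiMult multipliers applied to the heterozygous peak
#'   frequency to derive the heterozygous region (defaults 0.5 and 1.5).
#' @slot minRegionLo minimum left boundary of the region, excluding error
#'   k-mers (default 2).
#' @slot histMaxEntries number of leading histogram entries scanned for peaks
#'   (default 1000).
#' @slot histMassStop early-stop fraction of total k-mer mass (default 0.95).
#' @slot maxPeaks peak-count early stop (default 2).
#' @slot highHetCutoff heterozygosity fraction above which a lone spectrum peak
#'   is taken to be the heterozygous one (default 0.012).
#' @slot supportRequired support length required of a final SNP call
#'   (default: k).
#' @slot minEffectiveSites below this effective-site count the verdict is
#'   unreliable (default 50).
#' @slot minSketchSites sketches smaller than this trigger a warning
#'   (default 20000).
#' @slot identityThreshold decision bound on the mean log-likelihood-ratio
#'   score (default 0.63).
#' @slot simSites,simPHet,simReps count-level simulation defaults (200000
#'   sites, allele-split probability 0.5, 1000 replicates).
#' @exportClass KmerParams
setClass("KmerParams",
  representation(
    k = "integer",
    regionLoMult = "numeric",
    regionHiMult = "numeric",
    minRegionLo = "integer",
    histMaxEntries = "integer",
    histMassStop = "numeric",
    maxPeaks = "integer",
    highHetCutoff = "numeric",
    supportRequired = "integer",
    minEffectiveSites = "integer",
    minSketchSites = "integer",
    identityThreshold = "numeric",
    simSites = "integer",
    simPHet = "numeric",
    simReps = "integer"
  )
)

setValidity("KmerParams", function(object) {
  msg <- character()
  k <- object@k
  if (length(k) != 1L || is.na(k) || k %% 2L == 0L || k < 3L || k > 25L)
    msg <- c(msg, "k must be odd and in [3, 25] (2-bit codes are exchanged as exact doubles)")
  if (object@regionLoMult <= 0 || object@regionHiMult <= 0)
    msg <- c(msg, "region multipliers must be > 0")
  if (object@regionLoMult > object@regionHiMult)
    msg <- c(msg, "regionLoMult must not exceed regionHiMult")
  if (object@identityThreshold <= 0)
    msg <- c(msg, "identityThreshold must be > 0")
  if (object@histMassStop <= 0 || object@histMassStop > 1)
    msg <- c(msg, "histMassStop must be in (0, 1]")
  if (object@supportRequired < 1L || object@supportRequired > k)
    msg <- c(msg, "supportRequired must be in [1, k]")
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{KmerParams} object
#'
#' @param k odd k-mer size.
#' @param regionLoMult,regionHiMult heterozygous-region multipliers.
#' @param minRegionLo minimum left region boundary.
#' @param histMaxEntries,histMassStop,maxPeaks peak-scan limits.
#' @param highHetCutoff high-heterozygosity cutoff fraction.
#' @param supportRequired support length a final call must reach (defaults
#'   to \code{k}).
#' @param minEffectiveSites unreliability floor on effective sites.
#' @param minSketchSites sketch-size warning floor.
#' @param identityThreshold decision bound for the likelihood score.
#' @param simSites,simPHet,simReps count-level simulation defaults.
#' @return a validated \linkS4class{KmerParams} object.
#' @examples
#' kmerParams()
#' kmerParams(k = 15L)
#' @export
kmerParams <- function(k = 21L, regionLoMult = 0.5, regionHiMult = 1.5,
                       minRegionLo = 2L, histMaxEntries = 1000L,
                       histMassStop = 0.95, maxPeaks = 2L,
                       highHetCutoff = 0.012, supportRequired = k,
                       minEffectiveSites = 50L, minSketchSites = 20000L,
                       identityThreshold = 0.63, simSites = 200000L,
                       simPHet = 0.5, simReps = 1000L) {
  new("KmerParams",
      k = as.integer(k), regionLoMult = regionLoMult,
      regionHiMult = regionHiMult, minRegionLo = as.integer(minRegionLo),
      histMaxEntries = as.integer(histMaxEntries), histMassStop = histMassStop,
      maxPeaks = as.integer(maxPeaks), highHetCutoff = highHetCutoff,
      supportRequired = as.integer(supportRequired),
      minEffectiveSites = as.integer(minEffectiveSites),
      minSketchSites = as.integer(minSketchSites),
      identityThreshold = identityThreshold, simSites = as.integer(simSites),
      simPHet = simPHet, simReps = as.integer(simReps))
}

setMethod("show", "KmerParams", function(object) {
  cat("KmerParams: k =", object@k,
      "| het region", object@regionLoMult, "x -", object@regionHiMult,
      "x (lo >=", object@minRegionLo, ")",
      "| support >=", object@supportRequired,
      "| threshold", object@identityThreshold, "\n")
})

# half-away-from-zero rounding; base round() is banker's rounding
roundHalfUp <- function(x) trunc(x + sign(x) * 0.5)
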