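#' Extract heterozygous-region k-mers
#'
#' Selects exactly the canonical k-mers whose occurrence count lies inside
#' the heterozygous region (inclusive).
#'
#' @param table a \linkS4class{KmerCountTable}.
#' @param region a \linkS4class{HetRegion}.
#' @return sorted numeric vector of canonical codes.
#' @export
extractHetKmers <- function(table, region) {
  stopifnot(is(table, "KmerCountTable"), is(region, "HetRegion"))
  keep <- table@count >= region@lo & table@count <= region@hi
  out <- table@code[keep]
  if (!length(out))
    warning("no heterozygous k-mers; check coverage/region")
  out
}

#' Find candidate SNP k-mer pairs
#'
#' Returns every unordered pair of heterozygous-set k-mers for which some
#' orientation of one differs from some orientation of the other at exactly
#' the middle base. Each pair is recorded once, oriented so that
#' \code{orientedA} is the lexicographically smallest orientation in which
#' the middle-base property holds; output is sorted by codes.
#'
#' @param hetCodes sorted numeric vector of canonical codes (from
#'   \code{\link{extractHetKmers}}).
#' @param params a \linkS4class{KmerParams} object.
#' @return data.frame with \code{codeA}, \code{codeB}, \code{orientedA},
#'   \code{orientedB}.
#' @export
findCandidatePairs <- function(hetCodes, params = kmerParams()) {
  if (!length(hetCodes))
    return(data.frame(codeA = numeric(), codeB = numeric(),
                      orientedA = character(), orientedB = character(),
                      stringsAsFactors = FALSE))
  df <- cpp_find_pairs(sort(hetCodes), params@k)
  df[order(df$codeA, df$codeB), , drop = FALSE]
}

#' Support length of candidate pairs
#'
#' Starting from the oriented k-mer pair (variant centered), the shared
#' flanks are extended base by base in each direction; a step succeeds iff
#' exactly one nucleotide makes both shifted allele k-mers members of the
#' heterozygous set (an ambiguous step stops the walk, avoiding chimeric
#' contexts). The support length is \code{1 + left + right} steps, at most k;
#' full support (= k) means both length 2k-1 allele contexts are completely
#' represented in the heterozygous set.
#'
#' @param pairs data.frame from \code{\link{findCandidatePairs}}.
#' @param hetCodes sorted numeric vector of heterozygous canonical codes.
#' @param params a \linkS4class{KmerParams} object.
#' @return \code{pairs} with added columns \code{support}, \code{ctxA},
#'   \code{ctxB} (the extended regions; length \code{k + support - 1}).
#' @export
supportLength <- function(pairs, hetCodes, params = kmerParams()) {
  if (!nrow(pairs)) {
    pairs$support <- integer()
    pairs$ctxA <- character()
    pairs$ctxB <- character()
    return(pairs)
  }
  res <- cpp_support(pairs$orientedA, pairs$orientedB, sort(hetCodes),
                     params@k)
  pairs$support <- res$support
  pairs$ctxA <- res$ctxA
  pairs$ctxB <- res$ctxB
  pairs
}

#' Maximum-weight matching over candidate pairs
#'
#' Selects a set of pairs such that no k-mer appears in more than one
#' selected pair, maximizing total support. Each connected component of the
#' conflict graph is solved exactly by branch-and-bound (components are tiny
#' in practice); components larger than \code{maxExactEdges} fall back to a
#' deterministic greedy (by decreasing weight, then increasing codes). Ties
#' between optimal matchings resolve toward lexicographically smaller code
#' pairs.
#'
#' @param pairs data.frame with \code{codeA}, \code{codeB}, \code{support}.
#' @param maxExactEdges exact-search cap per component.
#' @return the selected subset of \code{pairs}, sorted by codes.
#' @export
maxWeightMatching <- function(pairs, maxExactEdges = 25L) {
  if (!nrow(pairs)) return(pairs)
  pairs <- pairs[order(pairs$codeA, pairs$codeB), , drop = FALSE]
  verts <- sort(unique(c(pairs$codeA, pairs$codeB)))
  ia <- match(pairs$codeA, verts)
  ib <- match(pairs$codeB, verts)
  g <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
  comp <- igraph::components(g)$membership
  edgeComp <- comp[ia]
  sel <- logical(nrow(pairs))
  for (cid in unique(edgeComp)) {
    eidx <- which(edgeComp == cid)
    if (length(eidx) == 1L) {
      sel[eidx] <- TRUE
      next
    }
    if (length(eidx) <= maxExactEdges) {
      sel[eidx[matchExact(ia[eidx], ib[eidx], pairs$support[eidx])]] <- TRUE
    } else {
      sel[eidx[matchGreedy(ia[eidx], ib[eidx], pairs$support[eidx])]] <- TRUE
    }
  }
  pairs[sel, , drop = FALSE]
}

# exact maximum-weight matching on one small component.
# edges visited in sorted order; replacement only on strictly greater weight,
# so among ties the matching containing earlier (smaller-code) edges wins.
matchExact <- function(ia, ib, w) {
  m <- length(w)
  best <- list(weight = -1, take = logical(m))
  suffix <- rev(cumsum(rev(w)))  # bound for pruning
  recurse <- function(i, used, take, acc) {
    if (i > m) {
      if (acc > best$weight) best <<- list(weight = acc, take = take)
      return(invisible(NULL))
    }
    if (acc + suffix[i] <= best$weight) return(invisible(NULL))
    # take edge i first so ties prefer earlier edges
    if (!used[ia[i]] && !used[ib[i]]) {
      used2 <- used
      used2[c(ia[i], ib[i])] <- TRUE
      take2 <- take
      take2[i] <- TRUE
      recurse(i + 1L, used2, take2, acc + w[i])
    }
    recurse(i + 1L, used, take, acc)
  }
  recurse(1L, logical(max(ia, ib)), logical(m), 0)
  which(best$take)
}

matchGreedy <- function(ia, ib, w) {
  ord <- order(-w, ia, ib)
  used <- logical(max(ia, ib))
  keep <- integer()
  for (i in ord) {
    if (!used[ia[i]] && !used[ib[i]]) {
      used[c(ia[i], ib[i])] <- TRUE
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

#' Stage 1: call isolated heterozygous SNPs from low-error reads
#'
#' Runs the full calling chain: k-mer counting, histogram, peak detection,
#' heterozygous-region extraction, middle-base pairing, support-length
#' computation, maximum-weight matching, and the full-support filter
#' (\code{support == supportRequired}, default k). Because no reference is
#' involved, every call is heterozygous by construction, and only isolated
#' substitution SNPs (unique 2k-1 contexts) are callable.
#'
#' @param reads sequences or FASTA/FASTQ path(s); low-error data only.
#' @param params a \linkS4class{KmerParams} object.
#' @param highHet is the species heterozygosity above ~1.2%?
#' @param verbose log progress to stderr.
#' @return data.frame with \code{site_id}, \code{ref_context},
#'   \code{alt_context} (length 2k-1, variant centered, differing only
#'   there), and \code{support}; sorted by \code{ref_context} with stable
#'   ids. A warning is issued below \code{minSketchSites} calls.
#' @export
callSnps <- function(reads, params = kmerParams(), highHet = FALSE,
                     verbose = FALSE) {
  tab <- countKmers(reads, params)
  calls <- callSnpsFromTable(tab, params, highHet = highHet,
                             verbose = verbose)
  if (nrow(calls) < params@minSketchSites)
    warning(sprintf(paste0("only %d SNP sites called; sketches below ~%d",
                           " sites lose stability at low query coverage"),
                    nrow(calls), params@minSketchSites))
  calls
}

# the calling chain from a prebuilt count table (shared with stage-1
# orchestration, which also needs the table for the genome profile)
callSnpsFromTable <- function(tab, params, highHet = FALSE, verbose = FALSE,
                              region = NULL) {
  say <- function(...) if (verbose) message("[stage1] ", ...)
  if (is.null(region)) {
    hist <- buildHistogram(tab, params)
    peaks <- detectPeaks(hist, params)
    say("peaks at ", paste(peaks$freq, collapse = ", "))
    hp <- selectHetPeak(peaks, highHet = highHet, params = params)
    region <- hetRegion(hp, params)
  }
  say("het region [", region@lo, ", ", region@hi, "]")
  het <- extractHetKmers(tab, region)
  say(length(het), " heterozygous-region k-mers")
  pairs <- findCandidatePairs(het, params)
  pairs <- supportLength(pairs, het, params)
  say(nrow(pairs), " candidate pairs")
  sel <- maxWeightMatching(pairs)
  sel <- sel[sel$support >= params@supportRequired, , drop = FALSE]
  if (!nrow(sel))
    stop("no SNPs called at the required support; coverage may be too low")
  ref <- pmin(sel$ctxA, sel$ctxB)
  alt <- pmax(sel$ctxA, sel$ctxB)
  ord <- order(ref, alt)
  data.frame(site_id = seq_along(ord), ref_context = ref[ord],
             alt_context = alt[ord], support = sel$support[ord],
             stringsAsFactors = FALSE)
}
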