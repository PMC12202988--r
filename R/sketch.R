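#' Variant sketch: deduplicated per-site ref/alt k-mer sets
#'
#' The compact identity fingerprint of an individual: for every called SNP
#' site, the canonical k-mers tiling its ref and alt contexts, after global
#' deduplication. Any canonical k-mer occurring more than once anywhere in
#' the sketch (within a site, across sites, across ref/alt, or — by
#' canonicality — as a reverse complement) is removed from all positions, so
#' every retained k-mer attributes its counts to exactly one (site, allele)
#' slot. Sites reduced below one k-mer on either allele are dropped.
#'
#' @slot kmers data.frame with columns \code{site} (integer), \code{allele}
#'   ("ref"/"alt"), \code{slot} (1-based index within the allele),
#'   \code{kmer} (canonical sequence) and \code{code} (numeric canonical
#'   code).
#' @slot sites data.frame with columns \code{site} and \code{individual}.
#' @slot k k-mer size.
#' @exportClass VariantSketch
setClass("VariantSketch",
  representation(kmers = "data.frame", sites = "data.frame", k = "integer"))

setValidity("VariantSketch", function(object) {
  msg <- character()
  km <- object@kmers
  need <- c("site", "allele", "slot", "kmer", "code")
  if (!all(need %in% names(km)))
    msg <- c(msg, "kmers must have site/allele/slot/kmer/code columns")
  else {
    if (anyDuplicated(km$code))
      msg <- c(msg, "duplicate k-mer codes violate sketch independence")
    if (nrow(km) && !all(nchar(km$kmer) == object@k))
      msg <- c(msg, "k-mer lengths disagree with k")
    both <- tapply(km$allele, km$site, function(a) all(c("ref", "alt") %in% a))
    if (length(both) && !all(both))
      msg <- c(msg, "every site must retain >= 1 ref and >= 1 alt k-mer")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "VariantSketch", function(object) {
  cat("VariantSketch:", nrow(object@sites), "sites,", nrow(object@kmers),
      "k-mers (k =", object@k, "),",
      length(unique(object@sites$individual)), "individual(s)\n")
})

#' @describeIn VariantSketch-class number of sites retained.
#' @param x a \linkS4class{VariantSketch}.
#' @export
nSites <- function(x) nrow(x@sites)

#' @describeIn VariantSketch-class per-site k-mer table.
#' @export
sketchKmers <- function(x) x@kmers

# remove every k-mer whose canonical code occurs more than once; drop sites
# left without both alleles
dedupSketch <- function(km, sites, k, warnDrop = TRUE) {
  dup <- km$code %in% km$code[duplicated(km$code)]
  km <- km[!dup, , drop = FALSE]
  ok <- tapply(km$allele, km$site, function(a) all(c("ref", "alt") %in% a))
  keep <- as.integer(names(ok)[ok])
  dropped <- setdiff(sites$site, keep)
  if (length(dropped) && warnDrop)
    warning(length(dropped),
            " site(s) dropped: no unique k-mer left on one allele")
  km <- km[km$site %in% keep, , drop = FALSE]
  sites <- sites[sites$site %in% keep, , drop = FALSE]
  if (!nrow(sites))
    stop("no sites left after k-mer deduplication")
  # canonical order (ref before alt) and slot renumbering
  km <- km[order(km$site, km$allele != "ref", km$slot), , drop = FALSE]
  km$slot <- stats::ave(seq_len(nrow(km)), km$site, km$allele,
                        FUN = seq_along)
  rownames(km) <- rownames(sites) <- NULL
  new("VariantSketch", kmers = km, sites = sites, k = as.integer(k))
}

#' Build a variant sketch from SNP calls
#'
#' Each allele context of length 2k-1 is tiled by a k-mer sliding window
#' (k windows per allele), windows are canonicalized, and duplicates are
#' removed globally (see \linkS4class{VariantSketch}).
#'
#' @param snps data.frame from \code{\link{callSnps}} (needs
#'   \code{site_id}, \code{ref_context}, \code{alt_context}).
#' @param params a \linkS4class{KmerParams} object.
#' @param individual provenance label.
#' @return a \linkS4class{VariantSketch}.
#' @export
buildSketch <- function(snps, params = kmerParams(), individual = "sample") {
  if (!nrow(snps)) stop("no SNP calls to sketch")
  k <- params@k
  if (!all(nchar(snps$ref_context) == 2L * k - 1L))
    stop("contexts must have length 2k-1")
  tile <- function(ctx) {
    starts <- seq_len(k)
    substring(ctx, starts, starts + k - 1L)
  }
  km <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    data.frame(site = rep(as.integer(snps$site_id[i]), 2L * k),
               allele = rep(c("ref", "alt"), each = k),
               slot = rep(seq_len(k), 2L),
               kmer = c(tile(snps$ref_context[i]), tile(snps$alt_context[i])),
               stringsAsFactors = FALSE)
  }))
  res <- cpp_canonical(km$kmer, k)
  km$kmer <- res$kmer
  km$code <- res$code
  sites <- data.frame(site = as.integer(snps$site_id),
                      individual = individual, stringsAsFactors = FALSE)
  dedupSketch(km, sites, k)
}

#' Write a variant sketch as FASTA
#'
#' One record per retained k-mer with header
#' \code{>site\{ID\}|\{allele\}|\{index\}}; a TSV sidecar
#' (\code{<path>.sites.tsv}) records per-site k-mer counts and the
#' individual of origin. Output is deterministic and round-trips bit-exactly
#' through \code{\link{readSketch}}.
#'
#' @param sketch a \linkS4class{VariantSketch}.
#' @param path output FASTA path.
#' @param sidecar write the TSV sidecar too?
#' @return \code{path}, invisibly.
#' @export
writeSketch <- function(sketch, path, sidecar = TRUE) {
  stopifnot(is(sketch, "VariantSketch"))
  km <- sketch@kmers
  if (!nrow(km)) stop("refusing to write an empty sketch")
  km <- km[order(km$site, km$allele != "ref", km$slot), , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(km$kmer)
  names(seqs) <- sprintf("site%d|%s|%d", km$site, km$allele, km$slot)
  Biostrings::writeXStringSet(seqs, path, width = 200L)
  if (sidecar) {
    counts <- as.data.frame.matrix(table(km$site, km$allele))
    side <- data.frame(site_id = as.integer(rownames(counts)),
                       n_ref_kmers = counts$ref, n_alt_kmers = counts$alt)
    side$individual <-
      sketch@sites$individual[match(side$site_id, sketch@sites$site)]
    write.table(side, paste0(path, ".sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a variant sketch FASTA
#'
#' Validates the global-uniqueness invariant (duplicate k-mers mean a
#' corrupt sketch) and the k-mer length.
#'
#' @param path sketch FASTA path.
#' @param k expected k-mer size.
#' @return a \linkS4class{VariantSketch}.
#' @export
readSketch <- function(path, k = 21L) {
  seqs <- Biostrings::readDNAStringSet(path)
  widths <- unique(Biostrings::width(seqs))
  if (length(widths) != 1L || widths != k)
    stop("wrong k: file has ", paste(widths, collapse = "/"),
         "-mers, expected ", k)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(hdr) != 3L)) stop("corrupt sketch: malformed header")
  km <- data.frame(site = as.integer(sub("^site", "", vapply(hdr, `[`, "", 1L))),
                   allele = vapply(hdr, `[`, "", 2L),
                   slot = as.integer(vapply(hdr, `[`, "", 3L)),
                   kmer = as.character(seqs), stringsAsFactors = FALSE)
  if (any(is.na(km$site)) || !all(km$allele %in% c("ref", "alt")))
    stop("corrupt sketch: malformed header")
  res <- cpp_canonical(km$kmer, as.integer(k))
  if (any(km$kmer != res$kmer)) stop("corrupt sketch: non-canonical k-mer")
  km$code <- res$code
  if (anyDuplicated(km$code)) stop("corrupt sketch: duplicate k-mer")
  km <- km[order(km$site, km$allele != "ref", km$slot), , drop = FALSE]
  rownames(km) <- NULL
  side <- paste0(path, ".sites.tsv")
  sites <- data.frame(site = sort(unique(km$site)),
                      individual = basename(path), stringsAsFactors = FALSE)
  if (file.exists(side)) {
    tsv <- read.table(side, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    sites$individual <- tsv$individual[match(sites$site, tsv$site_id)]
  }
  new("VariantSketch", kmers = km, sites = sites, k = as.integer(k))
}

#' Merge variant sketches from several individuals
#'
#' Site ids are remapped to stay globally unique (provenance is kept in the
#' sites table) and the same remove-all duplicate rule as
#' \code{\link{buildSketch}} is re-applied across individuals.
#'
#' @param sketches list of \linkS4class{VariantSketch} objects.
#' @return a \linkS4class{VariantSketch}.
#' @export
mergeSketches <- function(sketches) {
  if (is(sketches, "VariantSketch")) sketches <- list(sketches)
  stopifnot(length(sketches) >= 1L,
            all(vapply(sketches, is, TRUE, "VariantSketch")))
  ks <- vapply(sketches, function(s) s@k, integer(1))
  if (length(unique(ks)) != 1L)
    stop("mixed k: ", paste(unique(ks), collapse = ", "))
  offset <- 0L
  km <- list(); sites <- list()
  for (s in sketches) {
    kmi <- s@kmers; si <- s@sites
    remap <- setNames(offset + seq_len(nrow(si)), si$site)
    kmi$site <- as.integer(remap[as.character(kmi$site)])
    si$site <- as.integer(remap[as.character(si$site)])
    offset <- offset + nrow(si)
    km[[length(km) + 1L]] <- kmi
    sites[[length(sites) + 1L]] <- si
  }
  dedupSketch(do.call(rbind, km), do.call(rbind, sites), ks[1])
}
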