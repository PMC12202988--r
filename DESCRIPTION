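Package: sketchmer
Title: Reference-Free Sample Swap Detection from k-mer Variant Sketches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Verifies whether whole-genome sequencing runs come from the same
    diploid individual without a reference genome. Stage 1 calls isolated
    heterozygous SNPs from one low-error run by k-mer spectrum analysis
    (peak detection, heterozygous-region extraction, middle-base k-mer
    pairing, support-length computation and maximum-weight matching) and
    stores them as a deduplicated variant-sketch FASTA. Stage 2 streams any
    other run over the sketch, collapses per-site k-mer counts to modal
    allele depths, and scores sample identity with a relatedness score
    (shared-heterozygosity fraction) and a mean log-likelihood-ratio
    statistic against a fixed decision bound. Includes count-level and
    read-level simulators for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
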