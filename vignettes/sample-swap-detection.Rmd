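---
title: "Reference-free sample-swap detection with k-mer variant sketches"
author: "sketchmer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free sample-swap detection with k-mer variant sketches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchmer)
```

## The problem

Cohort sequencing projects routinely mix technologies and batches, and a
mislabelled FASTQ — a *sample swap* — silently corrupts every downstream
analysis. The established checks genotype a preselected panel of
population-informative SNPs against a reference genome, which works for
human but not for the growing number of species with no reference or no
population allele-frequency panel. `sketchmer` verifies whether two
whole-genome sequencing runs come from the same diploid individual using
nothing but the reads themselves.

The idea is a two-stage design. **Stage 1** takes one low-error run
(HiFi- or Illumina-like) from the target individual and calls *isolated
heterozygous SNPs* purely from k-mer statistics; the SNPs are stored as a
*variant sketch* — a deduplicated FASTA of the 21-mers tiling each allele
of each site. **Stage 2** streams any other run (including high-error long
reads) over the sketch, counts exact k-mer matches per site and allele,
and scores identity. Because every sketch site is heterozygous in the
donor, an identical sample shows both alleles nearly everywhere, a
first-degree relative at about half the sites, and an unrelated sample
almost nowhere.

## Stage 1: isolated SNP calling from the k-mer spectrum

All k-mer handling is canonical: a k-mer and its reverse complement are the
same object, represented by the lexicographically smaller string under
A<C<G<T (2-bit packed, A=0, C=1, G=2, T=3). Windows containing ambiguous
bases are skipped whole, and bases are uppercased on input. `k` defaults to
21 and must be odd so a middle base exists; it is capped at 25 because
codes cross the R boundary as exact doubles (2k bits ≤ 52).

### Spectrum peaks and the heterozygous region

`countKmers()` + `buildHistogram()` produce the k-mer abundance histogram.
In a diploid, heterozygous k-mers occur on one haplotype only and cluster
near the per-haplotype coverage `c`, homozygous k-mers near `2c`, and
sequencing-error k-mers pile up at frequency 1–2. `detectPeaks()` scans the
first 1,000 histogram entries in increasing order and reports a peak at
every strict 3-point local maximum (`n[f-1] < n[f] > n[f+1]`); plateaus do
not count. The scan stops early once two peaks are found or once 95% of the
total k-mer mass has been consumed — both stops suppress spurious peaks in
the sparse right tail. Frequency 1 contributes to the mass but can never be
a peak (it has no left neighbour), which is deliberate: it is dominated by
error k-mers.

`selectHetPeak()` interprets the peaks. With two, the lower-frequency one
is heterozygous. With one, the interpretation is ambiguous and a species
prior is required (`highHet`): above roughly 1.2% heterozygosity the
heterozygous peak overtakes the homozygous one, so a lone peak is taken as
heterozygous; below it the lone peak is homozygous and the heterozygous
coverage is half of it (rounded half-away-from-zero, clamped to ≥ 2). The
heterozygous *region* is then `[max(2, round(0.5 c_het)), round(1.5 c_het)]`
— wide enough to capture most heterozygous k-mers while excluding the error
spike (left floor 2) and most homozygous mass. Rounding is
half-away-from-zero throughout so the bounds are bit-reproducible.

`fitGenomeProfile()` additionally fits the spectrum above the region floor
with a two-negative-binomial mixture for a rough sanity report (coverages,
genome size, heterozygosity). The homozygous mean is constrained to twice
the heterozygous mean — the diploid expectation — because with free means
the faint heterozygous shoulder is barely identifiable under a strong
homozygous peak; component amplitudes are profiled out by weighted linear
least squares (weights `1/(y+1)`, the Poisson variance-stabilizing choice),
leaving a 3-parameter Nelder-Mead problem with a restart polish. Failures
set `fitOk = FALSE` rather than raising: the profile is advisory, not on
the calling path.

### Pairing, support and matching

Within the heterozygous region, `findCandidatePairs()` proposes a SNP for
every pair of k-mers for which *some orientation* of one differs from some
orientation of the other at exactly the middle position. Orientation
matters: the middle-base property is not invariant under canonicalization,
so both orientations of each canonical k-mer are examined and each pair is
recorded once, in the orientation with the lexicographically smallest
first member.

`supportLength()` measures how far a candidate's shared flanks extend: a
step left or right succeeds iff *exactly one* base keeps both shifted
allele k-mers inside the heterozygous set. If two bases extend (a branch,
typically a repeat or a chimeric join), the walk stops — extending through
a branch would fabricate contexts. Support is `1 + left + right` steps,
capped at `k`; full support `k` means both complete `2k-1` contexts are
represented in the heterozygous set.

One k-mer can appear in several candidates; final calls must use each
k-mer at most once. `maxWeightMatching()` finds the support-maximizing
matching: each connected component of the conflict graph is solved exactly
by branch-and-bound over its edges (components are nearly always a handful
of edges; igraph supplies the component decomposition), with a
deterministic greedy fallback above a configurable component size. Ties
between optimal matchings resolve toward lexicographically smaller code
pairs, so output is reproducible. Finally only calls with full support
(`support == k = 21`) are kept: this filter is what pushes precision above
90% at moderate coverage, at some cost in recall.

Since no reference exists, all calls are heterozygous by construction, and
only isolated substitutions — no indels, no clustered variants — are
callable: a SNP with a second variant inside its `2k-1` context never
reaches full support.

## The variant sketch

`buildSketch()` tiles each allele context with its k sliding windows and
keeps the canonical forms. Any canonical k-mer occurring more than once
anywhere in the sketch — within a site, across sites, across alleles, or
(automatically, through canonicality) as a reverse complement — is removed
from *all* positions, not merely deduplicated to one copy: a shared k-mer
cannot attribute its counts to a single (site, allele) slot, so keeping any
copy would corrupt counting. Sites left without at least one k-mer on each
allele are dropped. The sketch serializes as FASTA
(`>site{ID}|{allele}|{index}`, one k-mer per record) with a TSV sidecar of
per-site k-mer counts and the individual of origin; the file is
self-validating (duplicate or non-canonical k-mers are rejected on read).
Sketches from several individuals can be merged; the same remove-all rule
re-applies across individuals and site ids are remapped to stay unique.

Sketches below ~20,000 sites trigger a warning: with few sites, a shallow
query may fall under the 50-effective-site floor and become unscorable.

## Stage 2: counting and scoring

`countSample()` decomposes query reads into canonical k-mers and increments
the matching sketch slot on every hit (binary search over the sorted code
table). An optional expected-coverage bound stops the stream early once the
mean count per sketch k-mer reaches it, checked every 100,000 reads.

Per site and allele, the slot vector collapses to a scalar depth with the
*mode of the positive counts* (`siteAlleleCount()`), 0 if no slot was hit;
ties break toward the smaller value. The mode rather than the maximum
resists error-inflated outliers (counts 8, 9, 8, 7 give 8, not 9). Zeros
are excluded deliberately: a 150 bp read covers only part of a 41 bp
context's window set, so at sub-1x coverage most slots are legitimately
zero and a mode over all slots would be 0 even when the allele was clearly
observed — which would leave no usable sites in exactly the shallow-
coverage regime the likelihood score exists for.

### Relatedness score

Sites with `ref + alt ≥ 1` are genotyped by their `ref/(ref+alt)` ratio.
The het/hom cutoff is not fixed: `genotypeCutoff()` builds a 50-bin
histogram of the ratios and takes the bin center with minimal frequency in
[0.60, 0.90] — the valley between the heterozygous cluster at 0.5 and the
homozygous cluster at 1 — applied symmetrically (`ratio ≥ v` or
`≤ 1-v` ⇒ hom; a ratio exactly at the cutoff counts as homozygous). Ties
resolve toward 0.75, and fewer than 200 informative sites fall back to
0.75 with a warning. The relatedness score is

$$\mathrm{rel} = \frac{\mathrm{Het}}{\mathrm{Het} + \mathrm{Hom}}$$

over the query's labelled sites: 1 for the same individual, 0.5 for
parent–offspring or full siblings. Because the sketch holds no homozygous
sites, relationships beyond first degree are not resolvable, and the score
is only quantitative at substantial coverage (around 20x) where both
alleles of a heterozygous site are reliably sampled.

### Likelihood score

Identity at low coverage is decided by a mean log-likelihood-ratio
statistic over *effective sites* — sites with `ref + alt ≥ 2` (a single
stray k-mer hit is not evidence). Each effective site with query counts
`(r, a)` is compared against a pseudo-sample fixed at `(1, 1)`, the
idealized heterozygote. With binomial kernels `p^r (1-p)^a` (coefficients
cancel), per-sample MLEs `r/(r+a)` and `1/2`, and the pooled MLE
`(r+1)/(r+a+2)` under the identity hypothesis:

$$\lambda = -2\left[\log \mathcal{L}^{(*)} - \log \mathcal{L}^{(1)}
  - \log \mathcal{L}^{(2)}\right] \ge 0, \qquad
  \bar\lambda_{LR} = \frac{1}{N}\sum_{\text{effective}} \lambda$$

A balanced site `(r \approx a)` scores near 0; a homozygous-looking site
`(r, 0)` scores `-2[(r+1)\log\frac{r+1}{r+2} + \log\frac{1}{r+2}
+ 2\log 2]` (1.73 at `r = 2`, growing with depth). Fewer than 50 effective
sites ⇒ verdict `unreliable`; otherwise `same` iff
`\bar\lambda \le 0.63`, `different` above. This kernel is a deliberate
minimal instantiation: reference-based k-mer identity checkers use richer
multinomial likelihoods with empirically fitted bias terms, which are not
reproduced here; the direction of the bound (identical ⇒ low score) and
the bound itself remain caller-configurable (`threshold`,
`flipDirection`) so the rule can be recalibrated against the simulator.

### Operating point of the decision bound

The 0.63 bound should be read together with coverage. Under the count-level
protocol below, the identical-pair mean of $\bar\lambda$ falls with depth
while the first-degree mean rises, and the identical curve crosses 0.63
only around 3x:

```{r operating-point, eval = FALSE}
set.seed(1)
for (cov in c(0.5, 1, 2, 3, 4, 6, 30)) {
  s <- likelihoodScore(simulateSiteCounts(cov, "identical", 100000L))
  f <- likelihoodScore(simulateSiteCounts(cov, "first_degree", 100000L))
  cat(sprintf("%4.1fx identical %.2f first-degree %.2f\n",
              cov, s$lambdaBar, f$lambdaBar))
}
```

At 30x the two distributions are separated by orders of magnitude
(~0.07 vs ~3.1) and the bound sits comfortably between them; below ~3x
*both* arms score above 0.63 under this kernel and only the relative
comparison is meaningful. The end-to-end demonstrations in the test suite
therefore query at 4x; shallower runs still produce correct orderings but
the fixed bound is no longer calibrated for them.

## The simulators

Two generators back the validation, both deterministic under `set.seed`.

`simulateSiteCounts()` is the count-level protocol used to calibrate the
scores: 200,000 sketch sites, per-site depth `d ~ Poisson(coverage)`;
identical samples split `ref ~ Binomial(d, 0.5)`; first-degree relatives
split half the sites binomially and put the full depth on one random
allele at the other half (the relative is homozygous there, allele chosen
independently per site — no linkage). `runScoreStudy()` sweeps the
13-level coverage grid (0.1x–30x) for both relationships and records the
mean, 1st and 99th percentile of $\bar\lambda$ over (by default) 1,000
replicates.

`simulateDiploid()` + `simulateReads()` back the read-level tests: a
uniform random genome (optionally shared between individuals so "different
individual" means different genotypes on the same background, as in a real
cohort), heterozygous substitutions placed by a renewal process whose
geometric gap is solved so the realized density equals the requested rate
despite the `2k-1` minimum spacing that guarantees isolation; reads drawn
uniformly from both haplotypes and strands with i.i.d. substitution errors
and exact read count `round(coverage · L / readLen)`. Coverage is total
bases over the haploid length, so each haplotype receives half the nominal
depth — matching how sequencing depth is usually quoted.

What the generators deliberately do not model: repeats and homologous
families (the main source of false SNPs in real genomes), indels and
structural variation, homopolymer error bias, GC skew, linkage between
sites. Passing tests on this synthetic data therefore demonstrate the
correctness of the machinery and the calibration of the scores under the
stated model — not robustness to repeat-rich genomes, where every k-mer
method loses precision in homologous regions.

A note on read length: with 150 bp reads only `(150-21+1)/150 ≈ 87%` of
base coverage survives as k-mer coverage, and 0.2% errors remove another
`1-(1-0.002)^21 ≈ 4%`. At 4x nominal (2x per haplotype) the expected
spectrum is monotone decreasing after the error bin — there is no
heterozygous peak to find — so stage 1 legitimately refuses with "no peak
detected". From 6x upward the peak exists and calling proceeds. Long-read
low-error data does not pay the window penalty, which is why nominal 4x
suffices there.

## Problem sizes and runtime choices

The shipped tests run stage 1 on 150–300 kb genomes at 10x (seconds) and
the precision study on a 2 Mb genome at 4–10x; the score calibration uses
100 replicates of 200,000 sites at 30x. These sizes put every quantity's
Monte-Carlo error well inside the tolerances asserted while keeping the
whole suite around a minute of compute. `scripts/acceptance.R` re-derives
the headline numbers at the same sizes from a fresh seed.

## Known limitations

* Stage 1 requires low-error reads; there is no error model beyond the
  frequency floor, so high-error data produces no usable heterozygous
  region.
* Substitutions only; an indel shifts every overlapping k-mer and the site
  is simply never called.
* Diploid organisms only — the peak interpretation and the 2x mean
  constraint are diploid assumptions.
* `k` is odd and ≤ 25 in this implementation (packed codes as exact
  doubles).
* The likelihood kernel is deliberately minimal; its absolute scale below
  ~3x coverage is kernel-specific, and the 0.63 bound
  should be recalibrated (via `runScoreStudy()`) if the kernel or the
  aggregation rule is changed.
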