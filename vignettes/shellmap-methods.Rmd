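---
title: "Mapping the snail shell-polymorphism supergene with RAD-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the snail shell-polymorphism supergene with RAD-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellmap)
```

## The genetic system

The land snail *Cepaea nemoralis* carries a classic visible polymorphism:
shell ground colour (pink dominant over yellow) and the presence of dark
bands (absence dominant over presence). Both loci, written `C` and `B`
here, sit with at least three others in a tightly linked cluster — a
supergene — inherited as one Mendelian unit. shellmap implements the
analysis chain needed to put anonymous molecular markers around that
supergene using restriction site-associated DNA sequencing (RAD-seq) of a
single laboratory cross, plus the cross-level statistics that motivate the
search.

The mapping cross is a *pseudo-testcross*: a father heterozygous at both
loci with the dominant alleles in repulsion (`CP-Bb / Cy-BO`) mated to a
double homozygous recessive mother (`Cy-Bb / Cy-Bb`). Every offspring
phenotype then reveals which paternal haplotype it received: pink-banded
offspring carry `CP-Bb`, yellow-unbanded offspring carry `Cy-BO`, and the
two remaining classes (pink-unbanded, yellow-banded) each require a
crossover between `C` and `B`. A dominant RAD allele found only in the
father consequently has a fully predictable presence/absence pattern
across the panel if it is linked to the supergene — this is the entire
basis of the cosegregation search.

## Cross-level statistics

**Mendelian tests.** `chi2_segregation()` is Pearson's goodness-of-fit
statistic against an arbitrary expected ratio (1:1:1:1 for a two-locus
testcross under free recombination), with `df = classes - 1`. On the
pooled repulsion-cross counts (0, 156, 133, 0) it gives 292.7 on 3 df.
For the single coupling cross (18, 0, 0, 16) Pearson's statistic under
1:1:1:1 is 34.24; the original report prints 14.2 for this cross without
stating the expectation tested, and the two cannot be reconciled from the
printed counts. The package computes and reports Pearson's value; the
discrepancy is noted here rather than resolved.

**Upper bound on the supergene recombination fraction.** With zero
recombinants in $n$ informative offspring, the likelihood of the
recombination fraction $\theta$ is $(1-\theta)^n$. Under a flat prior
truncated to $[0, 0.5]$ (a recombination fraction cannot exceed 1/2 in a
backcross), the posterior $1-\alpha$ upper quantile has the closed form

$$u = 1 - \left[1 - \alpha^\* \right]^{1/(n+1)}, \qquad
  \alpha^\* = \mathrm{level} \cdot (1 - 0.5^{\,n+1}).$$

`recombination_upper_limit(323)` gives 0.92%. The original report prints
0.5% for the same data; that value follows from the same formula only if
each offspring is counted as two meioses ($n = 646$). Because only one
parent is doubly heterozygous, each offspring contributes a single
informative meiosis, so the function implements the stated formula and
reports `n` explicitly; neither printed value is asserted in the tests.
The $n = 0$ case returns the prior quantile (0.475 at the 95% level),
which is a useful sanity anchor.

**Chromosomal co-location probability.**
`supergene_cluster_probability(22, 8, 5)` answers: if eight loci were
placed independently and uniformly over 22 chromosomes, how often would
some chromosome receive five or more? It is computed exactly by dynamic
programming over the multinomial occupancy distribution (complement of
"all chromosomes below the threshold"), giving $2.1 \times 10^{-4}$ —
the smallness of which is the classical argument that the supergene's
linkage is not coincidental. When $2 k_{\min} > m$ the per-chromosome
events are disjoint and the DP provably equals the direct binomial sum;
the tests check both this identity and brute-force enumeration on small
cases.

## From reads to RAD loci

Read 1 of each pair is laid out as a 5-base inline barcode, the 6-base
`TGCAGG` remnant that SbfI digestion leaves on the fragment, and genomic
sequence; 101-base reads therefore yield 96-base tags after barcode
trimming. Design choices, in pipeline order:

* **Demultiplexing** (`demultiplex()`) is exact-match on the barcode and
  remnant by default. The upstream protocol only promises barcodes with
  pairwise distance $\ge 2$; exactness is the reproducible reading, and a
  1-mismatch rescue mode (unambiguous by construction) is available
  behind a flag.
* **Allele clustering** (`cluster_alleles()`) keeps distinct tags at read
  depth $\ge 2$ and joins alleles into a locus by single linkage at up to
  5 mismatches. Only positions where both alleles have base quality
  above 20 enter the comparison (per-position allele quality is the
  maximum over its reads); `N` never matches anything, regardless of
  quality. Single linkage is the most permissive reading of "up to five
  bases", and canonical output ordering (representative by depth, then
  sequence) makes clustering invariant to read order.
* **Fragment counts** (`estimate_fragment_counts()`). RAD libraries are
  heavily PCR-amplified (the emulated library runs at ~67% duplicates),
  so read counts overstate template molecules. Shearing is random, so
  distinct template fragments essentially always differ in their
  second-read sequence while PCR duplicates are identical: the fragment
  count is the number of distinct read-2 sequences per allele per
  individual. Exact sequence identity is used; alignment-based
  shear-point inference is impossible without a reference genome. Two
  fragments can collide on the same shear point (301 possible lengths),
  which biases fragment counts down by well under 1% at the coverages
  used here.
* **Cross-individual merging** (`merge_across_individuals()`) joins
  alleles across individuals by single linkage at up to 3 mismatches
  (allele-pair linkage; whether the upstream tool compared allele pairs
  or locus consensi is not documented). Loci seen in one individual are
  discarded, as are merged loci with more than four alleles — at most
  four alleles can segregate in a two-parent cross, so larger clusters
  are presumed collapsed repeats.
* **Yield prediction** (`expected_locus_count()`): an independent-base
  genome model with GC fraction $g$ assigns each motif base probability
  $g/2$ or $(1-g)/2$; the expectation is genome size x motif probability
  x two tags per site. For a 6.6 Gb (diploid) genome at 37% GC and the
  8-base SbfI motif this gives 52,508.

## The cosegregation search

Patterns are binary presence vectors over a fixed 24-individual panel:
father, mother, twelve pink-banded then ten yellow-unbanded offspring.
(The original marker table legend miscounts its own panel as "9x
yellow-unbanded"; every printed string has 24 characters, which fixes the
panel at 2 + 12 + 10.) A locus is a candidate (`find_candidates()`) when:

1. some allele matches the colour or banding in-phase expectation with at
   most 2 dropouts (expected-present, observed-absent) and at most 2
   putative recombinants (expected-absent, observed-present); and
2. every other allele fits an alternative-allele expectation: *shared by
   both parents* (expected in all 24; up to 5 dropouts) or *father-only
   complement* (expected in the father plus the opposite offspring
   class, i.e. at most 14 individuals; up to 2 dropouts, gains capped by
   the recombinant allowance).

The dropout and recombinant budgets are independent, not pooled. Entries
marked `x` in the packaged marker table (sequence-absent but later
PCR-confirmed) count as dropouts during the search, which is how the
search actually saw them. A mother-only alternative allele segregates
1:1 independently of the supergene, so it has no fixed binary
expectation; such loci are rejected rather than scored against an
unstable target — on the packaged panel this situation does not arise.
The two in-phase expectations differ at all 22 offspring, so no pattern
within the allowances can match both phases; a locus whose alternative
allele is the father's complement is, equivalently, in phase with the
other supergene locus, and the search reports the phase of the matching
in-phase allele.

Because Hamming clustering cannot join alleles separated by an indel or
by more than the clustering distance, a truly biallelic locus can surface
as two singletons. `rescue_split_loci()` re-compares accepted singleton
alleles against all alleles with an ends-free pairwise alignment
(match +1 / mismatch -1, gap open 5 / extend 2) and regroups pairs at
$\ge 90\%$ identity (matches over alignment columns) across at least 50
aligned columns — the overlap floor stands in for an alignment
significance filter, which the identity rule alone does not provide.

`infer_orientation()` places unassayed candidates relative to mapped
markers by the recombinant offspring they share: a candidate switching in
the same offspring as a mapped marker lies on the same side of the
supergene, switching in different offspring on the opposite side, and a
candidate with no informative switch is undetermined. An unexpected
absence is ambiguous with dropout, so orientation calls built on
unconfirmed losses should be treated as provisional — the workflow
expects recombinants to be PCR-validated first.

## Linkage mapping

`twopoint()` computes, over pairwise-complete offspring, the recombinant
count $R$, $\hat r = R/N$ and the LOD score
$R\log_{10}\hat r + (N-R)\log_{10}(1-\hat r) + N\log_{10}2$ (with
$0 \log 0 = 0$). Dominant markers anchored to opposite paternal
haplotypes give complementary calls, so `orient_genotypes()` flips
banding-anchored markers into a common orientation first — the phase
anchor is known a priori from the search, so no data-driven flipping is
needed. Groups form by single linkage at LOD $\ge 3$
(`form_groups()`).

`order_markers()` maximizes the multipoint log-likelihood, the sum of
adjacent-interval backcross likelihoods at their profile estimates
$\hat r$. Intervals are treated independently — for complete phase-known
backcross data this is the exact Markov likelihood, and interference
enters only through the Kosambi transform at map-building time; a full
multipoint EM over missing data is deliberately out of scope. Panels of
up to eight markers are ordered exhaustively. Larger panels use a
multi-start local search: one candidate order per anchor marker (the
rest sorted by Kosambi distance from it), each refined by segment
reversals, single-marker relocation and window permutations (window
$\le 3$) to convergence. Likelihood ties break toward fewer obligate
crossovers, then lexicographically, and the flips report lists all local
permutations within a stated log-likelihood margin of the optimum, which
is the practical measure of how well the data resolve the order.
Co-segregating markers are genuinely unorderable and appear as
zero-length intervals.

`build_map()` converts adjacent $\hat r$ to centimorgans with Kosambi's
function $d = 25\ln\frac{1+2r}{1-2r}$ and sums them; 1 recombinant in
102 offspring is 0.98 cM, and pooling with a second cross
(`pool_recombination()`, summed counts before the transform) turns
1/102 + 0/66 into 1/168 or 0.6 cM. The reference analysis obtained its
35.8 cM total from a multipoint fit, so small differences from the
summed-adjacent convention are expected; on simulated data the
summed-adjacent estimate is consistent with the generating 35.8 cM truth
(checked to 3 standard errors over 30 replicates).

## The synthetic-data generator

No raw sequencing data ships with the package; a seeded generator
reproduces the statistical structure the analysis assumes, with full
ground truth, at three levels:

* **Gametes** (`simulate_cross()`): one gamete per parent; crossovers on
  the doubly heterozygous parent's chromosome placed per adjacent map
  interval with probability given by the Kosambi inverse of the interval
  length, at most one per interval — adequate at the $\le 36$ cM scale
  modelled here and consistent with two-point estimation. The supergene
  is one non-recombining point carrying `C` and `B`.
* **Presence matrices** (`simulate_presence_matrix()`): each truly
  present allele draws a Poisson fragment depth and is observed at depth
  $\ge 2$; dropout therefore has closed-form rate
  $P(\mathrm{Pois}(\lambda) \le 1)$, which the tests verify empirically.
  Coverage is Poisson per allele (not per locus) because dropout acts on
  alleles in the search.
* **Reads** (`simulate_reads()`): in-silico SbfI digestion of a toy
  genome, two 96-base tags per site, uniform shear in [300, 600] bp
  determining read 2, `1 + Geometric` PCR copies per fragment (expected
  duplicate share equal to the configured rate), inline barcodes from a
  parity-check code with pairwise distance 2, constant high qualities by
  default and an optional per-base error rate. Variant alleles are
  planted as two fixed substitutions in a site's downstream tag and ride
  a designated haplotype: the dominant-colour or dominant-banding
  paternal haplotype, or a parent-specific unlinked background allele.

Defaults mirror the emulated study: mean fragment coverage 6.6 per
allele per individual, 66.7% PCR duplicates, depth-2 presence calls, a
2 + 12 + 10 panel, and a 13-locus map (eleven markers flanking the
supergene, three of them co-located 0.98 cM from it, C and B at zero
distance, 35.8 cM total). The exact inter-marker spacings of the
reference map are not published, so the generator fixes one realistic
set (0, 6, 11, 16, 20.92x3, 21.9, 21.9, 26.9, 30.9, 33.9, 35.8 cM) and
all simulation-based checks are run against it.

What the generator does **not** emulate: base-quality degradation
profiles, adapter read-through, chimeric PCR products, repeat-induced
collapsed loci, null alleles from restriction-site polymorphism, or
size-selection shape beyond uniform shear. Passing the end-to-end checks
therefore demonstrates that the pipeline's logic is correct under its own
model assumptions, not that real libraries are free of these artefacts —
on real data the excess-allele filter, the PCR validation step and the
orientation cross-checks carry that load.

## Problem sizes and numerical choices

The shipped checks use problem sizes chosen to exercise the statistics
meaningfully while keeping a full run lightweight: 20 seeded read-level
libraries (10 restriction sites, 5 planted linked loci, coverage 10) for
end-to-end recovery; 200 simulated 13-marker panels of 102 offspring for
order recovery, where success means the true order attains the
search's maximum likelihood (whole-map reversal, blocks of
sample-identical markers, and exact likelihood ties carry no ordering
information and are counted accordingly); $10^5$ random patterns against
the closed-form false-positive rate of the search; and $10^6$ draws for
the Monte-Carlo check of the co-location probability. Tolerances for
stochastic checks are three standard errors throughout. Likelihood
comparisons use an absolute tie tolerance of $10^{-9}$; degenerate
inputs (all-identical markers, empty pattern sets, crosses with no
doubly heterozygous parent) return flagged results or informative errors
rather than guesses.

## Known limitations

* The search's alternative-allele logic covers biallelic and
  father-centric multi-allelic configurations; loci whose extra alleles
  are mother-specific are conservatively rejected.
* Ordering above eight markers is a local search; it is multi-start and
  move-rich, but global optimality is not guaranteed in principle.
* The two printed-value discrepancies noted above (the coupling-cross
  chi-square and the 0.5% recombination bound) are surfaced, not
  resolved; the implementation follows the stated formulas.
* Only the colour and banding loci are modelled; the remaining supergene
  loci (band spreading, pigmentation, interruption) and epistatic
  modifiers are documented but outside the diplotype model.
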