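---
title: "Confidence-guided hierarchical assembly for read-based phasing"
author: "HierPhase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-guided hierarchical assembly for read-based phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(HierPhase))
```

## The problem

A diploid genome carries two haplotypes: for every heterozygous variant,
one allele sits on each chromosome copy. Short-read sequencing observes
fragments — read pairs — that may span two or more heterozygous sites,
and read-based phasing reconstructs which alleles co-occur on the same
copy from those co-observations. The dominant formulation is minimum
error correction (MEC): find the pair of complementary haplotypes that
requires the fewest allele corrections in the fragments. MEC is a global
objective; when noise is locally dense, corrections chosen to satisfy
the global optimum can drag well-supported regions into the wrong phase.

HierPhase implements the alternative this package is built around: a
*hierarchical assembly* that phases the most trustworthy variant pairs
first and extends outward, so that local noise is resolved locally and
cannot rewrite decisions already taken on clean data. A local MEC search
is retained as a fallback for exactly the situations in which the greedy
score ordering is known to be unreliable.

## Fragments and variant blocks

Only heterozygous bi-allelic SNPs are used; each fragment is reduced to
a sparse string over those sites with symbols `0` (reference allele),
`1` (alternative allele) and `-` (anything else: another base, a
deletion, a low-quality base, or no coverage). A fragment is
*informative* if it covers at least two sites. Two variants are
connected when an informative fragment covers both; connectivity is
transitive, and each connected component forms a *variant block*, the
independent unit of phasing. Variants never co-covered by any fragment
cannot be phased against each other, so singleton components are
reported as unphaseable.

Because both haplotypes of a block are complementary under the
heterozygous assumption (the variant caller's heterozygous calls are
trusted), a block's phasing is fully described by one 0/1 vector, and
every pair of variants admits exactly two candidate phasings: *cis*
(0–0 / 1–1) and *trans* (0–1 / 1–0).

## The confidence score

For a variant pair, every co-covering read falls into one of the four
allele combinations. Under a candidate solution, reads in the two cells
it designates as haplotypes are counted as $n_1$ and $n_2$, and the
remaining reads as unexpected observations $n_3$, with
$N = n_1 + n_2 + n_3$. With outcome likelihoods $P_1 = P_2 = 0.49$ for
the haplotypes and $P_3 = 0.02$ for errors, the multinomial score is

$$MS = \log_2\!\left[\binom{N}{n_1}\binom{N-n_1}{n_2}
P_1^{n_1} P_2^{n_2} P_3^{n_3}\right],$$

the log probability of the observed partition under a balanced diploid
sampling model. Because deeper pairs have systematically lower log
probabilities, a depth normalizer

$$F = \log_2\!\left[\binom{N}{N/2}\binom{N}{N/2}
P_1^{N/2} P_2^{N/2}\right]$$

is subtracted ($NS = MS - F$); both binomial coefficients are evaluated
through log-gamma so odd $N$ poses no difficulty. Finally the pair's
read depth relative to the deepest pair in its block,
$c = N / N_{\max}$, enters through a logistic weight
$s(c) = 1/(1+e^{-(c-0.5)})$, and the confidence score of the candidate
is

$$CS = \log_2 s(c) + NS.$$

The score of a *pair* is the better of its two candidates. CS ranges
from $-\infty$ to 0; values near zero mean the read counts look like a
clean, balanced, well-covered diploid pair. Two remarks on the exact
form used:

* A literal reading in which the sigmoid multiplies $NS$ *inside* the
  logarithm is undefined whenever $NS < 0$, which is almost always.
  The package multiplies the sigmoid with the underlying probability —
  equivalently adds $\log_2 s(c)$ to $NS$ — which preserves the
  intended monotone coverage adjustment and the stated range.
* $F$ as defined above is *not* the multinomial score of the perfectly
  balanced outcome (that would use $\binom{N}{N/2}\binom{N/2}{N/2}$),
  so $NS$ is not exactly zero at the balanced case. The normalizer is
  kept in this form deliberately; only differences of scores at equal
  $N$ ever matter to the assembly, and those are unaffected by the
  choice.

Default likelihoods ($0.49/0.49/0.02$) are exposed through
`scoringParams()`.

## Hierarchical assembly

Each block starts with one cluster per variant. Clusters are repeatedly
merged — $n-1$ merges for an $n$-variant block — and each merge is led
by the best directly observed variant pair between two clusters
(single-linkage over pair CS). Among equal scores the closer pair in
genomic distance leads, on the assumption that nearby variants are less
likely to be separated by mapping artefacts; remaining ties resolve by
leftmost position so runs are deterministic.

To join two phased clusters the four-cell table of the leading pair is
relabeled by the clusters' current haplotypes, and the CS of the two
possible joinings (keep or swap the second cluster's labels) decides
the orientation.

Two classes of *ambiguous* pairs get special treatment, because their
scores cannot be trusted:

* **singleton pairs** — all reads in a single cell, so only one
  haplotype was ever observed. Their CS is very poor (the model expects
  a balanced split), yet the single observed cell is usually *correct*;
  they are used only once no normal pair remains across any cluster
  boundary, and before low-coverage pairs.
* **low-coverage pairs** — fewer reads than the block's median pair
  depth (computed once per block). Used last.

## The local MEC fallback

When the sites of two clusters interleave, the merge decides many
adjacent-variant relations at once. A *junction* is a boundary between
position-adjacent variants from different clusters; a merge with
`minJunctions` (default 3) or more junctions is decided not by the CS
but by a two-candidate MEC vote: every fragment spanning a junction is
recruited, each candidate's penalty is the number of corrections needed
to make the recruited fragments consistent with it, and the lower
penalty wins. The same vote (with all fragments of the merged region
recruited) fires when an ambiguous pair leads a merge with at least two
junctions, and on exact CS ties. Penalty ties keep the first candidate
and flag the merge low-confidence in the merge log. Note that a
fragment can only discriminate the two candidates if it covers sites of
both clusters, and any such fragment necessarily spans a junction, so
the two recruitment scopes always elect the same candidate; both are
kept for the audit trail.

The voting search is exhaustive over its two candidates, so it is exact
and cheap; a genuinely exhaustive MEC solver over all $2^{n-1}$
assignments (`bruteForceMEC`) ships as an independent oracle for
testing and analysis, refusing blocks beyond 16 variants.

The two objectives can legitimately disagree. In the packaged
three-variant, 50-read instance (`divergenceBlock()` in the test
helpers), three concentrated read types pile 12 reads each into one
cell of every pair while two read types split 7/7 across the
complementary cells. Global MEC prefers the concentrated solution (14
corrections, unique optimum); the assembly trusts the balanced 1:1
split, as a diploid sampling model should, and outputs the other
phasing. Which is right depends on whether the concentration reflects
biology or mapping bias; the package reproduces the disagreement
deterministically rather than hiding it.

## Evaluation metrics

Comparison against a truth phasing anchors at the first commonly phased
site of a block (complement invariance makes the anchor arbitrary) and
tracks agreement along the block. Each boundary where agreement
toggles is a raw switch; two adjacent toggles flank one isolated
mis-phased site and collapse into a single *flip* error, while the rest
are *switch* errors. Runs of more than two adjacent toggles are
resolved as the minimum-cost pairing, pairing left to right; the
leftover unpaired boundary is classified as the switch. The metric
suite is:

* **phasing error rate** — pooled $(\text{flips} + \text{switches}) /
  \text{phased variants}$, where each block needs one decision per
  variant except its leftmost;
* **perfect ratio** — fraction of blocks with zero errors;
* **QAN50** — blocks are split at switch errors (flips, being single
  isolated sites, do not break a stretch), each sub-block contributes
  its first-to-last-phased genomic span weighted by its phased-variant
  proportion, and QAN50 is the N50 of these adjusted spans (largest
  span at which the descending cumulative sum reaches half the total);
* **EC rate** — corrected characters over total informative fragment
  characters, the quantity MEC methods minimize, reported for
  cross-method comparison.

Sites phased by only one side of the comparison are excluded and count
as unphased in QAN50's proportions.

## The fragment simulator

`simulateTruth()` places variant positions uniformly over a span and
draws haplotype 1 uniformly; `simulateFragments()` emulates paired-end
sequencing directly at the variant sites: insert length
$\mathcal{N}(850, 50^2)$, two 250 bp reads per fragment, uniform
starts, originating haplotype drawn with probability `skew` (0.5 =
balanced, 0.1 = extreme 10/90 imbalance), and every covered site
corrupted with probability `seqError` — by default to the *opposite*
allele, the worst case for phasing; a `"missing"` mode writes gaps
instead. Fragments covering fewer than two sites are discarded. The
default density is 82 bp per variant, and the benchmark grid
(coverages 20/30/40, error rates 0.002/0.01/0.03, skews 50/50 to
10/90, block sizes 30–500; `scenarioGrid()` enumerates the 45
conditions) mirrors a realistic short-read WGS design.

What the simulator deliberately omits is mapping: fragments are never
misplaced, so there is no alignment error, no reference bias and no
mismapped-read contamination. Consequently absolute error rates are
much lower than what the same method achieves on aligned reads, and
the package's tests assert *trends* — error rates non-decreasing in
the sequencing error rate, and an order-of-magnitude degradation under
extreme 10/90 skew — not absolute values. Passing them shows the
algorithm behaves correctly as a function of its inputs, not that real
data would yield these rates.

## Numerical and design choices

* All pair scoring runs in log space via log-gamma; nothing overflows
  at any realistic depth. $0 \log 0 = 0$ by convention; a zero
  likelihood with a positive count scores $-\infty$.
* The block maximum depth $N_{\max}$ and the median low-coverage
  threshold are fixed at block initialization and not updated during
  assembly, so scores are comparable across the whole merge sequence.
* Mates of a read pair are merged into one fragment; when they
  disagree at a shared site the site is gapped as unreliable.
* Default extraction filters are `minMapq = 0`, `minBaseq = 0` — all
  reads participate, so block discovery sees the full connectivity of
  the data; both are configurable for stricter pipelines.
* Returned haplotypes are canonicalized to start with allele 0, making
  runs byte-comparable; all metrics are invariant under global
  complement anyway.
* Phased VCF output encodes each block through `0|1`/`1|0` genotypes
  plus a `PS` tag holding the position of the block's first variant.
* Positions in the plain fragment format are 1-based site indices per
  chromosome; genomic coordinates stay 1-based as in VCF.

## Scale of the packaged benchmarks

The test suite and the acceptance script phase, per run: 50–100
noise-free blocks of 10–200 variants; 200 error-free blocks of up to
12 variants checked against the exhaustive MEC oracle; 500 randomized
merge instances checked against two-candidate penalty minimization;
and, for the condition trends at coverage 30, blocks of sizes
30/50/100 (2 per size per replicate): 25 replicates per error rate for
the monotonicity comparison, and 500 replicates — paired seeds across
the two conditions — for the 50/50 versus 10/90 skew contrast. The
heavy replication of the skew contrast is necessary because both error
rates are tiny fractions of a percent under site-level noise, of the
order of $10^{-4}$ skewed and $10^{-5}$ balanced, so roughly 175,000
phasing decisions per condition are needed before the contrast is
resolvable above Poisson noise. These sizes keep a full run within
minutes on one CPU while preserving the qualitative structure of the
full 45-condition benchmark design.

One finding of these benchmarks deserves emphasis. Under site-level
corruption alone, the dominant residual error mode at balanced
sampling is the *weak bridge*: a pair of adjacent cluster regions
connected by only one or two fragments, where a single corrupted
bridging read switches the entire downstream segment. This floor —
around $7\times10^{-5}$ per decision at coverage 30 and error rate
0.03 — affects the skewed condition equally, because it depends on the
variant layout rather than on which haplotype was sampled. Extreme
10/90 skew roughly doubles to quadruples the error rate on top of
that floor (a paired comparison over 500 replicates gives about 28
versus 12 errors on identical layouts). On aligned reads, where
mis-mapped fragments systematically contaminate allele-combination
cells, the same skew degrades phasing by well over an order of
magnitude; the fragment-level simulator reproduces the direction of
the effect but, by design, not its magnitude.

## Limitations

* Diploid only; multi-allelic sites, indels and polyploid genomes are
  out of scope, as is variant calling itself.
* The score is count-based; base qualities do not weight the
  likelihoods (they only gate symbols at extraction).
* The local MEC vote is exact for its two candidates but the assembly
  as a whole remains a heuristic: no global optimality claim is made,
  and on adversarial inputs it knowingly deviates from the global MEC
  optimum (see the divergence instance above).
* The simulator's omission of mapping noise means absolute simulated
  error rates understate real-data error rates by orders of magnitude.
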