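---
title: "Sequence-context mutation rate models by IUPAC pattern partition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-context mutation rate models by IUPAC pattern partition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutpatterns)
library(dplyr)
```

## The problem

The germline mutation rate of a genomic site depends strongly on its local
sequence context: the CpG effect on C→T transitions is the textbook case, but
wider contexts (up to nine or more bases) carry real signal for every
substitution type and for indels. Estimating a separate rate for every k-mer
works only for small k — with 7-mers or 9-mers most contexts hold too few
observed de novo mutations, and the per-k-mer estimates drown in sampling
noise.

`mutpatterns` addresses this by *pattern partitioning*: the set of all k-mers
is partitioned by IUPAC ambiguity patterns so that every k-mer is matched by
exactly one pattern, and all k-mers matched by a pattern share one rate. The
partition is chosen to minimize a penalized binomial deviance, so contexts
with genuinely similar rates are pooled and contexts that differ get their
own patterns. The fitted object is directly interpretable: a short list of
patterns ordered by rate.

## The model

For one mutation class (say C→T after strand collapsing), each genomic
opportunity is a Bernoulli trial. Given per-k-mer counts of mutated ($m_j$)
and unmutated ($u_j$) sites, a candidate partition $\{p_1, \dots, p_n\}$ has
loss

$$\mathrm{loss} = \sum_{i=1}^{n}\Big(-2\big(M_i \log r_i + U_i \log(1-r_i)\big) + c\Big),$$

where $M_i, U_i$ sum $m_j, u_j$ over the k-mers matching pattern $i$, $c$ is
a per-pattern complexity penalty, and the pattern rate is regularized toward
the class mean rate $\mu = \sum m_j / \sum (m_j + u_j)$ by a pseudo count
$\alpha$:

$$r_i = \frac{M_i + \alpha}{M_i + U_i + \alpha/\mu}.$$

Natural logarithms are used; at $c = 2$ and $\alpha = 0$ the loss of a
partition is exactly the AIC of the corresponding binomial model, which the
test suite verifies against an independent `dbinom()` computation.

### Finding the optimal partition

Every reachable partition can be produced by recursively splitting the
all-N pattern, one position at a time, into the *two-partitions* of that
position's IUPAC code (the disjoint covering code pairs; `two_partitions()`
lists them). The minimal loss obeys

$$f(p) = \min\Big(\mathrm{loss}(\{p\}),\; \min_{i,\,(x,y)} f(p[i{\to}x]) + f(p[i{\to}y])\Big),$$

which `optimal_partition()` evaluates bottom-up over all $15^k$ patterns,
ordered by coarseness (product of per-position set sizes), so each pattern is
solved exactly once. Memory and time are exponential in k; the implementation
guards the pattern-space size and the practical exact range on one core is
k ≤ 5. `greedy_partition()` implements the polynomial heuristic — take the
single most promising split of the current pattern and recurse into the two
children — which is never better than the exact optimum (a property the
tests check on 100 random instances) but runs for much larger k.

Ties prefer not splitting, then the first split in the fixed two-partition
order, so results are deterministic. For strand-collapsed SNV tables the
central pattern position ranges over the codes A, C and M only. Tables with
degenerate mean rate (0 or 1) are refused rather than patched.

### Hyperparameters

$\alpha$ and $c$ are chosen by repeated 2-fold cross-validation
(`grid_search()`): the count table is split by multivariate hypergeometric
sampling — fold 1 receives exactly half the mutated and half the background
counts, drawn without replacement across k-mers — a partition is trained on
each fold and scored by the held-out negative log-likelihood under the
trained pattern rates, and the grid pair with the lowest mean over
2 × 5 evaluations wins. Ties prefer the larger $c$, then the larger $\alpha$
(stronger regularization at equal fit). Fold draws derive only from the
configuration seed and are shared across grid points, so grid points are
compared on identical folds and the result is independent of evaluation
order. The default grids ($\alpha \in \{0.1, 0.5, 1, 2, 5, 10, 20\}$,
$c \in \{0.5, 1, 2, 5, 10, 20, 50, 100\}$) are this package's own choice and
are fully configurable.

Model fit on held-out counts is reported as Nagelkerke's pseudo
$r^2 = (1 - e^{2(\ell_0-\ell_M)/n})/(1 - e^{2\ell_0/n})$, with the null
log-likelihood $\ell_0$ taken by default from the test table's own mean
rate, so $r^2 = 0$ means "no better than a constant fitted to the test
data" (a flag switches to the training-set mean). A joint $r^2$ across
classes pools $\ell_M$, $\ell_0$ and $n$ before applying the formula.

## Counting k-mers

`count_snv_kmers()` builds the six substitution tables. Every masked,
N-free position whose full window fits on the chromosome contributes one
background opportunity to each of the three tables sharing its central
base; central G/T sites are reverse-complemented (k-mer and alleles) first,
so all tables are keyed by central A/C. An observed SNV adds one mutated
count to exactly one table and removes that site from the same table's
background (once per site, so recurrent records cannot push $m > m+u$).
Flanks of a masked site may extend outside the mask; a site is counted iff
the site itself is masked.

Indels (`count_indel_kmers()`) need two extra ideas. First, an indel's
position is often ambiguous — several breakpoints can explain the same
alternative sequence (any insertion point inside a homopolymer, for
example). `enumerate_indel_placements()` returns all of them, including
placements whose inserted content is a rotation of the reported one, and
one placement is chosen uniformly at random per event. The choice is
derived from the seed and the record's own coordinates, so counting is
reproducible and invariant to record order. Second, both the breakpoint
k-mer and its reverse complement are counted: insertions use the inter-base
context (k/2 bases each side, k even), deletions use the odd k-mers
centered on the first and the last deleted base, whose reverse complements
are each other's start/end contexts — so a single DEL table covers both
orientations and all tables are reverse-complement symmetric by
construction. Length-stratified tables (multiples of 3 versus not) feed the
in-frame/frameshift split downstream.

## From rates to genes

The gene-level engine converts fitted models into expected counts of eight
functional classes per transcript: synonymous, missense, nonsense, start
disruption, stop disruption, canonical splice disruption (the 2 intronic
bases each side of internal exon boundaries — the essential-splice
definition), in-frame indel and frameshift indel. `transcript_site_table()`
enumerates all three alternative bases at every CDS and splice position,
classifies each by translating the mutated codon (category precedence:
start > stop > splice > nonsense > missense > synonymous), and attaches the
pattern rate of its strand-collapsed context.

Three calibration steps make the rates comparable across datasets:

* **Cohort-to-generation scaling.** Trained rates reflect the mutation
  yield of the training cohort. `scale_snv_models()` multiplies all six
  models by one factor so the count-weighted mean per-site rate over the
  masked genome is 1.28 × 10⁻⁸ per base per generation;
  `scale_indel_models()` targets 0.68 × 10⁻⁹ the same way. Both identities
  are exact by construction and asserted to a relative 10⁻¹⁰ in the tests.
* **Generation scaling.** A per-generation rate r becomes the probability
  $1 - (1-r)^{2 n_\mathrm{gen}}$ of at least one event across the observed
  transmissions, which stays below 1 for arbitrarily large cohorts. When
  $n_\mathrm{gen}$ is unknown (segregating variants), `calibrate_ngen()`
  solves for it from the observed exome-wide synonymous count — the
  expectation is strictly increasing in $n_\mathrm{gen}$, so a monotone
  root search converges to relative tolerance 10⁻⁶.
* **Coverage correction.** `coverage_correction()` regresses the
  per-transcript synonymous observed/expected ratio on mean allele number
  (lowess, default span 0.05), drops transcripts with mean AN ≤ 50,000, and
  divides each transcript's expectations by its fitted value.

Because every possible mutation has its own probability, the null count of
a category in a transcript is Poisson-binomial. `burden_pvalue()` samples
it (exactly: per-site Binomial success counts scattered uniformly over
samples) and reports the add-one-corrected upper tail
$(1 + \#\{X \ge \mathrm{obs}\})/(1 + N)$, which never returns zero, plus
the empirical 5th–95th percentile interval of the sampled counts. For
calibration studies the `randomize` option returns
$P(X > \mathrm{obs}) + U \cdot P(X = \mathrm{obs})$ instead, which is
exactly uniform under the null — the default tail p-value is conservative
for discrete counts, so uniformity must be checked on the randomized
version (the test suite does this across 500 simulated null genes).

Constraint is summarized per gene by the LoF observed/expected ratio
(LoF = nonsense + essential splice + frameshift) with a 0.5 pseudo score on
both counts, and by a conservative variant dividing the observed count by
the lower bound of the 90% interval of the expected count.

Indel opportunities are enumerated per breakpoint: every inter-base
position inside the CDS is one insertion opportunity and every CDS base one
deletion opportunity, scored by the length-stratified models (3n → in-frame,
non-3n → frameshift). The length profile of individual events is not
modeled — the per-breakpoint context rate is the unit of the indel model —
which is this package's own reading of an enumeration the underlying method
leaves open.

## The synthetic test bed

`simulate_genome()`, `simulate_mutations()` and `simulate_transcriptome()`
generate the study conditions every test runs under: an i.i.d. genome
(default GC fraction 0.41, human-like), mutations drawn site-by-site from a
known pattern partition (at most one event per site, matching the counting
model's contract), and non-overlapping multi-exon transcripts with valid
ORFs and GT–AG introns embedded on both strands. All randomness flows from
one master seed through named substreams, so each fixture is individually
reproducible.

The default SNV truth is a four-pattern C→T partition with a strong CpG
effect (NCG 0.02, TCH 0.008, VCT 0.004, VCM 0.001 per cohort); the indel
truth uses a flat insertion rate and an A/T-elevated deletion rate, both
reverse-complement symmetric. The parameter-recovery study (count →
cross-validate → exact fit on a 1 Mb genome) requires every fitted per-k-mer
rate to fall inside the 99% binomial envelope of its truth value; it runs at
1 Mb with a 3 × 3 hyperparameter grid and 5 repeats, sizes chosen to make
the envelope test sharp while the whole suite stays interactive.

What the generator does *not* emulate: regional rate variation (replication
timing, chromatin), clustered mutations, C→G enriched regions, sequencing
error, or genotype-level data. Passing tests therefore demonstrate
correctness of the estimator and its calibration under the stated model,
not robustness to those real-data complications — on real data the mask and
exclusion-region machinery (`read_mask()`, `subtract_mask()`) exists
precisely because those complications matter.

## Numerical choices and limitations

* $0 \log 0 = 0$ throughout; empty patterns cost exactly $c$ and get rate
  $\mu$.
* Losses are compared with strict `<`, so equal-loss splits resolve to the
  coarser (unsplit) pattern deterministically.
* Pattern sums for all $15^k$ patterns are computed by one 4→15 axis
  transform per position, not by per-pattern matching.
* Held-out likelihoods return $-\infty$ (flagged) when a trained rate of 0
  or 1 meets opposing counts; CV grid points that fail to train are
  excluded with a warning rather than patched.
* The exact optimizer is exponential in k (15ᵏ states); use the greedy
  search beyond k ≈ 5 on one core. Indels longer than 50 bp are skipped
  with a warning. Multi-nucleotide substitutions and complex indels are out
  of scope.
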