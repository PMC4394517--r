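---
title: "Inferring minimum MHC class II B locus numbers from cloned alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring minimum MHC class II B locus numbers from cloned alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcloci)
```

## The problem

Teleost *MHC* class II *B* genes are multi-copy and highly polymorphic, and
most sequencing surveys observe *alleles* (distinct clone-validated
sequences) without knowing which *locus* each allele belongs to. Loci are
not directly observable: a PCR on genomic DNA amplifies every paralog the
primers match. What a diploid genome does guarantee is an arithmetic
constraint -- an individual carries at most two alleles of any one locus --
and that constraint is enough to put a lower bound on the locus number and
to forbid allele groupings that would require three or more alleles of one
individual at a single locus. `mhcloci` packages that inference chain:

1. **Clone-support validation.** A sequence is accepted as a real allele
   only when it occurs, identically, in at least `min_support = 3`
   independent clones of one individual. This is the standard filter
   against PCR and sequencing artifacts; raising the threshold can only
   shrink the allele set (a tested monotonicity property). The threshold
   reconciles the two phrasings that usually accompany this rule ("more
   than two clones" for acceptance; "one or two clones" excluded) into
   the single integer that satisfies both. Support is counted per
   individual, because a sequencing artifact cannot recur identically in
   another fish, whereas a real shared allele can; an allele is retained
   if any individual reaches the threshold, and every individual
   contributing a clone of it is listed as a carrier.
2. **Exon/intron annotation.** Each genomic allele is annotated by spliced
   alignment of a cDNA against it, with introns allowed only between a
   `GT` donor and an `AG` acceptor. Among all consistent exon chains the
   annotator prefers the fewest introns, then the leftmost intron starts;
   both choices are deterministic tie-breaks, not heuristics, because at
   single-gene scale (a few kb) the search is exhaustive.
3. **Polymorphism and selection.** Validated cDNA alleles are aligned,
   polymorphic sites counted per region, and the Nei-Gojobori (1986)
   codon test applied separately to the peptide-binding region (PBR,
   operationally the exons 2-3 portion of the ORF) and the remainder.
   Elevated nonsynonymous substitution in the PBR is the classic
   signature of diversifying selection on peptide-binding residues.
4. **Diploid-constrained grouping.** Alleles are clustered by sequence
   distance under the hard rule that no group may hold more than two
   alleles of one individual; the number of groups spanned by the most
   allele-rich individual, floored by the arithmetic bound
   ceiling(max allele count / 2), is the **minimum** locus estimate.
5. **Intron repeat profiling.** Tandem repeats (a GT microsatellite, a
   decamer, a 16-mer in the motivating system) explain most of the
   between-locus intron length differences, making intron length a cheap
   locus-diagnostic marker; the package tabulates lengths and dominant
   repeat units per inferred group.

Every stage is exercised against a ground-truthed simulator
(`simulate_dataset()`), so the whole chain is testable without any
downloads.

## The codon test

For a sense codon, each of the three positions contributes a synonymous
site fraction: the number of synonymous single-base changes divided by the
number of changes considered at that position. Changes that would create a
stop codon are excluded from the denominator by default (`stops =
"exclude"`, matching the convention of the widely used MEGA
implementation; `stops = "nonsyn"` counts them as nonsynonymous instead).
Summing fractions gives s per codon, with n = 3 - s. Between two codons
that differ at k positions, all k! substitution orderings are enumerated,
orderings that pass through a stop codon are discarded, and synonymous /
nonsynonymous step counts are averaged over the remaining pathways (all
pathways, if every one passes through a stop -- a rare degenerate case).
Proportions pS = Sd/S and pN = Nd/N (sites averaged between the two
sequences, codons containing gaps or N dropped pairwise) are corrected for
multiple hits with the Jukes-Cantor transform d = -(3/4) ln(1 - (4/3) p),
which is undefined at p >= 3/4 and reported as `NA` with the raw
proportion retained.

`selection_test()` averages dN and dS over all sequence pairs in a region
and tests H1: dN > dS one-tailed -- one-tailed because the scientific
hypothesis is positive selection -- with Z = (dN - dS)/SE. The SE comes
from a bootstrap over codon columns (default 1000 replicates, seeded;
runs are reproducible bit-for-bit given inputs, replicate count and
seed). An analytic alternative (`variance = "analytic"`) sums binomial
variances of the two distances and ignores their covariance; the
bootstrap is the default because it needs no independence assumption
across sites within a codon. When the sequences are identical in the
region the test is reported as not applicable rather than as p = 1.

Calibration: under the package's neutral generator
(`simulate_neutral_codons()`, equal rates at all sites, stop-creating
substitutions rejected) the test rejects at p < 0.05 in about 5% of 200
replicates of 20 sequences x 200 codons -- the acceptance suite pins this
to the interval [0.02, 0.08].

## The grouping algorithm

Distances are p-distances (mismatched columns / compared columns, gap
columns excluded) between whole sequences, or between annotated exon
concatenations when whole-length and partial genomic alleles are mixed --
introns vary so strongly in length that including them would reward or
punish alleles for repeat copy number rather than descent.

Grouping is agglomerative with average linkage. A merge is *forbidden*
(not post-hoc corrected) whenever the merged group would contain more
than two alleles of any individual, and merging continues while any legal
merge exists; ties in linkage distance are broken by the
lexicographically smallest pair of group labels, so output is
deterministic. For small allele sets (`exhaustive_limit = 10` or fewer)
the greedy agglomeration is replaced by an exhaustive search over all
diploid-legal set partitions, taking the partition with the fewest groups
and, among those, the smallest total within-group mean distance. The
design was genuinely open here: greedy merging can stall above the true
minimum on adversarial carrier patterns (three groups pairwise blocked by
three different individuals, say, where a different merge order reaches
two), and at small n the exact search costs nothing -- Bell(10) is about
116,000 partitions, pruned further by the constraint. At study scale
(tens of alleles) the greedy path is used and the constraint structure of
real data keeps it at the minimum in practice.

Two post-processing rules mirror how such data are read in practice:

* **Outliers.** A singleton group whose nearest neighbor is farther than
  the 0.90 quantile of all pairwise distances is moved to `unassigned`:
  an allele without any close relative supports no locus assignment. The
  quantile is configurable; note that with few alleles the top decile of
  pairwise distances is dominated by any true outlier's own distances,
  so the rule is conservative at small n.
* **The estimate is a floor.** Two tight clusters can always be two
  closely related loci that no clustering can separate, so the report
  labels the result a *minimum* estimate:
  `max(groups spanned by the most allele-rich individual, diploid bound)`.

## The simulator and what it does (not) emulate

`sim_config()` defaults encode the motivating study's conditions: a
6-exon/5-intron gene whose cDNA is a 25-nt 5'UTR + 747-nt ORF + 22-nt
3'UTR (exon lengths 79/270/282/90/33/40 nt), four loci in eight diploid
individuals, 8-20 clones sequenced per template, and 0.1% per-base clone
error. Loci diverge from a shared root at 5% of ORF sites; alleles within
a locus at 0.5%. Mutations are placed codon-aware: candidate positions
inside the PBR are drawn with weight `pbr_multiplier = 5`, and
synonymous PBR candidates are accepted with probability 1/multiplier --
giving the generator a controllable dN/dS ground truth. The same
pressure applies to between-locus (founder) divergence as to
within-locus divergence, since the paralogs of this family diversified
under the same peptide-binding selection; this is what makes the pooled
allele set, which always mixes loci, show the PBR-restricted dN > dS
signature. Intron 2 carries a GT microsatellite (8-25 copies per
locus), intron 3 the GTCCAGTTGA decamer (2-18 copies), intron 4 the
ACCTGTCTGTCTGCTC 16-mer (1-6 copies); intron length differences between
loci are therefore exactly unit length x copy-number difference, a tested
arithmetic identity. Each individual misses a locus with probability 0.1,
reflecting that no allele group was shared by all individuals in the
motivating data. Copy-number ranges are scaled to keep genomic alleles
near 1.5 kb; the real intron 3 spans a wider range (136-770 bp), which
changes nothing in the algorithms, only run time.

Deliberate simplifications: clone errors are substitutions only (indel
errors would defeat exact-identity collapsing and are off by default);
allele genealogies are star-like rather than coalescent; there is no
recombination or gene conversion; and splice sites are always canonical.
Passing tests on this generator therefore show that the pipeline recovers
structure *of the kind assumed*, not that real data meet those
assumptions -- in particular, chimeric PCR products and shared ancestral
polymorphism between paralogs would blur real locus groups in ways the
simulator does not model.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; all user-facing notation
  (GFF3, `242A>G`, `E74G`) is 1-based biological numbering counted from
  the ORF start / initiator Met. Both conventions for the deposited
  substitution labels were checked; ORF-start numbering is the one that
  reproduces them.
* `find_orf()` returns the longest ATG-initiated, stop-terminated frame,
  ties to the smallest start; "no ORF" is an explicit result, not an
  error. ORF lengths include the stop codon, so a 747-nt ORF encodes 248
  residues.
* `spliced_align()` demands an exact splice by default
  (`max_mismatch_per_exon = 0`): cDNA and genomic sequence of the *same*
  allele should agree exactly. A per-exon mismatch budget supports
  cross-allele annotation (used for annotating whole-length alleles with
  a congener's cDNA); the post-intron re-anchoring stays exact either
  way. `min_exon = 20` nt guards against spurious micro-exons.
* The alignment scoring constants (+1 match, -1 mismatch, -5 gap open,
  -1 gap extend) are exposed but irrelevant for near-identical allele
  sets, where any sane scheme yields the same alignment; the pairwise
  engine is `Biostrings::pairwiseAlignment()`, merged star-wise against
  the first input sequence.
* The PBR interval is clipped to the ORF and expanded outward to whole
  codons (start rounded down, end rounded up), because the codon test
  consumes whole codons; the terminal stop codon is excluded from every
  region.
* Tandem repeats are detected by period autocorrelation (a base matching
  the base u positions earlier), with tracts extended across
  interruptions while purity stays >= 0.85, the unit read off the purest
  stretch and reported in its lexicographically smallest rotation, and
  overlapping calls resolved by purity x span, ties to the shorter unit.
  Homopolymer tracts are gated at 6 bases regardless of the nominal
  period. This deliberately replaces alignment-scored repeat finding;
  the repeats that matter here are short and near-perfect.

## Problem sizes used in the checks

The acceptance suite and `scripts/acceptance.R` run: 50 full
simulate-validate-annotate-group pipelines at study scale (the composite
runs use 100 bootstrap replicates for the per-region Z-test; the
single-run selection analyses use the default 1000); 200 neutral
calibration replicates (20 x 200 codons, 1000 bootstrap replicates
each); 200 randomized grouping checks of the diploid invariant; 150
brute-force minimality comparisons at <= 6 alleles; and 100 splicing
round trips. These sizes keep the full check under a few minutes on one
CPU while leaving the statistical assertions (e.g. the [0.02, 0.08]
type-I band) comfortably powered.

## Known limitations

* The locus estimate is a lower bound by construction; closely related
  loci sharing recent ancestry are indistinguishable from alleles of one
  locus without segregation data.
* Exact-identity collapsing discards low-frequency true alleles whose
  clones happen to carry errors; with 0.1%/base error and kb-scale
  templates a few percent of borderline alleles are lost (visible in the
  simulator scorecards), the same compromise the clone-support rule
  makes on real data.
* Only forward-strand, canonical GT-AG genes are annotated; reverse
  orientation must be fixed upstream.
* Bayesian tree estimation is intentionally out of scope: the package
  computes neighbor-joining trees for visualisation and exports a NEXUS
  file with a GTR+gamma MrBayes block so the tree-based picture can be
  reproduced externally. The grouping itself never depends on the tree,
  only on the distance matrix and the diploid constraint.
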