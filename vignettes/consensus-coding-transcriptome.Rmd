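---
title: "Building consensus coding transcriptomes from multiple de novo assemblies"
author: "transcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building consensus coding transcriptomes from multiple de novo assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcat)
```

## The model

Short-read de novo assemblers disagree: applied to the same RNA-Seq
library, CLC-style, IDBA-style and Trinity-style assemblers produce
transcript sets that differ in number, length distribution and content,
and each contains bioinformatic artifacts.  `transcat` treats the
assemblers as independent noisy observers of the same underlying coding
transcriptome and extracts a consensus in two clustering passes:

* **Pass 1 (within assembler).**  Strictly redundant transcripts —
  exact duplicates and exact substrings, on either strand — are
  removed.  In identity/coverage terms this is local identity
  $c = 1.00$ with aligned fraction of the shorter sequence
  $aS = 1.00$; the aligned fraction of the longer sequence is only
  bounded below by $aL = 0.005$, which admits length ratios up to
  200x so that a short transcript can still be judged against a very
  long one.
* **Pass 2 (between assemblers).**  After pooling, open reading frames
  of at least 100 amino acids are extracted and the coding sequences
  are clustered at $c = 0.98$ — one percentage point more permissive
  than pass 1 to absorb typical Illumina error — again with
  $aS = 1.00$ and $aL = 0.005$ by default.  Each cluster is
  represented by its longest CDS (a *uniCDS*); the transcripts owning
  representative CDSs, with their UTRs intact, are the final
  transcriptome.

The cluster membership table is the analysis object: which assemblers
contributed members (the 7 provenance categories), and how much longer
the representative is than each assembler's own best CDS (the
*extension* an assembler alone would have missed).

### Alignment semantics

One fixed-parameter Smith–Waterman kernel (match $+2$, mismatch $-3$,
gap open $-5$, gap extend $-2$; affine gaps, so a gap of length $L$
costs $5 + 2L$) backs every decision.  Identity is identical columns
divided by alignment columns, gap columns included — the documented
local-identity convention of the clustering tools this package
re-implements.  `N` never matches anything, including another `N`:
ambiguous bases cannot create redundancy calls.  Both strands are
considered in pass 1 (assemblers emit transcripts in either
orientation); pass 2 operates on strand-adjusted CDSs and therefore
uses the forward strand only, which is configurable.

Greedy incremental clustering processes sequences longest-first (ties
by id, ascending) and joins each sequence to the first existing cluster
— in creation order — whose representative satisfies all three
thresholds, else founds a new cluster.  Both orderings are total, so
the result is independent of input order and worker count.  A k-mer
prescreen (capped at $k = 24$) skips pairs that cannot share the exact
match run implied by the thresholds: an alignment at identity $c$
spanning at least $S$ columns contains an exact run of at least
$\lfloor cS/((1-c)S + 1)\rfloor$ matching bases, so the prescreen can
never discard a qualifying pair.  The test suite enforces this by
comparing the clusterer, prescreen enabled, against a reference greedy
implementation that runs full Smith–Waterman for every comparison.

### ORF detection

For each of the six reading frames the maximal stop-free codon
stretches are enumerated.  A stretch is reported from its first ATG
(`complete` when a stop follows, `3prime_partial` when it runs off the
sequence end); a stretch with no ATG is reported only when it abuts the
5' end of its reading direction with no upstream stop
(`5prime_partial`, or `internal` when open at both ends).  The stop
codon is excluded from the reported sequence and coordinates; the
100-aa floor is inclusive and configurable.  Codons containing `N`
translate to `X` and never count as stops.  Only the longest ORF per
stretch is reported — no nested sub-ORFs at internal ATGs — but a
transcript may carry several ORFs on either strand, which is what makes
the final transcript count smaller than the uniCDS count whenever one
transcript owns two representatives.  The coding-likelihood rescoring
performed by Markov-model ORF finders is deliberately not reproduced;
detection here is purely structural (length and stop topology).

### Category mapping

The provenance categories follow: 1 = all three assemblers,
2 = CLC+IDBA_tran, 3 = CLC+Trinity, 4 = IDBA_tran+Trinity, 5 = CLC
only, 6 = Trinity only, 7 = IDBA_tran only.  There is no settled
community convention for numbering the single-assembler categories
(6-vs-7 orderings both circulate), so the mapping is a configuration
option (`category_map`) rather than a constant; every table emitted by
the pipeline also spells out the member label set alongside the
category number.  With $N \ne 3$ assemblers the
$2^N - 1$ non-empty provenance subsets are numbered by decreasing
subset size, then label order.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cds_identity` | 0.98 | pass-2 identity threshold (fraction) |
| `cds_aS` | 1.00 | minimum aligned fraction of the shorter CDS |
| `cds_aL` | 0.005 | minimum aligned fraction of the longer CDS |
| `min_aa` | 100 | ORF reporting floor, amino acids, inclusive |
| `both_strands` | pass 1 yes, pass 2 no | reverse-complement matching |

Defaults reproduce the published procedure; the aS ratio is the one
parameter the original study swept (100, 99, 98, 97, 96, 95, 90, 85,
80, 75%), and `as_sweep()` reports the uniCDS count and annotatability
per value, flagging the largest aS at which the number of unique
database subjects drops below the aS = 1.00 baseline ("information-loss
onset").

Numerical details: threshold comparisons use a $10^{-9}$ tolerance so
that rational identities (e.g. 49/50) compare cleanly against decimal
thresholds; representative ties at equal length are broken by
assembler-label order then id; the best alignment cell and traceback
use fixed tie-break orders (diagonal, then gap-in-query, then
gap-in-subject), making every summary deterministic.

## Evaluation metrics

`assembly_stats()` reports transcript count, smallest/largest/median
lengths, total size and N50 (smallest prefix of the descending lengths
reaching half the total).  `annotatability()` counts queries with at
least one hit at e ≤ 1e-3 (each query once) and distinct subjects over
qualifying hits, from 12-column tabular similarity-search output.
`compare_to_reference()` applies the recovery rule — identity ≥ 98%
over ≥ 50% of the *original* transcript, single best alignment, no
chaining of disjoint fragments — in both directions, yielding missing
originals and invented (artifact) assembled transcripts;
`coverage_binned_recovery()` splits those sets at a 10x read-coverage
threshold.

## The synthetic-data generator

The generator is the package's instrument for making every pipeline
stage checkable against ground truth, and its design is deliberately
constructive rather than statistical:

* Transcripts are built over a constrained alphabet in which the
  substrings `ATG` and `CAT` (an ATG on the reverse strand) never occur
  outside planted start codons, and a 21-nt block carrying stop codons
  in all six reading frames caps both transcript ends.  Together these
  guarantee — not just with high probability — that the planted ORFs
  are exactly the reportable ones, so ORF recovery can be asserted
  coordinate-exact.
* Assembler imperfections are substitution-only by default, planted
  away from the terminal two codons of every CDS, and truncation points
  keep 7 nt clear of substitutions and are screened so they expose no
  unplanned reportable stretch.  Consequences: the best local alignment
  between two copies of a gene is always their full coordinate overlap,
  merge decisions depend only on realized identity, and the manifest
  can predict the entire clustering outcome by plain string comparison.
  The end-to-end acceptance test exploits exactly this: an
  alignment-free "manifest oracle" recomputes every count the pipeline
  reports.
* Duplicates are exact copies or exact substrings, so pass 1 must
  remove precisely them; artifacts are constructed transcripts unique
  to one assembler, with or without a planted ORF, so they must land in
  the single-assembler categories or in the invented set.
* Planted read coverages are drawn independently of the fates
  (log-normal around 20x); they exercise the coverage-binning
  arithmetic but do not emulate the empirical coupling between low
  coverage and assembly failure, so coverage-binned fractions on
  synthetic data are not comparable to values observed on real reads.

What passing tests therefore show: the pipeline's bookkeeping —
deduplication, CDS extraction, clustering decisions at the planted
identity/coverage margins, categories, extensions, redundancy and
recovery sets — is exact under controlled conditions.  What they do not
show: behavior on real assemblies with indels, chimeras, alternative
splicing, or coverage-dependent fragmentation, none of which the
generator emulates (an indel mode exists in principle but is out of the
default conditions precisely to keep the margins analytic).

With the default study conditions (50 genes, 0.5% substitution error,
98% identity threshold) two copies of a gene diverge by about 1% in
expectation, safely below the 2% threshold, and paralog pairs at the
default 8% divergence sit safely above it — but a short CDS can
occasionally realize more than 2% pairwise divergence and legitimately
split into two clusters.  The manifest oracle predicts those splits
exactly, which is why the acceptance test asserts equality with the
oracle rather than with the naive "genes + artifacts" count (the uniCDS
count is asserted to be at least that).

## Problem sizes

The shipped test suite validates the clusterer against a full
Smith–Waterman reference greedy on 200 planted-family instances (up to
30 sequences of 100–1200 nt, spanning both published parameter sets),
the deduplicator against a brute-force containment filter on 100
fixtures, the ORF scanner against a naive six-frame oracle on 500
random 2-kb sequences, and the end-to-end pipeline on the canonical
50-gene study.  These sizes keep the full oracle route tractable on a
single CPU while exercising every threshold; the pipeline itself scales
to much larger inputs, with the k-mer prescreen doing the heavy
pruning.

## Known limitations

* Greedy incremental clustering matches the input/output contract of
  the established tool at these parameter sets, not its internal
  short-word statistics; pathological co-optimal alignments could in
  principle tip a borderline membership either way.
* Recovery coverage uses the single best alignment; disjoint fragments
  of an original are not chained toward the 50% rule.
* Only translation table 1 is supported.
* The aS-sweep monotonicity of uniCDS counts is an empirical property
  of greedy clustering, not a theorem; `as_sweep()` therefore checks it
  per run and reports a violation rather than silently accepting it.
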