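---
title: "Quantifying spurious alignments of ultra-short ancient DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spurious alignments of ultra-short ancient DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spuriometer)
```

## The problem

DNA surviving in ancient skeletal material is fragmented into pieces that
are often shorter than 35 bp, and it is vastly outnumbered by microbial
DNA from the organisms that decomposed the remains. The standard way to
separate endogenous from microbial sequences — align everything to a related
reference genome and keep alignments with few differences — breaks down for
ultra-short reads, because a 20–30 bp microbial fragment can align to a
3 Gb genome purely by chance within the aligner's mismatch allowance. Such
*spurious alignments* contaminate every downstream analysis, and their rate
depends strongly on read length, so each sample needs its own minimum-length
cutoff.

`spuriometer` implements a bait-based measurement of that rate. The idea:
inject artificial single-base mutations into the reference at positions
where hominin genomes are not expected to vary, then look at which allele
each read carries where it overlaps such a site. A read genuinely derived
from the source organism shows the *original* base; a read that aligned by
chance shows the *mutated* base most of the time, because chance alignments
must match the reference (including its injected mutations) nearly
everywhere to survive the mismatch ceiling.

## Mutating the reference

`selectMutationSites()` places a candidate site every `spacing` bp (default
100) along each sequence. Real applications exclude polymorphic positions,
indel neighbourhoods, repeats and non-unique regions; those arrive here as a
pre-made exclusion track (BED/`GRanges`). A candidate falling inside the
track, or on an `N`, is relocated to the nearest included position, and the
relocated site is kept only if it is at least `minAdjacent` bp (default 75)
from both the previously accepted site and the next grid candidate;
otherwise it is dropped. Three choices the grid rule leaves open were fixed
as follows, all for determinism:

* the grid is anchored per sequence, with the first candidate at position
  `spacing` (1-based);
* relocation distance ties are broken leftward;
* a relocated site violating the 75-bp rule is dropped, not re-relocated —
  the rule licenses a single relocation attempt.

Replacement bases must not distort the genome's nucleotide composition,
because composition shifts would themselves change alignment behaviour.
Two schemes are provided (`buildReplacementScheme()`):

* **batch** (default): the mutated bases are a permutation of the original
  bases across all sites with no site keeping its base, so genome-wide base
  counts are preserved *exactly*. A fixed-point-free multiset reassignment
  exists whenever no single base occupies more than half of the sites;
  degenerate inputs raise an error rather than silently biasing
  composition.
* **matrix**: a 4×4 zero-diagonal flow matrix with row and column sums
  equal to the base frequencies is fitted by iterative proportional fitting
  and row-normalised, giving replacement probabilities under which the
  expected composition is stationary (`f Q = f`, residual < 1e-9).

`mutateReference()` returns the mutated genome together with a
`MutatedSites` table; `revertReference()` applied to the output restores
the input byte-for-byte, which is also the package's round-trip test.

## Classifying alignments

For each alignment overlapping a mutated site (`classifyAlignments()`):

* **Strand guard.** Cytosine deamination converts C to T (read as G to A on
  the opposite strand) and could flip alleles between the states being
  compared. With single-stranded libraries the original strand is known, so
  forward-orientation alignments are disregarded when either the original
  or the mutated state is C, and reverse-orientation alignments when either
  state is G (`EXCLUDED_STRAND`).
* **Call.** Surviving observations are `TRUE_HOMININ` if the read shows the
  original base and `SPURIOUS` if it shows the mutated or any other base.
  Reads overlapping two sites (rare under a 75-bp minimum spacing and
  ≤ 76 bp reads) are classified by the 5′-most non-guarded site in read
  orientation.
* **Features.** Raw mismatch counts against the mutated reference are
  corrected by subtracting one mismatch for every overlapped site at which
  the read does not carry the mutated allele — such reads are forced to
  carry a mismatch there by construction, true and spurious alike — and
  floored at zero. Indel events are counted from the CIGAR. Terminal
  C-to-T flags and the full 12-type substitution spectrum are computed
  against the *unmutated* reference, in read orientation.

Length-dependent mappability is handled as in large-scale practice: one
unique-mappability track per k in {20, 23, 26, 29, 32, 35}, the decision
using the largest k not exceeding the read length, and an alignment deemed
usable if any k-mer start inside its span is flagged. For the small genomes
this package targets, `buildMappabilityTracks()` computes the tracks
exhaustively: a position is unique iff its k-mer matches no other
forward-strand position within one mismatch and its reverse complement
matches no position at all. Candidate pairs are generated with the exact
half-split pigeonhole trick (two k-mers within one mismatch must share an
exact half) and verified directly, which is exhaustive but intended for
genomes up to a few hundred kb.

## Correcting the counts

The aligner's edit-distance rule (`maxMismatches()`) reproduces the
Poisson-tail ceiling of `bwa aln -n 0.01`: the maximum mismatch count
*m*(*l*) is the smallest *k* with P(X > k) < 0.01 for X ~ Poisson(0.02 ·
*l*), evaluated by exact cumulative summation. At the dominant lengths this
gives

```{r}
data.frame(l = c(20, 30, 40), m = maxMismatches(c(20, 30, 40)),
           M = maxMismatchProportion(c(20, 30, 40)))
```

i.e. a maximum mismatch proportion *M* of about 10%. Assuming
(conservatively) that every spurious alignment carries the maximum number
of mismatches, a spurious alignment shows the mutated state with
probability 1 − *M* (~90%) and each other state — including the original
base, which gets it misclassified as true — with probability *M*/3 (~3.3%).
`correctCounts()` undoes that misclassification:

N′_T = N_T − N_¬T · M/(3 − M),  N′_¬T = N_¬T / (1 − M/3),

an exact mass shift (N′_T + N′_¬T = N_T + N_¬T) that always moves counts
toward spurious, and `spuriousFraction()` reports N′_¬T/(N′_T + N′_¬T).
Numerical choices: corrected true counts can go negative under extreme
contamination and are clamped at zero with a warning; per-bin intervals are
Wilson score intervals at the effective sample size N_T + N_¬T, chosen for
stable behaviour at proportions near 0 and 1.

Estimates are formed in 1-bp length bins (`fractionByLength()`), each bin
corrected with its own *M*(*l*); cumulative curves (`cumulativeFraction()`)
apply the correction per stratum *before* summing, which dominates a single
pooled *M* because *M* varies non-monotonically with length (e.g. 0.100 at
20 bp, 0.136 at 22 bp, 0.075 at 40 bp). `findLengthCutoff()` scans the
cumulative curve for the smallest length L at which the corrected spurious
fraction among reads ≥ L drops below τ; L_1% and L_10% are the τ = 0.01 and
0.10 cutoffs, reported as "not reached" when no length qualifies.
`usableBasesFoldChange()` totals the bases of true-classified,
filter-passing reads at a cutoff relative to the conventional 35-bp
baseline.

Two feature filters mirror what distinguishes genuine ancient reads:
`indel` removes alignments with any insertion or deletion, and `deam` keeps
only alignments with a terminal C-to-T substitution. The deamination filter
is taken to require a C-to-T at *either* terminus: that is how the
filter's effect on per-length curves is described where it is introduced,
and the both-termini reading would interact with the strand guard to
discard most of the data.

## Lineage assignment

Informative sites are built (`buildInformativeSites()`) by sampling one
allele from each of three diploid genotypes (modern human, Neandertal,
Denisovan), calling the ancestral state as the allele shared by at least
four of five aligned primate genomes, and keeping biallelic sites whose
derived-allele carriers form one of the four patterns ModernHuman /
Neandertal / Denisovan / NeandertalDenisovan. Patterns with the modern
human plus one archaic, all three, or none are uninformative and dropped.

`derivedSharing()` then iterates over read-site overlaps on the unmutated
reference, discards observations whose read base (in read orientation) is a
T within three positions of either read end — the deamination blind spot —
and observations showing neither allele (sequencing error), and reports the
percentage of derived-allele observations per class. Intervals here are
exact (Clopper–Pearson) binomial intervals at the 90% level: with per-class
counts often in the tens, the exact interval's guaranteed coverage is worth
its conservatism. Neandertal and Denisovan sharing are compared with a
two-sided Fisher exact test (`lineageTest()`), degenerate tables giving
p = 1, and p-values across a family of samples × cutoffs are adjusted with
Benjamini–Hochberg by default (`adjustLineagePValues()`; the method is an
assumption and configurable).

## The synthetic-data generator

Every statistical claim in the test suite is exercised against simulated
data with known ground truth (`simConfig()` and friends), emulating:

* an endogenous organism diverged from the reference at 0.002
  substitutions/bp, with terminal C-to-T damage applied in read orientation
  at probability p₀·dⁱ at position *i* from either end (defaults p₀ = 0.3,
  d = 0.5, a two-parameter geometric form that reproduces the U-shaped
  terminal substitution spectrum of single-stranded libraries);
* fragment lengths uniform on 20–40 bp — the design of the in-silico
  fragmented contaminant control, which also gives every length bin equal
  power;
* indels in 0.5% of endogenous and 52% of spurious alignments (the rates
  observed for true and spurious alignments of a deeply sequenced
  Neandertal dataset);
* a spurious mixture proportion that by default declines with length from
  0.5 at 20 bp at rate 0.15/bp, mirroring the enrichment of chance
  alignments among the shortest reads; any constant or per-length profile
  can be configured.

`simulateClassifiedMixture()` bypasses alignment entirely: spurious records
carry the mutated allele with probability 1 − *M*(*l*) and each other
allele with *M*(*l*)/3, and the maximum mismatch count *m*(*l*) — exactly
the worst-case model underlying the correction, which makes the corrected
estimator calibrated in this mode and lets the tests measure its bias.
`simulateEndogenous()`/`simulateContaminant()` generate actual read
sequences (FASTA/FASTQ) for the alignment-level operations; chance
alignments themselves are not simulated, since that would require a real
aligner — the end-to-end path through an external aligner is supported but
not part of the test suite.

What passing tests do *not* show about real data: the generator draws
i.i.d. bases (no repeat structure, no GC heterogeneity), models no
sequencing error or quality scores, fixes spurious mismatch counts at the
ceiling rather than at their true (unknown) distribution, and emulates
contaminants as a single unrelated pool rather than a phylogenetically
structured community. Estimates on real data inherit none of these
simplifications' guarantees; in particular the correction remains
*conservative* (it assumes maximal mismatches), so real spurious fractions
are, if anything, overestimated.

## Problem sizes and reproducibility

The test suite and acceptance checks run on deliberately small instances:
simulated genomes of 0.6–20 kb, mixtures of 5·10⁴ records, 20-replicate
seed panels, and exhaustive Fisher-table enumeration up to margins of 30 —
sizes chosen so the whole suite completes in minutes on one core while
keeping every binomial check at ≥ 3σ separation. All stochastic entry
points take explicit seeds, restore the caller's RNG state, and identical
configurations produce byte-identical outputs. Replicate seeds in tests are
drawn through a master RNG rather than used as consecutive integers:
consecutive Mersenne–Twister seeds produce measurably correlated streams at
matching offsets, which we observed as identical binomial counts across
supposedly independent replicates.

## Limitations

* The mappability builder is quadratic in candidate pairs within hash
  groups and is not meant for mammalian-scale genomes; large genomes need
  external mappability software, whose output can be imported via
  `readMappabilityTracks()`.
* The classifier assumes deduplicated, single-end input with preserved
  strand orientation (single-stranded library protocol); paired-end records
  are discarded.
* Genotype filtering, ancestral-alignment construction and contamination
  estimation are out of scope; the lineage module consumes already-filtered
  tables.
* The correction treats *M* as an upper bound on spurious mismatch rates;
  if an aligner admitted more mismatches than the Poisson rule assumes, the
  correction would under-shift.
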