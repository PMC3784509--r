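---
title: "Duplex consensus calling and somatic mtDNA mutation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling and somatic mtDNA mutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoDuplex)
```

## The problem and the model

Somatic mitochondrial point mutations occur at frequencies of roughly
10^-6^–10^-5^ per base — one to two orders of magnitude below the raw error
rate of short-read sequencing (about one wrong base per 10^2^–10^3^
sequenced). Duplex consensus sequencing solves this by tagging both strands
of each DNA fragment with a random 12-bp double-stranded tag on each end
(ends called α and β). After PCR and paired-end sequencing, reads sharing
one 24-nt concatenated tag form a *family* descending from a single parental
strand; the two families of one fragment have mutually swapped tag halves
(α-β and β-α orientation).

Errors then separate by stage:

* **Sequencing errors** affect single reads and are removed by the
  per-family *single-strand consensus* (SSCS): a position is called only if
  covered by at least `minFamily` (default 3) reads of which at least
  `agreement` (default 70%, with 70% exactly passing) agree; otherwise it is
  undefined (`N`).
* **Late PCR errors** propagate to a subset of one family. A subset can
  never reach 70% of its family here (it is at most half), so these produce
  undefined positions, not miscalls.
* **First-round PCR errors and DNA damage** (e.g. 8-oxo-dG, read as G→T on
  the lesion strand) are copied into *every* read of one strand's family and
  survive the SSCS. They are removed by the *duplex consensus* (DCS):
  position-wise comparison of the two strand-mate SSCS, keeping a base only
  where both agree on a non-N call. A lesion present on one parental strand
  can never satisfy both-strand identity.
* **True mutations** exist on both parental strands and survive all stages.

Around the consensus core sit the protocol's filters: exact-spacer and
canonical-tag read validation, a 4-base trim after the spacer (end-repair
artifacts), 5-base soft-clipping of consensus ends (alignment artifacts),
removal of tag families at identical coordinates whose keys differ by fewer
than 3 bases (tag-error derivatives), and a nuclear-pseudogene (NUMT) screen
implemented as a Smith–Waterman score comparison against user-supplied decoy
sequences (a read is dropped when any decoy outscores the mitochondrial
reference).

## Mutation statistics

**Frequency.** De novo mutation frequency is the number of unique
(position, alternate) pairs — each type of mutation scored once per position
— divided by the total number of DCS bases sequenced, with a Wilson score
interval on that count. Positions where a variant exceeds the clonality
cutoff (fraction of molecules > 1%) are treated as inherited or clonally
expanded and excluded from the de novo set; variants above 90% are
additionally flagged homoplasmic. A `numerator = "molecules"` mode counts
mutant molecules instead, for sensitivity analysis; the unique-site rule is
the primary definition.

**Spectrum.** Each of the 12 directional substitution classes (L-strand
representation) is normalised by its *exposure*: the number of times the
wild-type source base was sequenced, i.e. that base's occurrence count in
the DCS pileup. Complement-collapsed classes (G→A/C→T, …) sum counts and
exposures of their two members. Indels are scored independently as unique
events per total bases. Proportions over the six collapsed classes plus
indels sum to one.

**Strand asymmetry.** A mutation makes complementary changes on the two
strands, so without strand bias the L-strand frequency of a class should
equal the L-strand frequency of its reciprocal (e.g. G→A vs C→T), each with
its own exposure. The comparison uses the two-proportion score test
*without* continuity correction: exposures here are 10^5^–10^7^ against site
counts of 1–100, a regime where the Yates correction makes null p-values
grossly conservative (the package's calibration test draws symmetric
mutations and checks the p-values are uniform).

**Regions.** The control region (D-loop) is taken as bp 16024–576, wrapping
the replication origin, and the coding region as 577–16023, following the
main-text convention; the 1-bp variant boundary that also appears in the
source literature (16025/16024) is treated as equivalent to within one base
and does not move any statistic. Per-sample region frequencies are compared
with Welch two-sample two-tailed t-tests (the unit of replication is the
sample), and group fold changes carry first-order delta-method standard
errors.

**Coding impact.** Substitutions in the 13 protein-coding genes are
classified under the vertebrate mitochondrial genetic code (ATA = Met,
TGA = Trp, AGA/AGG = stop; `Biostrings::getGeneticCode("2")`), translating
the affected codon on the gene's mRNA-sense strand; nonsense changes count
as nonsynonymous. Where genes overlap (ATP8/ATP6, ND4L/ND4) a substitution
is nonsynonymous if nonsynonymous in *any* overlapping gene context, and
site enumeration counts each genomic position once under the same rule —
a conservative, deterministic convention. The null expectation for the
nonsynonymous fraction enumerates all three alternates at every
protein-coding position with **uniform weighting** (the alternative —
weighting by an observed spectrum — is not used; the uniform convention is
the one whose value the package reproduces). Trailing incomplete stop
codons, completed in vivo by polyadenylation, are excluded from enumeration
(fewer than five codons genome-wide). Pathogenicity scores are consumed
from an external two-column table and compared between groups with the
Wilcoxon rank-sum test (exact enumeration below combined n = 20 without
ties, normal approximation with continuity and tie correction otherwise).

## The reference genome

`humanMitoGenome()` returns real human mtDNA on rCRS coordinates. Because
this package ships no sequence data, it derives the genome at run time from
the human mitochondrial sequence bundled with the **seqinr** package
(GenBank NC_001807.4, 16,571 bp). That deposit carries one extra cytosine in
each of two D-loop poly-C tracts relative to rCRS numbering; deleting one
base from each (positions 310 and 16190 of NC_001807) yields a 16,569-bp
sequence on which every gene of the packaged annotation
(`rcrsAnnotation()`: 13 protein genes, 2 rRNAs, 22 tRNAs, control region)
sits at its exact rCRS coordinates — the test suite verifies that all 13
protein genes translate without internal stops. The sequence differs from
the rCRS deposit at a few dozen polymorphic positions, which is immaterial
for site enumeration, exposures and region statistics; users wanting the
exact rCRS can supply it via `loadReference()`.

## What the simulator emulates — and what it does not

`simulateLibrary()` generates fragments uniformly on the circular genome
(reads may wrap the origin, exercising the wrap-aware arithmetic used
throughout), two tag families per fragment with per-strand sizes from a
shifted Poisson (minimum 1, mean 6 — family-size distributions are a
convention, not a published value), and the four error classes above.
Defaults are the study conditions: 101-bp reads, 12-bp tags, a fixed 5-bp
spacer (`TGACT`; the protocol's invariant spacer sequence is not printed in
the source, so any fixed string serves), sequencing errors at 10^-3^/base,
strand-specific damage at 10^-4^/base concentrated 80% on G→T to mimic
8-oxo-dG, late PCR errors at 10^-4^/base/duplication modelled as a single
lineage split (an error arises at a uniform duplication step and propagates
to the corresponding fraction of the family — full PCR genealogies are not
simulated), and true mutations at 10^-5^/base/fragment, between the young
and aged somatic frequencies the method was built to measure. Every
non-reference base in the output is attributable to exactly one row of the
ground-truth ledger, a property the test suite checks exhaustively on small
libraries.

Deliberately not emulated: GC bias, indel errors (indel calling is
exercised through hand-built pileup fixtures instead), quality-score
profiles (the pipeline's filters are identity-based; qualities are written
as constant placeholders), chimeric reads, and alignment error — the
simulator emits ground-truth alignments, so tests of the consensus machinery
are not confounded by aligner behaviour. Passing tests therefore demonstrate
the correctness of the consensus and statistical machinery under the stated
error model, not robustness to alignment artifacts in real data, where an
external aligner (and optionally the BAM→SAM route) supplies the mappings.

Two geometric conventions matter for interpreting simulated sensitivity
experiments. First, a deterministic `injectTrueMutations` event is placed
uniformly within the *sequenced core* of one read segment — clear of the
4-base trimmed start and the 5-base clipped ends — so a single-event
experiment measures pipeline sensitivity rather than fragment coverage.
Second, singleton families receive no late PCR events (a strict proper
subset of one read is empty).

## Numerical and degenerate-input choices

* Consensus ties (no unique modal base) are undefined; with the 70% rule a
  tie can never pass anyway, so no tie-break order exists to document.
* Clipping `n` from each end of a segment shorter than `2n` yields an all-N
  segment, not an error; all-N families are dropped and counted.
* Near-tag deduplication follows the literal protocol — every family in a
  linked component (Hamming distance < 3, strict) is removed; distance
  exactly 3 links nothing. `keepLargest = TRUE` implements the common
  alternative of retaining one representative. Components are built at the
  DCS level within groups sharing the unordered coordinate pair.
* The clonality cutoff is a strict `> 1%`, homoplasmy `> 90%`, and the
  agreement threshold a non-strict `>= 70%`, matching the protocol's
  phrasings; homoplasmic implies clonal by construction.
* Wilson bounds are computed from the closed form and clamped to [0, 1];
  k = 0 gives a lower bound of exactly 0 and k = n an upper bound of
  exactly 1. `prop.test(correct = FALSE)` reproduces them and serves as the
  independent cross-check in the tests.
* Zero exposures yield missing (NA) frequencies, never zero; a zero DCS
  denominator is an error.
* Simulated clonality requires molecule depth above ~100 for a singleton
  variant to fall under the 1% cutoff; simulation scenarios in the tests are
  sized accordingly (depths of roughly 200–1,200 molecules per position,
  comparable to the several thousand genome equivalents of a real library).

## Problem sizes used by the packaged experiments

The test suite and the acceptance script size their simulations as follows:
site enumeration runs over the full 16,569-bp genome (seconds); the
sensitivity-floor experiment uses ~74,000 fragments at reduced family sizes
(minimum 3, mean 4), yielding just over 10^7^ defined DCS bases; frequency
recovery uses 20 seeded replicates of 1,500–7,000 fragments on an 800-bp
circle spanning configured frequencies 10^-6^–10^-4^; suppression-ordering
and clonality-cutoff checks use 250–3,000 fragments on 400–900-bp circles.
These sizes were chosen so each experiment's Poisson-level expectations are
informative at desk scale.

## Known limitations

* No kilobase-scale deletion or rearrangement detection, no haplotype
  phasing, and no multiple-testing correction beyond reporting raw
  p-values.
* The SAM reader handles the minimal ungapped subset the simulator emits;
  real-data BAMs should be converted (e.g. `samtools view`) and mapped by an
  external aligner. Origin-spanning simulated reads keep simple `<n>M`
  CIGARs with positions interpreted modulo the genome length, which a real
  aligner would instead split.
* SSCS reads are not re-aligned before DCS formation; strand mates are
  paired purely by swapped tag keys and coordinates.
* Pathogenicity scoring is consumed, never computed.
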