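# mitoDuplex

Error-corrected detection of rare somatic mitochondrial DNA point mutations
from duplex-tagged sequencing libraries, with the downstream statistics used
to characterise them.

Somatic mtDNA mutations occur at ~10⁻⁶–10⁻⁵ per base, below the raw error
rate of short-read sequencing (~10⁻²–10⁻³). Duplex consensus sequencing
recovers them by tagging both strands of each DNA fragment with random 12-bp
duplex tags: reads sharing a 24-nt tag key form a family descended from one
parental strand; a per-family **single-strand consensus** (SSCS — position
defined only with ≥ 3 reads and ≥ 70% agreement) removes sequencing and late
PCR errors, and the **duplex consensus** (DCS — position-wise identity of
the two strand-mate SSCS) removes first-round PCR/damage errors, leaving
true mutations that were present on both parental strands.

On top of the consensus caller the package computes:

* **de novo mutation frequency** — unique (position, alternate) pairs per DCS
  base, under a clonality cutoff (variants > 1% of molecules are treated as
  inherited/expanded and excluded; > 90% flagged homoplasmic), with Wilson
  score intervals;
* **mutation spectrum** — the 12 directional / 6 complement-collapsed
  substitution classes, each normalised by the number of times its wild-type
  base was sequenced; indels independently per total bases;
* **region comparison** — D-loop (bp 16024–576, wrapping the origin) versus
  coding region (bp 577–16023), Welch two-tailed t-tests across samples and
  fold changes with delta-method uncertainty;
* **L-strand asymmetry** — reciprocal-mutation frequencies (G→A vs C→T on the
  light strand, …) with two-proportion score tests;
* **coding impact** — synonymous/nonsynonymous classification under the
  vertebrate mitochondrial genetic code, the uniform-enumeration expected
  nonsynonymous fraction (~75.7% for the human 13-gene set), and Wilcoxon
  rank-sum comparison of externally supplied pathogenicity scores.

A seeded simulator (`simulateLibrary()`) generates duplex-tagged paired-end
libraries carrying the four stage-specific error classes (true mutations,
single-strand damage, late PCR errors, sequencing errors) plus a
ground-truth ledger, so every stage is testable without external data.
`humanMitoGenome()` provides real human mtDNA on rCRS coordinates (derived
at run time from the sequence bundled with seqinr, coordinate-normalised;
see the vignette), and `rcrsAnnotation()` the standard 13 + 2 + 22 + 1 gene
table.

## Worked example

Simulate a library at a configured true mutation frequency of 2×10⁻⁵ on the
human mitochondrial genome and run the full pipeline:

```r
library(mitoDuplex)

g   <- humanMitoGenome()
a   <- rcrsAnnotation()
cfg <- DuplexSimConfig(g, nFragments = 20000, trueMutationRate = 2e-5,
                       familyMin = 3L, familyMean = 4, seed = 7L)
out <- runFull(cfg, annotation = a)

st <- out$summary$statistics
cat(sprintf("DCS bases: %d\nde novo sites: %d\nfrequency: %.3g [%.3g, %.3g]\n",
            st$dcsBases, st$deNovoSites, st$frequency,
            st$frequencyLower, st$frequencyUpper))
#> DCS bases: 2792282
#> de novo sites: 54
#> frequency: 1.93e-05 [1.48e-05, 2.52e-05]

print(out$spectrum)
#> Mutation spectrum (54 point mutation sites, 0 indel events over 2792282 DCS bases)
#>    class sites exposure    frequency proportion
#>  G>A/C>T     8  1242147 6.440462e-06 0.14814815
#>  T>C/A>G    11  1550135 7.096156e-06 0.20370370
#>  G>T/C>A     4  1242147 3.220231e-06 0.07407407
#>  G>C/C>G    12  1242147 9.660692e-06 0.22222222
#>  T>A/A>T    11  1550135 7.096156e-06 0.20370370
#>  T>G/A>C     8  1550135 5.160841e-06 0.14814815
```

The estimate 1.93×10⁻⁵ recovers the configured 2×10⁻⁵ inside its Wilson
interval; 54 unique de novo sites were scored once each over 2.79 million
duplex-consensus bases, and the simulator's uniform substitution process
yields a flat spectrum (each class's frequency is its site count divided by
the exposure of its wild-type base). With the damage channel enabled
instead, SSCS-level G→T artifacts appear at the configured damage rate and
the DCS level removes all of them — the package's tests verify that ordering
on every seeded run.

Classify coding consequences and compare against the null expectation:

```r
ann <- annotateConsequences(out$result$calls, g, a)
observedNonsynFraction(ann)        # 0.676 in this run
expectedNonsynFraction(g, a)       # 0.758, uniform enumeration over 13 genes
```

A thin command-line wrapper for shell use is installed at
`inst/scripts/mitoduplex.R` (subcommands `sim` and `full`, YAML-configured).

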