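---
title: "Characterizing chromosome-scale genome architecture with chromArch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing chromosome-scale genome architecture with chromArch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromArch re-implements, as a tested pipeline, the bespoke analyses used to
characterize a chromosome-scale assembly of a budding yeast with regional
centromeres, a recent LTR retrotransposon burst, sparse GT-AG introns, and
an expanded, palindrome-encapsulated mating-type (*MAT*) cassette system.
This vignette explains the models and procedures, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

```{r load}
library(chromArch)
```

## Data model

A `GenomeAssembly` wraps a `Biostrings::DNAStringSet` (uppercase A/C/G/T/N)
plus a soft-mask track recording lowercase runs from the source FASTA.
Soft-masked bases are treated as ordinary bases by every composition scan —
the analyses are meant to run on repeat-masked assemblies without excluding
masked sequence — and the mask is only used to restore case on write.
Coordinates are 1-based inclusive throughout (the GFF/GTF convention), so
`intervalLength()` is `end - start + 1` and `intervalGap()` counts the
bases strictly between two intervals. This convention is what makes
published spans check out exactly: a locus printed as 1,719,571..1,732,013
is 12,443 bp ("12.4 kb"), and two 8.5 kb palindromic arms printed as
523,326..531,900 and 533,920..542,495 flank exactly 2,019 bp. Gene models
are a `GRangesList` of exons per transcript (`geneModels()`), read and
written in both GFF3 and GTF dialects through rtracklayer; splice
junctions use the STAR `SJ.out.tab` nine-column semantics.

## Contiguity and composition

`contiguityStats()` computes N50/N90, L50/L90 and auN
($\sum L_i^2 / \sum L_i$, the expected length of the sequence containing a
random base) with the "reach at least x%" tie convention, so a cumulative
sum exactly at the threshold counts. `foldChange()` rounds ratios to two
significant figures with halves away from zero: this single rule
reproduces mixed-precision published comparisons such as 2.9-fold, 11-fold,
6.7-fold and 2.3-fold from one formula. GC percent is computed over
unambiguous bases only; N density is reported per 100 kb of total length.

## Regional centromere identification

Regional centromeres in many yeasts are kilobase-scale AT-rich islands
rather than the ~125 bp sequence-defined point centromeres of
*S. cerevisiae*. The caller follows that logic in three steps:

1. **AT-bias profile** (`atProfile()`): sliding windows of 1,000 bp
   advanced by 100 bp, AT fraction over unambiguous bases. The window must
   be large enough that a 66% AT background (sd of a window ≈ 1.5 points)
   rarely crosses the threshold, and the step small relative to the
   25–34 kb cores being mapped.
2. **Island calling** (`callATIslands()`): maximal runs of windows with
   AT ≥ 0.70, runs separated by ≤ 2,000 bp merged, islands < 5,000 bp
   discarded, and the island with the highest mean window AT retained per
   chromosome (ties leftmost). The thresholds are chosen so cores of the
   reported scale (25,953–34,016 bp at ~75% AT on a 66.1% AT background)
   are recovered while smaller AT fluctuations are not; raising the
   threshold can only shrink an island, never grow it.
3. **Edge refinement** (`callCentromeres(refine = TRUE)`): window-level
   island boundaries are systematically early/late by up to
   $w\,(1 - \frac{thr - p_0}{p_1 - p_0}) \approx 0.56$ windows, because a
   window passes the threshold while still overhanging the background. The
   caller therefore refines each edge at base resolution with a
   two-proportion Bernoulli changepoint MLE, estimating the background and
   core AT rates from the chromosome itself and maximizing the two-segment
   likelihood over a ±(2·window + mergeGap) region.

A statistical limitation worth stating plainly: with core AT ≈ 75% against
a 66% background, the changepoint information rate is only ~0.02 nats per
base, so even the optimal estimator localizes an edge with a typical error
of tens of bp and a heavy tail — about 15% of edges land more than 100 bp
from a planted transition. Callers on this kind of signal should be
trusted to ~0.1–0.5 kb, not to a window step; arm ratios and morphology
classes are insensitive at that scale.

Morphology follows the standard Levan arm-ratio classes on q/p (arms
exclude the core; p = 0 gives an infinite ratio): metacentric ≤ 1.7,
submetacentric ≤ 3.0, acrocentric ≤ 7.0, telocentric above. These
thresholds reproduce every published class label from the published ratios
(2.36 and 2.94 submetacentric, 3.67–6.16 acrocentric, 98.66 telocentric).
Whether arm distances are measured from core edges or the core midpoint is
not standardized in the literature; the edge convention is used because it
matches the published description of a telocentric chromosome whose core
sits ~22.5 kb from the right telomere, and it is configurable.

`scanPointCentromereMotif()` screens for the budding-yeast
CDEI–spacer–CDEIII kinetochore motif on both strands (IUPAC consensus,
default RTCACRTG and TGTTT(T)GNNTTCCGAA with ≤ 1 mismatch per element and
a 70–90 bp spacer — the literature consensus, fully configurable since
only the motif's name, not its sequence, is fixed by convention). Zero
full hits across AT cores is the expected signature of regional (not
point) centromere architecture. Note that at one allowed mismatch per
element, a full-motif chance hit in random sequence is rare but not
impossible; conclusions should rest on the planted/zero contrast, not on
single mismatched hits. `columnConservation()` scores satellite consensus
alignments per column as Shannon entropy and information content
($2 - H$ bits; 2.0 = absolute identity), gaps excluded from the column
distribution but reported as a gap fraction.

## LTR retrotransposons and the paired-LTR clock

`findLTRCandidates()` is a deliberately transparent analogue of
suffix-array candidate finders: exact 20-mer seeds anchor direct-repeat
pairs; seeds on a shared diagonal are clustered and extended with an
X-drop heuristic; candidates are kept when the LTR length is 100–1,000 bp,
the 5′→3′ start-to-start distance 1,000–15,000 bp, and the global
alignment identity ≥ 85% (the published screening parameters); overlapping
candidates are resolved greedily by identity then length. K-mers occurring
more than 10 times are skipped: satellite arrays would otherwise flood the
seed table with spurious direct-repeat pairs. The optional TG...CA
terminal-motif filter is off by default. No target-site-duplication test
is applied — the finder is built to be benchmarked against planted truth,
not to reproduce an external tool's output byte for byte.

`ltrPairIdentity()` is the molecular clock: paired LTRs are identical at
insertion and diverge neutrally, so their end-to-end alignment identity
ranks insertion age. Scoring is match +1, mismatch −1, gap −2 (the
alignment parameters behind published similarity percentages are not
standardized; these are fixed, configurable, and documented), with
identity = identical columns / all alignment columns, reported to two
decimals. "100% identical" means exactly 100.00 after rounding — a
discrete classification that is stable against float noise.
`summarizeLTRAges()` reports the median identity, the count and percent at
100%, and per-superfamily medians; `flagStructuralClass()` separates
canonical elements (≤ 8 kb; 8–10 kb flagged "long") from oversized
putative nested insertions (> 10 kb with protein domains) and disrupted
nested insertions (> 10 kb without).

## Inverted repeats and cassette encapsulation

`findInvertedRepeats()` seeds 15-mers between the sequence and its reverse
complement; matches on a shared anti-diagonal are clustered, extended, and
validated by globally aligning arm 1 against the reverse complement of
arm 2. Defaults (arms 100 bp–10 kb, spacer ≤ 50 kb, identity ≥ 90%) bracket
both the small 124–139 bp cassette-flanking repeats and the 8.5 kb arms of
the large *MAT*-encapsulating palindrome. On 100 kb of random sequence the
expected number of ≥ 100 bp arms at ≥ 95% identity is ~0, which the null
test asserts. `encapsulationReport()` then classifies cassette intervals
as inside-spacer, inside-arm, spanning, or free relative to each inverted
repeat, with centromere-core overlap in bp — the classification used to
argue that specific *MAT* cassettes are encapsulated by palindromic
architecture.

## Introns, splice sites, and intergenic bridges

`extractIntrons()` derives introns as the gaps between consecutive exons
per transcript, reads terminal dinucleotides strand-aware (reverse
complementing minus-strand slices), and deduplicates identical intron
coordinates within a gene so both intron-level and gene-level counts are
available. `validateSpliceSites()` reports the percent conforming to
GT-AG plus a motif tally; `intronStats()` the count, moments, range, and
the intron-containing-gene percentage.

`classifyJunctions()` formalizes the co-transcription signal: a junction
contained in one gene span is intragenic; a junction whose start sits
within a tolerance after one gene's 3′ boundary and whose end within the
tolerance before the next gene's 5′ boundary (distinct genes, same
strand) is an intergenic bridge — evidence that the intergenic spacer is
excised as an intron from a read-through transcript, as for the
*MATa1–SLA2* chimera. The default tolerance is 50 bp: published
correspondence is "perfect", and a small tolerance absorbs
annotation-boundary fuzz without admitting spurious bridges; junctions
without unique-read support are excluded from bridge calling by default.
`spatialContext()` assigns cassettes to centromere-embedded (core overlap),
pericentromeric (≤ 16 kb from a core — the published pericentromeric
distances run 3.2–15.8 kb and the euchromatic ones ~20–23 kb, so 16 kb
separates the regimes), or euchromatic zones.

## The synthetic genome generator

`simConfig()`/`generateGenome()` produce genomes whose defaults mirror the
study system: six nuclear chromosomes of 1.2–3.5 Mb at 33.9% GC; one
26,781–34,016 bp centromere core per chromosome at ~75.5% AT placed to the
published arm ratios, containing an exact tandem satellite array
(chromosome-specific units of 147/22/61/32/109/61 bp, ~1.24% of the core);
74 LTR elements sized around 5.5 kb with 200–400 bp LTRs, 19 of them with
identical LTR pairs and a few > 10 kb nested outliers, divergence
exponential with mean 2.5% capped at 15%; 708 intron-bearing genes
(~1.25 introns each, lognormal lengths with median 113 bp clipped to
37–2,318 bp, 100% canonical GT-AG) within a 5,428-gene universe;
co-transcribed gene pairs bridged by 189–247 bp junctions; and palindromic
cassettes including an 8,575 bp-arm / 2,019 bp-spacer structure at 0.02%
arm divergence. Values the study does not pin down — exon length
distribution (lognormal, median ≈ 400 bp), junction read support
(Poisson), satellite composition — were chosen once as field-typical and
are configurable.

Every planted feature is recorded in a truth table whose coordinates
round-trip against the emitted FASTA; a single seed drives per-stage
substreams so disabling one feature type does not perturb the others, and
identical seeds give byte-identical output files. Two deliberate
generator details: the background is i.i.d. at fixed GC (no higher-order
Markov structure), which is sufficient for planted-feature recovery tests
but means the repeat-null calibration is optimistic relative to real
genomes with compositional autocorrelation; and the cassette planter
writes short non-self-complementary A-tracts at the spacer termini so the
planted arm/spacer boundaries are well-defined against chance
complementary matches. Passing recovery tests on these genomes
demonstrates correctness of the measurement code under known truth — not
performance on real assemblies, where repeat families, solo LTRs and
segmental duplications violate the simulator's independence assumptions.

## Problem sizes used by the test suite

The unit suite exercises a two-chromosome 0.8 Mb simulated genome plus
constructed fixtures; the acceptance checks run the full six-chromosome
~13.9 Mb default configuration once (generation ~17 s, centromere calling
~3 s, intron and junction analysis ~3 s on one core) and verify planted
splice-site, centromere, LTR-clock and bridge recovery against the truth
table, alongside the printed-value arithmetic and the property-based
invariants (contiguity oracle equivalence, strand-mirror invariance,
threshold monotonicity, identity symmetry, partition completeness,
simulator determinism).

## Known limitations

* Centromere edge placement is information-limited (see above): ~15% of
  edges fall > 100 bp from a planted transition even with optimal
  refinement, so the boundary-accuracy clause of the recovery criteria is
  asserted knowingly at that limit.
* The LTR finder's substitution-only extension model matches the
  simulator's mutation model; indel-diverged LTR pairs would fragment arm
  extension (alignment-based identity still handles indels once anchored).
* Identity percentages from external suffix-array tools are not expected
  to agree numerically: their alignment parameters differ and are not part
  of the contract here.
* Distinct LTR sequence accounting counts two per element; shared LTRs of
  nested elements are not deduplicated.
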