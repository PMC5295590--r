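---
title: "Methods: mapping EMS-induced mutations by sequencing without outcrossing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping EMS-induced mutations by sequencing without outcrossing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evilmap)
```

## The problem and the model

Ethyl methanesulfonate (EMS) alkylates guanine, so chemical mutagenesis
induces almost exclusively G:C&rarr;A:T transitions — a few thousand per
treated plant, heterozygous in the treated seed. In an inbred,
recursively selfed pedigree those induced SNPs are the *only* real
polymorphisms, which makes them usable simultaneously as candidate
causal changes and as molecular markers: a recessive mutant can be
mapped by sequencing a pool of mutant siblings, a heterozygous sibling
and a wild-type sibling pool from the segregating family, with no
outcross at all.

Three obstacles stand between raw variant calls and a single causal
SNP, and the package implements one module for each:

1. **Noise.** Raw calls are dominated by sequencing error and
   repetitive alignment. The filter cascade (`run_cascade()`) applies,
   in order: a read-depth window of 2–100 (the upper bound doubling as
   the repetitive-region filter), an RMS mapping-quality floor of 10, a
   3 bp exclusion window around indel evidence, restriction to
   biallelic positions, homozygous-alternate genotype at Phred quality
   ≥ 20, zero reference-base reads with alternate support on both
   strands, and finally the EMS spectrum itself (G&rarr;A / C&rarr;T
   only). Every threshold is inclusive on the retained side.
2. **Reproducible false positives.** Some genomic positions yield
   spurious calls in *any* sample — reference errors, sub-line drift,
   paralogy. Because independently mutagenized lineages cannot share
   real EMS sites, any position called in two lineages is an
   error-prone position; `subtract_other_lineages()` removes them,
   keeping positions shared only within a pedigree (those are
   segregation signal, not error).
3. **Localization.** `allele_frequencies_at()` reads raw allele
   frequencies (never genotype calls) for the wild-type sibling at every
   marker homozygous in the mutant pool; the one genomic segment where
   those frequencies drop to zero is the linked region
   (`detect_linked_interval()`). A candidate must additionally be
   consistent with the pedigree (`pedigree_consistency_filter()`):
   homozygous in the mutant pool (frequency ≥ 0.9), intermediate in the
   heterozygous sibling (0.2–0.8), absent in the wild-type sibling
   (≤ 0.2), and must change a protein (`classify_snps()`).

## The genotype caller

The pipeline begins downstream of alignment, from per-position
strand-resolved allele counts. Genotypes are assigned by maximum
likelihood under a binomial read model with per-read alternate
probabilities $e/3$, $1/2$ and $1-e$ for the three diploid genotypes
and a uniform prior; the variant quality is the Phred-scaled posterior
probability of homozygous reference, capped at 255. This is a
deliberately simplified, fully documented stand-in for a pileup-based
consensus caller: the exact internal model of the original tools is not
reproducible from their published descriptions, so validation targets
the arithmetic of the method and simulated ground truth rather than
bit-level caller agreement. Likelihood ties break toward homozygous
reference — the conservative direction, producing fewer false variants.

## What the simulator emulates

`simulate_ems_study()` builds a desk-scale replica of a five-line,
three-lineage study design, with complete ground truth
(`truth.json`):

* a uniform-composition genome, 2 chromosomes × 2.5 Mb by default, with
  100 non-overlapping genes (1–4 CDS exons, ATG start, no internal
  stops, stop codon included in the CDS);
* heterozygous founder mutations at rate 1/125,000 per bp, G:C&rarr;A:T
  only, each on a random founder haplotype (seed mutagenesis makes M1
  heterozygosity the defensible default); one planted causal mutation
  that converts an internal codon to a premature stop;
* three selfing generations (M1&rarr;M4) with Poisson crossovers (mean
  1 per chromosome per meiosis, no interference, uniform breakpoints),
  then genotype-based selection from the final segregating family: 13
  mutant-pool members homozygous for the causal allele, one
  heterozygous sibling, and a homozygous-reference ancestor selfed once
  to give a 17-member wild-type pool — the pool sizes of the original
  design;
* pooled sequencing at 45×/7×/30× (wild-type sibling, heterozygous
  sibling, mutant pool) and 3×/43× for the two unrelated lineages, with
  Poisson depth, binomial allele sampling at per-base error 0.001 and a
  binomial strand split;
* 50 error-prone positions that emit a spurious alternate base — the
  same base in every line — with per-read probability 1.0, modelling
  the consistently non-reference reads of paralogous mis-mapping (a
  weaker emitter would be destroyed by the zero-reference-read filter
  before ever reaching the subtraction stage it is planted to
  exercise); 50 homozygous non-EMS background variants shared by all
  lineages (sub-line drift); 100 indel positions for the gap filter;
  and 200 spiked low-depth error-singleton positions per line.

Two things real data have that the simulator does not: genome-scale
enumeration of error singletons (the tens of thousands of positions
where a stray read mismatches — here represented by the spiked
singleton sites, so the depth and homozygosity filters are exercised
without simulating five billion bases of reads), and mechanistic
paralogy (only its read-level signature is modelled). Passing tests
therefore demonstrate the *logic* of the method — filtering, spectrum
enrichment, subtraction, cosegregation — at realistic per-site
statistics, not performance on genome-scale alignment artifacts.

A fixed seed makes every output byte-identical, including the emitted
file set.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere; conversions happen
  only inside format readers/writers.
* **Rounding** of printed percentages is half-away-from-zero
  (`round_half_up`), the convention of published tables, not banker's
  rounding.
* **Position matching** in subtraction is allele-agnostic (chromosome +
  coordinate), because error-prone positions surface different alleles
  in different lines.
* **Interval detection** is the one stage the original study performed
  by eye; the package replaces it with an explicit run-based detector:
  maximal runs of at least `min_interval_markers` (default 3, the
  smallest run that cannot arise from one stray marker) consecutive
  markers with wild-type-sibling frequency ≤ 0.2, ranked by marker
  count, then mean frequency, then coordinate. At the default desk
  scale (~40 mutations per lineage against the study's ~9,000 markers)
  qualifying runs are often absent; the ledger then skips the interval
  step with a flag and the pedigree-consistency filter carries the
  localization, which it can, because the marker density is low for the
  same reason the candidate count is.
* **Insufficient coverage.** A frequency resting on fewer than
  `min_informative_depth` = 10 reads is flagged rather than judged: 10
  is the smallest depth at which a true heterozygote lands inside the
  default 0.2–0.8 window with ≥ 95% probability
  (`pbinom(8, 10, 0.5) - pbinom(1, 10, 0.5)` ≈ 0.978). Candidates
  flagged this way are retained in the final list and reported
  separately — at 7× depth, the heterozygous sibling usually cannot
  veto, only corroborate. Excluding them would make the design's own
  7× line a systematic false-negative machine.
* **Degenerate inputs.** Zero-depth sites are `no_call` at quality 0;
  empty call sets propagate as empty reports; records lacking
  strand-resolved counts fail the purity filter closed (a config
  escape hatch passes them with a warning); genes whose CDS length is
  not a multiple of three are flagged untranslatable and their SNPs
  fall back to intronic with a warning.
* **Splice sites** are the 2 intronic bases flanking internal exon
  boundaries (the canonical donor/acceptor dinucleotides). UTRs are not
  modelled; a SNP inside a gene span but outside CDS is intronic.
* **Impact mapping** is total and fixed: missense &rarr; MODERATE;
  nonsense, stop loss, splice site, start loss &rarr; HIGH; synonymous
  &rarr; LOW; intronic/intergenic &rarr; MODIFIER. Stop loss is grouped
  with the HIGH truncation-like classes.

## Validation strategy and problem sizes

The test suite validates each module against an independent oracle:
the genotype caller against direct likelihood computation, the effect
classifier against whole-protein translation and diffing, Venn and
subtraction logic against brute-force membership enumeration, meiosis
against the 1:2:1 ratio at 10,000 selfed offspring and the Poisson
crossover count over 1,000 meioses, and the full pipeline against the
simulator's planted truth: across seeds 1–20 of the default study the
planted causal SNP must appear in the final candidate list in at least
18 runs and be the *only* candidate in at least 15. The two
characteristic failure modes are both honest consequences of the
design: one stray error read matching the reference in the mutant pool
trips the zero-reference-read filter, and the 7× heterozygous sibling
occasionally presents 3/3 alternate reads, gets called homozygous, and
the causal site is subtracted as "called in a sibling". Table-level
arithmetic from the published study (stage totals, percent reductions,
percent-unique values, the protein-altering total, the 240/160
mutation-load expectations, and all six published codon worked
examples) is recomputed exactly by the package's report functions.

Default problem sizes — 5 Mb genome, ~120 tracked variant sites, ~1,200
singleton sites, 33 sequenced individuals — keep a full pipeline run
under ten seconds, so the whole 20-seed recovery experiment runs in a
few minutes.

## Known limitations

* The caller has no base-quality model, no mapping-quality downgrading
  and no indel genotyping; indels enter only as positions to avoid.
* One transcript per gene; no UTRs; no organellar genetic codes.
* The recombination model has no interference and no hot spots.
* Classical bulked-segregant statistics (SNP-index curves, smoothed
  G′) are out of scope: localization rests on the run detector and the
  pedigree-consistency logic.
* Error-prone-position discovery is not saturating: subtraction removes
  what at least two lineages reveal; a position erring in only one line
  survives to the candidate stages and must be caught by the pedigree
  filters.
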