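---
title: "Haploid gene-trap screens: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploid gene-trap screens: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscreen)
```

## The screen and its statistical model

A gene-trap retrovirus integrated into a near-haploid cell creates a
loss-of-function allele when the cassette lands in an exon (any orientation)
or in an intron in the gene's transcriptional direction; antisense intronic
cassettes are largely spliced around and tolerated. A library of millions of
independently mutagenized cells is treated with a toxic compound; clones
whose disrupted gene confers resistance expand, and the insertion sites of
the pooled survivors are recovered by inverse PCR: genomic DNA is digested
with MseI (TTAA) or NlaIII (CATG), self-ligated, and the fragment flanking
each proviral junction is sequenced as a 50 bp single-end read.

For each annotated gene the read-out is a 2×2 contingency table — unique
inactivating insertion sites in the gene versus all other genes, selected
pool versus unselected control library — tested with the one-sided Fisher's
exact test. The margins are the *genome-wide* totals of inactivating sites
in each pool, so a gene's p-value asks: among all inactivating insertions
recovered, is this gene over-represented after selection? The one-sided
(enrichment) p equals the hypergeometric upper tail and needs no
pseudocounts when a cell of the table is zero. Raw p-values are the primary
output, matching how such screens are read; a Benjamini–Hochberg column is
appended for convenience and is clearly an addition of this package.

The test treats sites as exchangeable draws and ignores clone expansion
dynamics: a resistant clone that expands more contributes more *reads* but
still one *site*, which is why counting unique sites (not reads) is the
robust choice and why read counts enter only through the support filters and
the display threshold.

## What the simulator emulates — and what it does not

`screen_sim_config()` fixes the simulated study conditions. The defaults are
a 2 × 1 Mb genome with 100 genes, 50,000 single-integration cells, survival
probabilities 0.9 (insertion inactivating a resistance gene) versus 0.001
(background), 50 bp reads, and a shifted negative-binomial per-site depth,
1 + NB(mu = 19, size = 0.5), giving mean depth 20. These mirror, at desk
scale, a screen whose real counterpart uses ~75 million insertions and a
genome three orders of magnitude larger; the scaled-down defaults keep every
stochastic property the analysis depends on (uniform integration, fair-coin
orientation, genotype-dependent survival, restriction-site fragment
truncation, overdispersed depth with a singleton tail) while letting the
full pipeline run in seconds per screen.

Emulated features:

- uniform integration positions and independent fair-coin orientations;
- per-cell survival under selection as an independent Bernoulli draw
  conditioned on whether the insertion inactivates a resistance gene;
- reads that start exactly at the junction base, run in the proviral
  direction, and truncate at the end of the first TTAA/CATG occurrence
  within the read length — so short-fragment reads exist, as in a real
  MseI/NlaIII inverse-PCR library;
- overdispersed per-site read counts with support ≥ 1 (dispersion 0.5), so
  the single-read filter removes a nontrivial tail. No published per-site
  depth distribution exists for this protocol; the negative binomial is this
  package's modelling choice, not an inference from data.

Not emulated: sequencing errors and PCR chimeras (the mapper is exact-match,
so errors would only inflate the discarded fraction), integration-site
sequence preferences, clone expansion dynamics beyond the survival
probability, and repetitive genome structure (i.i.d. bases are repeat-free
at read scale; `inject_repeat()` adds repeats deliberately to exercise
multi-mapper discarding). Passing tests on the simulator therefore
demonstrate the *pipeline logic* — trimming, unique mapping, filtering,
classification, the test — not robustness to real-data artefacts such as
mapping bias or hotspot integration.

## Coordinate and orientation conventions

All internal coordinates are 0-based half-open; GTF (1-based closed) and SAM
(1-based) are converted at their parser boundaries. An insertion position is
the first genomic base 3′ of the proviral junction. For a minus-orientation
insertion the read is the reverse complement of the bases ending at the
junction, so a reverse-strand alignment reports the forward-strand
coordinate of the *last* base of the match — this keeps simulator truth and
mapper output identical for both orientations. How the original analysis
converted minus-strand alignments to junction coordinates is not public;
anyone comparing against externally produced site tables should check for a
±(read length − 1) offset on minus-strand sites. The SAM import path
(`import_external_alignments`) instead reports the leftmost aligned base,
per SAM convention, because external aligners do not share the simulator's
junction semantics.

A site exactly at an exon boundary belongs to the exon on its left-closed
side: half-open intervals make the membership unambiguous. UTR exons count
as exons, as in exon/intron-table annotations. Overlapping genes each
evaluate the site independently — the only assumption-free choice — so the
per-gene site total can exceed the number of distinct inactivating sites.

## Filters and their edge cases

- **Trimming** returns the prefix through the last base of the *leftmost*
  TTAA/CATG occurrence (the site is retained: fragments end "after the
  restriction site"). Trimming is idempotent and always yields a prefix.
- **Mapping** retains a read iff it is ≥ 20 bp after trimming and matches
  the genome exactly once over both strands. The 20 bp floor is a
  configurable default: no published floor exists, and 20 bp gives unique
  placement with high probability on repeat-free synthetic genomes.
- **Proximity filter**: sites 1–2 bp apart on a chromosome are alignment
  jitter of one junction; *all* members of such a cluster are discarded
  (the removal rule states no survivor), irrespective of orientation.
  `keep_max_reads = TRUE` instead retains the best-supported member, for
  sensitivity analysis. Distance 0 — the same position on opposite strands —
  is two genuine, distinguishable junctions and never triggers the filter.
- **Singleton filter**: sites with one read are discarded. The pipeline
  applies proximity first, then singletons, following the narrative order of
  the protocol; `filter_order_diagnostic()` reports the (usually tiny)
  difference the reverse order would make.
- **Skip flag**: a simulated event that cannot yield 20 mappable bases —
  whether the insertion sits near a chromosome end or a restriction site
  truncates its fragment below 20 bp — is recorded in the truth table with
  `skip = TRUE` rather than silently dropped. Recovery guarantees are stated
  over non-skipped events; with i.i.d. bases roughly one event in eight is
  skip-flagged for restriction-site truncation, which is the simulator's
  honest rendering of the short-fragment losses a real MseI/NlaIII library
  incurs.
- **Display filter**: genes with fewer than 10 (primary screens) or 50
  (validation screens) total reads are hidden from bubble plots; "less
  than" keeps a gene at exactly the threshold. This is presentation only and
  never feeds back into the statistics.

## Adduct mass arithmetic

Ophiobolin A carries a 1,4-dicarbonyl that condenses with primary amines in
a Paal-Knorr reaction, forming a pyrrole and losing two waters; the amine of
ethanolamine — free or as the phosphatidylethanolamine head group — is its
cellular target. The calculator works at full double precision from
most-abundant-isotope masses (C 12, H 1.0078250319, N 14.0030740052, O
15.9949146221, P 30.97376151, S 31.97207069) and rounds only for
presentation, half-up at 4 decimals, the precision at which instrument
software prints m/z. Rounding order matters at the last digit: the window is
built from the *4-decimal-rounded* protonated mass, then each bound is
rounded again — with a ±5 ppm half-width this reproduces the published
window 426.2982–426.3024 for the protonated ethanolamine adduct exactly.
The ppm width of the original window is not stated anywhere; ±5 ppm with
this rounding convention reproduces the printed bounds and is the default.
The ophiobolin A formula C25H36O4 comes from standard chemical references;
the printed exact mass 400.2614, which the formula reproduces at 4 d.p.,
is the authoritative anchor.

## Assay quantifications

The assay helpers encode the defining identities of the measurements around
such a screen: the PE fraction is phosphate in the PE fraction over total
phosphate (scale-invariant, bounded in [0, 1]); ¹⁴C flux is counts per nmol
phospholipid, optionally vehicle-relative; calcein leakage normalizes
fluorescence between a vehicle series (0%) and a detergent series (100%)
per time point, reporting out-of-range values with a flag rather than
clipping them, since instrument noise can undershoot or overshoot the
references; viability normalizes the vehicle to 1. ΔΔCT uses the standard
sign convention (fold = 2^−ΔΔCT, test minus calibrator, so an expression
increase gives negative ΔΔCT), with a `fold_magnitude` field
(2^|mean ΔΔCT|) for comparison against magnitude-style reports — a 6.2-cycle
magnitude corresponds to the ~70-fold regime.

## Problem sizes and numerical checks

The test suite runs the full pipeline at the simulator's default scale: ten
seeded planted screens (three resistance genes each) for recovery, one
hundred genotype-independent selections for null calibration of the Fisher
read-out (the expected behaviour is conservative: far fewer than 5% of
genes below p = 0.05, because the discrete test cannot exhaust its level at
small per-gene counts), and a 1,500-event repeat-free screen for exact
position recovery through mapping and calling. The null-calibration
replicates simulate insertions, selection, and per-site depths and count
directly, without re-synthesizing and re-mapping FASTQ for every replicate;
exact read-level recovery is established separately, so the shortcut
changes nothing about what the calibration measures. The hypergeometric
tail is checked against exact rational enumeration over every 2×2 table
with margins up to 40, and against `fisher.test` on random larger tables.
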