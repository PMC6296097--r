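---
title: "Coverage and variant-density anomaly regions on a partitioned assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage and variant-density anomaly regions on a partitioned assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqtracks)
library(dplyr)
```

## The problem

Whole-genome resequencing of a panel of accessions against one reference
assembly produces two cheap, genome-wide evidence channels: per-base read
depth and the spatial density of variant calls. Read together, they
separate four situations a breeder or geneticist cares about:

* **reference-like** segments — depth near the accession mean, unremarkable
  variant density;
* **divergent** segments — depth near the mean but variant density far
  above it (syntenic sequence that has drifted, e.g. a foreign haplotype
  block);
* **deleted or introgressed** segments — depth collapsing toward zero
  (either the sequence is gone, or it was replaced by alien sequence that
  no longer aligns);
* **copy-number gains** — depth around twice the mean.

The motivating organism is bread wheat, whose chromosome-scale
pseudomolecules exceed the 512 Mbp position limit of the classic
BAI/tabix index formats. Browser-facing data (BAM, VCF, coverage tracks)
are therefore addressed on "parts" — each pseudomolecule split into
smaller pieces — and every analysis needs coordinate liftover between the
two systems. `seqtracks` implements the whole track-generation chain:
liftover and GFF3 splitting, MAPQ filtering and depth profiles, pileup
mismatch screening, variant classification and windowed density, anomaly
segmentation, and joint region typing, plus a seeded synthetic-data
generator so everything is testable without real data.

## The segmentation rule

Both anomaly callers use the same three-step rule over a signal sampled
on consecutive units (bases for depth, windows for density), with the
accession-wide mean $\mu$ and population standard deviation $\sigma$:

1. **Threshold.** Units with signal strictly greater than $\mu + k\sigma$
   seed *High* runs; strictly less than $\mu - k\sigma$ seed *Low* runs
   ($k = 2$ by default). The inequality is strict: a unit exactly at the
   boundary does not seed.
2. **Merge.** Same-direction runs separated by at most the merge gap are
   merged, gap included (500 bp for depth, 40 kbp for density).
3. **Length filter.** Merged regions shorter than the minimum are
   dropped: 5 kbp for High depth, 50 kbp for Low depth, 500 kbp for
   density in either direction. The asymmetry reflects confidence: at
   shallow coverage, local dropout is common, so credible low-coverage
   calls need more length.

Lengths are measured on 0-based half-open coordinates (`end - start`),
so gap bases absorbed by merging count toward the minimum. Assembly-gap
(N) positions can be masked: masked units are excluded from $\mu$ and
$\sigma$, cannot seed, and break runs, but the distance across them still
counts toward the merge gap. If $\sigma = 0$ the rule degenerates
gracefully: every off-mean unit seeds.

Statistics default to one mean per accession over the whole genome
(anomaly files are per-accession), but `depth_stats()` and
`density_stats()` take any scope — per chromosome or per part — if local
baselines are wanted.

### Per-base versus windowed exceedance

The track definition evaluates depth exceedance per base, and
`call_coverage_anomalies()` defaults to that. At shallow baseline depth,
however, per-base exceedance is dominated by Poisson shot noise: with
$\lambda = 10$, $P[X > \mu + 2\sigma] \approx 3\times10^{-3}$ per base,
so spurious seeds occur every ~300 bp — closer together than the 500 bp
merge gap — and chains of merged noise can survive the 5 kbp High filter.
This is a property of the rule itself, not of any implementation. The
caller therefore offers a windowed mode (`window` argument): exceedance
evaluated on non-overlapping mean-depth windows, whose standard error
shrinks with $\sqrt{\text{window}}$. The recovery pipeline
(`recover_planted_features()`) uses 1 kbp windows, at which a 2-fold gain
or a deletion is separated from baseline by dozens of standard errors
while region bounds stay well within the merge-gap tolerance. Real
deep-coverage data ($\lambda \gtrsim 30$) can use the per-base default.

## Upstream filters and tracks

**Alignments.** Records with MAPQ below 5 are removed before any depth
computation (`filter_alignments()`); in a highly repetitive genome these
are placements the aligner itself distrusts. `mapq_table()` reports the
cumulative MAPQ distribution used to justify the cut-off. Depth counts
aligned reference bases only: deletions inside a read's alignment and
clipped bases do not cover.

**Mismatch ("SNP coverage") sites.** `pileup_columns()` tallies aligned
bases, deletion-spanning reads and anchored insertions per position;
`call_mismatch_sites()` flags positions where non-reference evidence
strictly exceeds 90% of depth at a depth of at least 3 reads. This is a
screening rule over raw alignment mismatches, not genotyping: no
likelihoods, no base-quality weighting. Conventions worth stating:
deletions count in both the alternative numerator and the depth
denominator; insertions anchor to the last consumed reference position
and contribute to the `indel` class tally but not to depth (they occupy
no reference base); ties among alternative symbols break in the fixed
order A < C < G < T < indel; reference-N positions are never called.
"Exceeding 90%" is read literally as a strict inequality — a 9-of-10
column is not called — and both thresholds are arguments.

**Variant classes and density.** `classify_variants()` assigns each VCF
record exactly one of `PASS`, `Het`, `LowQualHom`, `LowQualHet` from its
QUAL and genotype. The QUAL cut separating "high" from "low" quality is
not canonical; the default is 20 (Phred 1% error) and should be set
deliberately. Zygosity comes from the genotype field alone.
`variant_density()` counts calls per non-overlapping 10 kbp window
anchored at position 1; by default only the homozygous classes are
counted, matching the default track display. Terminal partial windows
never enter $\mu/\sigma$ but may still belong to a region.

## Joint region typing

`classify_regions()` turns the qualitative reading of the two tracks
into an explicit rule on the depth ratio $r$ (interval mean depth over
accession mean) and the interval's mean window density $d$:

| order | condition | label |
|---|---|---|
| 1 | $r <$ `low_cut` (0.25) | `DELETED_OR_INTROGRESSED` |
| 2 | $|r-1| \le 2\sigma/\mu$ and $d \le \mu_d + 2\sigma_d$ | `CS_LIKE` |
| 2 | $|r-1| \le 2\sigma/\mu$ and $d > \mu_d + 2\sigma_d$ | `DIVERGENT` |
| 3 | $r \in$ [1.75, 2.5] and depth $> \mu + 2\sigma$ | `CNV_GAIN` |
| 4 | otherwise: nearest rule, flagged `ambiguous` | — |

None of the cut-offs is printed anywhere authoritative; "good coverage"
and "low density" are qualitative notions, so every number above is an
explicit argument chosen to reproduce the archetypal cases (a ~2-fold
gain clears rule 3; an unaligned introgression sits far below rule 1's
cut). The gain band [1.75, 2.5] brackets a single-copy duplication while
excluding higher multiplicities. With a gene annotation supplied, each
region also gets `gene_cov_frac` — the fraction of genic bases at depth
above half the mean — because alien introgressions tend to retain genic
coverage spikes that true deletions lack.

## The synthetic generator

`sim_config()`/`simulate_panel()` emulate exactly the signal structure
above: per-base depth as Poisson counts around a baseline
$\lambda = 10$ (shallow-WGS scale), variant calls as a spatial Poisson
process at 1.7/kbp baseline (the order observed for wheat accessions
against a distant reference: tens of millions of homozygous calls over a
~14 Gbp genome), with planted intervals that modulate both. Defaults per
type: deletion — depth ×0, no variants; introgression — depth ×0.25,
5× variants; copy-number gain — depth ×2; haplotype block — baseline
depth, 5× variants. Homozygous fraction 0.85 and high-QUAL fraction 0.8
shape the class mix. All draws flow from one seed; identical seeds give
identical panels.

What the generator does **not** model: GC bias, mapping-quality decay in
repeats, sequencing error, correlated noise, genic coverage islands
inside introgressions. Passing recovery tests therefore demonstrate the
*rule chain* recovers clean planted signals exactly — they say nothing
about aligner behaviour on real repetitive genomes.

The shipped benchmark (`recovery_sim_config()`) is one 10 Mbp part with
a 60 kbp deletion, a 600 kbp high-density block and a 200 kbp 2× gain,
all aligned to the 1 kbp/10 kbp window grids so boundary error is
measurable. The 10 Mbp size keeps the planted features a small fraction
of the genome (so they do not dominate the accession statistics they
must exceed) while running in seconds:

```{r recovery}
panel <- simulate_panel(recovery_sim_config(seed = 42))
calls <- recover_planted_features(panel)
calls
score_recovery(calls, panel$truth)
```

`score_recovery()` counts a truth feature as recovered when a call of
matching type overlaps it with reciprocal overlap at least 0.5, greedy
by overlap size.

## Coordinate scheme and liftover

A `partition_scheme` is validated so parts contiguously tile each
chromosome and names are unique; the part count is data, never a
constant. All arithmetic is 1-based closed internally; BED (0-based
half-open) only at the I/O edge. `to_part()`/`from_part()` are exact
inverses on every in-range coordinate. `split_gff3()` re-addresses
features to parts while treating the attribute column as opaque bytes —
a structured GFF3 parser would re-encode it — and refuses
boundary-crossing features by default (silent truncation corrupts gene
models); clip mode splits them with `.p1`/`.p2` ID suffixes.
`interval_width()` follows the coordinate convention: `end - start` for
positions quoted in a common unit (Mbp borders), `end - start + 1` for
1-based closed base-pair intervals.

## Numerical and testing choices

* Population (not sample) standard deviation everywhere: the positions
  are the population, not a sample from it.
* Strict inequalities at every threshold boundary, documented per
  function.
* Segmentation is verified against an independent brute-force
  merge-to-fixpoint oracle on randomized exceedance vectors, and the
  mismatch rule against exhaustive enumeration of all count compositions
  up to depth 12. Pileups and depth are cross-checked against the
  Rsamtools pileup engine on simulated micro-SAMs.
* Test problem sizes (10 Mbp benchmark part, vectors of a few hundred
  units for the oracle comparisons) were chosen so the full suite runs
  in about two minutes while keeping every planted effect several
  standard errors beyond its rule margin.

## Known limitations

* The liftover handles pseudomolecule ↔ parts of one assembly only, not
  cross-assembly liftover.
* The mismatch screen is not a variant caller and should not be
  interpreted as one.
* Haplotype grouping across accessions (judging two accessions
  "identical" over a region) is informal in practice and out of scope.
* bigWig output is delegated to standard tooling; the package writes
  bedGraph.
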