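---
title: "Discovering bacterial small RNAs from strand-specific short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering bacterial small RNAs from strand-specific short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnascan)
library(dplyr)
```

## The problem

Bacterial small regulatory RNAs (sRNAs) — typically 50–200 nt — act as
post-transcriptional regulators, and deep sequencing of the low-molecular-weight
RNA fraction is the standard survey instrument for finding them genome-wide.
`srnascan` implements such a survey pipeline for multi-replicon bacterial
genomes, modelled on the design used for the cyanobacterium *Synechocystis*
sp. PCC 6803 (one circular chromosome plus megaplasmids pSYSX, pSYSG, pSYSA
and pSYSM): strand-specific 81-nt reads are quality-filtered, mapped reads are
categorized against the annotation, the non-annotated read set is assembled
into transcribed clusters, clusters are filtered by support and length, and
the surviving candidates are classified into three structural classes.

The pipeline ingests *pre-aligned* reads (SAM/BAM or BED). Adapter trimming
and the alignment itself are upstream concerns, already handled well by
dedicated tools; re-running them inside an analysis package would add nothing
but version skew.

## The procedure and its assumptions

**Quality control.** A read is discarded when its mean Phred score is below
20 or its length is below 18 nt. Both rules are evaluated so the discard
reason distinguishes quality, length, or both. QC applies where base
qualities exist (FASTQ, SAM QUAL); BED input skips QC with a warning.

**Read categorization.** Every mapped read receives exactly one label:

1. sense overlap (≥ 1 base) with an rRNA, tRNA or CDS feature → that
   category, with the **largest overlap** winning and ties broken by
   rRNA > tRNA > mRNA;
2. otherwise, sense overlap with a misc_RNA feature → `misc_rna`;
3. otherwise, any overlap with a feature on the opposite strand →
   `antisense`;
4. otherwise → `intergenic`.

Sense precedence reflects that antisense is defined residually — a read is
*cis*-antisense only if it is not explained by the gene on its own strand.
The ≥ 1-base rule is a deliberate choice: no fractional-overlap threshold is
stated in the survey design this models, and a threshold would introduce a
second arbitrary parameter. Reporting groups rRNA/tRNA/mRNA into an
"annotated" panel; intergenic, antisense and misc_rna form the
"non-annotated" panel in which sRNA discovery happens. misc_RNA is annotated
for categorization purposes but tallied in the non-annotated panel, matching
how surveys report RNAs of unknown function alongside novel candidates.

**Cluster assembly.** A transcribed region is a maximal chain of
same-strand, same-replicon reads in which consecutive reads share at least
one base (`min_read_overlap`, default 1). Half-open abutment — one read
ending exactly where the next begins — does **not** join reads: with
coordinates stored 0-based half-open, `[100, 181)` and `[181, 262)` share no
base. For intervals, connected overlap components coincide with merged
intervals, so the implementation is a single sorted sweep per
replicon/strand; the test suite cross-checks it against a quadratic
union-find oracle and against an independent interval-merge routine.
Clusters are built only from the non-annotated read set (intergenic +
antisense; misc_rna optionally), since reads explained by known genes are
not evidence for novel sRNAs.

**Candidate filtering.** A cluster becomes a candidate when its support is
at least `min_reads = 10` and its span at least `min_length = 50` nt, both
inclusive. The survey wording this models is ambiguous between "more than
10" and "10 or more", and between "larger than 50 nt" and "50 nt or longer";
we read both thresholds inclusively and keep them configurable, and the
support statistic can be switched from member-read count (default) to peak
per-base coverage (`depth_statistic = "max_coverage"`), which is always
computed alongside.

**Classification.** Candidates are labelled with fixed precedence:

* `excluded_sense` — sense overlap with an annotated gene. Clusters seeded
  by antisense/intergenic reads can still spill into gene bodies; these are
  reported but not counted in Classes I–III.
* Class II (`II_antisense`) — overlap with an opposite-strand feature;
  the associated gene is the largest-overlap one. Antisense overlap is the
  most specific structural signal, hence it outranks the leader rule.
* Class III (`III_leader`) — the candidate lies wholly within the 300-nt
  window upstream of a same-strand gene's start (`leader_window = 300`,
  matching the empirical upper range of 5′UTR lengths in cyanobacteria; the
  nearest gene wins when windows overlap). The containment reading
  (`leader_rule = "contained"`) enforces that leader candidates stay within
  300 nt of the start codon; `leader_rule = "end_within"` relaxes this to
  the gene-proximal end only, for annotations with long operonic leaders.
* Class I (`I_intergenic`) — the residual: wholly intergenic, inside no
  leader window.

One class per candidate is enforced. Whether the leader rule should require
*no intervening gene* is genuinely open; we use nearest-gene because
intervening-gene bookkeeping would make Class III depend on annotation
completeness in a way the other classes do not.

**Bookkeeping.** `summarize_run()` asserts, as hard errors, that the class
counts partition the candidate total, that chromosome + plasmid counts do
too, and that per-plasmid counts sum to the plasmid total — the run-level
analogue of the arithmetic a survey prints in its results tables.

## The target screen is not an energy model

`screen_targets()` ranks candidate mRNA targets by the best local alignment
between the sRNA and the reverse complement of each transcript under a
simple scheme: match +2, G:U wobble +1, mismatch −1, gap −3 (linear). In the
sRNA-vs-reverse-complement alignment space a Watson–Crick pair becomes an
identity and a wobble becomes (G,A) or (T,C), so the scheme is a 4×4
substitution matrix driven through `Biostrings::pairwiseAlignment`. A
perfect duplex of length L scores 2L. This is a deliberately transparent
*complementarity screen* — it knows nothing of target-site accessibility or
hybridization thermodynamics, and its output column is named `score`, never
energy. When two alignments tie, the reported span is the aligner's
deterministic choice; ranking ties across genes are broken alphabetically by
`gene_id` so results are stable.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` + `simulate_reads()` exist so that every stage is
testable without downloading any sequencing run. The defaults are the study
conditions the pipeline targets:

| parameter | default | rationale |
|---|---|---|
| replicons | 100 kb chromosome + 4 plasmids (15–20 kb) | the 1 + 4 replicon structure of the target organism, scaled ~35× down so a full run takes seconds |
| genes | 60 chromosome + 30 plasmid, non-overlapping, gaps ≥ 400 nt | bacterial gene density with gaps comfortably above the 300-nt leader window |
| read length | 81 nt, constant Phred 40 | the library's read length; error-free reads, since base-call errors act upstream of this pipeline |
| planted sRNAs | 30 (10 per class), depth 20 reads, lengths 60–180 nt | the canonical 50–200 nt sRNA size range, at twice the depth threshold |
| background | 0 reads/kb (Poisson when set) | noise is opt-in so threshold-sharpness tests are exact |
| mixture | rRNA 0.4, tRNA 0.3, mRNA 0.2, intergenic 0.1 | a post-depletion-like composition for tally statistics |

Planted sRNAs satisfy their class definitions *by construction*: Class I
intervals keep ≥ 301 nt clearance from flanking genes (so they cannot fall
inside a leader window), Class II sits strictly inside a CDS on the opposite
strand, Class III fits wholly within an upstream window. Read starts jitter
uniformly within the planted span (reads truncate to the span when the sRNA
is shorter than 81 nt), so recovered cluster spans approximate but need not
equal planted spans — which is why `evaluate_recovery()` matches by
reciprocal overlap (default ≥ 0.5 of *both* spans, same strand) rather than
exact coordinates.

Two honest caveats. First, background reads that happen to land adjacent to
a planted sRNA can chain onto its cluster and stretch the called span;
full-coverage of the planted interval survives this, but strict reciprocal
matching is conservative under noise (the tests assert exactly this
distinction). Second, the generator does not model sequencing error,
non-uniform coverage along transcripts, rRNA-depletion artefacts, or
processed-transcript 5′/3′ end structure — so perfect recovery on synthetic
data demonstrates the *logic* of the pipeline, not its performance on a real
library, whose absolute candidate counts also depend on the aligner and
annotation release used upstream.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally (`length = end - start`
  always); every file boundary converts to the field conventions (GFF3/SAM
  and report TSV 1-based inclusive, BED 0-based half-open).
* Only primary mapped alignments are used; multi-mapped reads therefore
  contribute once, so cluster depth is never inflated by placement
  multiplicity. No MAPQ filter is applied by default (`min_mapq = 0`).
* Aligned spans come from reference-consuming CIGAR operations; soft-clips
  do not extend cluster geometry.
* Zero-read inputs yield empty (not failing) clusters, candidates and
  header-only exports; an empty candidate set reports precision as `NA`
  rather than 0, because 0/0 is not evidence of failure.
* One published validation row (`SYPCC_anti_04`) prints end < start; the
  packaged table keeps the row verbatim, flags it `coordinate_valid =
  FALSE`, and excludes it from length statistics only — inventing a
  correction would be worse than carrying the typo.

## Problem sizes used in the tests

The shipped suite runs the full pipeline on the default synthetic study
(about 160 kb of genome, 600–800 reads), 500 random cluster instances of up
to 200 reads against the union-find oracle, 200 random small genomes against
the categorization oracle, and a 10,000-read mixture tally checked within
three binomial standard errors. These sizes make the whole suite complete in
a few minutes on one core while still exercising every code path at depths
where boundary effects (abutment, ties, truncation) actually occur.

## A worked example

```{r example}
cfg <- simulation_config(seed = 42)
sim <- simulate_reads(cfg)
call <- call_srnas(sim$reads, sim$annotation)
call
glance(call)
evaluate_recovery(call, sim$truth)
```

## Known limitations

* Processed fragments of longer transcripts are indistinguishable from
  primary sRNA transcripts in this data type; no attempt is made to separate
  them.
* The target screen ranks complementarity only; it is a pre-filter for
  experimental follow-up, not a predictor of regulatory outcome.
* Paired-end and multi-sample designs are out of scope (the modelled
  library is single-end small-RNA).
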