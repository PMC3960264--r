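# srnascan

Discovery of bacterial small regulatory RNAs (sRNAs) from strand-specific
short-read data on multi-replicon genomes.

## What it does, and for whom

Small regulatory RNAs — bacterial non-coding RNAs of roughly 50–200 nt —
are routinely surveyed by deep sequencing of the low-molecular-weight RNA
fraction. `srnascan` is an R implementation of such a survey pipeline,
designed around genomes with one chromosome and several plasmids (the
motivating system is the cyanobacterium *Synechocystis* sp. PCC 6803 with
its megaplasmids pSYSX, pSYSG, pSYSA and pSYSM). It is aimed at
microbiologists who have pre-aligned strand-specific reads (SAM/BAM) plus a
genome FASTA and GFF3 annotation, and want reproducible, tested candidate
calls rather than one-off scripts.

The pipeline:

1. **QC** — discard reads with mean Phred < 20 or length < 18 nt
   (`qc_filter_reads()`).
2. **Ingest** — keep primary mapped alignments only, with a conservation
   tally `kept + unmapped + non_primary + low_mapq = total`
   (`read_alignments()`).
3. **Categorize** — each read gets exactly one of rRNA / tRNA / mRNA
   (sense overlap with annotation, largest overlap wins, ties
   rRNA > tRNA > mRNA) or misc_rna / antisense / intergenic
   (`categorize_reads()`, `tally_read_categories()`).
4. **Cluster** — the non-annotated read set (intergenic + antisense) is
   assembled into transcribed regions: maximal chains of same-strand reads
   with ≥ 1 shared base; abutting reads do not join (`build_clusters()`).
5. **Call** — clusters with ≥ 10 supporting reads and span ≥ 50 nt become
   candidates (`filter_candidates()`), classified with fixed precedence
   into **Class I** (intergenic), **Class II** (cis-antisense to a gene) or
   **Class III** (wholly within the 300-nt 5′-leader window of a
   same-strand gene); sense-contaminated clusters are excluded and reported
   (`classify_candidates()`, or `call_srnas()` end-to-end).
6. **Screen** — candidate targets are ranked by a local complementarity
   score against the reverse complement of each transcript (match +2, G:U
   +1, mismatch −1, gap −3); a transparent screen, explicitly *not* a
   hybridization-energy model (`screen_targets()`).

A synthetic-data generator (`simulate_genome()`, `simulate_reads()`) plants
sRNAs of all three classes at controlled depths on a scaled-down
1-chromosome + 4-plasmid genome and emits pre-aligned SAM, so the whole
pipeline is verifiable against known truth (`evaluate_recovery()`) without
any external data. `summarize_run()` enforces the count identities
(classes partition the total; chromosome + plasmids partition the total)
as hard errors. The 27 RT-PCR-validated candidates from the motivating
survey ship as a reference table (`validated_srnas()`).

## Worked example

```r
library(srnascan)

cfg <- simulation_config(seed = 42)   # 30 planted sRNAs, 10 per class, depth 20
sim <- simulate_reads(cfg)
call <- call_srnas(sim$reads, sim$annotation)
call
#> <srna_call> 600 reads -> 30 clusters -> 30 candidates
#>   Class I (intergenic): 10; Class II (antisense): 10; Class III (5'-leader): 10; excluded (sense): 0

evaluate_recovery(call, sim$truth)
#> <srna_recovery> sensitivity 1, precision 1 (30 planted, 30 candidates)
#>        called
#> planted  I II III excluded_sense missed
#>     I   10  0   0              0      0
#>     II   0 10   0              0      0
#>     III  0  0  10              0      0
```

Every planted sRNA was recovered (sensitivity 1), every called candidate
matched a planted one (precision 1), and the confusion table is diagonal:
each candidate carries the class it was planted with. `tidy(call)` returns
the candidate table (with 1-based coordinates alongside the internal
0-based half-open ones), `glance(call)` a one-row run summary, and
`autoplot(call)` the per-class/per-replicon bar chart. For file-based
inputs use `run_srna_pipeline(sam, fasta, gff, out_dir)`, which writes
GFF3/BED6/TSV exports and a JSON run summary.

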