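# exonmut

Exon-wise sequence comparison, variant naming and mutation hotspot detection
for targeted gene screens.

## What it does

In targeted mutation screens (the motivating case is TP53 in colorectal
cancer), each subject's gene is sequenced and compared to a coding reference
one exon at a time. `exonmut` implements that workflow as a tested R library
plus a small command line:

- **Global alignment.** Each sample exon is aligned end-to-end against the
  corresponding reference exon by Needleman–Wunsch global alignment with
  affine gap penalties (default `match = +1`, `mismatch = -1`,
  `gap_open = -2`, `gap_extend = -0.5`). The per-pair *identity score* is
  the number of identical aligned residues divided by the number of
  alignment columns, so gaps count against identity.
- **Variant calling.** Alignment differences become variant events in
  1-based cDNA (c.) coordinates: mismatch columns are single-nucleotide
  substitutions, maximal gap runs are deletions/insertions. Indels are
  shifted to their 3′-most equivalent position (HGVS convention) and named —
  `c.404G>T`, `c.455delC`, `c.450_478del29`, `c.622_623insGATA`.
- **Cohort aggregation.** `compare_cohort()` runs the pipeline over a list
  of samples and returns per-exon mutation counts, a per-position recurrence
  table, the altered/unaltered sample split, and sliding-window hotspot
  intervals (default: 50-nt windows holding ≥ 4 events, merged and trimmed
  to the events they cover).
- **Synthetic cohorts.** `build_fixture_cohort()` generates a deterministic
  100-sample study (50 tumor, 50 healthy) by planting a fixed 78-event
  variant catalogue into a synthetic TP53-like reference;
  `random_cohort()` plants seeded random catalogues for property testing.
  Planted catalogues are recovered exactly by the caller, so every stage is
  verifiable end to end without external data.

## Worked example

```r
library(exonmut)

fx <- build_fixture_cohort(seed = 1)          # model + 100 samples + catalogue
s  <- compare_cohort(fx$samples[1:50], fx$model)   # the tumor arm
s
#> Cohort summary (tumor): 50 samples, 42 altered, 8 unaltered
#>   48 variant events across 9 exon(s)
#>   events per exon: 2:1 3:2 4:6 5:12 6:6 7:4 8:12 9:0 10:4 11:1

recurrent_positions(s)
#>   position count
#> 1      818     4
#> 2      108     2
#> 3      404     2
#> 4      844     2
#> 5      994     2

hotspot_windows(s, width = 50, min_events = 4)
#>   cdna_start cdna_end exon_id event_count recurrent_positions
#> 1         69      108       4           5                 108
#> 2        254      285       4           4
#> 3        404      487       5          11                 404
#> 4        575      639       6           6
#> 5        816      857       8          12             818,844
#> 6        994     1024      10           4                 994
```

Reading the output: 42 of the 50 tumor samples differ from the reference in
at least one exon; exons 5 and 8 carry 12 events each while exon 9 carries
none; position c.818 is hit four times. The two strongest hotspot intervals
sit at cDNA 404–487 (exon 5) and 816–857 (exon 8) — exactly where the
recurrent positions cluster. The healthy arm
(`compare_cohort(fx$samples[51:100], fx$model)`) is summarized separately
and carries only its planted synonymous substitutions.

The same pipeline is scriptable:

```sh
exec/exonmut simulate --fixture --seed 1 --out cohort/
exec/exonmut cohort cohort/ --out summary/
exec/exonmut compare cohort/reference.fasta cohort/T10.fasta   # one pair
```

`cohort` writes `tumor_summary.tsv`, `tumor_variants.tsv`,
`tumor_histogram.tsv` and `tumor_hotspots.tsv` (and the same for the healthy
group), each headed by the configuration that produced it.

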