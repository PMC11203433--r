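---
title: "Exon-wise variant detection and mutation hotspots: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-wise variant detection and mutation hotspots: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonmut)
```

## The problem

Targeted mutation screens of a tumor-suppressor gene compare each subject's
sequenced exons against a coding reference and ask two cohort-level
questions: which exons accumulate mutations, and do mutations cluster at
recurrent positions or narrow intervals ("hotspots")? `exonmut` implements
this workflow for per-exon nucleotide sequences: global alignment, variant
extraction and naming in cDNA coordinates, and cohort aggregation, plus a
synthetic-cohort generator so the whole chain is testable end to end.

## Coordinate model

All positions are 1-based inclusive cDNA (c.) coordinates with c.1 the
first base of the model's coding reference. A `gene_model` requires exon
spans that start at 1, are contiguous, and cover the reference exactly;
introns are not modeled because input arrives exon by exon, and intronic or
splice variants are out of scope. The default TP53-like model covers the
ten coding exons, labeled 2–11, over a 1182-nt coding sequence
(exon 2 at c.1–74 through exon 11 at c.1101–1182). These spans are a
package reconstruction chosen to be consistent with the bundled variant
catalogue's exon assignments, not an annotation download; the variant
machinery is model-agnostic and any `load_gene_model()` TSV works.

## Alignment

`global_align()` computes an optimal end-to-end (Needleman–Wunsch)
alignment with affine gap penalties, delegating the dynamic program to
Biostrings' `pairwiseAlignment`. The default scheme is

| parameter | value | rationale |
|---|---|---|
| match | +1 | unit reward per identical column |
| mismatch | −1 | a point mutation costs 2 relative to a match |
| gap open | −2 | one 1-nt gap (−2.5) is costlier than a mismatch |
| gap extend | −0.5 | long deletions stay one event, not many |

With these values a substitution is always explained as a mismatch column
rather than an insertion/deletion pair, and a multi-base deletion stays a
single gap run — which is what the variant caller assumes. The scheme is
configurable everywhere (`--scheme` on the command line) and echoed into
every output header. Where several alignments tie, the library's
deterministic tie-break is accepted as-is: indel placement inside repeats
is arbitrary among equivalent representations and is canonicalized later by
3′ normalization, so the choice does not affect calls.

The identity score is the number of identical aligned residue pairs divided
by the total number of alignment columns. Counting gap columns in the
denominator is a deliberate reading of "aligned residues compared": it
makes the score penalize gaps and equal 1 exactly for identical, gap-free
sequences. The score is reported for every comparison but drives no
downstream logic. An `N` in a sample is accepted, scored as a mismatch, and
skipped (with a warning) by the caller, since an ambiguous base call is not
evidence of a variant.

## Variant extraction and naming

`call_variants()` classifies alignment columns: mismatches become
single-nucleotide substitutions (adjacent mismatch columns stay separate
substitutions — the catalogue model has no delins type), maximal sample-row
gap runs become one deletion each, maximal reference-row gap runs one
insertion each. Events are then 3′-normalized: an indel inside a repeated
context is shifted to its highest-coordinate equivalent representation,
bounded by the containing exon (per-exon input cannot produce cross-exon
events). Normalization is idempotent and validates the claimed reference
allele against the model, which catches catalogue/reference drift early.

Names follow c. notation in two dialects. The default dialect writes
single-base deletions with the deleted base (`c.455delC`) and multi-base
deletions with a length suffix (`c.450_478del29`), matching how screening
reports commonly print them; `hgvs` mode drops both suffixes
(`c.450_478del`). `parse_variant()` inverts `format_variant()` for both
dialects and, given a model, fills omitted reference alleles and assigns
exons.

## Cohort aggregation

`compare_cohort()` applies align + call + normalize to every sample × exon
and returns a `cohort_summary`. Counting rule: one variant event per sample
per position; per-exon counts are event counts. Samples from different
groups (tumor vs healthy) are never pooled — a mixed list is an error — so
a synonymous-carrier control arm always forms its own summary. Zero-length
or absent exon sequences are logged and excluded rather than treated as
whole-exon deletions.

Hotspots are detected by sliding a `width`-nt window in 1-nt steps,
flagging windows with at least `min_events` events (an event counts at its
start coordinate), merging overlapping flagged windows, and trimming each
merged interval to the span of the events it contains (reported intervals
are therefore tight around the data, not window-aligned). The defaults —
width 50 nt, 4 events — are a package calibration: narrative descriptions
of hotspot regions in screening studies span roughly 50–100 nt, and
requiring 4 events in a 50-sample cohort keeps singleton scatter out while
letting a cluster of recurrent positions through. Both knobs are exposed in
the API and CLI; there is no significance test behind the threshold, and
none is claimed.

## The synthetic cohort generator

`build_fixture_cohort(seed)` reconstructs a two-arm study design as
deterministic, fully specified data: 50 tumor samples carrying 48 coding
events (42 samples altered, 8 reference-identical; six samples carry events
in two different exons, assigned by fixed sample index), with per-exon
totals 1, 2, 6, 12, 6, 4, 12, 0, 4, 1 for exons 2–11 and recurrences
c.818 ×4 and c.108/c.404/c.844/c.994 ×2; and 50 healthy samples of which 30
carry one synonymous substitution each, at least three carriers per exon.
Clinically recorded events keep their documented alleles
(`c.404G>T`, `c.524G>A`, `c.622_623insGATA`, …); catalogue entries known
only by position, and the filler events that bring exons up to their
totals, are substitutions at fixed positions whose alternate base is the
transition of whatever the seeded reference carries.

The reference is seeded random ACGT except at a small pinned-site set that
makes the catalogue self-consistent: recorded alleles match
(G at 404, T at 487, G at 818, C at 844, …), c.453–455 is a CCC run
bounded by non-C so `c.455delC` is the 3′-normal form of deleting any of
the three Cs, c.479 differs from c.450 so `c.450_478del29` cannot shift,
and c.623 is not G so the GATA insertion cannot shift. Consequently the
seed changes only the background sequence and unpinned alleles; positions,
event types, sample assignments and all summary counts are
seed-invariant — which is exactly what the acceptance script relies on.

What the generator emulates is the *catalogue structure* of a screen:
which samples carry which events where. What it does not emulate:
sequencing error, read-level evidence, coverage dropouts, real codon
structure (the "synonymous" labels are design roles, not translated
consequences), linkage between events, or the real transcript sequence.
Passing tests therefore demonstrate that the comparison machinery is exact
on clean per-exon sequences, not that upstream sequencing artifacts are
handled.

`random_cohort()` plants at most one uniform random variant per sample per
exon (probability `mutation_rate`, indel share `indel_fraction`, deletions
of 1–3 nt, insertions of 1–4 nt). One event per exon per sample keeps
call-to-catalogue matching unambiguous; returned catalogues are stored
3′-normalized so the planted set equals what an exact caller recovers —
the round-trip invariant the test suite leans on.

## Numerical and degenerate-input choices

- Validation errors name the offending exon or sequence position.
- Deletions spanning an exon boundary cannot arise from per-exon input and
  are rejected by the coordinate checks.
- An insertion called before an exon's first base is anchored at
  (start − 1, start); it can only arise from alignments of exon-edge
  indels.
- Determinism: same inputs, scheme and seed give byte-identical outputs;
  every output TSV carries its configuration as `#` header lines.
- Problem sizes in the test suite (exhaustive alignment-oracle pairs up to
  length 4 over a two-letter alphabet plus a seeded sample at lengths 5–8;
  1000 round-trip variant specs; 100-sample fixture) were chosen so the
  whole suite exercises every pipeline stage at full depth in a few
  minutes on one core; the exhaustive oracle space grows as the Delannoy
  numbers and is enumerated in full only where that is tractable.

## Known limitations

- No statistical test of hotspot significance; intervals are descriptive.
- No protein-level (p.) consequences, pathogenicity or database
  annotation; positions are CDS-relative throughout.
- The aligner is global-only and nucleotide-only, by design.
- Multi-allelic events at one position in one sample (two overlapping
  events) are outside the catalogue model; the caller would report the
  alignment's literal column differences.
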