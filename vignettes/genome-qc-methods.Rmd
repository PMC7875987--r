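---
title: "Methods: dark-region discovery, gap-closure liftover and assembly QC"
author: "darkmap package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dark-region discovery, gap-closure liftover and assembly QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkmap)
```

# Scope

`darkmap` implements the bespoke computations that recur in reference-genome
upgrade projects: deciding which parts of a genome short reads cannot see
(dark and camouflaged regions), deciding which gaps of a predecessor assembly
a new assembly resolves, annotating sequence landmarks (telomere arrays,
satellite-rich centromere candidates, GC extremes, CpG islands), estimating
copy number of dispersed duplications from read depth, applying
annotation-derived transcript filters, and comparing per-read mappability
between assemblies. Everything runs on plain-text formats (FASTA, BED,
BedGraph, PAF, VCF) and is exercised end to end on seeded synthetic genomes
with known ground truth, generated by the package itself.

All interval coordinates in the package are 0-based half-open (the BED
convention); VCF-style variant positions are 1-based.

# Dark and camouflaged regions

A genomic window is **dark by depth** for a sample when its sequencing depth
is at most 5x (inclusive). It is **camouflaged** when depth is adequate
(at least 10x, inclusive) but the fraction of reads with mapping quality
above 10 is strictly below 10% — the signature of near-identical
duplications, where reads map but not uniquely. Both calls operate on
fixed 25 bp window tracks (depth and high-MQ fraction), the resolution at
which such tracks are conventionally computed from alignments; the package
consumes them as BedGraph and never touches BAMs.

Per sample, selected windows are merged into intervals. For dark calling a
guard protects the downstream consensus from low-coverage samples: if one
sample's merged dark total exceeds 60 Mb, the integer depth threshold is
decremented (5, 4, 3, ...) and the call repeated until the total fits under
the cap or the threshold reaches 0. The decrement-until-under-cap rule is
the package's concrete reading of "a lower cutoff for low-coverage
samples"; the effective threshold is always reported.

## Consensus across samples

On the shared window grid, a window is retained as consensus dark when the
fraction of samples dark there strictly exceeds 0.9 (so 23 of 25 samples
qualifies at 0.92; 22 of 25 does not at 0.88). For camouflaged consensus
the denominator changes: samples that are dark in a window cannot testify
about camouflage there, so they are removed from that window's denominator
before the fraction is computed. A window camouflaged in 9 of 10 eligible
samples (15 of 25 being dark) sits exactly at 0.9 and is dropped — the
bound is strict. Windows with no eligible sample are skipped and counted
in a diagnostics attribute.

Eligibility uses each sample's *own* merged dark calls, not the dark
consensus: the exclusion is about what an individual sample can observe.
Consensus is computed window-wise on the 25 bp grid and merged afterwards;
region-level voting was rejected because the underlying tracks are
window-level. Retained regions carry the minimum window support fraction of
their span, which makes the reported score conservative.

Technology-level comparisons (`intersect_technologies`) partition the base
union of several region sets into exclusive and shared cells; the partition
is exact base-level set algebra, so cells always sum to the union and each
technology's cells sum to its merged length.

# Gap-closure liftover

Gaps of the old assembly are maximal N-runs (minimum run length 1 by
default, configurable to 10 for NCBI-style conventions). For each gap the
1 kb flanks on either side are extracted, clipped at sequence ends and at
neighbouring gaps (and flagged when truncated), then placed on the new
assembly.

## Flank placement

For desk-scale data the package ships its own seeded anchor mapper: it
takes `max_mismatch + 1` disjoint exact k-mers (k = 31) from each flank,
finds their exact occurrences in the new assembly in one dictionary pass,
and verifies every implied diagonal over the full flank length by Hamming
distance. By pigeonhole, any full-length placement with at most
`max_mismatch` substitutions must contain at least one exact seed, so the
candidate generation is complete for the substitution model. A unique best
placement gets mapping quality 60; ties get 0 and a `multi_hit` flag;
placements with more than `max_mismatch` substitutions are discarded. The
mapper does not model indels or partial (clipped) alignments — real-data
users supply placements from a production mapper as PAF via
`ingest_placements()`, and the mapq threshold then applies to the supplied
values.

## Classification

A gap is **closed** when: both flanks place on the same sequence with
mapq strictly above 20; they are colinear on one strand in gap-facing
order; the inner-edge distance is non-negative and strictly below 100 kb;
and no N-run of the new assembly lies in the inter-flank span. The
distance is measured between the gap-facing flank edges, giving directly
the filled-sequence interval; abutting flanks close with a zero-length
fill. A gap is **artificial** when both placements lie on one sequence and
their intervals strictly overlap — the flanks cover the same new sequence,
so the gap never represented missing bases. Everything else, including
ambiguous (mapq 0) flanks, is **unresolved**. "Mapped properly" is read as
colinear same-strand placement of the two as-extracted flanks (equivalent
to convergent forward–reverse orientation of a read pair built from them);
classification is symmetric under reverse-complementing the new assembly.

Closed gaps get a fill profile: GC over non-N fill bases and base-wise
repeat coverage. Summaries split counts by old-sequence class (placed
chromosome vs unplaced scaffold, by name pattern) and always conserve the
total gap count.

# Sequence landmarks

* **GC windows**: 50 bp non-overlapping windows anchored at coordinate 0;
  GC is computed over non-N bases; all-N windows carry NA; the final
  partial window is normalised by its true length. Windows with GC
  strictly above 0.90 merge into extreme-GC regions.
* **CpG islands**: classic Gardiner–Garden criteria — 200 bp windows
  sliding one base, GC >= 0.5 and observed/expected CpG >= 0.6 with
  obs/exp = (window length × #CG)/(#C × #G); qualifying windows merged,
  and per-island statistics recomputed over the merged span. This is the
  classic formulation, implemented and labelled as such (the `cpg_lh`
  utility scores islands slightly differently).
* **Telomere arrays**: exact TTAGGG (plus strand) and CCCTAA (minus
  strand) units chained when consecutive units are separated by at most 10
  non-repeat bases ("less than 11 variant bases" read as an inter-unit gap
  of at most 10; units need not stay in frame across a gap). Chains of at
  least 12 units are arrays; arrays on one strand within 100 bp merge,
  summing unit counts. An array is "terminal" within a configurable 10 kb
  of a sequence end — a config default, not an externally fixed value.
* **Centromere blocks**: per 5 kb window, the base-union coverage of
  annotated satellite classes (CarSat1/Carsat2/SAT1_CF by default);
  windows strictly above 80% merge into blocks carrying their minimum
  window fraction. Overlapping repeat annotations are unioned first, so a
  fraction can never exceed 1.
* Soft-masked (lowercase) input is uppercased on read; masking never
  affects landmark calls.

# Assembly statistics and reference patching

Contigs are scaffolds split at N-runs. N50 is the length of the shortest
piece in the smallest prefix of the descending-sorted lengths whose sum
reaches half the total; L50 is that prefix's size. Gap density is gaps per
Mb of total length.

`patch_reference` replaces reference alleles with variant alleles at sites
with depth at least 30 (inclusive) and variant-allele ratio strictly above
0.90. Replacements are applied in input coordinates in one pass
(indel-safe); the report carries each applied site's position on the
patched assembly (`new_pos`). A site whose variant allele is already
present while the reference allele is not (or, for insertions, even while
the reference prefix still matches) is recognised as already applied and
skipped — this makes patching idempotent: re-running the applied-site
report, in patched coordinates, applies nothing. Reference-mismatching
sites are skipped and flagged, never fatal.

# Copy number from depth

Total copy number of a region is `2 × mean(region window depth) /
autosomal median depth`, so a diploid region at typical depth scores 2.0.
For dispersed duplications, diagnostic variant sites separate the copies:
reads from the ancestral locus carry the reference allele, reads
mis-mapped from homologous copies elsewhere carry the variant allele, so
`cn_ref = 2 × mean(ref depth)/median` and `cn_hom = 2 × mean(alt
depth)/median`; the report includes the consistency gap
`|cn_total − (cn_ref + cn_hom)|`.

One numerical choice matters here. Integer window depths at 25 bp windows
have a discrete, right-skewed distribution whose raw median sits a little
below the mean (at 30x with realistic overdispersion the raw median is 29,
a 3% bias that propagates into every call). The autosomal median is
therefore computed as the median of 100-window chunk means: chunk means
are nearly symmetric, removing the discreteness bias, while the median
over chunks stays robust to copy-number-variant regions. Sequences named
as sex chromosomes can be excluded from the normaliser via `sex_seqs`.

# Annotation rules

* **Functional overlap**: a filled gap is flagged for a feature class
  (exon, ATAC peak = the operational promoter definition, miRNA) when any
  feature overlaps it by at least 1 bp.
* **Novel genes**: candidate iff gene body covered at least 80%
  (inclusive) by filled-gap sequence, not a pseudogene, not previously
  annotated on unplaced scaffolds, and no homologous fragment elsewhere.
  The last three are consumed as precomputed booleans — no homology search
  is run here.
* **ORFs**: longest ATG-initiated, stop-terminated frame on the sense
  strand; length in amino acids excludes the stop; by default a stop is
  required (a flag allows open-ended frames).
* **lncRNA**: at least two exons, spliced length strictly over 200 nt,
  longest ORF strictly under 100 aa, no same-strand overlap with
  protein-coding exons. A transcript with an ORF of exactly 100 aa
  satisfies the protein-coding definition ("at least 100 aa"), so the
  coding call wins at the boundary and lncRNA requires < 100 — the two
  definitions would otherwise overlap at exactly 100.
* **Transcript filters**, applied in order: (1) single-exon models
  spanning more than 10 kb (the intronic-fraction clause is vacuous for a
  single exon and implemented as stated); (2) internal-priming artefacts,
  quantified as at least 12 A (plus strand; T on minus) in the 20 bp
  genomic window downstream of the 3′ end — both numbers are
  configuration, as the underlying heuristic is not standardised; (3)
  within genes retaining at least one high-scoring transcript (BLAST
  coverage >= 0.5 and at most 2 exons past the stop codon), members with
  more than 2 exons wholly downstream of the stop or BLAST coverage below
  0.5 are removed. Rule 3 can never remove a gene's last transcript,
  because it requires a surviving high scorer. BLAST coverage is a
  consumed input column.

# Paired ends and cs-tag mappability

BAC-style end pairs are **concordant** when both ends lie on one sequence
in convergent forward–reverse orientation with an outer-span distance
strictly below 500 kb; the outer span (leftmost start to rightmost end) is
used because the measurement points are not otherwise standardised. Pairs
with an unplaced end are excluded and counted. Discordant end positions
cluster by single linkage within 50 kb into breakpoint evidence.

Per-read mapped-base fractions come from cs difference strings: query
bases consumed by matches (`:`) and mismatches (`*`) count as mapped;
insertions (`+`) consume query but map nowhere; deletions (`-`) and
introns (`~`) consume target only. Records of one read (primary plus
supplementary; secondary records excluded) are unioned by query
coordinate, so overlapping split alignments never double-count. Between
two assemblies, a read maps "more than 5% better" when the absolute
difference of its mapped fractions strictly exceeds 0.05 — read as
percentage points of the read, the natural unit for a percentage of
mapped bases; reads absent from one side score 0 there.

# The synthetic-data generator

`genome_plan()`/`generate_genome()` build seeded random genomes (default
background GC 0.41, a typical mammalian value) with planted telomere
arrays, satellite blocks (tandem copies of a fixed 60 bp monomer),
guaranteed-GC windows, dispersed duplications with diagnostic
substitutions (one per 200 bp of copy by default), and dark/camouflaged
zones. Overlapping sequence-writing features are rejected with a clash
report. A single integer seed determines every byte of output; global RNG
state is saved and restored around every draw, and per-sample streams are
split deterministically from the one seed.

`degrade_assembly()` turns the genome into a gapped "old" assembly:
at each planned position it removes `replaced_length` true bases under an
N-run of `n_length`, and with `overlap_length > 0` the bases before the
gap reappear after it, so the lifted flanks overlap — an artificial gap
when nothing was removed at all. `simulate_tracks()` draws window depth
from a negative binomial (dispersion `size` = 20 by default, giving a
variance/mean ratio of about 2.5 at 30x, typical of short-read coverage)
with dark zones at 0.5x, duplication regions scaled by planted diploid
copy number, and high-MQ fractions from Beta distributions with means
0.98 (background) and 0.02 (camouflaged zones). For duplications,
`hom_copies` is the diploid count of homologous copies the simulated
individual carries (independent of how many copies were written into the
assembly string), which is what depth and allelic-depth simulation use.
`simulate_cs_alignments()` emits PAF records with cs strings for an intact
assembly and for one with planted deletions, including split
(supplementary) records with overlapping query spans and duplicate
secondary records that consumers must ignore; its truth is the exact
query-union fraction per read.

What the generator does *not* emulate: read-level errors and quality
profiles, GC-dependent coverage bias, library artefacts, alignment noise
at repeat boundaries, or indel-containing flank placements. Passing the
recovery checks therefore demonstrates the correctness of the decision
rules and estimators under their stated models, not robustness to every
artefact of real sequencing data.

# Problem sizes and numerical choices

The test suite exercises: a 2 Mb assembly pair with 200 planted gaps (150
closable, 20 artificial, 30 with ambiguously duplicated flanks); 25
simulated samples at 30–90x over a 5 Mb genome with 30 dark and 20
camouflaged zones; 50 seeded replicates of a 3-copy duplication at 30x;
10,000 cs-tagged reads; and 10,000 patch variants — sizes chosen so the
whole suite completes in a couple of minutes on one core while keeping
every estimator's sampling error far from its pass boundary. Exact-oracle
checks (consensus counting, base partition, telomere chaining, N50/L50,
ORF scan, Hamming placement) compare against independently coded
brute-force implementations.

Tie-breaks and degenerate inputs: equal-best flank placements report the
first candidate with mapq 0; empty consensus eligibility skips the window;
zero-length fills are closed, not artificial (only strictly overlapping
flanks are artificial); all-N windows propagate NA rather than 0; and
`covered_fraction` refuses zero-length targets.

# Limitations

The built-in flank mapper models substitutions only; the dark/camouflaged
caller consumes precomputed tracks and inherits whatever filtering
produced them; CpG island scoring follows the classic criteria rather than
any particular tool's variant; and the transcript filters operate on
supplied models and BLAST coverages — they re-apply published decision
rules, they do not re-derive annotations.
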