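---
title: "Methods: VLRB repertoire analysis from long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VLRB repertoire analysis from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological system and the measurement problem

Jawless vertebrates (lampreys, hagfish) mount adaptive immune responses with
variable lymphocyte receptors (VLRs) built from leucine-rich repeats (LRRs)
rather than immunoglobulin domains. The secreted antibody of this system,
VLRB, is assembled somatically from a cassette library into a mature protein

SP → LRR-NT → LRR1 → LRRv × (k−1) → LRRve → CP → LRR-CT → stalk,

where the signal peptide (SP, 21 aa) and the invariant stalk (87 aa) come from
the single germline gene, the capping LRR-NT (31 aa) and LRR-CT flank the
variable region, LRR1 (18 aa) is the conserved first repeat, and diversity is
carried by 1–9 variable 24-aa LRRv cassettes (the most C-terminal one is
called the LRRve) joined through an 11-aa connecting peptide (CP) to the
LRR-CT, which displays a variable loop between a conserved tryptophan and a
conserved cysteine. Because the number of incorporated LRRv units varies,
mature transcripts differ in length by whole 24-aa steps — which is why
long-read (HiFi) amplicon sequencing, rather than a fixed-length short-read
protocol, is the natural measurement, and why the analysis must annotate each
molecule structurally instead of aligning to a fixed reference.

`vlrbkit` implements the complete analysis path from multiplexed HiFi
amplicon reads to a structurally annotated, consensus-filtered repertoire
with clustering, cross-animal sharing and amino-acid property analytics —
plus a synthetic repertoire/read simulator so every stage can be validated
against a known ground truth without any external data.

## Amplicon model and preprocessing

The amplicon design is encoded in `vlrb_config()`: a forward PCR primer
`TAT + 6-nt barcode + GTGGATCAAGTGGATCGC` whose constant segment anneals in
the invariant SP coding sequence; an RT oligonucleotide carrying the
antisense-primer annealing site, a 12-nt unique molecular identifier (UMI)
and a stalk-region annealing segment; and a reverse PCR primer
`TAT + 6-nt barcode + CCAGCACACTGGATCAG`. The trimmed insert therefore starts
with the SP-annealing segment — which anchors the reading frame at insert
position 0 — and ends at the stop codon. In the simulator the stalk-side
annealing site is modeled immediately downstream of the stop codon, so
trimming the UMI tail never truncates the 87-aa stalk open reading frame.

Preprocessing follows a discard-on-imperfection philosophy appropriate for
high-accuracy HiFi reads:

* **Demultiplexing** (`demultiplex()`) requires exact matches of both primer
  constant segments at their fixed offsets on either strand, and agreement of
  the two 6-nt barcodes with the barcode table. Primer matching is
  case-insensitive (the printed forward primer mixes cases); no indel
  tolerance. Rejection reasons are reported per read.
* **UMI collapse** (`collapse_umi_bins()`) bins reads by sample and exact
  UMI. Within a bin, reads are single-linkage clustered at ≥ 99 % nucleotide
  identity; a single cluster collapses to one molecule by position-wise
  majority vote (ties resolve to the most frequent full-length member, then
  lexicographically), while a bin with > 1 % internal divergence is discarded
  whole, since it most likely mixes distinct molecules under one UMI.
* **UMI-neighbor removal** (`remove_umi_neighbors()`) treats molecules of one
  sample with identical sequences whose UMIs differ by ≤ 1 nt (of 12) as PCR
  mutations of one UMI. Neighbor graphs are resolved per connected component
  to the single member with the highest read support (ties keep the
  lexicographically smallest UMI). Keeping the best-supported member is this
  package's choice; removing both members would discard real molecules.

Identity between length-mismatched sequences is computed from a unit-score
global alignment (match +1, mismatch −1, gap −1), counting identical aligned
columns, with ties between co-optimal alignments broken toward more matches
so the statistic is deterministic; equal-length pairs use the position-wise
(Hamming) shortcut. For the collapse step the denominator is the longer
sequence length: for the ≥ 99 %-identical pairs this step screens, the
optimal alignment gaps only the length difference, so this equals the
alignment length.

## ORF filtering and structural annotation

Translation starts at insert position 0 (`translate_from_start()`); no
three-frame search is needed because the amplicon anchors the frame. A stop
codon before the final codon marks a premature stop; a terminal stop is
trimmed. Retained proteins must then carry the 30-aa diagnostic stalk motif
`DCGKPACTTLLNCANFLSCLCSTCALCRKR` with at most 2 substitutions in the best
ungapped window (`match_stalk()`; ties go to the most C-terminal window).
Records with 3 or more differences, or no window, are removed. Ungapped
matching is deliberate: an indel-bearing stalk would fail the 87-aa stalk
length filter anyway. The stalk subunit is the 87-aa region ending at the
C-terminus; the motif occupies its last 30 residues, so a motif that is not
flush with the C-terminus produces an off-length stalk that the consensus
filter later removes.

Identical proteins are collapsed per sample (`dedup_proteins()`), with the
number of collapsed molecules kept as the record's abundance.

Annotation (`annotate_protein()`) is fully deterministic and ungapped:

* **LRR1**: 18-residue windows are scanned from the end of SP (position 21)
  through the expected LRR-NT region plus a 20-residue margin; a window
  matches when all five conserved residues of `xLxLxxNxxxxLxxxxFx` are
  identical at their positions. The most N-terminal match wins. LRR-NT is
  defined residually as `[21, LRR1 start)`; no separate LRR-NT detector
  exists, and its 31-aa filter constrains it downstream.
* **LRRv**: the region from LRR1's end toward the stalk is tiled in 24-aa
  candidate units; a unit is accepted when the four conserved leucines of
  `xLxxLxxLxLx` match exactly at some offset. Tiling stops at the first
  failing unit, which marks the CP/LRR-CT region; the last accepted unit is
  the LRRve. Gapped-alignment variants of both detectors are not provided:
  every record surviving the exact 18/24-aa length filters is gap-free, so
  on the final dataset the two modes coincide and the ungapped rule is the
  simpler, deterministic one (the `lrrv_min_segment` config field is kept
  for interface completeness but is inert in ungapped matching).
* **CP and the loop**: CP is defined positionally as the 11 residues after
  the LRRve (a template-alignment definition would depend on the dataset);
  the remainder up to the stalk is the LRR-CT. Within it, the anchor pair is
  the first tryptophan and the first cysteine at least 7 residues downstream
  (`Wxxx-loop-xxC`): the core loop spans W+4 … C−3 inclusive and the extended
  loop spans W … C inclusive, so extended = core + 7 always. A 15-residue
  core loop yields a 22-residue extended loop.

All coordinates are 0-based half-open spans in protein coordinates, and a
failed detection is a status (`no_lrr1`, `no_lrrv`, `no_loop`), never an
error, so stepwise accounting stays exact.

## Consensus filter, clustering, sharing

`apply_consensus_filter()` applies six length checks **sequentially** —
LRRv 24 aa (and ≥ 1 unit), LRR1 18 aa, LRR-NT 31 aa, stalk 87 aa, SP 21 aa,
CP 11 aa — charging each rejected record to the first failing step. The
order matters for the per-step counts and is part of the method.

`greedy_cluster()` re-implements greedy incremental clustering in the CD-HIT
convention: sequences sorted by decreasing length (ties lexicographic), each
joining the first cluster whose representative reaches the identity
threshold, with the shorter sequence length as denominator. No k-mer
prefilter is used — at the scales this package targets, exact greedy
clustering is affordable and removes a heuristic source of divergence. One
consequence of the shorter-sequence denominator worth knowing: a protein
that differs from a longer one only by a whole extra cassette can reach
identity 1.0, so even a 100 % threshold does not always split nested
sequences. The cluster-size cumulative distribution (`cluster_size_cdf()`)
serves as a surrogate diversity measure, and `threshold_sweep()` reports,
per threshold, the total cluster count and the percentage of sequences in
the N largest clusters, N being the genomic locus count of the subunit.

`shared_sequences()` counts distinct proteins present with 100 % identity in
at least k animals (k = 2 … n); fractions are relative to the combined
number of per-animal unique proteins, matching the convention in which a
protein found in two animals contributes two records to the denominator.

## Amino-acid properties

Hydropathy is the grand average of hydropathy (GRAVY) over the
Kyte–Doolittle scale; polarity averages the Grantham polarity scale. Both
scales ship as exported named vectors (`aa_hydropathy`, `aa_polarity`) and
every scoring function accepts a replacement scale. Positional statistics
group LRRv units by ordinal position with the LRRve as its own group
(molecules with a single variable unit contribute only to the LRRve group);
summaries are mean ± sample SD (n−1 denominator; a single observation
reports SD 0 so degenerate groups stay numeric). Extended loops are split
into high/low hydropathy groups at 0.35, the published bimodality threshold,
which is configurable (`hydropathy_split`). Position frequency matrices are
column-stochastic with the per-position majority residue attached.

## The simulator: what it emulates, and what it does not

`sim_config()` / `build_cassette_library()` / `simulate_repertoire()` /
`simulate_reads()` generate a complete synthetic study. Choices and
rationale:

* **Cassette counts** default to the published genomic locus counts
  (SP 1, LRR-NT 79, LRR1 66, LRRv 601, CP 29, LRR-CT 91, stalk 1).
* **LRRv count per molecule** is truncated-geometric on 1…9 with mean 2.2,
  matching the reported average of ≈ 2.2 variable units per molecule.
* **Core-loop lengths** are drawn uniformly on 10–25 aa, covering the
  reported mean 16.6 ± 2.3 and mode 15; no generative model for loop length
  is published, so uniform is the assumption-light choice.
* **Sharing**: 1.7 % of transcripts are copied verbatim into a second animal
  (replacing one of its molecules, so per-animal totals are preserved). The
  biological mechanism of public sequences is not modeled, only the
  observable.
* **Errors**: substitutions at 0.1 % per base (HiFi-scale accuracy), applied
  independently per PCR duplicate; duplicates per molecule are
  1 + Poisson(0.4), consistent with the reported reads-to-molecules ratio.
  Roughly half of all reads are emitted reverse-complemented.
* **Nonfunctional molecules** (default 5 %) get either a random in-frame
  stop codon or a 1-nt deletion. Lesions are placed in the variable body —
  downstream of the 18-nt primer-annealing segment and upstream of the
  stalk-coding region — because lesions inside primer-annealing segments
  would be masked by the primer oligo in the amplicon (and would surface as
  demultiplexing failures, not as the ORF-filter removals this models). The
  much larger nonfunctional fraction observed in the original tissue data is
  attributed by its authors to co-purified immature lymphocytes and
  platform artifacts, not to a property of the circulating repertoire, so
  the default models a mature repertoire.
* **Reverse translation** uses one fixed codon per amino acid. Protein-level
  behavior is unaffected; nucleotide-level identity thresholds are still
  exercised through substitution errors. The first six SP residues (VDQVDR)
  reverse-translate exactly to the forward-primer annealing segment, which
  is what anchors the reading frame.
* **Filler alphabet**: non-conserved cassette positions are drawn from the
  15 residues excluding L, N, F (motif-conserved letters) and W, C (loop
  anchors). Consequently motif hits and anchor pairs occur exactly where the
  architecture places them, and ground-truth recovery can be asserted
  exactly. This is the simulator's strongest idealization: real cassettes
  contain leucines and cysteines outside conserved positions, so real data
  can contain spurious motif windows that shift a detection. Passing the
  recovery tests therefore demonstrates correctness of the machinery, not
  robustness of motif detection on adversarial real sequences. UMI
  collisions, by contrast, are *not* idealized away: UMIs are drawn freely,
  and the validation accounts for natural collisions through the truth
  table.

## Numerical and engineering choices

* Spans are 0-based half-open everywhere; conversions happen only at R's
  1-based string boundaries, inside the accessors.
* The alignment primitive is a row-vectorized dynamic program over an
  encoded (score, matches) pair, making the tie-break exact rather than
  implementation-defined; tests cross-check its scores against an
  independent aligner and its match counts against an anti-diagonal
  re-implementation.
* All randomness flows through explicit seeds; the pipeline itself is
  deterministic, and re-running it on the same reads reproduces the run
  report bit-for-bit (timings aside).
* Validation problem sizes: the ground-truth recovery suite uses 10,002
  molecules across 6 animals (1,667 each) with 5 % nonfunctional records,
  the clustering oracle uses 50 random families of 15–100 sequences at six
  thresholds, and the property-score oracle uses 1,000 random peptides —
  sizes at which the package's exact (non-heuristic) algorithms run in
  seconds to a couple of minutes on one core while still exercising every
  code path at realistic multiplicities.

## Known limitations

* Study-scale dataset quantities (millions of reads; the retained counts,
  shared-sequence counts and per-threshold cluster counts reported for real
  lamprey sequencing runs) require such a dataset and are out of scope here;
  the operations that produce them are validated on synthetic data instead.
* Gene-conversion mechanics (partial cassette templates, multiple priming
  sites) are not modeled; cassettes are sampled whole. Real repertoires show
  more LRRv diversity than whole-cassette sampling produces.
* Quality scores are ignored throughout (HiFi reads are treated as
  high-accuracy strings), and chimeric PCR products are not simulated.
* Statistical significance tests annotated on the original figures (t-tests,
  ANOVA) are not reproduced; the package emits the underlying summary
  statistics.
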