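# vlrbkit

Repertoire analysis of **variable lymphocyte receptor B (VLRB)** antibodies —
the leucine-rich-repeat (LRR) based antibodies of jawless vertebrates such as
the sea lamprey — from long-read (PacBio HiFi) amplicon sequencing.

Unlike immunoglobulins, mature VLRB proteins are assembled somatically from a
cassette library into

```
SP — LRR-NT — LRR1 — LRRv × (k−1) — LRRve — CP — LRR-CT — stalk
      31 aa    18 aa        24 aa each      11 aa  (loop)   87 aa
```

with 1–9 variable LRRv units, so transcripts differ in length by whole 24-aa
steps and cannot be analyzed with fixed-length short-read protocols. This
package takes multiplexed HiFi amplicon reads through:

1. **Demultiplexing** — exact primer/barcode matching on either strand, with
   per-read rejection reasons;
2. **UMI error correction** — reads sharing a 12-nt UMI collapse to one
   molecule at ≥ 99 % identity (divergent bins are discarded), then 1-nt UMI
   neighbors of identical molecules are removed;
3. **ORF filtering** — frame-anchored translation, premature-stop removal,
   and detection of the invariant 30-aa stalk motif
   `DCGKPACTTLLNCANFLSCLCSTCALCRKR` tolerating ≤ 2 substitutions;
4. **Structural annotation** — LRR1 via the conserved residues of
   `xLxLxxNxxxxLxxxxFx`, LRRv units by 24-aa tiling on the conserved leucines
   of `xLxxLxxLxLx`, CP, and the LRR-CT loop between the conserved W and C
   anchors (`Wxxx-loop-xxC`; extended loop = core loop + 7 flanking
   residues);
5. **Consensus filtering** — sequential length checks (LRRv 24, LRR1 18,
   LRR-NT 31, stalk 87, SP 21, CP 11 aa) with per-step accounting;
6. **Repertoire analytics** — CD-HIT-style greedy identity clustering with
   cluster-size CDFs and threshold sweeps, cross-animal sharing of identical
   proteins, Kyte–Doolittle hydropathy (GRAVY) and Grantham polarity
   statistics per LRRv position, and the bimodal hydropathy split of
   extended loops at 0.35.

A first-class **simulator** generates cassette libraries (locus counts
SP 1 / LRR-NT 79 / LRR1 66 / LRRv 601 / CP 29 / LRR-CT 91 / stalk 1),
ground-truth repertoires (mean ≈ 2.2 LRRv units/molecule, configurable
sharing and nonfunctional fractions) and barcoded, UMI-tagged reads with PCR
duplicates and substitution errors — so the full pipeline is testable
against exact ground truth without any external data.

## Worked example

```r
library(vlrbkit)

scfg <- sim_config(molecules_per_animal = 200, error_rate = 0.001,
                   nonfunctional_fraction = 0.05)
lib <- build_cassette_library(scfg, seed = 42)
tx  <- simulate_repertoire(lib, scfg, seed = 43)
rd  <- simulate_reads(tx, scfg, seed = 44)
res <- run_pipeline(rd$reads)
print(res$report)
```

```
VLRB pipeline run report
  reads                          1704
  rejected (primer/barcode)       120
  demultiplexed                  1584
  UMI molecules                  1156
  UMI neighbors removed             1
  premature stop (8a)              81
  no stalk (8b)                     0
  unique proteins                1074
  no LRR1 (10a)                     9
  no LRRv (10b)                     4
  no loop (11)                      5
  annotated                      1056
  filter lrrv_length                0
  ...
  filter stalk_length               3
  retained                       1053
```

Reading it: 1,704 reads from 1,200 simulated molecules across 6 animals;
120 reads carried a substitution inside a primer/barcode segment and were
discarded (exact-match rule). UMI collapse left 1,156 molecules (duplicate
reads merged; bins mixing distinct molecules under one UMI dropped), one
1-nt UMI neighbor was removed, the 81 premature stops are the injected
nonfunctional molecules, and 18 error-bearing molecules failed structural
annotation. The stepwise counts telescope by construction — each stage's
output is the next stage's input.

```r
res$properties$lengths$summary   # mean LRRv units 2.21; core loop 16.8 ± 4.7 aa
head(res$sharing, 1)             # k=2: 5 proteins shared by ≥2 animals (0.47 %)
head(res$properties$positional[, c("group", "n", "hydropathy_mean")], 2)
#   group   n hydropathy_mean
# 1 LRRv1 582      -0.2599227
# 2 LRRv2 318      -0.1869759
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/vlrbkit.R", package="vlrbkit"))')" \
  simulate --seed 7 --out-dir sim_out
Rscript .../vlrbkit.R run-all --reads sim_out/reads.fastq --out-dir run_out
```

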