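# ervscan

Discovery, classification and expression profiling of endogenous
retrovirus (ERV) protease loci — a desk-scale, fully seeded
re-implementation of the analysis chain used to survey ERVK protease
diversity in a genome.

## Who this is for

Researchers who want to study retroviral protease (PR) and reverse
transcriptase (RT) remnants — where they sit in a genome, which ERV clade
they descend from, whether their active-site motifs could support an
active enzyme, and how their transcription differs between conditions —
without depending on licensed repeat libraries, external aligners, or
network downloads. Every stage runs against a built-in synthetic-data
generator with known ground truth, so the whole pipeline is testable
offline.

## What it computes

* **Six-frame translated search** (Smith–Waterman over BLOSUM62, stop
  codons penalized at −10), frame-split hit merging, and flush extension
  of hits to full query length.
* **LTR retroelement detection** as similar direct-repeat pairs
  (12-mer seeds, X-drop extension, ≥ 85% identity over 100–1000 bp at
  1–15 kb spacing), with the domain co-occurrence rule that discards
  standalone RVT_1 (LINE-like) matches.
* **Curation and locus grouping**: gap-induction removal (≥ 95% rule),
  half-length domain flags, single-linkage loci at ≤ 10 kb separation,
  exact-duplicate classes, 15-kb flank matching against alternative
  assemblies.
* **Codon-aware alignment** with frameshift (`!`, `!!`) and stop
  annotation; protein distances `d = −ln(1 − p − 0.2 p²)`.
* **Evolutionary placement**: neighbor-joining reference tree, per-edge
  pendant attachment under a fixed amino-acid model, likelihood-weight
  verdicts (clade / UNPLACED below 0.90 / INTERNAL).
* **Protease motif triage**: B1/C2 extraction by consensus anchoring and a
  data-driven three-tier activity classifier
  (PREDICTED_ACTIVE / POTENTIALLY_ACTIVE / PREDICTED_INACTIVE) that
  reproduces all 58 rows of the published ERVK motif survey shipped in
  `inst/extdata/ervk_motif_survey.tsv`.
* **Expression contrasts**: per-locus fragment counts from SAM,
  `FPKM = count / (len/1000) / (lib/10⁶)`, exact Mann–Whitney / Wilcoxon
  signed-rank tests (full null enumeration at small n), explicit
  Bonferroni families, and a Gag co-expression check.

## Worked example

```r
library(ervscan)

refs <- make_reference_set(rng_seed = 7)          # 10-clade HML-like library
cfg  <- simulation_config(genome_length = 3e5, n_elements = 6,
                          substitution_rate = 0.02, stop_prob = 0,
                          fs_prob = 0, solo_ltr_prob = 0, rng_seed = 71)
sim  <- plant_proviruses(cfg, refs)               # genome + truth
rq   <- reference_queries(refs)                   # PR/RT queries + PSSMs

disc <- run_discover(sim$genome, rq$queries, rq$profiles)
nrow(disc$annotations); nrow(disc$loci)
#> [1] 24
#> [1] 6

pr  <- disc$annotations[disc$annotations$kind == "PR", ]
res <- run_classify_motifs(sim$genome, pr, refs)
res$classified[1:3, c("start", "end", "verdict", "weight")]
#>   start   end verdict weight
#> 1  9080  9398    HML1      1
#> 2 61922 62240    HML2      1
#> 3 87257 87575    HML4      1
res$motif_table
#>   count    b1    c2           activity
#> 1     3 DTGAD GRDLL   PREDICTED_ACTIVE
#> 2     1 DTEVD GRDLL POTENTIALLY_ACTIVE
#> 3     1 DTGAD GQDLL POTENTIALLY_ACTIVE
#> 4     1 DTVAD GRDLL POTENTIALLY_ACTIVE
```

All six planted elements are rediscovered (24 annotations: each element
is seen by both the translated-search and profile-scan routes for both PR
and RT), every one is placed into its true clade with placement weight 1,
and the planted B1/C2 motif pairs are recovered verbatim and triaged: the
canonical `DTGAD+GRDLL` pairs are predicted active, while the planted
single-deviation variants (`DTEVD`, `DTVAD`, and the `GQDLL` helix) land
in the potentially-active tier — matching their published classes.

Checking the classifier against the published motif survey:

```r
survey_concordance()$concordance
#> [1] 1
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ervscan-cli.R", package="ervscan"))') \
    all --seed 1 --out run1
```

Subcommands: `simulate` (requires `--seed`), `discover`, `classify`,
`motifs`, `express`, `all`. Outputs are FASTA / GFF3 (1-based) / SAM /
newick / TSV, plus a `run.log` and the exact `config.used`.

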