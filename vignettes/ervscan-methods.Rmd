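---
title: "ervscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ervscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Endogenous retroviruses (ERVs) are the genomic remnants of ancient
retroviral infections. The human ERVK group (Betaretrovirus-like, clades
HML1–HML10) still carries recognizable *gag–pro–pol* coding regions, and a
subset of its protease (PR) loci could, if transcribed and translated,
produce an active aspartic protease — an enzyme class with documented
immunological and pathological effects in exogenous retroviral infection.
`ervscan` re-implements, at desk scale and fully seeded, the analytical
chain needed to study this question on synthetic or user-supplied data:

1. **discover** PR/RT-like coding regions (six-frame translated local
   alignment + PSSM profile scan + direct-repeat LTR detection),
2. **curate and group** hits into loci,
3. **classify** loci into ERV clades by evolutionary placement on a
   reference phylogeny,
4. **triage** protease active-site motifs into predicted activity tiers,
5. **contrast** locus-level expression (FPKM) between disease conditions
   with nonparametric tests.

Every stage is testable offline because the package carries its own
generator of genomes with planted, ground-truthed proviruses.

# Models and procedures

## Translated homology search

A protein query is aligned locally (Smith–Waterman, BLOSUM62, gap open 11
/ extend 1 — common translated-search defaults, since none are published
for this procedure) against all six frame translations of the target.
Stop codons translate to `*` and score −10 against everything: an
interrupted ORF still aligns but pays for each stop, and interruption is
flagged explicitly downstream rather than hidden by the aligner. The
minimum reported score (75) was fixed once so that a 106-aa protease at
30% amino-acid divergence is comfortably recovered while the best random
106-aa alignment in a 12-kb window stays far below it.

Megabase targets are scanned with an *ungapped prescan*: the query is
swept over every offset of each frame translation (a vectorized
profile-sum), and only regions scoring ≥ 40 matrix units are given to the
full dynamic program. Exact-word seeding (BLAST's default trick) was
rejected after measurement: clade relatives at ~40% amino-acid identity
share essentially no exact 4-mers with a single query, whereas the scored
sweep keeps them. Targets that fit in one chunk are always aligned
exhaustively; that exact path is the one verified against a plain-R
Smith–Waterman oracle.

Hits from one gene split across frames (a hallmark of degraded ERVs) are
merged by single-linkage closure when they lie on the same strand within
1 kb and their query intervals are collinear (≤ 5 aa overlap). Merged
hits are extended "flush": 3 nt per missing query residue on either end,
clipped at contig bounds, so the retrieved nucleotide region always
covers a full-length protease if one is present.

## LTR retroelement detection

Candidate proviruses are pairs of similar direct repeats: exact 12-mer
seeds at a 1–15 kb separation, extended ungapped under an X-drop rule,
and kept when the repeat is 100–1000 bp at ≥ 85% identity (LTRharvest-like
scales; none are published). Overlaps resolve by identity, then length.
Profile-scan domain hits are retained only when their element carries a
second core retroviral domain of a different kind — the co-occurrence rule
that removes standalone RVT_1 matches contributed by LINE machinery.

## Codon-aware alignment

Nucleotide sequences are aligned *via their translations*. Each sequence
is first segmented into codon units by a small dynamic program that may
consume 1–2 nt at a penalty (a frameshift slip) and pays for internal
stops; leading/trailing partial codons are free (truncation is not a
frameshift). The segmented translations are aligned progressively (UPGMA
guide tree on k-mer distances, affine-gap profile–profile DP over expected
BLOSUM62 scores), and nucleotides are threaded back as intact codons.
Slips appear as `!` / `!!` in the nucleotide rows; removing `-` and `!`
from any row reproduces its input byte-for-byte — an invariant asserted on
every alignment the tests build. The exact slip column can float inside
the window where both reading frames are stop-free; tests therefore
assert the slip's neighborhood, not its exact coordinate.

Stop evidence alone cannot see every slip: a 1-nt deletion a few codons
into the protease whose frame happens to be compensated by the extraction
boundary translates cleanly end-to-end. When an intact reference is
available (as in the classification stage), rows are therefore segmented
*against the reference*: a pairwise nucleotide alignment supplies the
codon phase, and indels that are not a multiple of three become slips.
The gap penalties of that alignment (open 16, extend 4) are sized so that
an offsetting indel pair must buy roughly 25 nt of frame-restoration
signal — above the noise level of diverged rows, below any real slip
except one sitting within a few codons of the boundary, which no method
could distinguish from terminal divergence. Full MACSE-style
frameshift-aware alignment scoring is still not reproduced; the
analytical purpose of the stage is the stop/frameshift annotation that
gates the motif table.

Protein distances use the Kimura-style correction
`d = −ln(1 − p − 0.2 p²)` over shared non-gap columns; pairs beyond the
formula's domain (or sharing no columns) are reported as undefined rather
than clamped.

## Reference phylogeny and placement

The labeled reference tree is neighbor joining (`ape::nj`) on those
distances, negative branch lengths clamped to zero. Queries are
profile-aligned to the frozen reference columns, then attached to every
edge midpoint by a pendant branch optimized over a log grid
(1e-4 … 5.0; the upper end reaches the stationary regime, so a sequence
unrelated to every reference scores near-equally on all edges and falls
below the weight threshold instead of placing confidently somewhere
arbitrary); per-edge likelihoods are normalized into placement weights.
A query is UNPLACED below weight 0.90 (the published rule), takes a clade
label when one side of its best edge contains a single clade's leaves,
and is INTERNAL on the spine between clades.

The likelihood model is a single-rate F81-style amino-acid model
(uniform exchangeabilities; stationary frequencies estimated from the
reference alignment, with closed-form transition probabilities) rather
than the JTT matrix used with RAxML in the original procedure.
The classifications this package relies on are driven by deep,
well-separated clades, and parameter-recovery tests show 100% clade
recovery at ≤ 10% query divergence under this model; embedding a
published 190-parameter exchangeability matrix would add surface without
changing a verdict. Stationary frequencies can also be set uniform
(`placement_engine(freq = "uniform")`), which makes per-site mismatch
costs residue-independent. Likelihood-weight placements are sharp: one
extra matching residue toward one of two sister leaves decides the edge
(roughly five log-likelihood units per site), which is why the "midpoint
query" test constructs an exactly symmetric reference world and an
exactly balanced intermediate — under any asymmetry the concentrated
placement is the correct answer, not a defect.

## Motif triage

B1 (active-site loop, canonical `DTGAD`) and C2 (helix, canonical
`GRDLL`) columns are anchored by the consensus of intact reference rows;
per-row motifs keep gaps as missing residues. Rows with a stop or
frameshift anywhere in the mature PR span are excluded from frequency
tables — interruption, not sequence, is what disqualifies them.

The activity classifier is data (a loadable rule set), not code. The
shipped rules encode: strict catalytic aspartate at B1-1; Thr→Ser
tolerated at B1-2; small/charged substitutions of the B1-3 glycine count
as a deviation; B1-4 admits the residues observed in active exogenous
retroviral proteases; B1-5 admits Asp/Asn/Glu *without* deviation (its
character is not critical); C2 requires Gly, a large polar residue,
an acidic/His position, and the two leucines (Ile tolerated at position
4). A pair is PREDICTED_ACTIVE only as canonical `DTGAD|DTGVD` +
`GRDLL`; it is PREDICTED_INACTIVE when any residue leaves its allowed
set, a motif is not 5 residues, B1 accumulates two deviations, or B1 and
C2 deviate simultaneously; otherwise POTENTIALLY_ACTIVE. Two of these
clauses (the B1 two-deviation demotion and the deviation-free status of
B1-5 variants) were fixed by checking every row of the published ERVK
motif survey shipped in `inst/extdata/`; the shipped rules reproduce all
58 published rows, and `survey_concordance()` regenerates that check with
an exception report whenever the rules are edited.

## Expression

Fragments count once per locus on ≥ 1 bp overlap of their primary
alignment; the library size is the sample's total mapped primary
fragments ("normalized by library size"), and
`FPKM = count / (len/1000) / (lib/10⁶)`, so the conservation identity
`Σ FPKM·(len/1000)·(lib/10⁶) = Σ counts` holds exactly and is asserted
numerically. Rank tests enumerate the exact null for small samples
(unpaired ≤ 16 observations, paired ≤ 12; ties by average ranks, two-sided
by doubling) and fall back to the tie-corrected normal approximation with
continuity correction. Bonferroni families are explicit: all contrasts
sharing a variable set form one family. Multi-mapped reads: only primary
alignments count (the choice is logged; ERV multi-mapping is pervasive
and the original procedure is silent). Zero-count loci stay in group
distributions at FPKM 0. Normality screening is a reported diagnostic,
never a gate.

# The synthetic world

`simulation_config()` defaults *are* the acceptance conditions: a 2-Mb
i.i.d. uniform background, 50 non-overlapping proviruses at 10%
nucleotide divergence from their clade references, 10% premature-stop and
10% frameshift injection (so ~81% of non-solo elements intact), 10% solo
LTRs, LTR length 300 bp. Planted motifs are drawn from the published
vocabulary weighted by its counts; motif codons are never mutated — the
assigned motif *is* the element's ground truth — and reference evolution
likewise holds motif codons fixed, mirroring their conservation across
the real clade consensa. Frameshifts are single-nucleotide deletions
inside the PR ORF; stops are planted codons; background substitution in
coding regions rejects stop gains so that "intact" in the truth table is
exact. Reads are error-free, single-end, plus-strand, drawn
∝ abundance × locus length with uniform placement.

What the generator does *not* emulate: repeat-rich background (so
false-positive rates on real genomes will be higher than here), sequencing
error and quality strings, LTR promoter structure, recombination between
elements, and paired-end fragments. A green test therefore establishes
algorithmic correctness on a clean world, not performance on GRCh38. One
honest consequence visible in the defaults: at 10% per-copy divergence
the two LTRs of an element are ~82% identical, *below* the 85% detection
threshold, so most aged elements are not recoverable by direct-repeat
finding alone — which is exactly why discovery does not depend on it.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; 1-based inclusive only in
  GFF3/SAM. Minimum LTR spacing is 1001 bp because the detector's own
  precondition (spacing > maximum LTR length of 1000) forbids 1000.
* Gap-induction removal is inclusive (`≥ 95%`), computed once against the
  original alignment; the half-length domain flag is strict (`<`) and
  annotates without deleting.
* Exact-identity flank matching tolerates clipped ends (100% identity over
  ≥ 99% of the available flank); "partial" means a local alignment
  covering ≥ 20% of the flank at ≥ 90% identity. These thresholds are
  configuration, not constants.
* Placement ties (Δlog-likelihood < 1e-9) resolve to the lowest edge id;
  UPGMA guide-tree ties resolve lexicographically by sequence id.
* An all-zero paired contrast returns p = 1 with a warning; an element
  drawing both a stop and a frameshift records "stop" (the enum has no
  "both" at the element level, and the intact-fraction expectation is
  unaffected).

# Known limitations

Single-end read simulation only (counting nevertheless implements the
mates-count-once rule); no Γ rate heterogeneity or model selection in
placement; the LTR finder is seed-limited (a repeat pair with no shared
12-mer is invisible to both the implementation and its oracle); the
progressive aligner is O(n²·L²) and meant for dozens, not thousands, of
rows; bootstrap support is replaced by placement weights throughout.
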