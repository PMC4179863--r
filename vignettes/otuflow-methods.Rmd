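---
title: "otuflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{otuflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otuflow)
```

otuflow processes multiplexed 16S rRNA amplicon sequencing runs into
sample-by-OTU abundance tables with taxonomic annotation. This vignette
explains the models and procedures behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## The two-bin filtering model

Reads are demultiplexed by 5' barcode (Hamming distance within a budget;
ties between barcodes leave the read unassigned rather than guessing, to
avoid cross-sample bleed), primer-checked with IUPAC-aware matching, and
then sorted into three piles by a single pass of `classify_read()`:

* **high quality** — passes every structural filter (length bounds,
  ambiguous-base count, homopolymer run) *and* both quality thresholds:
  mean Phred quality `min_avg_qual` (default 27) and accumulated expected
  error `max_expected_error` (default 1.0), where the expected error of a
  read is $\sum_i 10^{-Q_i/10}$. Only these reads found OTUs, which keeps
  sequencing noise from inflating diversity.
* **mid quality** — passes the structural filters but fails a high-band
  quality threshold while staying inside a relaxed band: expected error at
  most `mid_relax` (default 4) times the high-band limit and mean quality
  within `mid_qual_slack` (default 5) Phred of it. Mid reads never found
  OTUs; they are only mapped onto established OTUs for counting, so they
  contribute abundance without contributing spurious clusters.
* **rejected** — everything else, tagged with the first failing criterion
  in a fixed precedence (`too_short`, `too_long`, `ambiguous`,
  `homopolymer`, `avg_qual`, `expected_error`) so reports are
  deterministic.

The mid band's exact definition is this package's own: the two-bin intent
is well established but no precise boundary is standard. The multiplicative
relaxation on expected error and additive slack on mean quality were chosen
because they relax both criteria proportionally to how each is expressed
(error is multiplicative in read length, Phred is logarithmic).

Before binning, a sliding window (default 50 bp, mean threshold 25) scans
from the 5' end and truncates the read at the start of the first window
whose mean quality falls below the threshold. Because base quality decays
toward the 3' end on both 454 and Illumina platforms, the default removes
the 3' tail and preserves the 5' region; a mirrored 5'-trimming mode is
available via `trim_direction = "5p"` for chemistry where the head is the
problem. Note the window rule is a genuine sliding scan: a window that
merely straddles the quality cliff already triggers the cut, so the kept
length is typically a few bases short of the cliff itself.

Clustering input is the high bin truncated to `truncation_len` (default
250 bp, the usual choice for 454-era pipelines): clustering wants a common,
high-confidence prefix, while abundance mapping and seed extension use the
full-length reads.

## OTU construction and abundance

Truncated high-quality reads are dereplicated exactly and clustered
greedily in descending abundance order: a sequence joins the first existing
centroid within the identity radius (default 0.97), otherwise founds a new
OTU. This built-in clusterer is deliberately simple — it performs no
denoising or chimera removal — and exists so the pipeline runs end-to-end
with no external dependency; `import_external_clusters()` accepts the seed
FASTA + membership table of any heavier clusterer in its place. Because
greedy clustering (and some external tools) can emit seeds that are
mutually within the radius, `check_otu_overlap()` reports such pairs and
`merge_overlapping_otus()` absorbs the smaller member of each pair until no
pair remains.

Abundance is estimated by mapping **both** high- and mid-quality
full-length reads onto the OTU seeds: each read goes to its single
best-identity seed at or above the radius (ties to the lexicographically
smallest OTU id, making the result order-independent), and unmapped reads
are counted but excluded. Column sums of the matrix therefore never exceed
the per-sample high+mid totals, and `matrix total + unmapped = high + mid`
exactly.

### One identity definition

Everywhere "identity" appears — clustering, mapping, overlap checks, seed
candidacy, the simulation harness — it is computed by one aligner: a
glocal alignment in which the *shorter* sequence must be consumed in full
and terminal gaps are free only on the longer one (match +1, mismatch −1,
linear gap −2, implemented in C++), with identity = matches / alignment
columns over the aligned region. Requiring full containment of the shorter
sequence matters: a pure free-end-gap (overlap) alignment lets two
unrelated reads share a coincidental few-base terminal overlap and score a
meaningless identity of ~1, whereas the glocal form scores unrelated
same-length reads near the random baseline while still rating a truncated
250 bp cluster representative at ~1 against its own full-length read.

## Seed extension

The clustering representative is a truncated read, which is a poor basis
for taxonomic annotation and tree building. `extend_seeds()` replaces it
with the best **full-length high-quality** member read of the OTU
(mid-quality reads are never eligible). Candidates are the members that
still align to the representative at or above the radius after tail
trimming; among them, selection is lexicographic:

1. identity to the representative closest to the candidates' median
   identity — the candidate nearest the centre of the OTU;
2. lowest per-base expected error;
3. greatest length;
4. smallest read id, for determinism.

Criterion 1 reads "closest to the OTU median" as closeness in alignment
identity, not in length — length is already criterion 3, and the median
identity is the natural centre-of-cluster statistic. The ordering follows
the sentence order of the desiderata; it is permutation-invariant in the
candidate list. Using a real member read rather than a consensus avoids
averaging two strains into a sequence nobody sequenced.

For paired-end data, `merge_pair()` joins mates before extension: the
reverse mate is reverse-complemented and overlap lengths are scanned from
longest to shortest (minimum 10 bp), accepting the first whose mismatch
fraction is at most 0.25. At overlap disagreements the higher-quality base
wins with quality `max(|Qf − Qr|, 2)`; agreements keep `max(Qf, Qr)`. This
max-based quality rule was chosen over a full posterior calculation for
transparency; the function is small and pluggable if a probabilistic rule
is preferred.

## Windowed LCA taxonomy

Each extended seed is classified from tabular alignment hits (BLAST
outfmt-6 or the built-in aligner) by `lca_assign()`:

1. **one reference, one vote** — multiple HSPs to the same subject
   collapse to the best-identity one, so a repetitive reference cannot
   dominate;
2. **identity window** — only hits within 1.5 percentage points of the
   best hit vote, capped at 200 hits (ties broken by identity, then
   bitscore, then subject id). The window admits hits that differ from the
   best only by about a sequencing error's worth of identity;
3. **depth cap** — the best hit's identity limits how deep the assignment
   may go: species requires ≥ 97%, genus 95, family 93, order 91, class
   88, phylum 78. A 96% best hit can therefore never produce a species
   call — the query's species is plausibly absent from the database;
4. **consensus walk** — from domain toward species, a rank is assigned
   when one name is shared by *strictly more than* `consensus_fraction`
   (default 0.9) of the voting references. References with no annotation
   at the current rank are discarded from that vote — so a single
   species-annotated reference among otherwise unannotated ones can carry
   a species call. The walk stops at the first failed vote or at the cap,
   and all deeper ranks stay unassigned.

Two cap arrangements ship: the default is monotone in taxonomic depth
(class 88 < order 91), because a cap list in which the rank *between*
family and class required less identity than class itself would be
internally inconsistent; configurations that state the caps the other way
around are honoured by `lca_spec(literal_printed_caps = TRUE)`. The strict
(`>`, not `≥`) consensus inequality is intentional: 9 of 10 references is
exactly 0.9 and does not pass a 0.9 threshold.

`aggregate_taxa()` sums OTU counts by assigned name at any rank, pooling
OTUs unassigned at that rank into an `unassigned` row, so totals are
preserved at every rank.

## The simulation harness

`synthesize_reference_db()` builds a labeled reference set by evolving
sequences down a taxonomy tree (one ancestor per phylum, then class, order,
family and genus ancestors, species leaves). Per-level substitution rates
(0.16, 0.08, 0.05, 0.035, 0.02, 0.008) place within-genus species pairs
near the species identity cap and make higher ranks progressively more
divergent, mimicking the identity structure that the per-rank caps assume.
What it does **not** emulate: the conserved/variable region architecture of
real 16S genes, indel-rich divergence, chimeras, and non-uniform taxon
abundance — so passing harness results demonstrate the classifier's
internal consistency, not its field accuracy on real databases.

`simulate_reads()` draws references, truncates each to the 5' prefix of
the requested read length (amplicons share the primer-proximal 5' region)
and applies i.i.d. substitutions, uniform over the three alternative bases;
an indel mode exists but substitution-only is the reference model, the
simplest one consistent with random mutation. All randomness flows from a
single integer seed and the RNG state is restored afterwards, so results
are reproducible and composable. `classify_simulated()` supports two
held-out designs: removing each read's own source from the database
(`exclude_self`), and additionally ignoring all hits at or above a given
identity (`exclude_relatives_identity`), which emulates a query with no
close relative in the database — with the 97% species cap this makes
species calls structurally impossible, a property the tests assert.

Scoring is per rank: TP (assigned, equals truth), FP (assigned, differs),
and among unassigned predictions TN (truth itself lacks the rank) vs FN.
Precision is TP/(TP+FP) and specificity TN/(TN+FP), reported as missing
when a denominator is zero rather than silently as 0 or 1.

`synthesize_run()` generates the end-to-end fixture: reads from three
mutually <90%-identical templates, barcoded and primer-tagged, with three
quality profiles (steadily high; uniformly mediocre at Q26, which survives
window trimming but fails the high band on both criteria; steeply decaying,
which window trimming cuts below the length floor). The profile fractions
(10% mid, 5% reject by default) give all three bins realistic occupancy.

## Problem sizes and numerical choices

The test suite exercises the full stated scales: 10,000 random hit tables
against an exhaustive recount oracle, 10,000 quality vectors against direct
summation (tolerance 1e-12), 1,000 random pair-merge reconstructions, a
1,000-read 4-sample end-to-end run, and a 5-seed read-length sweep on a
200-reference database with 50 reads per condition. The sweep's read count
is the package's scaled-down choice for a property (mean unassigned
fraction at 250 bp ≤ at 100 bp) that is stable well below the original
simulation scale. Degenerate inputs are defined rather than accidental:
empty hit lists give fully unassigned paths, empty read sets give valid
empty files and zero-dimension matrices, ties break lexicographically
everywhere (barcodes excepted: they unassign), and a cluster with no
surviving full-length candidate keeps its truncated representative and is
flagged.

## Known limitations

* The built-in clusterer is greedy and abundance-ordered; it does not
  denoise, detect chimeras, or implement abundance-weighted radii. Use the
  external-clusterer adapter for production-grade OTUs.
* Adapter trimming is exact-substring; error-tolerant adapter alignment is
  out of scope.
* Phred+64 encodings and interleaved paired files are not supported.
* The BIOM writer emits format 1.0 JSON (sparse); HDF5-based BIOM 2.x is
  intentionally avoided to keep the output plain text.
* Phylogenetic tree construction is a pass-through hook for external
  aligner/tree tools; no alignment or inference is implemented.
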