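---
title: "Detecting, annotating and masking microbial-like regions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, annotating and masking microbial-like regions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromask)
library(tibble)
```

# The problem and the model

Reference genome assemblies of eukaryotes — particularly those built from
museum specimens, herbarium material, or other degraded samples — carry
regions of microbial origin or of strong microbial similarity. In
competitive read-mapping pipelines (the standard approach for ancient
environmental DNA), those regions act as decoys in reverse: microbial
reads from the sample align into the contaminated parts of a eukaryotic
reference and inflate its apparent detection. `micromask` locates such
regions by a deliberately simple, exhaustive construction:

1. every contaminant-source genome is cut into **pseudo-reads** — all 60 bp
   windows at a 10 bp step;
2. pseudo-reads are aligned to the target end-to-end, keeping up to 10
   placements per read;
3. every maximal run of target bases covered by at least one pseudo-read
   is a **microbial-like region**.

The definition is intentionally conservative in the inclusive direction: a
single aligned 60-mer suffices. The package therefore speaks of
*microbial-like* sequence, never of contamination — a region may reflect
true contamination, horizontal transfer, organelle/bacterial homology, or
chance similarity; distinguishing those is out of scope. Masking is the
intended downstream use, and over-masking is the accepted cost of
conservative detection: a genuinely endogenous region that is masked can
no longer cause a false microbial assignment, while sample reads from that
region simply go unassigned.

## Assumptions

- Contaminant similarity is high: detections rely on ≤ 3 mismatches over
  60 bp (95% identity). More diverged homology is invisible to the default
  internal aligner; externally produced (e.g. gapped, more sensitive) SAM
  alignments can be ingested instead.
- Sources are taxon-labelled at whatever granularity the user cares about;
  attribution is purely by read counting, with no probabilistic
  reassignment of multimapping reads between taxa.
- Coordinates are 0-based half-open throughout (BED convention), so
  `LENGTH = END - START` exactly.

# Parameters

| parameter | default | units | role and rationale |
|---|---|---|---|
| `window` | 60 | bases | pseudo-read length; twice the ~30 bp organism-specificity floor, typical aeDNA fragment length |
| `step` | 10 | bases | window stride; leaves < 10 bp uncovered at contig/insert tails |
| `multimap` | 10 | placements | per-read cap; multicopy-locus detection saturates by ~10 |
| `max_mismatch` | 3 | mismatches | 5% of a 60 bp read; end-to-end ungapped extension |
| `seed_length` | 15 | bases | aligner seed; see *Seed length and completeness* |
| `top_taxa` | 5 | taxa | ranked attributions kept per BED row |
| `n_perm` | 300 | permutations | enrichment null; p floor 1/301 |
| `mask_mode` | hard | — | `N` masking; k-mer profilers treat `N` as a hard break |
| `rng_seed` | 214 | — | default seed for the permutation test |

# Numerical and design choices

## Seed length and completeness

The internal aligner finds candidate loci by exact hits of non-overlapping
seed tiles of the read (plus one tail-anchored tile), then extends each
candidate ungapped over the full read. By the pigeonhole principle the
search is *complete* — guaranteed to find every placement within the
mismatch budget — whenever the number of non-overlapping tiles exceeds the
budget. With 60 bp reads and a budget of 3, that requires 4 tiles, hence
the default seed length of 15 bp (4 × 15 = 60). A longer seed (say 20 bp)
fits only 3 tiles in 60 bp and can miss placements whose three mismatches
land in all three tiles; completeness is what lets the test suite assert
exact set-equality between the aligner and a brute-force Hamming-scan
oracle. 15 bp seeds over desk-scale targets produce negligible spurious
candidate load; both the seed length and the mismatch budget are exposed
as configuration.

## Tie-breaking and multimap truncation

Placements are reported in a canonical order — (mismatches, contig id,
start, strand with `+` first) — so repeated runs are byte-identical.
Truncation to the multimap cap is more subtle than it looks. If the cap
always kept the first *M* placements in canonical order, every window of a
12-copy repeat would retain the *same* first *M* copies, the remaining
copies would never be covered, and detected breadth would keep growing
linearly in *M* instead of saturating — contradicting the saturation
behaviour that motivates the cap of 10 in the first place. Short-read
aligners that report "up to k" placements do not share this pathology
because their tie-breaking among equal-score placements is effectively
randomized. `micromask` keeps determinism but reproduces the useful part
of that behaviour: placements strictly better than the boundary mismatch
count are always kept, and within the tie group at the boundary the
survivors are chosen cyclically starting at a per-read offset derived from
a hash of the read sequence. Different (overlapping) windows therefore
drop different copies, coverage of a repeat family saturates as the cap
grows, the selection is monotone in *M*, and identical inputs still give
identical outputs.

## Region calling

Regions are maximal runs of depth ≥ 1 (merge distance 0): overlapping and
bookended covered intervals join, and any run boundary is flanked by a
zero-depth base. `NREADS` counts alignment records — each retained
placement of a multimapper counts once — which matches per-base depth-sum
semantics and explains why a 119 bp region can be supported by tens of
thousands of pseudo-reads when thousands of source taxa each contribute a
few. Reads whose identifier does not parse as a pseudo-read (e.g. sample
reads) contribute to coverage if passed in, but never to `NREADS` or to
taxon attributions. Ranked attributions break count ties alphabetically,
so BED output is stable.

## The enrichment test

The observed statistic is the fraction of sample-read placements
overlapping any microbial-like region by ≥ 1 base (half-open intervals: a
read ending exactly where a region starts does not overlap). The null
re-places each read uniformly within its own contig, preserving contig
assignment and read length — contigs differ hugely in microbial-like
fraction, so a genome-wide null would conflate contig assignment with
position. The p-value uses the add-one estimator
\(p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n)\): it never returns
0, ties count against significance, and its floor at \(n = 300\) is
\(1/301 = 0.0033\) (at 2 significant digits). The analytic companion
`analytic_null_expectation()` enumerates, for every read, exactly which
valid starts overlap a region, giving the closed-form null mean the
permutations must converge to; because a read overlaps a region from up to
`read_length − 1` bases away, this expectation always exceeds the masked
base fraction. Reads longer than their contig cannot be re-placed and are
excluded from both sides of the test, with a warning.

## Sketching and ordination

MinHash sketches keep the 1000 smallest values of a fixed deterministic
64-bit hash over distinct canonical 21-mers (lexicographic minimum of
k-mer and reverse complement), the common sketching defaults. The Mash
distance uses the joint-bottom estimator: Jaccard \(j\) is the fraction of
shared hashes among the \(s\) smallest of the merged sketch, with
\(s = \min(\text{sketch size}, |\text{union}|)\) — the \(\min\) matters
for inputs with fewer than 1000 distinct k-mers, where a fixed denominator
would make identical inputs appear distant; \(d(a,a) = 0\) is
non-negotiable. Disjoint sketches saturate at \(d = 1\). "PCA on the
distance matrix" is implemented as classical metric scaling (PCoA):
double-centre \(-\tfrac12 D \circ D\), take the two leading eigenvectors
scaled by the square roots of their (non-negativity-clamped) eigenvalues.
Axis signs are fixed by making each axis's largest-magnitude loading
positive, so embeddings are fully deterministic and invariant to input
order.

Note that Mash distance saturates for *unrelated* sequences: two
independent random 8 kb sequences share essentially no 21-mers regardless
of GC content, so all their pairwise distances are 1 and carry no signal.
Meaningful ordination requires k-mer sharing *within* groups — which real
endogenous (one host genome) and exogenous (related contaminants) segment
collections have, and which the test fixtures emulate by deriving each
group from a common ancestor sequence.

# The synthetic-data generator

`generate_host()` draws i.i.d. bases at a chosen GC content;
`plant_inserts()` copies random source-genome fragments into the host at
uniformly drawn non-overlapping positions, substituting each base
independently at a chosen divergence rate and recording exact truth
coordinates; `sample_reads()` draws fixed-length reads with a chosen
fraction forced to overlap a region set, with an optional terminal C→T
damage toggle (off by default). All randomness is seeded per call.

What the generator emulates: planted contaminant blocks of known origin,
copy number and divergence; multi-taxon source sets with distinct
composition; read samples enriched (or not) for masked regions; assemblies
whose contigs are purely host or purely contaminant (the bimodal
per-contig fraction profile). What it deliberately does not emulate:
repeats and low-complexity sequence in the host background, realistic
phylogenetic structure among sources, gapped or quality-degraded reads,
and full damage patterns of ancient DNA. Passing tests therefore
demonstrate the correctness of the machinery — interval arithmetic,
alignment completeness, counting, statistics — under clean conditions,
not the field behaviour of the workflow on repeat-rich genomes, where
microbial-like calls can additionally arise from low-complexity
similarity.

Two generator conventions worth knowing:

- *Insert length vs edge loss.* Pseudo-read windows are step-aligned in
  **source** coordinates, so up to step − 1 bases at each edge of a
  planted insert are never spanned by a fully-interior window; the
  detector also gains up to `max_mismatch` bases of overhang at each edge.
  Base-level recall of planted inserts approaches 1 only for inserts much
  longer than these ~10 bp edge effects; the recovery fixtures use 5 kb
  inserts, where the expected recall floor is ≈ 99.6%.
- *Multicopy fixtures.* The saturation fixture plants 12 byte-identical
  copies of one 600 bp element — multicopy insertions of the same microbe,
  the situation the multimap cap exists for. A variant with 2%-diverged
  copies (an older repeat family) is also exercised; there the cap
  interacts with genuine mismatch ranking, and coverage approaches
  saturation more slowly.

# Problem sizes and runtimes

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while completing in minutes on a
single CPU: self-alignment validation over 20 genomes of 10–100 kb (~115 k
pseudo-reads), oracle equivalence over 500 read/target pairs of ≤ 2 kb,
recovery fixtures of 3–5 planted 5 kb inserts in ~100 kb hosts, 200-repeat
calibration of the permutation test at 300 permutations each, and
12-member sketch collections of 8 kb sequences.

# Known limitations

- The internal aligner is ungapped; indel-containing contaminant copies
  are found only via their gap-free flanks, or by ingesting external SAM.
- Attribution counts alignments, not evidence: a taxon over-represented in
  the source set is over-represented in `NREADS` terms.
- Min–max normalization of the genome-by-taxon table is per taxon
  (column) across assemblies; other conventions (per genome, global) are
  not provided.
- The enrichment null randomizes position only; it does not match GC or
  mappability, so strong compositional biases in the read set can inflate
  significance.
- `BedRow` organism/assembly metadata is carried, not validated, against
  any external taxonomy.
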