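---
title: "Methods: comparative lincRNA characterization with linctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative lincRNA characterization with linctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linctools)
```

# The analysis

Long intergenic noncoding RNAs (lincRNAs) are transcripts longer than 200
nucleotides that lie between protein-coding genes and lack a canonical open
reading frame. Their sequences evolve quickly, so cross-species comparisons
rest on three kinds of evidence that this package computes end to end:

1. **Composition and structure.** GC content by compartment (spliced exons
   vs introns vs coding sequence), and thermodynamic structural stability
   measured against a shuffle null: for a statistic $x$ (minimum free
   energy or folding strength) and $100$ dinucleotide-preserving shuffles
   with mean $\mu$ and standard deviation $\sigma$,
   $$Z = \frac{x - \mu}{\sigma}.$$
   Ratios ($x$ over the control mean) are emitted alongside. Transcripts
   in the top folding-strength quantile (90/95/97/99th) form the
   *structured* set.
2. **Homology.** All-vs-all local similarity search; a pair is connected
   when it shares a gapped local-alignment patch of more than 100
   matched+mismatched columns at an e-value below $10^{-5}$. Markov
   clustering (MCL) of the similarity graph yields conserved clusters
   (across species) and paralog groups (within species). Re-running after
   masking repeats and low-complexity sequence separates genuine
   conservation from similarity that repeats carry: a pair conserved only
   without masking is labeled TE-related.
3. **Genomic context.** Transposable-element coverage by compartment and
   class, closest protein-coding genes, GO enrichment of those neighbors,
   expression correlation of gene–lincRNA pairs by distance, and
   chromosomal density.

# The shuffle null

Stability is only meaningful relative to sequences of identical
composition. The null model is the Altschul–Erikson dinucleotide shuffle:
a uniform draw over all permutations of the sequence that preserve the
exact 16-entry dinucleotide count vector, the length, and the first and
last base. The implementation builds the dinucleotide transition
multigraph, samples a uniform random "last-edge" arborescence into the
terminal vertex by rejection, randomizes the order of the remaining
out-edges, and walks the resulting Eulerian path. The arborescence step is
essential: naive per-vertex edge shuffling without it is non-uniform over
the valid set. Uniformity is verified in the test suite by exhaustive
enumeration of the valid set for short sequences and a chi-square
goodness-of-fit over 10,000 draws.

Sequences containing N are shuffled within their contiguous N-free
segments so that annotation-derived sequences keep a defined null; U is
mapped to T at ingestion.

# The folding engine

The built-in engine works over pseudoknot-free nested secondary structures
with a minimum hairpin loop of 3 nt, no lone-pair prohibition, and an
optional maximum pairing span. Energies are simple per-pair terms
(defaults $-3$ for G–C, $-2$ for A–U, $-1$ for G–U, in abstract units)
rather than a full nearest-neighbor parameter set. This is a deliberate
trade: every statistic the pipeline reports is *comparative* — a native
sequence against shuffles of identical composition — so what must be
right is the ranking behavior, which the simple model preserves, while
the structure space stays small enough to verify exactly against
exhaustive enumeration (MFE agreement for $n \le 18$; base-pair
probabilities within $10^{-8}$ for $n \le 15$). Users who want Turner
energies can route through `backend_fold()`, an adapter for ViennaRNA's
RNAfold when it is installed; the two engines rank hairpin vs random
panels concordantly.

The partition function uses McCaskill-style inside/outside recursions at
Boltzmann weights $e^{-E/RT}$ (default $RT = 0.6$). *Folding strength* is
the expected fraction of paired nucleotides: the mean over sites of
$p_i = \sum_j P(i \text{ pairs } j)$, where $p_i$ is the per-site stem
probability. Magnitudes are kept in double range by giving every base a
scale factor $e^{-\ell}$, with $\ell$ initialized from the MFE and refined
by bisection on overflow; probabilities are scale-invariant ratios. Two
practical limits follow and are enforced rather than hidden: $RT$ much
below $\sim 10^{-2}$ makes individual pair weights unrepresentable (the
low-temperature-limit test therefore runs at $RT = 0.01$, where
suboptimal structures are already suppressed by factors of $e^{-100}$ or
more), and global folding of very long sequences should use `max_span` or
the sliding-window folding strength (window 400 nt, step 100, each site
taking its value from the window whose center is nearest).

The sign conventions are: stable sequences have *negative* `z_mfe`
(Z computed on raw, negative MFE, the formula as stated) and *positive*
`z_fs`. Both orientations are trivially recoverable from the stored
$x, \mu, \sigma$ columns, which the records keep precisely so the
standardization is recomputable to machine precision.

# Local similarity and e-values

The search is seed-and-extend: exact 11-mer word seeding, ungapped
X-drop extension (X-drop 30), and — once a seed extension reaches the gap trigger —
full affine-gap Smith–Waterman with traceback (match $+1$, mismatch $-2$,
gap open 5, extend 2; a gap of length $L$ costs $5 + 2L$). Additional
patches per pair are found by masking the aligned query span and
re-aligning. On planted-similarity pairs up to 300 nt the seeded score
equals full Smith–Waterman exactly (checked against an independent
implementation); protein-level search uses BLOSUM62 with gap 11/1.

E-values follow Karlin–Altschul statistics, $E = K m n e^{-\lambda S}$.
$\lambda$ is solved numerically from
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ and $K$ by the lattice-case
convolution series, so the statistics stay correct if a user changes the
scoring scheme. For the default schemes the computed constants reproduce
the published ungapped values ($\lambda = 1.33, K = 0.621$ for $+1/-2$;
$\lambda = 0.3176, K = 0.134$ for BLOSUM62 with Robinson–Robinson
frequencies). The ungapped constants are applied to gapped scores, which
is mildly conservative; the retention rule (patch $> 100$ columns *and*
$E < 10^{-5}$) is dominated by the patch-length condition on realistic
inputs, and the null calibration test (1,000 random 1 kb transcripts,
expected $\approx 0$ edges) checks the combined behavior.

Masked runs replace repeat intervals (mapped from genomic to transcript
coordinates) and DUST-style low-complexity windows (window 64, normalized
triplet-collision score, threshold 20) with N, which the aligner treats
as unalignable. The 100-nt patch rule is applied per single gapped
alignment; summed-patch retention is available via the edge table, which
keeps every patch.

MCL uses edge weights $-\log_{10} E$ capped at 200, self-loops at each
node's maximum incident weight, inflation 2.0 by default, and reads
clusters off the converged attractor structure as connected components.
Inflation 1 degenerates toward connected components and large inflation
toward singletons, which the tests exercise on toy graphs.

# The synthetic-data generator

Real universes for this analysis require genomes, repeat libraries and
RNA-seq; the generator instead emits universes whose *statistical
structure* matches what each stage assumes, together with the exact
planted truth, so every claim the pipeline makes is checkable:

- **Background.** Nucleotides are i.i.d. with per-transcript GC drawn
  uniformly from `gc_range` (default 0.30–0.45, intergenic-like).
  Lengths are uniform in `length_range`; the default 200–1500 nt brackets
  the median lengths (roughly 550–1000 nt) seen in real insect lincRNA
  sets. lincRNAs below 200 nt are rejected by construction.
- **Structure.** Exactly `round(structured_fraction * N)` transcripts
  (default fraction 0.1) receive one perfect inverted repeat (stem 15–40 bp, loop 4–8 nt) at a uniform
  position — a guaranteed folding signal that mimics no particular
  structure family.
- **Homology.** Families (default 10) copy a founder sequence to 2–3
  members spanning at least two species, with per-site substitutions at
  `family_divergence` and 1–2 short indels above 10% divergence. Hairpins
  are planted only into non-family transcripts so the two signals stay
  orthogonal (a hairpin overwrite inside a short family member could
  fragment its similarity patch below the 100-nt rule).
- **Repeats.** A deterministic 5-sequence consensus library (one per
  class: DNA, LINE, LTR, SINE, simple repeat, 80–500 bp) supplies copies
  mutated at 5% per site. "Insertion" is realized as a same-length
  replacement of background sequence, which preserves coordinates and
  coverage semantics; copies are placed without overlap by a random
  integer composition of the free space, so density 1.0 tiles a
  compartment exactly. Exon density must not exceed intron density (the
  generator plants depletion). Note the smallest placed fragment is
  30 bp, so compartments whose base budget (density × length) falls
  below 30 receive no copies.
- **Expression.** Values are unit-free and non-negative (`max(0, 10+2z)`
  on latent normals). Each lincRNA's latent profile correlates with its
  flanking gene's at the target correlation for their distance bin
  (default 0.5/0.3/0.1/0/0 across the bins 0–1 kb, 1–5 kb, 5–20 kb,
  20–100 kb, ≥100 kb).
- **Annotation.** Every lincRNA gets a protein-coding neighbor
  (coding-like sequence: ATG, no in-frame stops, TAA) at a random
  distance of 0.1–4 kb, with GO labels drawn from a miniature in-package
  ontology; four chromosomes per species.

What the generator does *not* emulate — sequencing error, assembly
artifacts, isoform structure, realistic repeat families, chromosome-scale
organization — bounds what a passing test shows: the pipeline's
statistics are correct and its planted-signal recovery works, not that
any particular biological dataset will carry such signal.

# Numerical and design choices

- Coordinates are 0-based half-open internally and converted at GFF3
  boundaries (1-based closed).
- ORF search runs on the three forward frames of the spliced, stranded
  transcript; a `both_strands` flag restores the both-strand behavior of
  classic ORF finders. The stop codon is excluded from the peptide
  length; the 25-aa threshold is the default.
- Quantile selection is per species by default (`pool = TRUE` for a
  pooled set); ties break by `z_fs` then id, so selections are
  deterministic. The member count is $\lceil (100-q)N/100 \rceil$.
- Degenerate cases carry flags rather than silent drops: $\sigma = 0$
  records (sequences invariant under shuffling), zero-variance expression
  pairs, all-zero coverage classes, transcripts alone on a chromosome.
- Multiple-testing: BH adjustment wherever a family of tests is emitted
  (GO terms, repeat classes, density windows).
- The closest-gene distance is unsigned and strand-agnostic; equidistant
  genes break by smaller start.
- Intergenic filtering removes transcripts overlapping a protein-coding
  *gene span* (introns included, either strand) — the fully-intergenic
  semantics of assembler class code "i".

# Problem sizes used by the checks

The test suite and the acceptance script size their simulations to run on
one CPU: shuffle invariants on 1,000 sequences of 2–2,000 nt; folding
oracles at $n \le 18$; Z-score calibration on 300 shuffle-origin
sequences plus 200+200 hairpin/random arms of 100 nt with 100 controls
each; structured-set recovery on 1,000 transcripts of 200–250 nt;
homology recovery on 3-species universes of 30 lincRNAs per species
across the divergence grid, with a 1,000-transcript random null; the
end-to-end demonstration universe is 3 species × 15 lincRNAs (200–300 nt,
10 controls). The acceptance script runs 3 species × 40 lincRNAs with 25
controls. These sizes are the package's own choices for a reproducible
desk-scale demonstration; all thresholds (200 nt, 25 aa, $10^{-5}$,
$10^{-6}$, 100 nt patches, 100 controls as the analysis default,
quantiles, inflation 2) are the analysis constants, not tuning knobs.

# Known limitations

- The built-in energy model is not a nearest-neighbor thermodynamic
  parameterization; absolute MFE values are not comparable to kcal/mol
  outputs, only rankings and shuffle-relative statistics are.
- Gapped e-values reuse ungapped $(\lambda, K)$.
- The expression generator's clamp at zero slightly attenuates planted
  correlations (well within the ±0.1 recovery tolerance used in tests).
- MCL is dense-matrix; similarity graphs beyond ~5,000 connected nodes
  would need a sparse implementation.
- No synteny-aware orthology: conservation is sequence-level only.

# Interfaces

All user-facing functions take a data frame first and return tibbles, so
stages compose with the pipe; `simulate_universe()`, the stage functions
(`intergenic_filter()`, `transcript_properties()`, `stability_table()`,
`select_structured()`, `all_vs_all()`, `mcl_cluster()`,
`classify_conservation()`, `repeat_overlap()`, `closest_gene()`,
`go_enrichment()`, `expression_distance_profile()`,
`chromosomal_density()`) and `run_pipeline()` are the package's command
set, with `scripts/acceptance.R` as the reproducible entry point; no
separate shell CLI is shipped. Results print as tibbles, `tidy()` and
`glance()` follow the broom conventions, and `autoplot()` /
`plot_*()` functions cover the standard figures.
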