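---
title: "Methods: small-RNA classification, hairpin discovery and target scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA classification, hairpin discovery and target scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAmine)
```

# Overview

sRNAmine implements the classical annotate-then-discover workflow for
plant small-RNA sequencing data: clean and collapse the reads, assign
tags to known RNA classes by perfect matching, evaluate EST-mapped
unannotated tags as hairpin precursors, and predict miRNA targets with a
point-based complementarity score. Every stage is driven by a seeded
synthetic-data module so the whole pipeline can be validated against
known ground truth at desk scale. This vignette explains the models, the
tunable parameters and the design choices where the method left room.

# Preprocessing

Raw reads are filtered on mean Phred quality (default `min_mean_q = 20`,
inclusive) and on ambiguous bases (any `N` discards the read). The 3'
adapter is clipped at its *leftmost* occurrence allowing `max_mismatch`
(default 1) mismatches over the overlapped region; partial adapter
suffixes at the read end count when at least 6 nt overlap. Reads whose
insert is empty are counted as adapter–adapter ligation products.
Inserts are kept when strictly longer than 17 nt and at most 30 nt
(`min_len = 18`, `max_len = 30`). The gel cut of the emulated library is
18–28 nt while the analysis keeps "> 17 nt"; both bounds are exposed so
either convention can be enforced. Surviving inserts are collapsed into
unique tags with counts, ordered by descending count with lexicographic
tie-breaks for reproducibility. Every raw read lands in exactly one
accounting bucket (clean / adapter-only / low-quality / outside window),
which the tests assert as a conservation law.

# Classification

A tag is assigned to a class only when its sequence equals a reference
sequence exactly — no mismatch tolerance, matching the rule that only
perfectly matched sequences count as known miRNAs. Multi-class matches
are resolved by a configurable priority order, default
`miRNA > rRNA > tRNA > snRNA > snoRNA > siRNA`; miRNA-first reflects the
purpose of the analysis, and the order only matters for the rare tag
present in two reference sets. Matching is orientation-aware: reference
sets are sense-strand mature sequences and no reverse-complement
matching is attempted. The per-class summary reports unique and total
counts with percentages against the all-tags row, and family abundances
are aggregated by parsing `miR<number>` from the mature identifiers
(`ahy-miR156f` → `miR156`).

# Hairpin discovery

Unannotated tags of mature size (20–24 nt) are matched exactly (either
strand) against the EST collection. For every hit the ±150 nt context is
extracted (truncated at EST boundaries, reverse-complemented for
minus-strand hits) and folded once to a single lowest-energy structure.

Acceptance applies stem-loop duplex criteria with these defaults, all
config-exposed in `duplex_criteria()`:

* at most 4 unpaired mature bases (`max_unpaired_mature`);
* no asymmetric bulge larger than 2 nt inside the duplex (`max_bulge`);
* the mature must lie wholly in one arm — any self-pairing or pairing
  into both arms is a terminal-loop overlap;
* negative folding energy;
* trimmed precursor length within 50–400 nt.

The miRNA\* is inferred from the structure as the duplex partner of the
mature with 2-nt 3' overhangs, projecting across unpaired mature ends;
its read support is looked up by exact match in the tag set, consistent
with the classification rule. Rejections carry machine-readable reason
codes (`loop_overlap`, `excess_mismatch`, `bulge_too_large`,
`inconsistent_duplex`, `no_stability`, `precursor_too_short/long`).

**Precursor delimitation.** Published precursor lengths (75–343 nt) are
shorter than the ~321 nt context windows, implying trimming, but no
delimiting rule is stated anywhere; we trim to the smallest balanced
window containing the mature/miRNA\* duplex and then extend outward
through the closing stem, tolerating interior loops of up to 4 nt per
side. A duplex-only trim was rejected during design because it caps
every precursor near `2×mature + loop`, disconnecting reported lengths
from the actual stem. The trimmed precursor is refolded and the
candidate re-evaluated on the refold, so reported structures always
satisfy the acceptance criteria. Tags hitting several loci are evaluated
per locus and reported once per hairpin: a tag whose sequence already
lies inside a kept precursor (typically the star arm) does not found a
second candidate.

## Folding engines

The default engine shells out to ViennaRNA's `RNAfold` and parses the
single MFE structure; energies are kcal/mol. The bundled fallback is a
weighted Nussinov base-pair maximisation (GC = 2, AU = GU = 1, minimum
loop 3 nt) implemented in C++ with two refinements: the traceback
prefers pairing over skipping and distant partners over near ones among
equal-score structures (keeping designed stems intact rather than
rerouting pairs into terminal loops), and helices shorter than 3 stacked
pairs are pruned afterwards — the same idea as lonely-pair removal in
thermodynamic folders, without which pair maximisation decorates every
loop with spurious 1–2 bp helices. The fallback's "energy" is minus the
total pair weight: a *surrogate* that orders structures by stability but
is never compared numerically to published folding energies. The test
suite checks that both engines agree on accept/reject for curated,
unambiguous hairpin fixtures.

# Target scoring

The statistic scores an antiparallel miRNA/transcript duplex: 0.5 per
G:U wobble, 1.0 per other non-Watson–Crick pairing, 2.0 per indel, and an
extra 0.5 for every non-wobble mismatch at miRNA positions 2–7 (1-based
from the 5' end). Wobbles and indels in the seed are exempt from the
surcharge. For miRNAs longer than 20 nt the total is the minimum over
all windows of 20 consecutive miRNA positions, with seed positions
keeping their full-miRNA numbering; insertion columns are counted in a
window only when both flanking miRNA positions lie inside it. A site is
accepted iff its total is strictly below 3.0.

The search (`align_duplex`) evaluates the ungapped duplex at every
transcript offset plus, up to `max_indels` (default 1, at most 2), every
single-nucleotide gap variant, and keeps the best alignment per cluster
of overlapping sites. The surcharge grammar ("mismatches … were further
penalized") is read as *per mismatch*, consistent with the scoring
lineage the rule descends from. Ties are broken by fewest indels, then
leftmost site: parsimony must come first because a gap placed in the
window-excluded tail of a long miRNA produces a spurious equal-score
alignment one nucleotide wider than the ungapped one. The tests compare
the search against an independently written brute-force enumeration over
all offset/gap placements.

# The synthetic-data generator

`sim_config()` defaults encode the emulated study conditions:

* 100,000 reads of 36 nt machine length; insert lengths drawn from a
  weight map peaking at 24 nt (48%) and 21 nt (20.9%), with 23 nt
  (7.7%) and 22 nt (7.2%) next — the published length distribution;
* class fractions from the published category table: known miRNA 9.52%,
  rRNA 4.08%, siRNA 8.85%, snRNA 0.02%, snoRNA 0.01%, tRNA 3.17%, plus
  1% reads from planted hairpin precursors; the remainder is uniform
  unannotated background, rejection-sampled against every reference so
  background never collides with an annotated sequence;
* known-miRNA reads follow a Zipf family-abundance skew (`alpha = 1.3`)
  over 20 families, mirroring the strongly skewed family frequencies of
  real libraries;
* 5% of reads carry a low-quality string and 3% are adapter–adapter
  ligation products, so that ~91–92% of reads survive preprocessing, as
  in the emulated study; per-base error is 0 by default (classification
  and discovery are exact-match; error modelling would only shift reads
  into the background class);
* planted hairpins are built as `stem + mature + loop(8–40 nt) +
  revcomp(mature) + revcomp(stem)` with total insert length drawn to put
  88% in 75–188 nt and the rest up to 343 nt; building the star arm
  explicitly guarantees a foldable duplex without invoking the folding
  engine during generation. A precursor emits miRNA\* reads with
  probability 0.2, and then 8% of its reads are star reads — roughly the
  published star detection rate (4 of 25 candidates) and star/mature
  count ratios;
* mature reference lengths are drawn from the length weights restricted
  to 20–24 nt and renormalised, which keeps the overall library length
  distribution on target even though miRNA-class reads take their mature
  sequence's length;
* adapter sequences are arbitrary documented constants (the classic
  Solexa small-RNA 3' adapter); only 3' adapter read-through is
  simulated, since the 5' adapter is removed by the sequencer in
  short-insert libraries.

What the generator does **not** model: platform-specific error and
quality profiles, expression structure beyond the family skew, genomic
context (EST-only, as in the emulated study), or sequence composition
biases. Passing the recovery tests therefore demonstrates correctness of
the algorithms under idealised reads, not robustness to real-data noise.

# Numerical and scale choices

All internal computation uses the DNA alphabet (U↔T normalised on
input); human-facing tables print RNA. Coordinates are 0-based half-open
internally and 1-based inclusive in reports. The test suite exercises a
100,000-read simulation for recovery checks and 50 random 1-kb
transcripts for the brute-force equivalence of the duplex search;
folding work in discovery is bounded by the number of exact EST hits,
which the ground truth keeps near the number of planted hairpins.
Determinism is part of the contract: identical configurations produce
byte-identical FASTA/FASTQ outputs, and the pipeline manifest records a
configuration hash that changes iff a parameter changes.

# Known limitations

* The "siRNA" category is a reference-set class in this implementation;
  how such reads are operationally defined in real analyses varies, and
  no clustering-based siRNA annotation is attempted.
* No suboptimal structure enumeration, shuffling p-values, or
  cross-species conservation evidence for candidates.
* Target prediction has no accessibility/energy term and no
  cleavage-vs-translational-inhibition classification; it is the pure
  complementarity statistic with the strict 3.0 threshold.
* The fallback folder's surrogate energies are not thermodynamic;
  candidate folding energies should be interpreted only when produced by
  the ViennaRNA engine.
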