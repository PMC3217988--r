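# sRNAmine

Desk-scale reimplementation of a plant small-RNA sequencing analysis:
from raw reads to known-miRNA classification, novel miRNA discovery by
hairpin evaluation, and miRNA target prediction — with a seeded synthetic
data generator so every stage runs against known ground truth.

## The problem

Deep sequencing of a plant small-RNA library (here modelled on a peanut,
*Arachis hypogaea*, library) yields tens of millions of 18–28 nt reads.
Turning them into miRNA annotations takes four steps:

1. **Preprocess** — quality/N filtering, 3' adapter clipping, removal of
   adapter–adapter ligation products and of inserts outside 18–30 nt,
   then collapsing to unique *tags* with read counts.
2. **Classify** — perfect-match assignment of each tag against reference
   RNA classes (known mature miRNAs, rRNA, tRNA, snRNA, snoRNA, siRNA);
   everything else is *unannotated*. A tag matching several classes takes
   the highest-priority one (miRNA first).
3. **Discover** — unannotated tags are mapped exactly onto an EST
   collection; ±150 nt contexts of hits are folded to their
   minimum-free-energy structure (ViennaRNA's RNAfold, with a bundled
   Nussinov fallback), and a candidate is accepted when the mature sits
   wholly in one stem arm with ≤ 4 unpaired bases, no asymmetric bulge
   > 2 nt in the miRNA/miRNA\* duplex, and does not span the terminal
   loop. The miRNA\* (duplex partner with 2-nt 3' overhangs) is inferred
   from the structure and searched among the sequenced tags.
4. **Targets** — candidate miRNAs are scored against transcripts with a
   point-based complementarity statistic:

   * G:U wobble pair — 0.5 points
   * any other non-Watson–Crick pairing — 1.0 point
   * each indel — 2.0 points
   * non-wobble mismatches at miRNA positions 2–7 (the seed) — extra 0.5
   * for miRNAs longer than 20 nt, the score is the minimum over all
     consecutive 20-position windows
   * a site is a predicted target iff its total score is **strictly below
     3.0**.

The `synthetic_data` module generates the whole study universe —
reference sets, ESTs with planted hairpin precursors, transcripts with
target sites of controlled defect composition, and a read library with a
24-nt-dominated length distribution and skewed miRNA family abundances —
under a single RNG seed, so recovery of every planted signal is testable.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/05_targets.R`; each stage writes its tables under `results/run/`
and narrates what it found. A 100,000-read run prints:

```
100000 raw reads -> 92215 clean (92.22%); 2808 adapter-only, 4977 low-quality, 0 outside 18-30 nt.
Modal length 24 nt (47.4%), as in deep-sequenced plant sRNA libraries.

     category unique unique_pct total total_pct
1       total  67782     100.00 92215    100.00
2       miRNA     60       0.09  8928      9.68
3        rRNA     30       0.04  3795      4.12
...
8 unannotated  67621      99.76 68505     74.29

67621 unannotated tags entered discovery; 20 novel miRNA candidates accepted, 2 hits rejected.
Ground truth: 20/20 sequenced planted hairpins recovered; 0 candidates are not planted (expected 0).
```

The clean-read fraction, the 24-nt mode and the class percentages follow
the configured library composition; all planted hairpins whose mature was
sequenced are recovered and nothing else is. The same machinery is
available programmatically:

```r
library(sRNAmine)
mir <- c(mir156 = "UGACAGAAGAGAGUGAGCAC")
tx  <- c(tx1 = paste0(strrep("A", 30), revcomp(as_dna("UGACAGAAGAGAGUGAGCAC")),
                      strrep("C", 30)))
call_targets(mir, tx)[, c("site_start", "total_score", "accepted")]
#>   site_start total_score accepted
#> 1         31           0     TRUE
```

A single G:U wobble in that site would score 0.5, a seed mismatch 1.5, an
indel 2.0; an engineered 3.0-point site is rejected (strict threshold).

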