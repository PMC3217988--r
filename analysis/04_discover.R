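#!/usr/bin/env Rscript
# Stage 4: novel miRNA discovery — map unannotated tags to the EST
# collection, fold +/-150 nt contexts of exact hits to minimum-free-energy
# structures, apply the hairpin duplex criteria with miRNA* detection, and
# summarize the candidates. Also recomputes the summary statistics of the
# published peanut novel-miRNA table bundled with the package.
# Requires stages 1-3.

suppressPackageStartupMessages(library(sRNAmine))

datadir <- "results/run/data"
outdir <- "results/run"
tags <- read_tags_fasta(file.path(outdir, "tags.fa"))
labels <- read.delim(file.path(outdir, "tag_labels.tsv"))
ests <- read_fasta(file.path(datadir, "ests.fa"))

unann <- tags[tags$sequence %in%
                labels$sequence[labels$label == "unannotated"], ]
dv <- discover_mirnas(unann, ests)
write_tsv(dv$candidates[, c("name", "count", "sequence", "length", "est_id",
                            "precursor_length", "folding_energy",
                            "star_seq", "star_count")],
          file.path(outdir, "novel_candidates.tsv"))
write_tsv(dv$rejections, file.path(outdir, "discovery_rejections.tsv"))

cand <- dv$candidates
cat(sprintf("%d unannotated tags entered discovery; %d novel miRNA candidates accepted, %d hits rejected.\n",
            nrow(unann), nrow(cand), nrow(dv$rejections)))
if (nrow(cand) > 0) {
  cand$is_star <- FALSE
  s <- summarize_novel(cand)
  cat(sprintf("Candidate precursors: %d-%d nt, folding energies %.1f to %.1f kcal/mol (mean %.2f).\n",
              s$min_precursor, s$max_precursor, s$min_mfe, s$max_mfe,
              s$mean_mfe))
  cat(sprintf("%d candidates have miRNA* read support.\n",
              sum(cand$star_count > 0)))
}

# cross-check against ground truth
truth <- jsonlite::read_json(file.path(datadir, "planted.json"),
                             simplifyVector = TRUE)
observable <- truth$mature_seq %in% unann$sequence
recovered <- truth$mature_seq %in% as_dna(cand$sequence)
cat(sprintf("Ground truth: %d/%d sequenced planted hairpins recovered; %d candidates are not planted (expected 0).\n",
            sum(recovered[observable]), sum(observable),
            length(setdiff(as_dna(cand$sequence),
                           c(truth$mature_seq, truth$star_seq)))))

# published-table regression
tbl <- read_novel_reference_table()
ps <- summarize_novel(tbl)
cat(sprintf("\nPublished reference table (%d rows, %d families): mean energy %.2f kcal/mol (range %.1f to %.1f),\n",
            ps$n_rows, ps$n_families, ps$mean_mfe, ps$min_mfe, ps$max_mfe))
cat(sprintf("precursors %d-%d nt with %.0f%% within 75-188 nt; %d families >1000 reads, %d families <10 reads.\n",
            ps$min_precursor, ps$max_precursor, 100 * ps$band_fraction,
            ps$n_high_reads, ps$n_low_reads))
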