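#!/usr/bin/env Rscript
# Stage 2: raw reads to clean collapsed tags — mean-quality/N filter, 3'
# adapter clipping, removal of adapter-only reads and of inserts outside the
# 18-30 nt window, then collapsing to unique tags with counts.
# Requires analysis/01_simulate.R to have run.

suppressPackageStartupMessages(library(sRNAmine))

datadir <- "results/run/data"
outdir <- "results/run"
cfg <- yaml::read_yaml(file.path(datadir, "sim_config.yaml"))

pp <- preprocess_fastq(file.path(datadir, "reads.fastq"), cfg$adapter3)
write_tsv(pp$stats, file.path(outdir, "preprocess_stats.tsv"))
write_tsv(pp$length_dist, file.path(outdir, "length_distribution.tsv"))
write_tags_fasta(pp$tags, file.path(outdir, "tags.fa"))

st <- pp$stats
cat(sprintf("%d raw reads -> %d clean (%.2f%%); %d adapter-only, %d low-quality, %d outside 18-30 nt.\n",
            st$n_raw, st$n_clean, 100 * st$n_clean / st$n_raw,
            st$n_adapter_only, st$n_low_quality, st$n_too_short))
cat(sprintf("%d unique tags. Length distribution (%% of clean reads):\n",
            nrow(pp$tags)))
ld <- pp$length_dist
print(data.frame(length = ld$length, percent = round(ld$total_percent, 1)))
cat(sprintf("Modal length %d nt (%.1f%%), as in deep-sequenced plant sRNA libraries.\n",
            ld$length[which.max(ld$total_count)], max(ld$total_percent)))
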