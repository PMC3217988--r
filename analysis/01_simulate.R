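#!/usr/bin/env Rscript
# Stage 1: generate the synthetic small-RNA study inputs under known ground
# truth — reference sets, an EST collection with planted hairpin precursors,
# and a 100k-read sequencing library emulating the published peanut library
# composition. Outputs land in results/run/data/.

suppressPackageStartupMessages(library(sRNAmine))

cfg <- sim_config(seed = 42L, n_reads = 100000L)
datadir <- "results/run/data"
dir.create(datadir, showWarnings = FALSE, recursive = TRUE)

refs <- make_reference_sets(cfg)
ests <- make_ests(cfg$n_ests, cfg$est_length, seed = cfg$seed)
planted <- plant_hairpins(ests, cfg, refs)
sim <- simulate_library(cfg, refs, planted)

write_fastq(sim$reads$id, sim$reads$seq, sim$reads$qual,
            file.path(datadir, "reads.fastq"))
for (cls in names(refs)) {
  write_fasta(refs[[cls]], file.path(datadir, paste0(cls, ".fa")))
}
write_fasta(planted$ests, file.path(datadir, "ests.fa"))
write_ground_truth(sim, datadir)
yaml::write_yaml(list(seed = cfg$seed, adapter3 = cfg$adapter3),
                 file.path(datadir, "sim_config.yaml"))

cat(sprintf("Simulated %d reads (%d nt machine length).\n",
            cfg$n_reads, cfg$read_length))
cat(sprintf("Reference sets: %s.\n",
            paste(sprintf("%s n=%d", names(refs),
                          lengths(refs)), collapse = ", ")))
cat(sprintf("Planted %d hairpin precursors (insert lengths %d-%d nt) into %d ESTs.\n",
            nrow(planted$precursors), min(planted$precursors$insert_len),
            max(planted$precursors$insert_len), cfg$n_ests))
print(table(sim$origin$class))
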