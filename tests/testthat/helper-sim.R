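# Shared seeded simulation used by several test files; built once per run.
.sim_cache <- new.env(parent = emptyenv())

small_sim <- function(seed = 101, n_reads = 20000L) {
  key <- paste0("s", seed, "_", n_reads)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- sim_config(seed = seed, n_reads = n_reads,
                    n_ests = 30L, est_length = 700L, n_hairpins = 15L)
  refs <- make_reference_sets(cfg)
  ests <- make_ests(cfg$n_ests, cfg$est_length, seed = cfg$seed)
  planted <- plant_hairpins(ests, cfg, refs)
  sim <- simulate_library(cfg, refs, planted)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads$id, sim$reads$seq, sim$reads$qual, fq)
  pp <- preprocess_fastq(fq, cfg$adapter3)
  cl <- categorize(pp$tags, refs)
  out <- list(cfg = cfg, refs = refs, planted = planted, sim = sim,
              fastq = fq, pp = pp, cl = cl)
  .sim_cache[[key]] <- out
  out
}
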