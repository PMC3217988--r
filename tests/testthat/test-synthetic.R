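test_that("reference sets honour sizes, length ranges and disjointness", {
  cfg <- sim_config(seed = 601, n_mirna_refs = 10L)
  refs <- make_reference_sets(cfg)
  expect_length(refs$miRNA, 10L)
  expect_true(all(nchar(refs$miRNA) >= 20 & nchar(refs$miRNA) <= 24))
  expect_equal(anyDuplicated(refs$miRNA), 0L)
  for (a in names(refs)) for (b in names(refs)) {
    if (a < b) expect_length(intersect(refs[[a]], refs[[b]]), 0L)
  }
  # a class in the fractions with no reference entries is a config error
  bad <- sim_config(seed = 601, class_sizes = c(rRNA = 0L, siRNA = 30L,
                                                snRNA = 10L, snoRNA = 10L,
                                                tRNA = 30L))
  expect_error(make_reference_sets(bad), "rRNA")
})

test_that("reference generation is byte-identical across repeated runs", {
  cfg <- sim_config(seed = 602)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(make_reference_sets(cfg)$miRNA, f1)
  write_fasta(make_reference_sets(cfg)$miRNA, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted hairpins fold into compliant stem-loops", {
  set.seed(603)
  crit <- duplex_criteria()
  for (i in 1:8) {
    est <- random_seq(700)
    mature <- random_seq(sample(20:24, 1))
    ph <- plant_hairpin(est, mature, seed = 603 + i)
    expect_gte(ph$insert_len, 75)
    expect_lte(ph$insert_len, 343)
    expect_true(ph$offset >= 0 && ph$offset <= 700 - 75)
    # the mature occurs verbatim at the recorded offset
    expect_equal(substr(ph$est, ph$offset + 1, ph$offset + nchar(mature)),
                 mature)
    # fold the insert with the pipeline's own engine and check the duplex
    f <- fold_mfe(ph$insert)
    a <- ph$offset - ph$insert_offset
    ev <- evaluate_candidate(ph$insert, a, nchar(mature),
                             f$structure, f$mfe, crit)
    expect_true(ev$accepted, label = paste("hairpin", i, ev$reason))
    # the structure-inferred star matches the recorded ground truth
    expect_equal(substr(ph$insert, ev$star_start, ev$star_end), ph$star_seq)
    # star is the reverse complement of the mature modulo the 2-nt offsets
    ov <- nchar(mature) - 2
    expect_equal(substr(ph$star_seq, 1, ov),
                 substr(revcomp(mature), 3, nchar(mature)))
  }
})

test_that("hairpin planting validates inputs and is deterministic", {
  est <- strrep("ACGT", 200)
  expect_error(plant_hairpin(est, strrep("A", 19), seed = 1), "20-24")
  expect_identical(plant_hairpin(est, "TGACAGAAGAGAGTGAGCACAT", seed = 7),
                   plant_hairpin(est, "TGACAGAAGAGAGTGAGCACAT", seed = 7))
})

test_that("short ESTs are rejected with an explicit message", {
  expect_error(plant_hairpin(strrep("A", 60), "TGACAGAAGAGAGTGAGCACAT",
                             seed = 1), "too short")
})

test_that("library class mixture matches the configuration within 3 sigma", {
  s <- small_sim()
  truth <- s$sim$origin
  n <- nrow(truth)
  cfg <- s$cfg
  shrink <- 1 - cfg$adapter_only_fraction
  checks <- c(miRNA = cfg$known_mirna_fraction * shrink,
              rRNA = cfg$contaminant_fractions[["rRNA"]] * shrink,
              tRNA = cfg$contaminant_fractions[["tRNA"]] * shrink,
              adapter_only = cfg$adapter_only_fraction)
  for (cls in names(checks)) {
    p <- checks[[cls]]
    obs <- sum(truth$class == cls)
    expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)) + 1,
              label = cls)
  }
  # hairpin reads: mature plus star emissions together
  p <- cfg$hairpin_fraction * shrink
  obs <- sum(truth$class %in% c("hairpin", "hairpin_star"))
  expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  # ground-truth closure: every read is recorded
  expect_setequal(truth$read_id, s$sim$reads$id)
})

test_that("with mutation_rate zero every insert matches its source verbatim", {
  s <- small_sim()
  truth <- s$sim$origin
  mi <- truth[truth$class == "miRNA", ]
  expect_true(all(mi$insert == unname(s$refs$miRNA[mi$source_id])))
  hp <- truth[truth$class == "hairpin", ]
  pre <- s$planted$precursors
  expect_true(all(hp$insert == pre$mature_seq[match(hp$source_id,
                                                    pre$precursor_id)]))
})

test_that("library simulation is byte-identical for a fixed configuration", {
  cfg <- sim_config(seed = 604, n_reads = 2000L)
  refs <- make_reference_sets(cfg)
  s1 <- simulate_library(cfg, refs, NULL)
  s2 <- simulate_library(cfg, refs, NULL)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(s1$reads$id, s1$reads$seq, s1$reads$qual, f1)
  write_fastq(s2$reads$id, s2$reads$seq, s2$reads$qual, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(length_weights = c("24" = 0.5, "21" = 0.4)),
               "sum to 1")
  expect_error(sim_config(known_mirna_fraction = 0.8,
                          contaminant_fractions = c(rRNA = 0.3)),
               "more than 1")
})

test_that("planted target sites reproduce their declared scores", {
  set.seed(605)
  txs <- setNames(vapply(1:6, function(i) random_seq(400), ""),
                  paste0("tx", 1:6))
  mirs <- c(m1 = "TGACAGAAGAGAGTGAGCAC")  # 20 nt; G at 2,6,9,11; T at 1,13 ...
  specs <- list(
    list(mirna_id = "m1", transcript_id = "tx1"),
    list(mirna_id = "m1", transcript_id = "tx2", wobble_pos = 11),
    list(mirna_id = "m1", transcript_id = "tx3", mismatch_pos = 3),
    list(mirna_id = "m1", transcript_id = "tx4", indel_pos = 10),
    list(mirna_id = "m1", transcript_id = "tx5", mismatch_pos = c(3, 12),
         wobble_pos = 15))
  ps <- plant_target_sites(txs, mirs, specs, seed = 606)
  expect_equal(ps$sites$expected_score, c(0, 0.5, 1.5, 2.0, 3.0))
  hits <- call_targets(mirs, ps$transcripts, max_indels = 1,
                       max_report = Inf)
  for (r in seq_len(nrow(ps$sites))) {
    h <- hits[hits$transcript_id == ps$sites$transcript_id[r] &
                hits$site_start == ps$sites$site_start[r] + 1, ]
    expect_equal(h$total_score, ps$sites$expected_score[r],
                 label = paste("site", r))
  }
  # defect positions outside the miRNA are rejected
  expect_error(plant_target_sites(txs, mirs,
                                  list(list(mirna_id = "m1",
                                            transcript_id = "tx1",
                                            mismatch_pos = 25)), seed = 1),
               "outside")
  # wobbles are impossible against A/C miRNA bases
  expect_error(plant_target_sites(txs, mirs,
                                  list(list(mirna_id = "m1",
                                            transcript_id = "tx1",
                                            wobble_pos = 3)), seed = 1),
               "wobble impossible")
})
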