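test_that("tags map to ESTs at every exact occurrence on both strands", {
  set.seed(801)
  tag <- random_seq(21)
  est1 <- paste0(random_seq(100), tag, random_seq(50), tag, random_seq(80))
  est2 <- paste0(random_seq(60), revcomp(tag), random_seq(40))
  ests <- c(e1 = est1, e2 = est2, e3 = random_seq(150))
  hits <- map_to_ests(tag, ests)
  h1 <- hits[hits$est_id == "e1", ]
  expect_equal(h1$start, oracle_find_all(tag, est1))
  expect_equal(h1$strand, c("+", "+"))
  h2 <- hits[hits$est_id == "e2", ]
  expect_equal(h2$start, 60)
  expect_equal(h2$strand, "-")
  expect_equal(h2$end, 60 + 21)
  # absent tags yield no rows
  expect_equal(nrow(map_to_ests(random_seq(22), ests)), 0L)
})

test_that("context extraction windows are truncated at EST bounds", {
  set.seed(802)
  est <- random_seq(1000)
  # interior hit: 150 + 21 + 150
  ctx <- extract_context(est, 200, 221, "+", flank = 150)
  expect_equal(nchar(ctx$window), 321)
  expect_equal(ctx$tag_offset, 150)
  expect_equal(substr(ctx$window, 151, 171), substr(est, 201, 221))
  # hit near the 5' end: left-truncated, no padding
  ctx2 <- extract_context(est, 10, 31, "+", flank = 150)
  expect_equal(nchar(ctx2$window), 31 + 150)
  expect_equal(ctx2$tag_offset, 10)
  # minus-strand window is the reverse complement of the plus extraction
  ctx3 <- extract_context(est, 200, 221, "-", flank = 150)
  expect_equal(ctx3$window, revcomp(ctx$window))
  expect_equal(ctx3$tag_offset, 150)
  expect_error(extract_context(est, 990, 1011, "+"), "outside")
})

test_that("hairpin criteria produce the documented rejection codes", {
  crit <- duplex_criteria()
  set.seed(803)
  # compliant planted hairpin
  mature <- random_seq(22)
  hp <- paste0(random_seq(25), mature, "CAAAACAAAC", revcomp(mature),
               random_seq(25))
  f <- fold_mfe(hp)
  ev <- evaluate_candidate(hp, 25L, 22L, f$structure, f$mfe, crit)
  expect_true(ev$accepted)
  expect_equal(ev$arm, "5p")
  # mature spanning the terminal loop
  half <- random_seq(11)
  hp2 <- paste0(random_seq(30), half, "CAAAAC", revcomp(half),
                random_seq(30))
  f2 <- fold_mfe(hp2)
  ev2 <- evaluate_candidate(hp2, 30L, 11 + 6 + 11, f2$structure, f2$mfe,
                            crit)
  expect_false(ev2$accepted)
  expect_equal(ev2$reason, "loop_overlap")
  # hand-constructed structure with five unpaired mature bases
  n <- 60L
  struct <- paste0(strrep("(", 15), strrep(".", 5), strrep(".", 10),
                   strrep(")", 15), strrep(".", 15))
  struct <- paste0(struct, strrep(".", n - nchar(struct)))
  ev3 <- evaluate_candidate(strrep("A", n), 10L, 20L, struct, -10, crit)
  expect_false(ev3$accepted)
  expect_equal(ev3$reason, "excess_mismatch")
  # non-negative folding energy is never accepted
  ev4 <- evaluate_candidate(strrep("A", 60), 10L, 21L, strrep(".", 60), 0,
                            crit)
  expect_false(ev4$accepted)
  expect_equal(ev4$reason, "no_stability")
  expect_error(evaluate_candidate(hp, 200L, 22L, f$structure, f$mfe, crit),
               "outside")
})

test_that("an asymmetric bulge beyond the limit is rejected", {
  # stem with a 4-nt bulge on the mature arm only: pairs 1-10 and 15-24
  left <- paste0(strrep("(", 10), "....", strrep("(", 10))
  right <- strrep(")", 20)
  struct <- paste0(left, strrep(".", 6), right)
  seq <- strrep("A", nchar(struct))
  ev <- evaluate_candidate(seq, 0L, 24L, struct, -10, duplex_criteria())
  expect_false(ev$accepted)
  expect_equal(ev$reason, "bulge_too_large")
})

test_that("star detection is exact-match only", {
  tags <- collapse_tags(c(rep("TGACAGAAGAGAGTGAGCACAT", 5),
                          rep("ACGTACGTACGTACGTACGTA", 2)))
  expect_equal(detect_star("TGACAGAAGAGAGTGAGCACAT", tags), 5L)
  expect_equal(detect_star("TGACAGAAGAGAGTGAGCACAA", tags), 0L)
  expect_equal(detect_star(c("ACGTACGTACGTACGTACGTA", "CCCCCCCCCCCCCCCCCCCCC"),
                           tags), c(2L, 0L))
})

test_that("planted hairpins are recovered and star support is found", {
  cfg <- sim_config(seed = 804, n_reads = 30000L, hairpin_fraction = 0.05,
                    star_emission_prob = 1, star_read_fraction = 0.3,
                    n_ests = 20L, est_length = 700L, n_hairpins = 10L)
  refs <- make_reference_sets(cfg)
  ests <- make_ests(cfg$n_ests, cfg$est_length, seed = cfg$seed)
  planted <- plant_hairpins(ests, cfg, refs)
  sim <- simulate_library(cfg, refs, planted)
  pp <- preprocess_fastq(list(id = sim$reads$id, seq = sim$reads$seq,
                              qual = sim$reads$qual), cfg$adapter3)
  cl <- categorize(pp$tags, refs)
  unann <- pp$tags[pp$tags$sequence %in%
                     cl$labels$sequence[cl$labels$label == "unannotated"], ]
  dv <- discover_mirnas(unann, planted$ests)
  pre <- planted$precursors
  observable <- pre$mature_seq %in% unann$sequence
  recovered <- pre$mature_seq %in% as_dna(dv$candidates$sequence)
  expect_gte(sum(recovered[observable]) / sum(observable), 0.95)
  # star reads were emitted for every precursor; candidates with star tags
  # in the library must report star support
  star_seen <- pre$star_seq %in% unann$sequence
  cand_star <- dv$candidates$star_count[match(as_dna(dv$candidates$sequence),
                                              pre$mature_seq)]
  expect_true(all(cand_star[star_seen[match(as_dna(dv$candidates$sequence),
                                            pre$mature_seq)]] > 0))
  # no background tag founds a candidate
  bg_cands <- setdiff(as_dna(dv$candidates$sequence),
                      c(pre$mature_seq, pre$star_seq))
  expect_length(bg_cands, 0L)
})

test_that("accepted candidates satisfy the precursor invariants", {
  s <- small_sim()
  unann <- s$pp$tags[s$pp$tags$sequence %in%
                       s$cl$labels$sequence[s$cl$labels$label ==
                                              "unannotated"], ]
  dv <- discover_mirnas(unann, s$planted$ests)
  cand <- dv$candidates
  expect_gt(nrow(cand), 0)
  expect_equal(cand$precursor_length, nchar(cand$precursor_seq))
  expect_equal(nchar(cand$structure), cand$precursor_length)
  expect_true(all(cand$folding_energy < 0))
  expect_true(all(cand$length >= 20 & cand$length <= 24))
  for (r in seq_len(nrow(cand))) {
    expect_true(grepl(as_dna(cand$sequence[r]),
                      as_dna(cand$precursor_seq[r]), fixed = TRUE))
    expect_silent(pair_table(cand$structure[r]))
  }
})

test_that("summary statistics of the published candidate table reproduce", {
  tbl <- read_novel_reference_table()
  expect_equal(nrow(tbl), 29L)
  s <- summarize_novel(tbl)
  expect_equal(s$n_families, 25L)
  expect_equal(round(s$mean_mfe, 2), -50.01)
  expect_equal(s$min_mfe, -87.2)
  expect_equal(s$max_mfe, -21.9)
  expect_equal(s$max_precursor, 343L)
  expect_equal(s$min_precursor, 75L)
  expect_equal(s$band_fraction, 0.88)
  expect_equal(s$n_high_reads, 5L)
  expect_equal(s$n_low_reads, 9L)
  expect_equal(s$max_count, 5716L)
  expect_error(summarize_novel(tbl[0, ]), "empty")
})
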