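cols <- function(states, pos = seq_along(states)) {
  data.frame(mirna_pos = pos, state = states)
}

test_that("per-column penalties follow the point scheme", {
  sch <- scoring_scheme()
  expect_equal(score_alignment(cols(rep("WC", 20))), 0)
  gu10 <- cols(c(rep("WC", 9), "GU", rep("WC", 10)))
  expect_equal(score_alignment(gu10, sch), 0.5)
  mm5 <- cols(c(rep("WC", 4), "MM", rep("WC", 15)))
  expect_equal(score_alignment(mm5, sch), 1.5)  # 1.0 + 0.5 seed surcharge
  mm15 <- cols(c(rep("WC", 14), "MM", rep("WC", 5)))
  expect_equal(score_alignment(mm15, sch), 1.0)
  # G:U in the seed is exempt from the surcharge
  gu5 <- cols(c(rep("WC", 4), "GU", rep("WC", 15)))
  expect_equal(score_alignment(gu5, sch), 0.5)
  # a target insertion costs 2.0 and carries no miRNA position
  ins <- data.frame(mirna_pos = c(1:10, NA, 11:20),
                    state = c(rep("WC", 10), "INS_target", rep("WC", 10)))
  expect_equal(score_alignment(ins, sch), 2.0)
  del <- cols(c(rep("WC", 9), "DEL_target", rep("WC", 10)))
  expect_equal(score_alignment(del, sch), 2.0)
  # an indel in the seed never triggers the seed surcharge
  del5 <- cols(c(rep("WC", 4), "DEL_target", rep("WC", 15)))
  expect_equal(score_alignment(del5, sch), 2.0)
  expect_error(score_alignment(cols("XX")), "unknown")
})

test_that("the 20-nt window minimum drops defects in the excluded tail", {
  sch <- scoring_scheme()
  # 22-nt miRNA, single mismatch at position 22: windows 1-20, 2-21, 3-22
  # score 0, 0 and 1; the minimum excludes the defect
  mm22 <- cols(c(rep("WC", 21), "MM"))
  expect_equal(score_alignment(mm22, sch), 1.0)
  expect_equal(window_total(mm22, sch), 0)
  # seed positions keep their full-miRNA numbering inside every window:
  # a mismatch at position 2 costs 1.5 in the only window containing it
  mm2 <- cols(c("WC", "MM", rep("WC", 20)))
  expect_equal(window_total(mm2, sch), 0)        # windows 3-22 exclude it
  mm2_and_21 <- cols(c("WC", "MM", rep("WC", 18), "MM", "WC"))
  # windows: 1-20 -> 1.5; 2-21 -> 2.5; 3-22 -> 1.0
  expect_equal(window_total(mm2_and_21, sch), 1.0)
  # degenerate cases: window covers the whole miRNA
  expect_equal(window_total(cols(rep("WC", 21)), sch), 0)
  expect_equal(window_total(cols(rep("WC", 20)), sch), 0)
})

test_that("a perfect site yields one all-WC alignment with score zero", {
  set.seed(701)
  m <- random_seq(21)
  tx <- paste0(random_seq(50), revcomp(m), random_seq(50))
  alns <- align_duplex(m, tx, max_indels = 0)
  best <- alns[[1]]
  expect_equal(best$total_score, 0)
  expect_equal(best$site_start, 50)
  expect_true(all(best$columns$state == "WC"))
  expect_equal(nrow(best$columns), 21)
  # transcript shorter than the miRNA yields no alignments
  expect_length(align_duplex(m, "ACGT"), 0)
})

test_that("duplex search equals brute-force enumeration on random pairs", {
  set.seed(702)
  for (i in 1:6) {
    m <- random_seq(sample(20:23, 1))
    tx <- paste0(random_seq(120), revcomp(m), random_seq(120))
    for (mi in 0:1) {
      got <- align_duplex(m, tx, max_indels = mi)
      got_df <- data.frame(
        start = vapply(got, `[[`, numeric(1), "site_start"),
        total = vapply(got, `[[`, numeric(1), "total_score"))
      got_df <- got_df[order(got_df$start), ]
      exp_df <- oracle_cluster_best(oracle_duplex_scan(m, tx, mi))
      expect_equal(got_df$start, exp_df$start,
                   label = sprintf("pair %d indels %d", i, mi))
      expect_equal(got_df$total, exp_df$total,
                   label = sprintf("pair %d indels %d", i, mi))
    }
  }
})

test_that("degrading any Watson-Crick column never lowers the total", {
  set.seed(703)
  sch <- scoring_scheme()
  for (i in 1:20) {
    k <- sample(20:24, 1)
    states <- sample(c("WC", "GU", "MM"), k, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))
    base <- window_total(cols(states), sch)
    wc <- which(states == "WC")
    j <- sample(wc, 1)
    for (worse in c("GU", "MM", "DEL_target")) {
      states2 <- states
      states2[j] <- worse
      expect_gte(window_total(cols(states2), sch), base)
    }
  }
})

test_that("total scores stay within the theoretical bounds", {
  set.seed(704)
  sch <- scoring_scheme()
  upper <- sch$window * sch$indel_penalty +
    length(sch$seed_range) * sch$seed_extra_penalty
  for (i in 1:20) {
    k <- sample(20:24, 1)
    states <- sample(c("WC", "GU", "MM", "DEL_target"), k, replace = TRUE)
    tot <- window_total(cols(states), sch)
    expect_gte(tot, 0)
    expect_lte(tot, upper)
  }
})

test_that("acceptance is strictly below 3.0 points", {
  set.seed(705)
  m <- c(mir = "TGACAGAAGAGAGTGAGCAC")
  txs <- setNames(vapply(1:5, function(i) random_seq(300), ""),
                  paste0("tx", 1:5))
  specs <- list(
    list(mirna_id = "mir", transcript_id = "tx1"),                    # 0
    list(mirna_id = "mir", transcript_id = "tx2", wobble_pos = 11),   # 0.5
    list(mirna_id = "mir", transcript_id = "tx3",
         mismatch_pos = c(10, 12), wobble_pos = 15),                  # 2.5
    list(mirna_id = "mir", transcript_id = "tx4",
         mismatch_pos = c(3, 12), wobble_pos = 15),                   # 3.0
    list(mirna_id = "mir", transcript_id = "tx5",
         mismatch_pos = c(3, 10, 12), wobble_pos = 11))               # 4.0
  ps <- plant_target_sites(txs, m, specs, seed = 706)
  expect_equal(ps$sites$expected_score, c(0, 0.5, 2.5, 3.0, 4.0))
  hits <- call_targets(m, ps$transcripts, max_indels = 1, max_report = Inf)
  planted <- merge(hits, ps$sites,
                   by = "transcript_id", suffixes = c("", ".y"))
  planted <- planted[planted$site_start == planted$site_start.y + 1, ]
  expect_equal(sum(planted$accepted), 3L)
  expect_false(planted$accepted[planted$expected_score == 3.0])
})
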