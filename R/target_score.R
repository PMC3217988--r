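#' Penalty scheme for miRNA target prediction
#'
#' The point-based complementarity score: each G:U wobble pair costs 0.5
#' point, each indel 2.0 points and every other non-Watson-Crick pairing
#' 1.0 point. Mismatches (but not G:U wobbles or indels) at miRNA positions
#' 2-7 from the 5' end — the seed region — carry an extra 0.5 point. For
#' miRNAs longer than 20 nt, the score of every window of 20 consecutive
#' miRNA positions is computed and the minimum is the total score. Sites
#' scoring strictly below 3.0 points are accepted as targets.
#'
#' @param wobble_penalty points per G:U wobble pair.
#' @param noncanonical_penalty points per non-wobble mismatch.
#' @param indel_penalty points per inserted or deleted nucleotide.
#' @param seed_extra_penalty extra points per non-wobble mismatch in the seed.
#' @param seed_range integer vector of seed positions (1-based from the
#'   miRNA 5' end).
#' @param window window width in miRNA positions.
#' @param accept_below acceptance threshold; sites are targets iff
#'   `total_score < accept_below` (strict).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(wobble_penalty = 0.5, noncanonical_penalty = 1.0,
                           indel_penalty = 2.0, seed_extra_penalty = 0.5,
                           seed_range = 2:7, window = 20L,
                           accept_below = 3.0) {
  stopifnot(wobble_penalty >= 0, noncanonical_penalty >= 0,
            indel_penalty >= 0, seed_extra_penalty >= 0,
            all(seed_range >= 1), window >= 1)
  structure(list(wobble_penalty = wobble_penalty,
                 noncanonical_penalty = noncanonical_penalty,
                 indel_penalty = indel_penalty,
                 seed_extra_penalty = seed_extra_penalty,
                 seed_range = as.integer(seed_range),
                 window = as.integer(window),
                 accept_below = accept_below),
            class = "scoring_scheme")
}

# pairing state of one miRNA/target base pair (antiparallel, both given
# 5'->3' in the DNA alphabet): WC, GU or MM
pair_state <- function(m, t) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(unname(comp[m]) == t, "WC",
         ifelse((m == "G" & t == "T") | (m == "T" & t == "G"), "GU", "MM"))
}

#' Score alignment columns under a penalty scheme
#'
#' Sums the per-column penalties of a duplex alignment without windowing:
#' WC columns are free, GU wobbles cost `wobble_penalty`, mismatches
#' `noncanonical_penalty` (plus `seed_extra_penalty` when the miRNA position
#' lies in the seed range), and indel columns `indel_penalty`. Indel and GU
#' columns never incur the seed surcharge.
#'
#' @param columns data frame with columns `state` (one of WC, GU, MM,
#'   INS_target, DEL_target) and `mirna_pos` (1-based miRNA position; `NA`
#'   for target insertions).
#' @param scheme a [scoring_scheme()].
#' @return total penalty, points.
#' @export
score_alignment <- function(columns, scheme = scoring_scheme()) {
  st <- columns$state
  if (!all(st %in% c("WC", "GU", "MM", "INS_target", "DEL_target"))) {
    stop("unknown column state")
  }
  pen <- c(WC = 0, GU = scheme$wobble_penalty,
           MM = scheme$noncanonical_penalty,
           INS_target = scheme$indel_penalty,
           DEL_target = scheme$indel_penalty)[st]
  seed_mm <- st == "MM" & !is.na(columns$mirna_pos) &
    columns$mirna_pos %in% scheme$seed_range
  sum(pen) + scheme$seed_extra_penalty * sum(seed_mm)
}

#' Windowed total score of a duplex alignment
#'
#' When the miRNA is longer than the window, the score of every run of
#' `scheme$window` consecutive miRNA positions is computed (seed positions
#' keep their numbering on the full miRNA) and the minimum is returned.
#' Insertion columns travel with their flanking miRNA positions: an
#' insertion is counted in a window iff both flanking positions lie inside
#' it.
#'
#' @inheritParams score_alignment
#' @return total score, points.
#' @export
window_total <- function(columns, scheme = scoring_scheme()) {
  pos <- columns$mirna_pos
  k <- max(pos, na.rm = TRUE)
  if (k <= scheme$window) return(score_alignment(columns, scheme))
  # flanks of insertion columns
  left_flank <- pos
  for (i in seq_along(pos)) {
    if (is.na(pos[i])) left_flank[i] <- if (i > 1) max(pos[seq_len(i - 1)], na.rm = TRUE) else 0L
  }
  scores <- vapply(seq_len(k - scheme$window + 1L), function(p) {
    hi <- p + scheme$window - 1L
    keep <- ifelse(is.na(pos),
                   left_flank >= p & left_flank + 1L <= hi,
                   pos >= p & pos <= hi)
    score_alignment(columns[keep, , drop = FALSE], scheme)
  }, numeric(1))
  min(scores)
}

# all single-gap configurations for a miRNA of length k:
# list of (type, g); type "DEL" = miRNA base g unpaired against a target
# deletion, "INS" = extra target base between miRNA positions g and g+1
gap_configs <- function(k, max_indels) {
  singles <- c(lapply(seq_len(k), function(g) list(type = "DEL", g = g)),
               lapply(seq_len(k - 1L), function(g) list(type = "INS", g = g)))
  cfgs <- list(list())
  if (max_indels >= 1) cfgs <- c(cfgs, lapply(singles, list))
  if (max_indels >= 2) {
    n <- length(singles)
    for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
      cfgs <- c(cfgs, list(list(singles[[a]], singles[[b]])))
    }
  }
  cfgs
}

#' Search a transcript for miRNA target duplexes
#'
#' Evaluates the antiparallel duplex of the miRNA against every transcript
#' offset — ungapped and, up to `max_indels`, with single-nucleotide gap
#' variants — scores each with [window_total()] semantics, and keeps the
#' best-scoring alignment per cluster of overlapping sites (ties broken by
#' leftmost site, then fewest indels).
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet), 18-26 nt.
#' @param transcript transcript sequence, sense strand.
#' @param max_indels maximum number of gap columns per alignment (0-2).
#' @param scheme a [scoring_scheme()].
#' @param mirna_id,transcript_id identifiers carried into the result.
#' @param max_score report only alignments scoring at or below this value
#'   (`Inf` reports the best alignment of every overlap cluster).
#' @return list of `duplex_alignment` objects sorted by `total_score`
#'   ascending, ties by `site_start`; empty list if the transcript is
#'   shorter than the miRNA.
#' @export
align_duplex <- function(mirna, transcript, max_indels = 1L,
                         scheme = scoring_scheme(),
                         mirna_id = "mirna", transcript_id = "transcript",
                         max_score = Inf) {
  stopifnot(max_indels >= 0, max_indels <= 2)
  m <- strsplit(as_dna(mirna), "")[[1]]
  tch <- strsplit(as_dna(transcript), "")[[1]]
  k <- length(m)
  if (k < 18L || k > 26L) stop("miRNA must be 18-26 nt")
  L <- length(tch)
  if (L < k) return(list())

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seed <- scheme$seed_range
  bases <- c("A", "C", "G", "T")
  tint <- match(tch, bases)
  # penalty lookup: miRNA position x target base
  P <- matrix(scheme$noncanonical_penalty, nrow = k, ncol = 4,
              dimnames = list(NULL, bases))
  for (i in seq_len(k)) {
    P[i, unname(comp[m[i]])] <- 0
    if (m[i] == "G") P[i, "T"] <- scheme$wobble_penalty
    if (m[i] == "T") P[i, "G"] <- scheme$wobble_penalty
    if (i %in% seed) {
      mm <- P[i, ] == scheme$noncanonical_penalty
      P[i, mm] <- P[i, mm] + scheme$seed_extra_penalty
    }
  }

  hits <- list()
  for (cfg in gap_configs(k, max_indels)) {
    del_pos <- vapply(Filter(function(x) x$type == "DEL", cfg), `[[`, 1L, "g")
    ins_pos <- vapply(Filter(function(x) x$type == "INS", cfg), `[[`, 1L, "g")
    if (anyDuplicated(del_pos) || anyDuplicated(ins_pos)) next
    site_len <- k - length(del_pos) + length(ins_pos)
    n_off <- L - site_len + 1L
    if (n_off < 1L) next
    s <- 0:(n_off - 1L)
    cons <- as.integer(!(seq_len(k) %in% del_pos))     # target bases consumed at i
    extra <- vapply(seq_len(k), function(i) sum(ins_pos == i), integer(1))
    cum_before <- cumsum(c(0L, (cons + extra)[-k]))
    # per-window cumulative penalties: E[, i] effective penalty of column i
    E <- matrix(0, nrow = n_off, ncol = k)
    for (i in seq_len(k)) {
      if (i %in% del_pos) { E[, i] <- scheme$indel_penalty; next }
      tpos <- s + site_len - cum_before[i]
      E[, i] <- P[cbind(i, tint[tpos])]
    }
    ins_cost <- length(ins_pos) * scheme$indel_penalty
    if (k <= scheme$window) {
      total <- rowSums(E) + ins_cost
    } else {
      cs <- cbind(0, E)
      for (j in 2:(k + 1L)) cs[, j] <- cs[, j] + cs[, j - 1L]
      total <- rep(Inf, n_off)
      for (p in seq_len(k - scheme$window + 1L)) {
        w <- cs[, p + scheme$window] - cs[, p]
        # insertions count only when both flanks are inside the window
        for (g in ins_pos) {
          if (g >= p && g + 1L <= p + scheme$window - 1L) {
            w <- w + scheme$indel_penalty
          }
        }
        total <- pmin(total, w)
      }
    }
    cid <- length(hits) + 1L
    hits[[cid]] <- list(start = s, end = s + site_len, total = total,
                        n_indels = length(del_pos) + length(ins_pos),
                        cfg = cfg)
  }
  n_per <- vapply(hits, function(h) length(h$start), integer(1))
  cand_start <- unlist(lapply(hits, `[[`, "start"), use.names = FALSE)
  cand_end <- unlist(lapply(hits, `[[`, "end"), use.names = FALSE)
  cand_total <- unlist(lapply(hits, `[[`, "total"), use.names = FALSE)
  cand_ind <- rep(vapply(hits, `[[`, integer(1), "n_indels"), n_per)
  cand_cfg <- rep(seq_along(hits), n_per)
  # reduce overlapping sites to the best alignment per overlap cluster
  # (min total, then fewest indels, then leftmost)
  ord <- order(cand_start, cand_end)
  run_max_end <- cummax(cand_end[ord])
  cluster_of_ord <- cumsum(c(TRUE, cand_start[ord][-1L] >=
                               run_max_end[-length(ord)]))
  cluster <- integer(length(ord))
  cluster[ord] <- cluster_of_ord
  sel <- order(cluster, cand_total, cand_ind, cand_start)
  keep <- sel[!duplicated(cluster[sel])]
  keep <- keep[cand_total[keep] <= max_score]
  keep <- keep[order(cand_total[keep], cand_start[keep])]

  lapply(keep, function(r) {
    build_alignment(m, tch, cand_start[r], hits[[cand_cfg[r]]]$cfg,
                    scheme, mirna_id, transcript_id, cand_total[r])
  })
}

# materialize the column table of one (offset, gap configuration) alignment
build_alignment <- function(m, tch, s, cfg, scheme, mirna_id, transcript_id,
                            total = NULL) {
  k <- length(m)
  del_pos <- vapply(Filter(function(x) x$type == "DEL", cfg), `[[`, 1L, "g")
  ins_pos <- vapply(Filter(function(x) x$type == "INS", cfg), `[[`, 1L, "g")
  site_len <- k - length(del_pos) + length(ins_pos)
  cons <- as.integer(!(seq_len(k) %in% del_pos))
  extra <- vapply(seq_len(k), function(i) sum(ins_pos == i), integer(1))
  cum_before <- cumsum(c(0L, (cons + extra)[-k]))
  tpos <- s + site_len - cum_before
  is_del <- seq_len(k) %in% del_pos
  state <- ifelse(is_del, "DEL_target",
                  unname(pair_state(m, tch[ifelse(is_del, 1L, tpos)])))
  target_char <- ifelse(is_del, "-", tch[ifelse(is_del, 1L, tpos)])
  columns <- data.frame(mirna_pos = seq_len(k), state = state,
                        mirna_char = m, target_char = target_char,
                        stringsAsFactors = FALSE)
  for (g in sort(ins_pos, decreasing = TRUE)) {
    ins_row <- data.frame(mirna_pos = NA_integer_, state = "INS_target",
                          mirna_char = "-",
                          target_char = tch[s + site_len - cum_before[g] -
                                              cons[g]],
                          stringsAsFactors = FALSE)
    columns <- rbind(columns[seq_len(g), ], ins_row,
                     columns[seq(g + 1L, k), ])
  }
  rownames(columns) <- NULL
  if (is.null(total)) total <- window_total(columns, scheme)
  structure(list(mirna_id = mirna_id, transcript_id = transcript_id,
                 site_start = s, site_end = s + site_len,
                 columns = columns, total_score = total,
                 n_indels = length(del_pos) + length(ins_pos)),
            class = "duplex_alignment")
}

#' Render a duplex alignment as three-row text
#'
#' Top row: miRNA 5'->3' (RNA alphabet); middle row: `|` for Watson-Crick
#' pairs, `o` for G:U wobbles, spaces for mismatches and gaps; bottom row:
#' target site 3'->5'.
#'
#' @param x a `duplex_alignment`.
#' @param ... unused.
#' @return character vector of three lines.
#' @method format duplex_alignment
#' @export
format.duplex_alignment <- function(x, ...) {
  sym <- c(WC = "|", GU = "o", MM = " ", INS_target = " ", DEL_target = " ")
  c(paste0("miRNA  5' ", paste(as_rna(x$columns$mirna_char), collapse = ""), " 3'"),
    paste0("          ", paste(sym[x$columns$state], collapse = "")),
    paste0("target 3' ", paste(as_rna(x$columns$target_char), collapse = ""), " 5'"))
}

#' Print a duplex alignment
#' @param x a `duplex_alignment`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s  site [%d,%d)  score %.1f\n",
              x$mirna_id, x$transcript_id, x$site_start, x$site_end,
              x$total_score))
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Call miRNA targets across transcript collections
#'
#' Runs [align_duplex()] for every (miRNA, transcript) pair and reports all
#' non-overlapping sites, flagging as accepted those with total score
#' strictly below `scheme$accept_below`.
#'
#' @param mirnas named character vector of miRNA sequences (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param scheme a [scoring_scheme()].
#' @param max_indels maximum gap columns per alignment.
#' @param max_report report only sites with total score at or below this
#'   value (the accepted flag is unaffected).
#' @return data frame with one row per reported site: `mirna_id`,
#'   `transcript_id`, `site_start` (1-based), `site_end` (inclusive),
#'   `total_score`, `n_indels`, `accepted`, `alignment` (three-row text,
#'   newline-separated).
#' @export
call_targets <- function(mirnas, transcripts, scheme = scoring_scheme(),
                         max_indels = 1L, max_report = scheme$accept_below) {
  stopifnot(length(mirnas) > 0, length(transcripts) > 0)
  if (is.null(names(mirnas))) names(mirnas) <- paste0("mir", seq_along(mirnas))
  if (is.null(names(transcripts))) {
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  }
  rows <- list()
  for (mi in names(mirnas)) {
    for (tx in names(transcripts)) {
      alns <- align_duplex(mirnas[[mi]], transcripts[[tx]], max_indels,
                           scheme, mirna_id = mi, transcript_id = tx,
                           max_score = max_report)
      for (a in alns) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mi, transcript_id = tx,
          site_start = a$site_start + 1L, site_end = a$site_end,
          total_score = a$total_score, n_indels = a$n_indels,
          accepted = a$total_score < scheme$accept_below,
          alignment = paste(format(a), collapse = "\n"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      total_score = numeric(0), n_indels = integer(0),
                      accepted = logical(0), alignment = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$total_score, out$mirna_id, out$transcript_id, out$site_start), ]
}
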