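#' Hairpin duplex acceptance criteria
#'
#' Codified stem-loop criteria for plant miRNA precursors: the mature must
#' lie wholly in one stem arm with at most `max_unpaired_mature` unpaired
#' bases, no asymmetric bulge larger than `max_bulge` inside the
#' miRNA/miRNA* duplex, the mature must not span the terminal loop, and the
#' structure must have negative folding energy. The trimmed precursor must
#' fall within `[min_precursor, max_precursor]` nt.
#'
#' @param max_unpaired_mature maximum unpaired mature bases.
#' @param max_bulge maximum asymmetric bulge inside the duplex, nt.
#' @param overhang 3' overhang used to infer the star strand, nt.
#' @param min_precursor,max_precursor precursor length bounds, nt.
#' @return an object of class `duplex_criteria`.
#' @export
duplex_criteria <- function(max_unpaired_mature = 4L, max_bulge = 2L,
                            overhang = 2L, min_precursor = 50L,
                            max_precursor = 400L) {
  stopifnot(max_unpaired_mature >= 0, max_bulge >= 0, overhang >= 0,
            min_precursor >= 0, max_precursor >= min_precursor)
  structure(list(max_unpaired_mature = as.integer(max_unpaired_mature),
                 max_bulge = as.integer(max_bulge),
                 overhang = as.integer(overhang),
                 min_precursor = as.integer(min_precursor),
                 max_precursor = as.integer(max_precursor)),
            class = "duplex_criteria")
}

#' Map tags to an EST collection by exact matching
#'
#' Finds every exact occurrence of each tag, or of its reverse complement,
#' in the ESTs.
#'
#' @param tags character vector of tag sequences (or an `srna_tags` data
#'   frame, in which case its `sequence` column is used).
#' @param ests named character vector of EST sequences.
#' @return data frame with columns `tag`, `est_id`, `start` (0-based),
#'   `end` (half-open) and `strand` (`+`/`-`); zero rows when nothing maps.
#' @export
map_to_ests <- function(tags, ests) {
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- as_dna(tags)
  est_set <- Biostrings::DNAStringSet(as_dna(ests))
  names(est_set) <- names(ests)
  scan <- function(seqs, strand) {
    rows <- list()
    for (w in unique(nchar(seqs))) {
      grp <- seqs[nchar(seqs) == w]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(grp)))
      for (e in seq_along(est_set)) {
        m <- Biostrings::matchPDict(pd, est_set[[e]])
        hits <- which(S4Vectors::elementNROWS(m) > 0)
        for (h in hits) {
          st <- BiocGenerics::start(m[[h]])
          rows[[length(rows) + 1L]] <- data.frame(
            tag = if (strand == "+") unname(grp[h]) else revcomp(unname(grp[h])),
            est_id = names(est_set)[e],
            start = st - 1L, end = st - 1L + w, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
    rows
  }
  fwd <- scan(tags, "+")
  rev <- scan(revcomp(tags), "-")
  out <- do.call(rbind, c(fwd, rev))
  if (is.null(out)) {
    return(data.frame(tag = character(0), est_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out[order(out$tag, out$est_id, out$start, out$strand), ]
}

#' Extract the flanking context of an EST hit
#'
#' Returns the EST subsequence from `start - flank` to `end + flank`
#' (truncated at the EST boundaries), reverse-complemented for minus-strand
#' hits so that the tag reads 5' to 3' within the window.
#'
#' @param est EST sequence.
#' @param start,end tag hit, 0-based half-open.
#' @param strand `+` or `-`.
#' @param flank context size each side, nt.
#' @return list with `window` (sequence), `tag_offset` (0-based tag start
#'   within the window) and `window_start` (0-based window start on the EST
#'   plus strand).
#' @export
extract_context <- function(est, start, end, strand = "+", flank = 150L) {
  n <- nchar(est)
  if (start < 0 || end > n || end <= start) stop("hit outside EST")
  a <- max(0L, start - flank)
  b <- min(n, end + flank)
  window <- substr(est, a + 1L, b)
  if (strand == "-") {
    window <- revcomp(window)
    tag_offset <- b - end
  } else {
    tag_offset <- start - a
  }
  list(window = window, tag_offset = tag_offset, window_start = a)
}

#' Evaluate a folded context window as a miRNA precursor candidate
#'
#' Applies the duplex criteria to the tag (putative mature) within the
#' folded window: the mature must sit wholly in one stem arm with at most
#' `criteria$max_unpaired_mature` unpaired bases, have no asymmetric bulge
#' larger than `criteria$max_bulge` inside the duplex, not span the terminal
#' loop, and the structure must fold with negative energy. On acceptance the
#' star strand (duplex partner with 2-nt 3' overhangs) and the trimmed
#' precursor (smallest balanced window containing the mature/star duplex and
#' its closing stem) are returned.
#'
#' @param window context window sequence.
#' @param tag_offset 0-based mature start within the window.
#' @param tag_len mature length, nt.
#' @param structure dot-bracket structure of the window.
#' @param mfe folding energy of the window.
#' @param criteria a [duplex_criteria()].
#' @return list with `accepted` (logical), `reason` (`"ok"` or a
#'   machine-readable rejection code), and on acceptance `arm` (`5p`/`3p`),
#'   `star_start`/`star_end` and `precursor_start`/`precursor_end` (all
#'   1-based inclusive within the window).
#' @export
evaluate_candidate <- function(window, tag_offset, tag_len, structure, mfe,
                               criteria = duplex_criteria()) {
  n <- nchar(window)
  if (nchar(structure) != n) stop("structure length does not match window")
  ms <- tag_offset + 1L
  me <- tag_offset + tag_len
  if (ms < 1L || me > n) stop("tag position outside window")
  reject <- function(reason) list(accepted = FALSE, reason = reason)
  if (mfe >= 0) return(reject("no_stability"))
  pt <- pair_table(structure)
  mp <- pt[ms:me]
  paired_i <- (ms:me)[!is.na(mp)]
  partners <- mp[!is.na(mp)]
  # a mature pairing with itself spans the terminal loop
  if (any(partners >= ms & partners <= me)) return(reject("loop_overlap"))
  if (length(partners) > 0L && !(all(partners > me) || all(partners < ms))) {
    return(reject("loop_overlap"))
  }
  if (sum(is.na(mp)) > criteria$max_unpaired_mature) {
    return(reject("excess_mismatch"))
  }
  if (length(partners) == 0L) return(reject("excess_mismatch"))
  arm <- if (all(partners > me)) "5p" else "3p"
  # partners must step outward monotonically along the mature
  if (any(diff(partners) >= 0)) return(reject("inconsistent_duplex"))
  for (j in seq_len(length(paired_i) - 1L)) {
    di <- paired_i[j + 1L] - paired_i[j] - 1L
    dj <- abs(partners[j] - partners[j + 1L]) - 1L
    if (abs(di - dj) > criteria$max_bulge) return(reject("bulge_too_large"))
  }
  # star strand: duplex partner with 2-nt 3' overhangs, projecting over
  # unpaired mature ends
  i1 <- paired_i[1L]; iL <- paired_i[length(paired_i)]
  p_ms <- pt[i1] + (i1 - ms)
  p_me <- pt[iL] - (me - iL)
  star_start <- max(1L, p_me + criteria$overhang)
  star_end <- min(n, p_ms + criteria$overhang)
  if (star_end <= star_start) return(reject("inconsistent_duplex"))
  # trim: smallest balanced window containing mature and star, extended
  # outward through the closing stem (pairs enclosing the duplex, tolerating
  # interior loops of up to 4 nt per side)
  lo <- min(ms, star_start); hi <- max(me, star_end)
  repeat {
    prt <- pt[lo:hi]
    out <- prt[!is.na(prt) & (prt < lo | prt > hi)]
    if (length(out) == 0L) break
    lo <- min(lo, out); hi <- max(hi, out)
  }
  repeat {
    ext <- FALSE
    for (a in (lo - 1L):max(1L, lo - 5L)) {
      if (a < 1L) break
      if (!is.na(pt[a]) && pt[a] > hi && pt[a] <= hi + 5L) {
        lo <- a; hi <- pt[a]; ext <- TRUE; break
      }
    }
    if (!ext) break
  }
  plen <- hi - lo + 1L
  if (plen < criteria$min_precursor) return(reject("precursor_too_short"))
  if (plen > criteria$max_precursor) return(reject("precursor_too_long"))
  list(accepted = TRUE, reason = "ok", arm = arm,
       star_start = star_start, star_end = star_end,
       precursor_start = lo, precursor_end = hi)
}

#' Discover novel miRNA candidates from unannotated tags
#'
#' Maps tags to ESTs, extracts the flanking context of every exact hit,
#' folds it to its minimum-free-energy structure, applies the hairpin
#' criteria, trims accepted windows to the minimal stem-loop containing the
#' miRNA/miRNA* duplex, refolds the trimmed precursor (rejecting candidates
#' whose trimmed refold no longer satisfies the criteria), deduplicates by
#' precursor sequence and looks up miRNA* read support in the tag set.
#'
#' @param tags an `srna_tags` data frame (normally the unannotated subset).
#' @param ests named character vector of EST sequences.
#' @param criteria a [duplex_criteria()].
#' @param engine folding engine, see [resolve_fold_engine()].
#' @param flank context size each side of a hit, nt.
#' @param min_count minimum tag count to enter discovery.
#' @return list with `candidates` (data frame: `name`, `count`, `sequence`
#'   (RNA), `length`, `est_id`, `precursor_length`, `folding_energy`,
#'   `star_seq`, `star_count`, `arm`, `precursor_seq`, `structure`), sorted
#'   by descending count, and `rejections` (data frame: `tag`, `est_id`,
#'   `start`, `reason`).
#' @export
discover_mirnas <- function(tags, ests, criteria = duplex_criteria(),
                            engine = "auto", flank = 150L, min_count = 1L) {
  pool <- tags[tags$count >= min_count &
                 tags$length >= 20L & tags$length <= 24L, , drop = FALSE]
  empty_cand <- data.frame(
    name = character(0), count = integer(0), sequence = character(0),
    length = integer(0), est_id = character(0),
    precursor_length = integer(0), folding_energy = numeric(0),
    star_seq = character(0), star_count = integer(0), arm = character(0),
    precursor_seq = character(0), structure = character(0))
  rej <- list()
  if (nrow(pool) == 0L) {
    return(list(candidates = empty_cand,
                rejections = data.frame(tag = character(0),
                                        est_id = character(0),
                                        start = integer(0),
                                        reason = character(0))))
  }
  hits <- map_to_ests(pool$sequence, ests)
  cands <- list()
  if (nrow(hits) > 0L) {
    ctx <- lapply(seq_len(nrow(hits)), function(r) {
      extract_context(ests[[hits$est_id[r]]], hits$start[r], hits$end[r],
                      hits$strand[r], flank)
    })
    folded <- fold_mfe(vapply(ctx, `[[`, character(1), "window"), engine)
    for (r in seq_len(nrow(hits))) {
      tl <- nchar(hits$tag[r])
      ev <- evaluate_candidate(ctx[[r]]$window, ctx[[r]]$tag_offset, tl,
                               folded$structure[r], folded$mfe[r], criteria)
      if (!ev$accepted) {
        rej[[length(rej) + 1L]] <- data.frame(
          tag = hits$tag[r], est_id = hits$est_id[r], start = hits$start[r],
          reason = ev$reason, stringsAsFactors = FALSE)
        next
      }
      pre_seq <- substr(ctx[[r]]$window, ev$precursor_start, ev$precursor_end)
      refold <- fold_mfe(pre_seq, engine)
      new_off <- ctx[[r]]$tag_offset - (ev$precursor_start - 1L)
      ev2 <- evaluate_candidate(pre_seq, new_off, tl,
                                refold$structure, refold$mfe, criteria)
      if (!ev2$accepted) {
        rej[[length(rej) + 1L]] <- data.frame(
          tag = hits$tag[r], est_id = hits$est_id[r], start = hits$start[r],
          reason = paste0("trim_refold:", ev2$reason),
          stringsAsFactors = FALSE)
        next
      }
      star <- substr(pre_seq, ev2$star_start, ev2$star_end)
      cands[[length(cands) + 1L]] <- data.frame(
        mature = hits$tag[r], est_id = hits$est_id[r],
        precursor_seq = pre_seq, precursor_length = nchar(pre_seq),
        folding_energy = refold$mfe, structure = refold$structure,
        star_seq = star, arm = ev2$arm, stringsAsFactors = FALSE)
    }
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(tag = character(0), est_id = character(0),
               start = integer(0), reason = character(0))
  if (length(cands) == 0L) {
    return(list(candidates = empty_cand, rejections = rejections))
  }
  cand <- do.call(rbind, cands)
  cand$count <- tags$count[match(cand$mature, tags$sequence)]
  cand <- cand[order(-cand$count, cand$mature), , drop = FALSE]
  # deduplicate: one report per hairpin locus. A tag whose sequence already
  # lies inside a kept precursor (e.g. the star arm of a kept candidate)
  # does not found a second candidate.
  keep <- logical(nrow(cand))
  kept_pre <- character(0)
  for (i in seq_len(nrow(cand))) {
    dup <- any(vapply(kept_pre, function(p) {
      grepl(cand$mature[i], p, fixed = TRUE)
    }, logical(1))) || cand$precursor_seq[i] %in% kept_pre
    if (!dup) {
      keep[i] <- TRUE
      kept_pre <- c(kept_pre, cand$precursor_seq[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand$star_count <- detect_star(cand$star_seq, tags)
  out <- data.frame(
    name = sprintf("novel-miR%d", seq_len(nrow(cand))),
    count = cand$count, sequence = as_rna(cand$mature),
    length = nchar(cand$mature), est_id = cand$est_id,
    precursor_length = cand$precursor_length,
    folding_energy = cand$folding_energy,
    star_seq = as_rna(cand$star_seq), star_count = cand$star_count,
    arm = cand$arm, precursor_seq = as_rna(cand$precursor_seq),
    structure = cand$structure, stringsAsFactors = FALSE)
  list(candidates = out, rejections = rejections)
}

#' Look up miRNA* read support for star sequences in a tag set
#'
#' Exact match only, consistent with the classification rule; unsupported
#' stars get count 0.
#'
#' @param star_seqs character vector of star sequences.
#' @param tags an `srna_tags` data frame.
#' @return integer vector of read counts.
#' @export
detect_star <- function(star_seqs, tags) {
  idx <- match(as_dna(star_seqs), tags$sequence)
  ifelse(is.na(idx), 0L, tags$count[idx])
}

#' Summary statistics of a novel-miRNA candidate table
#'
#' Works on any table with `name`, `count`, `precursor_length` and
#' `folding_energy` columns, where miRNA* rows (if present) are marked
#' either by an `is_star` column or by a trailing `*` in `name`. Folding
#' energy statistics are computed over all rows (miRNA* rows included);
#' precursor-length statistics and the length-band fraction over unique
#' precursors (the non-star rows); read-count thresholds over families
#' (non-star rows), strictly greater / strictly less.
#'
#' @param tbl candidate table.
#' @param band precursor length band of interest, nt.
#' @param high_reads,low_reads strict read-count thresholds.
#' @return list with `n_rows`, `n_families`, `mean_mfe`, `min_mfe`,
#'   `max_mfe`, `min_precursor`, `max_precursor`, `band_fraction`,
#'   `n_high_reads`, `n_low_reads`, `max_count`.
#' @export
summarize_novel <- function(tbl, band = c(75, 188), high_reads = 1000,
                            low_reads = 10) {
  if (nrow(tbl) == 0L) stop("summarize_novel: empty candidate table")
  is_star <- if ("is_star" %in% names(tbl)) tbl$is_star else
    grepl("\\*$", tbl$name)
  fam <- tbl[!is_star, , drop = FALSE]
  list(n_rows = nrow(tbl),
       n_families = nrow(fam),
       mean_mfe = mean(tbl$folding_energy),
       min_mfe = min(tbl$folding_energy),
       max_mfe = max(tbl$folding_energy),
       min_precursor = min(fam$precursor_length),
       max_precursor = max(fam$precursor_length),
       band_fraction = mean(fam$precursor_length >= band[1] &
                              fam$precursor_length <= band[2]),
       n_high_reads = sum(fam$count > high_reads),
       n_low_reads = sum(fam$count < low_reads),
       max_count = max(fam$count))
}

#' Published novel peanut miRNA reference table
#'
#' A transcribed summary table of 25 novel peanut miRNA families (plus four
#' miRNA* partners) reported from a deep-sequenced peanut small-RNA library,
#' bundled so summary statistics can be regression-tested against printed
#' values.
#'
#' @return data frame with columns `name`, `count`, `sequence`,
#'   `length`, `est_id`, `precursor_length`, `folding_energy`.
#' @export
read_novel_reference_table <- function() {
  read.delim(system.file("extdata", "peanut_novel_mirnas.tsv",
                         package = "sRNAmine"),
             stringsAsFactors = FALSE)
}
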