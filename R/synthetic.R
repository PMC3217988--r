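# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defines the conditions a simulated small-RNA sequencing library emulates:
#' an 18-28 nt insert population dominated by the 24 nt and 21 nt classes,
#' known-miRNA reads with skewed family abundances, reads emitted by hairpin
#' precursors planted in ESTs (with optional miRNA* emission), ncRNA
#' contaminant fragments, adapter-adapter ligation products and a uniform
#' unannotated background. Class proportions default to the published
#' peanut library composition (miRNA 9.52%, rRNA 4.08%, siRNA 8.85%, snRNA
#' 0.02%, snoRNA 0.01%, tRNA 3.17%, the remainder unannotated), and the
#' length weights to the published distribution (24 nt 48%, 21 nt 20.9%,
#' 23 nt 7.7%, 22 nt 7.2%).
#'
#' @param seed integer RNG seed.
#' @param n_reads number of reads to simulate.
#' @param length_weights named numeric vector mapping insert length (nt) to
#'   probability; must sum to 1.
#' @param known_mirna_fraction fraction of reads drawn from the known mature
#'   miRNA reference set.
#' @param contaminant_fractions named fractions per ncRNA contaminant class.
#' @param hairpin_fraction fraction of reads emitted by planted hairpin
#'   precursors (novel miRNAs).
#' @param adapter3,adapter5 adapter sequences (arbitrary documented
#'   constants; only 3' adapter read-through is simulated).
#' @param star_emission_prob probability that a planted precursor emits
#'   miRNA* reads at all.
#' @param star_read_fraction among reads of a star-emitting precursor, the
#'   fraction that are miRNA* rather than mature.
#' @param mutation_rate per-base sequencing error probability.
#' @param low_quality_fraction fraction of reads given a low-quality string.
#' @param adapter_only_fraction fraction of reads that are adapter-adapter
#'   ligation products.
#' @param read_length machine read length, nt.
#' @param n_mirna_refs,class_sizes reference set sizes (matures; per
#'   contaminant class).
#' @param n_ests,est_length,n_hairpins EST collection size and how many ESTs
#'   receive a planted hairpin.
#' @param family_skew_alpha Zipf exponent of the known-miRNA family
#'   abundance skew.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 100000L,
                       length_weights = c("18" = 0.021, "19" = 0.020,
                                          "20" = 0.050, "21" = 0.209,
                                          "22" = 0.072, "23" = 0.077,
                                          "24" = 0.480, "25" = 0.030,
                                          "26" = 0.020, "27" = 0.011,
                                          "28" = 0.010),
                       known_mirna_fraction = 0.0952,
                       contaminant_fractions = c(rRNA = 0.0408,
                                                 siRNA = 0.0885,
                                                 snRNA = 0.0002,
                                                 snoRNA = 0.0001,
                                                 tRNA = 0.0317),
                       hairpin_fraction = 0.01,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       star_emission_prob = 0.2,
                       star_read_fraction = 0.08,
                       mutation_rate = 0,
                       low_quality_fraction = 0.05,
                       adapter_only_fraction = 0.03,
                       read_length = 36L,
                       n_mirna_refs = 60L,
                       class_sizes = c(rRNA = 30L, siRNA = 30L, snRNA = 10L,
                                       snoRNA = 10L, tRNA = 30L),
                       n_ests = 40L, est_length = 800L, n_hairpins = 20L,
                       family_skew_alpha = 1.3) {
  if (abs(sum(length_weights) - 1) > 1e-9) {
    stop("length_weights must sum to 1")
  }
  props <- known_mirna_fraction + sum(contaminant_fractions) +
    hairpin_fraction
  if (props > 1) stop("class proportions sum to more than 1")
  lens <- as.integer(names(length_weights))
  if (any(lens < 17L | lens > 30L)) {
    stop("length_weights lengths must lie in 17-30 nt")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate disjoint reference sequence sets
#'
#' Produces a mature miRNA reference (20-24 nt, family-structured
#' identifiers like `ahy-miR156a`) plus one set per contaminant class named
#' in `config$contaminant_fractions`. No sequence appears in two classes.
#'
#' @param config a [sim_config()].
#' @return named list of named character vectors, one per class
#'   (`miRNA`, plus the contaminant classes).
#' @export
make_reference_sets <- function(config) {
  needed <- names(config$contaminant_fractions)
  sizes <- config$class_sizes[needed]
  if (any(is.na(sizes) | sizes == 0L)) {
    stop("class size missing or zero for a class in contaminant_fractions: ",
         paste(needed[is.na(sizes) | sizes == 0L], collapse = ", "))
  }
  with_seed(config$seed, {
    seen <- character(0)
    draw <- function(n, lens) {
      out <- character(0)
      while (length(out) < n) {
        cand <- random_dna(sample(lens$len, n - length(out), replace = TRUE,
                                  prob = lens$w))
        cand <- setdiff(unique(cand), seen)
        out <- c(out, cand)
      }
      seen <<- c(seen, out)
      out
    }
    # mature miRNAs: 20-24 nt, length weights renormalized over that range
    lw <- config$length_weights
    ml <- as.integer(names(lw))
    keep <- ml >= 20L & ml <= 24L
    mir_lens <- list(len = ml[keep], w = lw[keep] / sum(lw[keep]))
    matures <- draw(config$n_mirna_refs, mir_lens)
    fam_numbers <- c(156, 159, 160, 162, 164, 166, 167, 168, 169, 171,
                     172, 319, 390, 393, 396, 398, 408, 482, 1507, 2118)
    fam <- fam_numbers[((seq_along(matures) - 1L) %% length(fam_numbers)) + 1L]
    member <- letters[ave(fam, fam, FUN = seq_along)]
    names(matures) <- sprintf("ahy-miR%d%s", fam, member)
    refs <- list(miRNA = matures)
    frag_keep <- ml >= 18L & ml <= 28L
    frag_lens <- list(len = ml[frag_keep], w = lw[frag_keep] / sum(lw[frag_keep]))
    for (cls in needed) {
      s <- draw(sizes[[cls]], frag_lens)
      names(s) <- sprintf("%s_%03d", cls, seq_along(s))
      refs[[cls]] <- s
    }
    refs
  })
}

#' Generate a random EST collection
#'
#' @param n number of ESTs.
#' @param length EST length, nt.
#' @param seed RNG seed.
#' @return named character vector of EST sequences.
#' @export
make_ests <- function(n, length = 800L, seed = 1L) {
  with_seed(seed, setNames(random_dna(rep(length, n)),
                           sprintf("EST%05d", seq_len(n))))
}

#' Plant a hairpin precursor for a mature miRNA inside an EST
#'
#' Builds a stem-loop insert `lower-stem + mature + loop + revcomp(mature) +
#' revcomp(lower-stem)` whose duplex pairs the mature fully against its star
#' arm, and overwrites a randomly placed window of the EST with it. The star
#' sequence recorded is the duplex partner of the mature with 2-nt 3'
#' overhangs, as later inferred from the folded structure. Insert lengths
#' are drawn so that 88% fall in 75-188 nt and the rest up to 343 nt,
#' mirroring published precursor lengths.
#'
#' @param est EST sequence (character).
#' @param mature mature miRNA sequence, 20-24 nt.
#' @param seed RNG seed.
#' @param loop_range min/max loop length, nt.
#' @return list with `est` (modified sequence), `offset` (0-based start of
#'   the mature within the EST), `star_seq`, `insert`, `insert_offset` and
#'   `insert_len`.
#' @export
plant_hairpin <- function(est, mature, seed = 1L, loop_range = c(8L, 40L)) {
  mature <- as_dna(mature)
  k <- nchar(mature)
  if (k < 20L || k > 24L) stop("mature must be 20-24 nt")
  with_seed(seed, {
    loop_len <- sample(loop_range[1]:loop_range[2], 1L)
    target_len <- if (runif(1) < 0.88) sample(75:188, 1L) else sample(189:343, 1L)
    a <- max(3L, (target_len - 2L * k - loop_len) %/% 2L)
    insert_len <- 2L * a + 2L * k + loop_len
    if (nchar(est) < insert_len) {
      stop("EST too short to host a ", insert_len, " nt hairpin insert")
    }
    lower <- random_dna(a)
    loop <- random_dna(loop_len)
    insert <- paste0(lower, mature, loop, revcomp(mature), revcomp(lower))
    # star: duplex partner of the mature with a 2-nt 3' overhang each side
    star <- substr(insert, a + k + loop_len + 3L, a + 2L * k + loop_len + 2L)
    ins_off <- sample(0:(nchar(est) - insert_len), 1L)
    est_mod <- paste0(substr(est, 1L, ins_off),
                      insert,
                      substr(est, ins_off + insert_len + 1L, nchar(est)))
    list(est = est_mod, offset = ins_off + a, star_seq = star,
         insert = insert, insert_offset = ins_off, insert_len = insert_len)
  })
}

#' Plant hairpins for a set of novel matures into an EST collection
#'
#' @param ests named character vector of ESTs.
#' @param config a [sim_config()]; `n_hairpins` novel matures are generated
#'   (distinct from every reference sequence) and planted into the first
#'   `n_hairpins` ESTs.
#' @param references reference sets from [make_reference_sets()], used to
#'   keep novel matures disjoint from annotated classes.
#' @return list with `ests` (modified collection) and `precursors` (data
#'   frame: `precursor_id`, `est_id`, `mature_offset`, `insert_offset`,
#'   `insert_len`, `mature_seq`, `star_seq`).
#' @export
plant_hairpins <- function(ests, config, references) {
  n <- config$n_hairpins
  if (n > length(ests)) stop("more hairpins requested than ESTs available")
  with_seed(config$seed + 1L, {
    seen <- unlist(references, use.names = FALSE)
    lw <- config$length_weights
    ml <- as.integer(names(lw))
    keep <- ml >= 20L & ml <= 24L
    matures <- character(0)
    while (length(matures) < n) {
      cand <- random_dna(sample(ml[keep], n - length(matures), replace = TRUE,
                                prob = lw[keep] / sum(lw[keep])))
      cand <- setdiff(unique(cand), seen)
      matures <- c(matures, cand)
      seen <- c(seen, cand)
    }
    seeds <- sample.int(1e7, n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- plant_hairpin(ests[[i]], matures[i], seed = seeds[i])
      ests[[i]] <- ph$est
      rows[[i]] <- data.frame(
        precursor_id = sprintf("novel%02d", i), est_id = names(ests)[i],
        mature_offset = ph$offset, insert_offset = ph$insert_offset,
        insert_len = ph$insert_len, mature_seq = matures[i],
        star_seq = ph$star_seq, stringsAsFactors = FALSE)
    }
    list(ests = ests, precursors = do.call(rbind, rows))
  })
}

# flip each base to a random different base with probability `rate`
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(DNA_BASES_CHR, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a small-RNA sequencing library
#'
#' Draws a class for every read (known miRNA, contaminant classes, hairpin
#' precursor, unannotated background, adapter-adapter ligation product),
#' builds the insert, appends the 3' adapter, truncates to the machine read
#' length and attaches quality strings. A complete ground-truth record of
#' every read's origin is returned.
#'
#' @param config a [sim_config()].
#' @param references reference sets from [make_reference_sets()].
#' @param planted result of [plant_hairpins()] (or `NULL` to skip hairpin
#'   reads).
#' @return list with `reads` (list of `id`, `seq`, `qual`), `origin` (data
#'   frame: `read_id`, `class`, `source_id`, `insert`, `low_quality`) and
#'   `precursors` (pass-through from `planted`).
#' @export
simulate_library <- function(config, references, planted = NULL) {
  with_seed(config$seed + 2L, {
    n <- config$n_reads
    cls_names <- c("miRNA", names(config$contaminant_fractions),
                   "hairpin", "background", "adapter_only")
    hairpin_frac <- if (is.null(planted)) 0 else config$hairpin_fraction
    p_assign <- c(config$known_mirna_fraction,
                  unname(config$contaminant_fractions),
                  hairpin_frac)
    p_bg <- 1 - sum(p_assign)
    # adapter-only products displace a slice of every class uniformly
    probs <- c(p_assign, p_bg) * (1 - config$adapter_only_fraction)
    probs <- c(probs, config$adapter_only_fraction)
    cls <- sample(cls_names, n, replace = TRUE, prob = probs)

    insert <- character(n)
    source_id <- character(n)

    # known miRNAs with Zipf family-abundance skew
    idx <- which(cls == "miRNA")
    if (length(idx)) {
      matures <- references$miRNA
      fam <- parse_family(names(matures))
      fam_rank <- match(fam, unique(fam))
      w <- (1 / fam_rank^config$family_skew_alpha)
      w <- w / ave(rep(1, length(w)), fam, FUN = sum)  # split within family
      pick <- sample(seq_along(matures), length(idx), replace = TRUE, prob = w)
      insert[idx] <- unname(matures[pick])
      source_id[idx] <- names(matures)[pick]
    }
    for (cc in names(config$contaminant_fractions)) {
      idx <- which(cls == cc)
      if (length(idx)) {
        pick <- sample(seq_along(references[[cc]]), length(idx), replace = TRUE)
        insert[idx] <- unname(references[[cc]][pick])
        source_id[idx] <- names(references[[cc]])[pick]
      }
    }
    idx <- which(cls == "hairpin")
    if (length(idx)) {
      pre <- planted$precursors
      emits_star <- runif(nrow(pre)) < config$star_emission_prob
      w <- 1 / seq_len(nrow(pre))^1.2
      pick <- sample(seq_len(nrow(pre)), length(idx), replace = TRUE, prob = w)
      is_star <- emits_star[pick] & runif(length(idx)) < config$star_read_fraction
      insert[idx] <- ifelse(is_star, pre$star_seq[pick], pre$mature_seq[pick])
      source_id[idx] <- pre$precursor_id[pick]
      cls[idx][is_star] <- "hairpin_star"
    }
    idx <- which(cls == "background")
    if (length(idx)) {
      known <- c(unlist(references, use.names = FALSE),
                 if (!is.null(planted)) c(planted$precursors$mature_seq,
                                          planted$precursors$star_seq))
      lens <- as.integer(names(config$length_weights))
      bg <- character(0)
      while (length(bg) < length(idx)) {
        cand <- random_dna(sample(lens, length(idx) - length(bg),
                                  replace = TRUE,
                                  prob = config$length_weights))
        cand <- cand[!(cand %in% known)]   # duplicates among bg reads are fine
        bg <- c(bg, cand)
      }
      insert[idx] <- bg
      source_id[idx] <- "background"
    }
    idx <- which(cls == "adapter_only")
    if (length(idx)) {
      insert[idx] <- ""
      source_id[idx] <- "adapter_dimer"
    }

    if (config$mutation_rate > 0) {
      nz <- nchar(insert) > 0
      insert[nz] <- mutate_seqs(insert[nz], config$mutation_rate)
    }

    raw <- substr(paste0(insert, config$adapter3, config$adapter3), 1L,
                  config$read_length)
    low_q <- runif(n) < config$low_quality_fraction
    qual <- ifelse(low_q, strrep("#", nchar(raw)), strrep("I", nchar(raw)))
    id <- sprintf("read%07d", seq_len(n))
    list(reads = list(id = id, seq = raw, qual = qual),
         origin = data.frame(read_id = id, class = cls,
                             source_id = source_id, insert = insert,
                             low_quality = low_q, stringsAsFactors = FALSE),
         precursors = if (is.null(planted)) NULL else planted$precursors)
  })
}

#' Plant miRNA target sites of controlled defect composition
#'
#' Each defect spec plants, for one miRNA, a site that is the exact reverse
#' complement of the miRNA except for the requested G:U wobbles, mismatches
#' and target insertions (positions 1-based from the miRNA 5' end). The
#' expected score under the default penalty scheme is recorded:
#' `0.5*wobbles + 1.0*mismatches + 2.0*indels + 0.5*(mismatches in seed)`.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param mirnas named character vector of miRNA sequences.
#' @param defect_specs list of specs, each a list with `mirna_id`,
#'   `transcript_id`, optional `site_start` (0-based), and integer vectors
#'   `wobble_pos`, `mismatch_pos`, `indel_pos` (possibly empty). A wobble at
#'   a position where the miRNA base is A or C is impossible and errors.
#' @param scheme a [scoring_scheme()] used to record expected scores.
#' @param seed RNG seed for random site placement.
#' @return list with `transcripts` (modified) and `sites` (data frame:
#'   `mirna_id`, `transcript_id`, `site_start` 0-based, `site_len`,
#'   `expected_score`).
#' @export
plant_target_sites <- function(transcripts, mirnas, defect_specs,
                               scheme = scoring_scheme(), seed = 1L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  with_seed(seed, {
    rows <- vector("list", length(defect_specs))
    for (si in seq_along(defect_specs)) {
      spec <- defect_specs[[si]]
      m <- strsplit(as_dna(mirnas[[spec$mirna_id]]), "")[[1]]
      k <- length(m)
      wob <- spec$wobble_pos %||% integer(0)
      mis <- spec$mismatch_pos %||% integer(0)
      ind <- spec$indel_pos %||% integer(0)
      if (any(c(wob, mis, ind) < 1L) || any(c(wob, mis, ind) > k)) {
        stop("defect position outside miRNA length")
      }
      # target chars aligned 3'->5' against miRNA positions 1..k
      t_rev <- unname(comp[m])
      for (p in wob) {
        if (m[p] == "G") t_rev[p] <- "T"
        else if (m[p] == "T") t_rev[p] <- "G"
        else stop("wobble impossible at miRNA position ", p,
                  " (base ", m[p], ")")
      }
      t_rev[mis] <- m[mis]    # equal bases always mismatch, never wobble
      # target insertions between miRNA positions p and p+1
      out <- character(0)
      for (i in seq_len(k)) {
        out <- c(out, t_rev[i])
        if (i %in% ind) {
          ins <- setdiff(DNA_BASES_CHR, unname(comp[c(m[i], m[min(i + 1L, k)])]))[1]
          out <- c(out, ins)
        }
      }
      site <- paste(rev(out), collapse = "")
      tx <- transcripts[[spec$transcript_id]]
      slen <- nchar(site)
      start <- spec$site_start %||% sample(0:(nchar(tx) - slen), 1L)
      if (start + slen > nchar(tx)) stop("site does not fit in transcript")
      transcripts[[spec$transcript_id]] <-
        paste0(substr(tx, 1L, start), site,
               substr(tx, start + slen + 1L, nchar(tx)))
      expected <- scheme$wobble_penalty * length(wob) +
        scheme$noncanonical_penalty * length(mis) +
        scheme$indel_penalty * length(ind) +
        scheme$seed_extra_penalty * sum(mis %in% scheme$seed_range)
      rows[[si]] <- data.frame(
        mirna_id = spec$mirna_id, transcript_id = spec$transcript_id,
        site_start = start, site_len = slen, expected_score = expected,
        stringsAsFactors = FALSE)
    }
    list(transcripts = transcripts, sites = do.call(rbind, rows))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ground truth to disk
#'
#' @param sim result of [simulate_library()].
#' @param dir output directory.
#' @return `dir`, invisibly. Writes `ground_truth.tsv` (read origins) and
#'   `planted.json` (precursor records).
#' @export
write_ground_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$origin[, c("read_id", "class", "source_id")],
            file.path(dir, "ground_truth.tsv"))
  jsonlite::write_json(sim$precursors, file.path(dir, "planted.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
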