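# Independent oracles used to cross-check the implementation on small inputs.
# These re-derive results from the stated rules by direct enumeration and
# share no code with the package internals.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# penalty of one aligned pair under the point scheme, by explicit rules
oracle_pair_penalty <- function(m_char, t_char, m_pos, seed = 2:7) {
  if (t_char == "-" || m_char == "-") return(2.0)           # indel
  if (unname(ORACLE_COMP[m_char]) == t_char) return(0)      # Watson-Crick
  if ((m_char == "G" && t_char == "T") ||
      (m_char == "T" && t_char == "G")) return(0.5)         # G:U wobble
  pen <- 1.0                                                # other mismatch
  if (!is.na(m_pos) && m_pos %in% seed) pen <- pen + 0.5    # seed surcharge
  pen
}

# exhaustively score every (offset, gap placement) of a miRNA against a
# transcript; windowing enumerated explicitly on 20 consecutive miRNA
# positions. Vectorized over offsets only; the per-column geometry is
# derived in reversed-site coordinates, independently of the package's
# index arithmetic. Returns one row per placement.
oracle_duplex_scan <- function(mirna, transcript, max_indels = 1,
                               window = 20) {
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  tt <- strsplit(chartr("Uu", "Tt", toupper(transcript)), "")[[1]]
  k <- length(m)
  L <- length(tt)
  bases <- c("A", "C", "G", "T")
  # penalty of miRNA position i against target base c, from the rules
  P <- matrix(0, nrow = k, ncol = 4, dimnames = list(NULL, bases))
  for (i in 1:k) for (c in bases) {
    P[i, c] <- oracle_pair_penalty(m[i], c, i)
  }
  cfgs <- list(list(type = "none", g = 0L))
  if (max_indels >= 1) {
    for (g in 1:k) cfgs <- c(cfgs, list(list(type = "DEL", g = g)))
    for (g in 1:(k - 1)) cfgs <- c(cfgs, list(list(type = "INS", g = g)))
  }
  tint <- match(tt, bases)
  rows <- list()
  for (cfg in cfgs) {
    slen <- k + switch(cfg$type, none = 0L, DEL = -1L, INS = 1L)
    if (L < slen) next
    s <- 0:(L - slen)
    # reversed site: revsite[j] = tt[s + slen + 1 - j]
    rs <- function(j) tint[s + slen + 1L - j]
    # per-column penalties, one matrix column per alignment column
    pcols <- list(); ppos <- list()
    if (cfg$type == "none") {
      for (i in 1:k) { pcols[[i]] <- P[cbind(i, rs(i))]; ppos[[i]] <- i }
    } else if (cfg$type == "DEL") {
      for (i in 1:k) {
        pcols[[i]] <- if (i < cfg$g) P[cbind(i, rs(i))]
          else if (i == cfg$g) rep(2.0, length(s))
          else P[cbind(i, rs(i - 1L))]
        ppos[[i]] <- i
      }
    } else {
      ci <- 0L
      for (i in 1:k) {
        ci <- ci + 1L
        pcols[[ci]] <- if (i <= cfg$g) P[cbind(i, rs(i))]
          else P[cbind(i, rs(i + 1L))]
        ppos[[ci]] <- i
        if (i == cfg$g) {
          ci <- ci + 1L
          pcols[[ci]] <- rep(2.0, length(s))
          ppos[[ci]] <- NA_integer_
        }
      }
    }
    pen <- do.call(cbind, pcols)
    pos <- unlist(ppos)
    if (k <= window) {
      total <- rowSums(pen)
    } else {
      total <- rep(Inf, length(s))
      for (p in 1:(k - window + 1)) {
        inc <- ifelse(is.na(pos),
                      cfg$g >= p & cfg$g + 1L <= p + window - 1L,
                      pos >= p & pos <= p + window - 1L)
        total <- pmin(total, rowSums(pen[, inc, drop = FALSE]))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = s + slen, total = total,
      n_indels = as.integer(cfg$type != "none"))
  }
  do.call(rbind, rows)
}

# greedy overlap clustering and best-per-cluster reduction, matching the
# documented contract (min total, then fewest indels, then leftmost)
oracle_cluster_best <- function(placements) {
  d <- placements[order(placements$start, placements$end), ]
  cl <- integer(nrow(d)); cur <- 0L; cur_end <- -1L
  for (r in seq_len(nrow(d))) {
    if (d$start[r] >= cur_end) cur <- cur + 1L
    cl[r] <- cur
    cur_end <- max(cur_end, d$end[r])
  }
  out <- do.call(rbind, lapply(split(d, cl), function(sub) {
    sub[order(sub$total, sub$n_indels, sub$start)[1L], ]
  }))
  out[order(out$start), c("start", "total")]
}

# leftmost adapter occurrence by direct scanning of every offset
oracle_clip <- function(read, adapter, max_mm, min_overlap = 6) {
  rl <- nchar(read); al <- nchar(adapter)
  for (p in 0:(rl - min_overlap)) {
    ov <- min(al, rl - p)
    mm <- sum(strsplit(substr(read, p + 1, p + ov), "")[[1]] !=
                strsplit(substr(adapter, 1, ov), "")[[1]])
    if (mm <= max_mm) return(substr(read, 1, p))
  }
  read
}

# all exact occurrences of a pattern in a subject, by gregexpr
oracle_find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
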