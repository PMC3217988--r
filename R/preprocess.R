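#' Clip the 3' adapter from reads
#'
#' Finds the leftmost occurrence of the 3' adapter in each read, allowing up
#' to `max_mismatch` mismatches over the overlapped region (minimum overlap
#' 6 nt; partial adapter suffixes at the read end count), and returns the
#' read prefix before it. Reads without an adapter hit are returned whole;
#' reads that are adapter from their first base yield an empty insert.
#'
#' @param reads character vector of read sequences.
#' @param adapter3 3' adapter sequence, at least 6 nt.
#' @param max_mismatch mismatches tolerated in the adapter match.
#' @param min_overlap minimum read/adapter overlap, nt.
#' @return character vector of inserts (possibly empty strings).
#' @export
clip_adapter <- function(reads, adapter3, max_mismatch = 1L, min_overlap = 6L) {
  adapter3 <- as_dna(adapter3)
  if (nchar(adapter3) < 6L) stop("adapter3 must be at least 6 nt")
  reads <- as_dna(reads)
  len <- .clip_adapter_cpp(reads, adapter3, as.integer(max_mismatch),
                           as.integer(min_overlap))
  substr(reads, 1L, len)
}

#' Mean-quality and ambiguity filter
#'
#' Keeps a read iff its mean Phred quality is at least `min_mean_q`
#' (inclusive) and it contains no ambiguous base (N).
#'
#' @param reads character vector of read sequences.
#' @param quals character vector of Phred+33 quality strings, same lengths.
#' @param min_mean_q minimum mean Phred quality.
#' @return logical vector, `TRUE` = keep.
#' @export
quality_filter <- function(reads, quals, min_mean_q = 20) {
  if (any(nchar(reads) != nchar(quals))) {
    stop("read and quality strings differ in length")
  }
  q <- Biostrings::PhredQuality(quals)
  qint <- as(q, "IntegerList")
  meanq <- sum(qint) / S4Vectors::elementNROWS(qint)
  meanq >= min_mean_q & !grepl("N", reads, fixed = TRUE)
}

#' Insert length filter
#'
#' Keeps inserts strictly longer than 17 nt (i.e. >= `min_len`, default 18)
#' and at most `max_len` nt.
#'
#' @param inserts character vector of insert sequences.
#' @param min_len minimum kept length, nt (inclusive).
#' @param max_len maximum kept length, nt (inclusive).
#' @return logical vector, `TRUE` = keep.
#' @export
length_filter <- function(inserts, min_len = 18L, max_len = 30L) {
  n <- nchar(inserts)
  n >= min_len & n <= max_len
}

#' Collapse inserts into unique tags with counts
#'
#' @param inserts character vector of (filtered) insert sequences.
#' @return data frame of class `srna_tags` with columns `sequence`, `length`
#'   and `count`, sorted by descending count, ties broken lexicographically
#'   by sequence. Collapsing an already collapsed set (each sequence
#'   repeated `count` times) is the identity.
#' @export
collapse_tags <- function(inserts) {
  if (length(inserts) == 0L) {
    out <- data.frame(sequence = character(0), length = integer(0),
                      count = integer(0))
    class(out) <- c("srna_tags", class(out))
    return(out)
  }
  tab <- table(inserts)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$length <- nchar(out$sequence)
  out <- out[order(-out$count, out$sequence), c("sequence", "length", "count")]
  rownames(out) <- NULL
  class(out) <- c("srna_tags", class(out))
  out
}

#' Length distribution of a tag set
#'
#' @param tags an `srna_tags` data frame from [collapse_tags()].
#' @return data frame with one row per length: `length`, `unique_count`,
#'   `total_count`, `total_percent` (summing to 100).
#' @export
length_distribution <- function(tags) {
  if (nrow(tags) == 0L) stop("length_distribution: empty tag set")
  agg <- aggregate(cbind(unique_count = 1, total_count = tags$count),
                   by = list(length = tags$length), FUN = sum)
  agg$total_percent <- 100 * agg$total_count / sum(agg$total_count)
  agg[order(agg$length), ]
}

#' Preprocess a raw FASTQ into collapsed tags
#'
#' The clean-read pipeline: mean-quality/N filtering, 3' adapter clipping,
#' removal of adapter-only reads (adapter-adapter ligation products) and of
#' inserts outside the length window, then collapsing to unique tags. Every
#' raw read lands in exactly one accounting bucket.
#'
#' @param fastq path to a FASTQ file (Phred+33), or a list as returned by
#'   [read_fastq()].
#' @param adapter3 3' adapter sequence.
#' @param min_len,max_len kept insert length window, nt.
#' @param min_mean_q minimum mean Phred quality.
#' @param max_mismatch adapter mismatches tolerated.
#' @return list with `tags` (an `srna_tags` data frame), `stats` (a one-row
#'   data frame: `n_raw`, `n_clean`, `n_adapter_only`, `n_low_quality`,
#'   `n_too_short`), `length_dist`, and `clean` (the clean insert vector,
#'   for ground-truth comparisons).
#' @export
preprocess_fastq <- function(fastq, adapter3, min_len = 18L, max_len = 30L,
                             min_mean_q = 20, max_mismatch = 1L) {
  rd <- if (is.character(fastq)) read_fastq(fastq) else fastq
  n_raw <- length(rd$seq)
  ok_q <- quality_filter(rd$seq, rd$qual, min_mean_q)
  inserts <- clip_adapter(rd$seq[ok_q], adapter3, max_mismatch)
  adapter_only <- nchar(inserts) == 0L
  in_window <- length_filter(inserts, min_len, max_len)
  clean <- inserts[!adapter_only & in_window]
  stats <- data.frame(
    n_raw = n_raw,
    n_clean = length(clean),
    n_adapter_only = sum(adapter_only),
    n_low_quality = sum(!ok_q),
    n_too_short = sum(!adapter_only & !in_window))
  tags <- collapse_tags(clean)
  list(tags = tags, stats = stats,
       length_dist = if (nrow(tags) > 0) length_distribution(tags) else NULL,
       clean = clean)
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the `>tag<rank>_x<count>` convention used by collapsed
#' small-RNA FASTA files.
#'
#' @param tags an `srna_tags` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  seqs <- setNames(tags$sequence,
                   sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count))
  write_fasta(seqs, path)
}

#' Read a collapsed-tag FASTA back into an `srna_tags` data frame
#' @param path path to a FASTA with `>tag<rank>_x<count>` headers.
#' @return an `srna_tags` data frame.
#' @export
read_tags_fasta <- function(path) {
  seqs <- read_fasta(path)
  count <- as.integer(sub(".*_x(\\d+)$", "\\1", names(seqs)))
  out <- data.frame(sequence = unname(seqs), length = nchar(seqs),
                    count = count, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), ]
  rownames(out) <- NULL
  class(out) <- c("srna_tags", class(out))
  out
}

#' @importFrom stats aggregate
NULL
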