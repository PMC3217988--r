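#' @useDynLib sRNAmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors elementNROWS
#' @importFrom BiocGenerics start
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES_CHR <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T. All internal computation uses the DNA
#' alphabet; human-facing tables convert back to RNA with [as_rna()].
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over A/C/G/T (plus any ambiguity codes present).
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Convert a DNA-alphabet string to the RNA alphabet
#' @param x character vector of nucleotide sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement of DNA-alphabet sequences
#' @param x character vector over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

# random DNA strings of given lengths, using the current RNG stream
random_dna <- function(lengths) {
  vapply(lengths, function(l) {
    paste(sample(DNA_BASES_CHR, l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Read a FASTA file as a named character vector
#' @param path path to a FASTA file.
#' @return named character vector of DNA-alphabet sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as_dna(as.character(x)), names(x))
}

#' Write a named character vector as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path path to a FASTQ file.
#' @return list with `id`, `seq` (DNA alphabet) and `qual` character vectors.
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns about dropping its own metadata cols
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = names(x),
       seq = unname(as_dna(as.character(x))),
       qual = unname(as.character(Biostrings::quality(x))))
}

#' Write reads as FASTQ (Phred+33)
#' @param id,seq,qual parallel character vectors: read ids, sequences,
#'   quality strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  x <- Biostrings::DNAStringSet(as_dna(seq))
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::PhredQuality(qual))
  invisible(path)
}

#' Parse a dot-bracket structure into a pairing table
#'
#' @param structure dot-bracket string (round brackets only).
#' @return integer vector `p` with `p[i]` the 1-based partner of position `i`,
#'   or `NA` for unpaired positions.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  p <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    } else if (ch[i] != ".") {
      stop("unexpected character in dot-bracket string: ", ch[i])
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket structure")
  p
}

#' Write a data frame as a TSV file
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
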