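#' Which folding engine will be used?
#'
#' The default engine delegates to ViennaRNA's `RNAfold` when it is on the
#' PATH; otherwise the bundled weighted Nussinov folder is used. The fallback
#' maximises a base-pair weight (GC = 2, AU = GU = 1, minimum loop 3 nt) and
#' reports minus the total weight as a surrogate energy; surrogate energies
#' order structures by stability but are not kcal/mol and are never compared
#' to published folding energies.
#'
#' @param engine `"auto"`, `"vienna"` or `"nussinov"`.
#' @return the resolved engine name, `"vienna"` or `"nussinov"`.
#' @export
resolve_fold_engine <- function(engine = c("auto", "vienna", "nussinov")) {
  engine <- match.arg(engine)
  have_vienna <- nzchar(Sys.which("RNAfold"))
  if (engine == "auto") return(if (have_vienna) "vienna" else "nussinov")
  if (engine == "vienna" && !have_vienna) {
    stop("RNAfold not found on PATH; use engine = 'nussinov'")
  }
  engine
}

#' Fold sequences to their minimum-free-energy structure
#'
#' Returns one lowest-energy secondary structure per input sequence,
#' deterministically for a fixed input and engine.
#'
#' @param seqs character vector of nucleotide sequences (DNA or RNA
#'   alphabet; U and T are equivalent).
#' @param engine folding engine, see [resolve_fold_engine()].
#' @param min_loop minimum hairpin loop size for the fallback folder, nt.
#' @return data frame with columns `seq`, `structure` (dot-bracket), `mfe`
#'   (kcal/mol for the vienna engine; surrogate units otherwise) and
#'   `engine`.
#' @export
fold_mfe <- function(seqs, engine = "auto", min_loop = 3) {
  seqs <- as_dna(seqs)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) stop("fold_mfe: sequences contain non-ACGU/ACGT symbols")
  engine <- resolve_fold_engine(engine)
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(0), structure = character(0),
                      mfe = numeric(0), engine = character(0)))
  }
  if (engine == "vienna") {
    out <- fold_vienna(seqs)
  } else {
    out <- lapply(seqs, function(s) {
      raw <- .nussinov_fold_cpp(s, min_loop)
      prune_short_helices(raw$structure, s)
    })
    out <- data.frame(structure = vapply(out, `[[`, character(1), "structure"),
                      mfe = vapply(out, `[[`, numeric(1), "mfe"))
  }
  data.frame(seq = seqs, structure = out$structure, mfe = out$mfe,
             engine = engine, stringsAsFactors = FALSE)
}

# Pair maximization decorates terminal loops with spurious one- and two-pair
# helices; prune every helix shorter than `min_helix` stacked pairs (the
# same idea as lonely-pair removal in thermodynamic folders) and recompute
# the surrogate energy from the surviving pairs.
prune_short_helices <- function(structure, seq, min_helix = 3L) {
  pt <- pair_table(structure)
  ch <- strsplit(seq, "")[[1]]
  n <- length(pt)
  opens <- which(!is.na(pt) & pt > seq_len(n))
  keep <- rep(FALSE, n)
  visited <- rep(FALSE, n)
  for (i in opens) {
    if (visited[i]) next
    # walk down a stack of strictly nested adjacent pairs
    helix <- i
    while (TRUE) {
      j <- helix[length(helix)]
      if (j + 1L <= n && !is.na(pt[j + 1L]) && pt[j + 1L] == pt[j] - 1L &&
          pt[j + 1L] > j + 1L) {
        helix <- c(helix, j + 1L)
      } else break
    }
    visited[helix] <- TRUE
    if (length(helix) >= min_helix) keep[helix] <- TRUE
  }
  w <- 0
  db <- rep(".", n)
  for (i in which(keep)) {
    j <- pt[i]
    db[i] <- "("; db[j] <- ")"
    pair <- paste0(ch[i], ch[j])
    w <- w + if (pair %in% c("GC", "CG")) 2 else 1
  }
  list(structure = paste(db, collapse = ""), mfe = -w)
}

fold_vienna <- function(seqs) {
  inp <- as.vector(rbind(paste0(">s", seq_along(seqs)), seqs))
  res <- suppressWarnings(
    system2("RNAfold", "--noPS", input = inp, stdout = TRUE))
  # output per record: >name / sequence / structure ( mfe )
  struct_lines <- res[seq(3, length(res), by = 3)]
  m <- regmatches(struct_lines,
                  regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", struct_lines))
  mfe <- as.numeric(gsub("[() ]", "", m))
  structure <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)$", "", struct_lines)
  data.frame(structure = structure, mfe = mfe, stringsAsFactors = FALSE)
}
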