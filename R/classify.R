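#' Exact-match lookup of a tag against a reference set
#'
#' Only perfectly matching sequences count: a single mismatch yields no hit.
#'
#' @param tag one tag sequence.
#' @param reference named character vector of reference sequences.
#' @return character vector of reference ids whose sequence equals the tag
#'   exactly, in reference order (deterministic); empty if none.
#' @export
match_reference <- function(tag, reference) {
  names(reference)[as_dna(reference) == as_dna(tag)]
}

#' Parse a miRNA family name from a mature miRNA identifier
#'
#' Strips any species prefix and trailing member suffixes: `ahy-miR156f-5p`
#' becomes `miR156`.
#'
#' @param ids character vector of mature miRNA identifiers.
#' @return character vector of family names (`miR<number>`), `NA` where no
#'   family pattern is present.
#' @export
parse_family <- function(ids) {
  m <- regmatches(ids, regexpr("miR[0-9]+", ids, ignore.case = TRUE))
  out <- rep(NA_character_, length(ids))
  has <- grepl("miR[0-9]+", ids, ignore.case = TRUE)
  out[has] <- sub("mir", "miR", m, ignore.case = TRUE)
  out
}

#' Categorize tags against reference RNA classes
#'
#' Assigns each tag the first class in `priority` whose reference set
#' contains the tag's sequence exactly; tags matching no class are
#' `unannotated`. Produces the per-class unique/total count summary with
#' percentages computed against the all-tags totals.
#'
#' @param tags an `srna_tags` data frame.
#' @param references named list of reference sets (named character vectors),
#'   one per class.
#' @param priority character vector of class names, highest priority first;
#'   must name classes present in `references`.
#' @return list with `labels` (data frame: `sequence`, `length`, `count`,
#'   `label`, `hit_id`) and `summary` (a `category_summary` data frame with
#'   a `total` row and per-class rows: `category`, `unique_count`,
#'   `unique_percent`, `total_count`, `total_percent`).
#' @export
categorize <- function(tags, references,
                       priority = c("miRNA", "rRNA", "tRNA", "snRNA",
                                    "snoRNA", "siRNA")) {
  if (!all(priority %in% names(references))) {
    stop("priority names classes absent from references: ",
         paste(setdiff(priority, names(references)), collapse = ", "))
  }
  label <- rep("unannotated", nrow(tags))
  hit_id <- rep(NA_character_, nrow(tags))
  unmatched <- rep(TRUE, nrow(tags))
  for (cls in priority) {
    ref <- references[[cls]]
    idx <- match(tags$sequence, as_dna(ref))
    hit <- unmatched & !is.na(idx)
    label[hit] <- cls
    hit_id[hit] <- names(ref)[idx[hit]]
    unmatched <- unmatched & !hit
  }
  labels <- data.frame(sequence = tags$sequence, length = tags$length,
                       count = tags$count, label = label, hit_id = hit_id,
                       stringsAsFactors = FALSE)
  list(labels = labels,
       summary = category_summary(labels, c(priority, "unannotated")))
}

#' Per-class unique/total count summary
#'
#' @param labels data frame with `count` and `label` columns.
#' @param categories category order for the output rows.
#' @return a `category_summary` data frame; the leading `total` row carries
#'   the denominators (its percents are 100) and per-class unique and total
#'   counts partition the totals.
#' @export
category_summary <- function(labels, categories = unique(labels$label)) {
  uniq <- as.integer(table(factor(labels$label, levels = categories)))
  tot <- as.integer(tapply(labels$count, factor(labels$label, levels = categories),
                           sum, default = 0L))
  all_uniq <- nrow(labels)
  all_tot <- sum(labels$count)
  out <- data.frame(
    category = c("total", categories),
    unique_count = c(all_uniq, uniq),
    unique_percent = 100 * c(all_uniq, uniq) / all_uniq,
    total_count = c(all_tot, tot),
    total_percent = 100 * c(all_tot, tot) / all_tot,
    stringsAsFactors = FALSE)
  class(out) <- c("category_summary", class(out))
  out
}

#' Family-level abundance of known miRNA hits
#'
#' @param labels the `labels` data frame from [categorize()], or any data
#'   frame with `count`, `label` and `hit_id` columns.
#' @return data frame with one row per miRNA family: `family`,
#'   `member_count` (distinct mature ids matched) and `total_reads`, sorted
#'   by descending `total_reads`.
#' @export
family_abundance <- function(labels) {
  hits <- labels[labels$label == "miRNA" & !is.na(labels$hit_id), ]
  if (nrow(hits) == 0L) {
    return(data.frame(family = character(0), member_count = integer(0),
                      total_reads = integer(0)))
  }
  hits$family <- parse_family(hits$hit_id)
  out <- do.call(rbind, lapply(split(hits, hits$family), function(h) {
    data.frame(family = h$family[1],
               member_count = length(unique(h$hit_id)),
               total_reads = sum(h$count), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_reads, out$family), ]
  rownames(out) <- NULL
  out
}
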