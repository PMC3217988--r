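#' Assemble a pipeline configuration
#'
#' Collects per-stage parameter blocks with defaults; unknown fields in a
#' block are rejected by the stage constructors they feed.
#'
#' @param outdir run directory to create.
#' @param seed integer seed forwarded to the simulation block.
#' @param simulate list of [sim_config()] overrides, or `NULL` to skip
#'   simulation (then `fastq`, `references`, `ests` paths must be given).
#' @param preprocess,classify,discover,targets per-stage parameter lists.
#' @param fastq,references,ests optional input paths used when `simulate`
#'   is `NULL`: a FASTQ file, a directory of per-class reference FASTA
#'   files (`<class>.fa`), and an EST FASTA.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = list(),
                            preprocess = list(), classify = list(),
                            discover = list(), targets = list(),
                            fastq = NULL, references = NULL, ests = NULL) {
  structure(list(outdir = outdir, seed = seed, simulate = simulate,
                 preprocess = preprocess, classify = classify,
                 discover = discover, targets = targets,
                 fastq = fastq, references = references, ests = ests),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path path to a YAML file whose keys mirror [pipeline_config()].
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full small-RNA analysis pipeline
#'
#' Stage order: simulate (optional) -> preprocess -> classify -> discover ->
#' targets -> report. Each stage's output feeds the next; all outputs are
#' written under `config$outdir` and a manifest records package version,
#' configuration hash and per-stage counts. A stage failure aborts with the
#' stage name; outputs of earlier stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (also written as `manifest.json`), `tags`,
#'   `classification`, `novel` and `targets` results, invisibly returnable
#'   pieces for programmatic use.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    sim_out <- stage("simulate", {
      sc <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
      refs <- make_reference_sets(sc)
      ests <- make_ests(sc$n_ests, sc$est_length, seed = sc$seed)
      planted <- plant_hairpins(ests, sc, refs)
      sim <- simulate_library(sc, refs, planted)
      datadir <- file.path(config$outdir, "data")
      dir.create(datadir, showWarnings = FALSE)
      write_fastq(sim$reads$id, sim$reads$seq, sim$reads$qual,
                  file.path(datadir, "reads.fastq"))
      for (cls in names(refs)) {
        write_fasta(refs[[cls]], file.path(datadir, paste0(cls, ".fa")))
      }
      write_fasta(planted$ests, file.path(datadir, "ests.fa"))
      write_ground_truth(sim, datadir)
      list(sc = sc, refs = refs, ests = planted$ests, sim = sim)
    })
    refs <- sim_out$refs
    ests <- sim_out$ests
    fastq_path <- file.path(config$outdir, "data", "reads.fastq")
    adapter3 <- sim_out$sc$adapter3
    sim <- sim_out$sim
    counts$simulate <- list(n_reads = length(sim$reads$id),
                            n_hairpins = nrow(sim$precursors))
  } else {
    fastq_path <- config$fastq
    adapter3 <- config$preprocess$adapter3
    if (is.null(adapter3)) stop("stage preprocess failed: adapter3 required")
    refs <- stage("classify", {
      if (is.null(config$references) || !dir.exists(config$references)) {
        stop("reference directory not found: ", config$references)
      }
      fa <- list.files(config$references, pattern = "\\.fa$",
                       full.names = TRUE)
      setNames(lapply(fa, read_fasta),
               sub("\\.fa$", "", basename(fa)))
    })
    ests <- stage("discover", {
      if (is.null(config$ests) || !file.exists(config$ests)) {
        stop("EST file not found: ", config$ests)
      }
      read_fasta(config$ests)
    })
  }

  pp <- stage("preprocess", {
    args <- config$preprocess
    args$adapter3 <- NULL
    do.call(preprocess_fastq,
            c(list(fastq = fastq_path, adapter3 = adapter3), args))
  })
  write_tsv(pp$stats, file.path(config$outdir, "preprocess_stats.tsv"))
  write_tsv(pp$length_dist, file.path(config$outdir, "length_distribution.tsv"))
  write_tags_fasta(pp$tags, file.path(config$outdir, "tags.fa"))
  counts$preprocess <- as.list(pp$stats)

  cl <- stage("classify", {
    do.call(categorize, c(list(tags = pp$tags, references = refs),
                          config$classify))
  })
  write_tsv(cl$labels, file.path(config$outdir, "tag_labels.tsv"))
  write_tsv(as.data.frame(cl$summary),
            file.path(config$outdir, "category_summary.tsv"))
  fam <- family_abundance(cl$labels)
  write_tsv(fam, file.path(config$outdir, "family_abundance.tsv"))
  counts$classify <- list(n_tags = nrow(cl$labels),
                          n_unannotated =
                            sum(cl$labels$label == "unannotated"))

  nv <- stage("discover", {
    unann <- pp$tags[pp$tags$sequence %in%
                       cl$labels$sequence[cl$labels$label == "unannotated"], ]
    args <- config$discover
    crit <- do.call(duplex_criteria, args$criteria %||% list())
    args$criteria <- NULL
    do.call(discover_mirnas,
            c(list(tags = unann, ests = ests, criteria = crit), args))
  })
  write_tsv(nv$candidates[, c("name", "count", "sequence", "length",
                              "est_id", "precursor_length",
                              "folding_energy", "star_seq", "star_count")],
            file.path(config$outdir, "novel_candidates.tsv"))
  write_tsv(nv$rejections, file.path(config$outdir, "discovery_rejections.tsv"))
  if (nrow(nv$candidates) > 0) {
    write_fasta(setNames(as_dna(nv$candidates$precursor_seq),
                         nv$candidates$name),
                file.path(config$outdir, "precursors.fa"))
    writeLines(paste0(">", nv$candidates$name, "\n",
                      as_dna(nv$candidates$precursor_seq), "\n",
                      nv$candidates$structure),
               file.path(config$outdir, "precursors.dbn"))
  }
  counts$discover <- list(n_candidates = nrow(nv$candidates),
                          n_rejections = nrow(nv$rejections))

  tg <- stage("targets", {
    args <- config$targets
    max_mirnas <- args$max_mirnas %||% 20L
    args$max_mirnas <- NULL
    mirnas <- setNames(as_dna(nv$candidates$sequence), nv$candidates$name)
    if (length(mirnas) > max_mirnas) mirnas <- mirnas[seq_len(max_mirnas)]
    if (length(mirnas) == 0L) {
      data.frame(mirna_id = character(0), transcript_id = character(0),
                 site_start = integer(0), site_end = integer(0),
                 total_score = numeric(0), n_indels = integer(0),
                 accepted = logical(0), alignment = character(0))
    } else {
      do.call(call_targets, c(list(mirnas = mirnas, transcripts = ests),
                              args))
    }
  })
  write_tsv(tg, file.path(config$outdir, "target_hits.tsv"))
  counts$targets <- list(n_hits = nrow(tg), n_accepted = sum(tg$accepted))

  manifest <- list(package = "sRNAmine",
                   version = as.character(utils::packageVersion("sRNAmine")),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   counts = counts)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- render_summary(config$outdir)
  writeLines(report, file.path(config$outdir, "summary.txt"))
  list(manifest = manifest, stats = pp$stats, tags = pp$tags,
       classification = cl, family_abundance = fam, novel = nv,
       targets = tg, ground_truth = if (!is.null(sim)) sim else NULL)
}

fmt_table <- function(df) {
  txt <- utils::capture.output(print(df, row.names = FALSE))
  txt
}

#' Render a human-readable run summary
#'
#' Builds a text report from the stage outputs in a run directory: the
#' category distribution table with percentages, the family abundance
#' table, the novel-candidate table with folding-energy and
#' precursor-length statistics, and the target-hit table.
#'
#' @param outdir a run directory produced by [run_pipeline()].
#' @return character vector of report lines.
#' @export
render_summary <- function(outdir) {
  lines <- c("Small RNA analysis run summary", strrep("=", 32), "")
  p <- function(...) file.path(outdir, ...)
  if (file.exists(p("preprocess_stats.tsv"))) {
    st <- read.delim(p("preprocess_stats.tsv"))
    lines <- c(lines, sprintf(
      "Reads: %d raw; %d clean (%.2f%%); %d adapter-only; %d low-quality; %d outside length window",
      st$n_raw, st$n_clean, 100 * st$n_clean / st$n_raw,
      st$n_adapter_only, st$n_low_quality, st$n_too_short), "")
  }
  if (file.exists(p("category_summary.tsv"))) {
    cs <- read.delim(p("category_summary.tsv"))
    lines <- c(lines, "Distribution of small RNAs among categories:",
               fmt_table(cs), "")
  }
  if (file.exists(p("family_abundance.tsv"))) {
    fa <- read.delim(p("family_abundance.tsv"))
    if (nrow(fa) > 0) {
      lines <- c(lines, "Known miRNA families by abundance:",
                 fmt_table(utils::head(fa, 15)), "")
    }
  }
  if (file.exists(p("novel_candidates.tsv"))) {
    nc <- read.delim(p("novel_candidates.tsv"))
    if (nrow(nc) == 0) {
      lines <- c(lines, "Novel miRNA candidates: no candidates", "")
    } else {
      nc$is_star <- FALSE
      s <- summarize_novel(nc)
      lines <- c(lines, "Novel miRNA candidates:", fmt_table(nc), "",
                 sprintf("Folding energy: min %.1f, max %.1f, mean %.2f",
                         s$min_mfe, s$max_mfe, s$mean_mfe),
                 sprintf("Precursor length: %d-%d nt; %.0f%% within 75-188 nt",
                         s$min_precursor, s$max_precursor,
                         100 * s$band_fraction),
                 sprintf("Families with >1000 reads: %d; with <10 reads: %d",
                         s$n_high_reads, s$n_low_reads), "")
    }
  }
  if (file.exists(p("target_hits.tsv"))) {
    th <- read.delim(p("target_hits.tsv"))
    lines <- c(lines,
               sprintf("Predicted target sites (score < 3.0): %d",
                       sum(th$accepted)))
    if (nrow(th) > 0) {
      lines <- c(lines,
                 fmt_table(th[th$accepted,
                              c("mirna_id", "transcript_id", "site_start",
                                "site_end", "total_score")]))
    }
  }
  lines
}
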