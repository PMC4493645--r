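# TSV readers/writers for the pipeline's domain tables, FASTA proteome
# reading, and the all-in-one pipeline driver. The TSV dialect is
# tab-separated UTF-8 with a header row, '.' decimal point, no quoting;
# every writer emits rows sorted by (gene, tissue) so outputs diff
# bit-exact across runs.

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read an association table from TSV
#'
#' Expects columns \code{dataset}, \code{gene}, \code{tissue_term},
#' \code{score}. Duplicate (gene, tissue) rows and non-numeric scores are
#' errors.
#'
#' @param path TSV file path.
#' @param score_family Score family to attach.
#' @return An \code{assoc_table}.
#' @export
read_associations <- function(path, score_family = "expression_units") {
  df <- read_tsv_checked(path, c("dataset", "gene", "tissue_term", "score"))
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    ln <- which(is.na(score))[1L]
    stop("non-numeric score in ", path, " at data line ", ln, ": ",
         df$score[ln])
  }
  association_table(df$dataset[1L], df$gene, df$tissue_term, score,
                    score_family = score_family)
}

#' Write an association table to TSV
#'
#' @param table An \code{assoc_table}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_associations <- function(table, path) {
  write_tsv(data.frame(dataset = table$dataset, gene = table$gene,
                       tissue_term = table$tissue, score = table$score,
                       stringsAsFactors = FALSE), path)
}

#' Read a gold standard from 2-column TSV
#'
#' @param path TSV with columns \code{gene}, \code{tissue_term}.
#' @return data.frame (\code{gene}, \code{tissue}), deduplicated, sorted.
#' @export
read_gold <- function(path) {
  df <- read_tsv_checked(path, c("gene", "tissue_term"))
  out <- unique(data.frame(gene = df$gene, tissue = df$tissue_term,
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gold standard (or any association pair set) to TSV
#'
#' @param pairs data.frame (\code{gene}, \code{tissue}).
#' @param path Output path.
#' @export
write_gold <- function(pairs, path) {
  pairs <- pairs[order(pairs$gene, pairs$tissue), , drop = FALSE]
  write_tsv(data.frame(gene = pairs$gene, tissue_term = pairs$tissue,
                       stringsAsFactors = FALSE), path)
}

#' Read a staining table from TSV
#'
#' Expects columns \code{protein}, \code{antibody}, \code{tissue},
#' \code{staining}; the staining column may hold either the ordinal labels
#' (not detected/low/medium/high) or the numeric values 0/1/3/6.
#'
#' @param path TSV file path.
#' @return Long-format staining data.frame for
#'   \code{\link{score_staining}}.
#' @export
read_staining <- function(path) {
  df <- read_tsv_checked(path, c("protein", "antibody", "tissue", "staining"))
  v <- suppressWarnings(as.integer(df$staining))
  value <- if (anyNA(v)) translate_staining(df$staining) else v
  if (!all(value %in% c(0L, 1L, 3L, 6L)))
    stop("staining values must be in {0, 1, 3, 6}")
  data.frame(protein = df$protein, antibody = df$antibody,
             tissue = df$tissue, value = value, stringsAsFactors = FALSE)
}

#' Read a major-tissue list
#'
#' @param path Plain-text file, one term id per line.
#' @return Character vector of term ids.
#' @export
read_majors <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a proteome from FASTA
#'
#' @param path Amino-acid FASTA file.
#' @return Named character vector gene id -> sequence (first whitespace
#'   token of the header is the id).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Run the full synthetic-data pipeline
#'
#' Simulates ground truth, one association table per configured noise
#' profile, a staining table and a gold standard; scores the staining with
#' the published consensus parameters; builds a fold-enrichment calibration
#' curve per dataset; and runs the downstream analyses (expression breadth
#' per confidence level, shared-universe Venn overlap, mRNA reference set,
#' pooled transcriptomics evidence, integrated-vs-single benchmark). All
#' outputs are written as sorted TSV under \code{out_dir}; a fixed seed
#' makes the bundle byte-identical across runs.
#'
#' @param config A \code{sim_config}.
#' @param out_dir Output directory (created if needed).
#' @param alpha,beta Consensus staining parameters (published values).
#' @param window Associations per calibration window.
#' @param min_support Dataset support required for the mRNA reference set.
#' @param staining_proteins Number of proteins to stain (default 2000;
#'   keeps the antibody stage proportionate).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: \code{truth},
#'   \code{tables}, \code{gold}, \code{ihc}, \code{curves},
#'   \code{breadth}, \code{venn}, \code{report}, \code{mrna_reference},
#'   \code{benchmark}, \code{files}.
#' @export
run_pipeline <- function(config, out_dir, alpha = 3.0, beta = 0.7,
                         window = 100L, min_support = 3L,
                         staining_proteins = 2000L, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character()
  out <- function(name) {
    f <- file.path(out_dir, name)
    files[[length(files) + 1L]] <<- f
    f
  }

  ## simulate
  truth <- stage("simulate", generate_truth(config))
  say("truth: ", nrow(truth$expressed), " genes x ", ncol(truth$expressed),
      " tissues, ", sum(truth$expressed), " expressed pairs")
  tables <- stage("simulate", lapply(config$profiles, function(pr)
    simulate_dataset(truth, pr,
                     seed = stream_seed(config$seed,
                                        paste0("dataset:", pr$name)))))
  gold <- stage("simulate", simulate_gold(
    truth, config$gold_coverage, config$gold_bias,
    seed = stream_seed(config$seed, "gold")))
  prot <- rownames(truth$expressed)[seq_len(min(staining_proteins,
                                                nrow(truth$expressed)))]
  staining <- stage("simulate", simulate_staining(
    truth, config$antibody_count_prob, config$antibody_error,
    seed = stream_seed(config$seed, "staining"), proteins = prot))
  for (tab in tables) {
    say("dataset ", tab$dataset[1L], ": ", nrow(tab), " records")
    write_associations(tab, out(paste0("associations_", tab$dataset[1L],
                                       ".tsv")))
  }
  write_gold(gold, out("gold_standard.tsv"))

  ## score staining
  ihc <- stage("score", score_staining(staining, alpha, beta))
  say("ihc: ", nrow(ihc), " scored records from ",
      length(unique(staining$protein)), " proteins")
  write_associations(ihc, out("associations_ihc.tsv"))

  ## calibrate
  curves <- stage("calibrate", lapply(tables, function(tab)
    enrichment_curve(tab, gold, window = window)))
  for (nm in names(curves))
    write_tsv(as.data.frame(curves[[nm]]),
              out(paste0("curve_", nm, ".tsv")))

  ## analyze
  cutoffs <- lapply(config$profiles, `[[`, "cutoffs")
  breadth <- stage("analyze", lapply(c(low = "low", medium = "medium",
                                       high = "high"), function(lv) {
    h <- expression_breadth(tables[[1L]], cutoffs[[1L]], lv,
                            n_tissues = config$n_tissues)$histogram
    h
  }))
  bh <- data.frame(breadth = as.integer(names(breadth$low)),
                   low = as.integer(breadth$low),
                   medium = as.integer(breadth$medium),
                   high = as.integer(breadth$high))
  write_tsv(bh, out(paste0("breadth_", tables[[1L]]$dataset[1L], ".tsv")))

  uni <- stage("analyze", shared_universe(tables))
  sets <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    ok <- classify_confidence(t$score, cutoffs[[i]]) >= "medium" &
      t$gene %in% uni$genes & t$tissue %in% uni$tissues
    t[ok, c("gene", "tissue"), drop = FALSE]
  })
  names(sets) <- names(tables)
  venn <- stage("analyze", venn_counts(sets))
  write_tsv(data.frame(pattern = names(venn), count = as.integer(venn)),
            out("venn_medium.tsv"))
  report <- stage("analyze", overlap_report(venn))

  mrna <- stage("analyze", build_mrna_reference(tables, cutoffs,
                                                min_support = min_support))
  write_gold(mrna, out("mrna_reference.tsv"))
  pooled <- stage("analyze", pool_evidence(tables, cutoffs, "high"))
  bench <- stage("analyze", integrated_vs_single(pooled, tables[[1L]], gold))

  ## report
  con <- file(out("summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("genes\t%d", config$n_genes),
    sprintf("tissues\t%d", config$n_tissues),
    sprintf("gold_pairs\t%d", nrow(gold)),
    sprintf("mrna_reference_pairs\t%d", nrow(mrna)),
    sprintf("shared_genes\t%d", length(uni$genes)),
    sprintf("shared_tissues\t%d", length(uni$tissues)),
    sprintf("venn_union\t%d", report$union),
    sprintf("shared_by_all_pct\t%.1f", report$shared_by_all$percent),
    sprintf("benchmark_fraction_integrated\t%.4f",
            bench$fraction_integrated),
    sprintf("benchmark_fraction_single\t%.4f", bench$fraction_single),
    sprintf("benchmark_n\t%d", bench$n)), con)

  invisible(list(truth = truth, tables = tables, gold = gold, ihc = ihc,
                 curves = curves, breadth = breadth, venn = venn,
                 report = report, mrna_reference = mrna,
                 benchmark = bench, files = files))
}
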