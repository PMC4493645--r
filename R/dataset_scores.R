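# Per-dataset scoring rules: platform filtering, alias mapping, aggregation,
# staining translation, in-silico tryptic digestion and peptide-to-gene
# assignment. Each platform family contributes a raw quality score per
# (gene, tissue): microarray expression units (mean over probe sets), EST
# counts (summed over clusters), RPKM/FPKM used directly, unique tryptic
# peptide counts (averaged over samples sharing a tissue term), and ordinal
# immunohistochemistry staining.

#' Construct an association table
#'
#' The central container: one raw quality score per (gene, tissue term) for
#' one dataset. Rows are sorted by (gene, tissue) for reproducible output.
#'
#' @param dataset Dataset name (scalar).
#' @param gene,tissue,score Parallel vectors of gene ids, tissue term ids and
#'   non-negative scores.
#' @param score_family One of \code{"expression_units"}, \code{"rpkm"},
#'   \code{"fpkm"}, \code{"est_count"}, \code{"peptide_count"}, \code{"ihc"},
#'   \code{"zscore"}.
#' @return A data.frame of class \code{assoc_table} with columns
#'   \code{dataset}, \code{gene}, \code{tissue}, \code{score}.
#' @export
association_table <- function(dataset, gene, tissue, score,
                              score_family = "expression_units") {
  score_family <- match.arg(score_family, c(
    "expression_units", "rpkm", "fpkm", "est_count",
    "peptide_count", "ihc", "zscore"))
  stopifnot(length(gene) == length(tissue), length(gene) == length(score))
  if (any(score < 0)) stop("scores must be non-negative")
  key <- paste(gene, tissue, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (gene, tissue) record: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  out <- data.frame(dataset = rep(dataset, length(gene)),
                    gene = as.character(gene),
                    tissue = as.character(tissue),
                    score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, score_family = score_family,
            class = c("assoc_table", "data.frame"))
}

#' @export
print.assoc_table <- function(x, ...) {
  cat("Association table '", x$dataset[1L], "' (", attr(x, "score_family"),
      "): ", nrow(x), " gene-tissue records, ", length(unique(x$gene)),
      " genes, ", length(unique(x$tissue)), " tissues\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 6L))
  invisible(x)
}

#' Filter unreliable microarray probe sets
#'
#' Drops control probe sets (names starting with \code{AFFX}) and probe sets
#' annotated as cross-hybridizing or targeting multiple transcripts (names
#' ending in \code{_r_at}, \code{_i_at}, \code{_f_at} or \code{_x_at}).
#' Input order is preserved; applying the filter twice equals applying it
#' once.
#'
#' @param ids Character vector of probe-set names.
#' @return The kept names, in input order.
#' @export
filter_probe_sets <- function(ids) {
  stopifnot(is.character(ids), all(nzchar(ids)))
  drop <- grepl("_[rifx]_at$", ids) | startsWith(ids, "AFFX")
  ids[!drop]
}

#' Map platform identifiers to target gene identifiers
#'
#' Replaces each measurement's gene field with its alias target(s). A source
#' identifier mapping to k targets yields k measurements; measurements whose
#' identifier has no alias are dropped (their count is reported via a
#' message).
#'
#' @param measurements data.frame with at least columns \code{gene},
#'   \code{tissue}, \code{value} (and optionally \code{source_id}).
#' @param aliases data.frame with columns \code{alias}, \code{target}.
#' @param quiet Suppress the drop-count message.
#' @return The re-keyed measurements.
#' @export
map_aliases <- function(measurements, aliases, quiet = FALSE) {
  stopifnot(all(c("gene", "tissue", "value") %in% names(measurements)),
            all(c("alias", "target") %in% names(aliases)),
            all(nzchar(aliases$alias)), all(nzchar(aliases$target)))
  idx <- split(seq_len(nrow(aliases)), aliases$alias)
  hit <- match(measurements$gene, names(idx))
  dropped <- sum(is.na(hit))
  if (dropped && !quiet)
    message("map_aliases: dropped ", dropped,
            " measurement(s) with no alias target")
  keep <- which(!is.na(hit))
  reps <- lengths(idx)[hit[keep]]
  out <- measurements[rep(keep, reps), , drop = FALSE]
  out$gene <- aliases$target[unlist(idx[hit[keep]], use.names = FALSE)]
  rownames(out) <- NULL
  out
}

#' Aggregate multiple measurements of one gene
#'
#' Mean for expression-unit platforms (multiple probe sets per gene) and
#' peptide counts measured in samples sharing a tissue term; sum for EST
#' counts pooled over clusters of the same gene.
#'
#' @param values Non-empty numeric vector.
#' @param method \code{"mean"} or \code{"sum"}.
#' @return A single number.
#' @export
aggregate_gene_scores <- function(values, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (!length(values)) stop("cannot aggregate an empty set of values")
  if (method == "mean") mean(values) else sum(values)
}

#' Translate ordinal staining labels to numeric values
#'
#' The semi-quantitative immunohistochemistry readout is mapped onto the
#' numeric scale not detected = 0, low = 1, medium = 3, high = 6.
#'
#' @param label Character vector of staining labels (case-insensitive).
#' @return Integer vector of staining values.
#' @export
translate_staining <- function(label) {
  lut <- c("not detected" = 0L, "low" = 1L, "medium" = 3L, "high" = 6L)
  key <- tolower(trimws(label))
  bad <- setdiff(unique(key), names(lut))
  if (length(bad)) stop("unknown staining label: ", bad[1L])
  unname(lut[key])
}

#' In-silico tryptic digestion
#'
#' Cleaves after every lysine (K) or arginine (R) and enumerates all
#' fragments spanning at most \code{max_missed} internal cleavage sites.
#' The proline exception (no cleavage before P) is deliberately not applied:
#' plain K/R cleavage is deterministic and yields a superset of
#' proline-aware peptides.
#'
#' @param sequence Amino-acid string.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return data.frame with columns \code{peptide}, \code{start} (1-based
#'   position in \code{sequence}), \code{missed}; zero rows for an empty
#'   sequence.
#' @export
tryptic_digest <- function(sequence, max_missed = 2L) {
  stopifnot(length(sequence) == 1L, max_missed >= 0L)
  n <- nchar(sequence)
  empty <- data.frame(peptide = character(), start = integer(),
                      missed = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  # cut points: after each K/R except a terminal one
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  bounds <- c(0L, cuts, n)           # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    i <- seq_len(nfrag - m)
    if (!length(i)) break
    from <- bounds[i] + 1L
    to <- bounds[i + m + 1L]
    out[[m + 1L]] <- data.frame(
      peptide = substring(sequence, from, to),
      start = from, missed = m, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

#' Score tissues by unique tryptic peptide counts
#'
#' Matches observed peptides against the theoretical tryptic peptides of a
#' proteome. A peptide matching more than one gene is ambiguous evidence and
#' is discarded. The score of (gene, tissue) is the number of distinct
#' uniquely-matching peptides observed in that tissue.
#'
#' @param observed data.frame with columns \code{peptide}, \code{tissue}.
#' @param proteome Named character vector: gene id -> amino-acid sequence.
#' @param max_missed Missed cleavages allowed in the theoretical digest.
#' @param dataset Dataset name for the resulting table.
#' @return An \code{assoc_table} with score family \code{"peptide_count"}.
#' @export
map_peptides_to_genes <- function(observed, proteome, max_missed = 2L,
                                  dataset = "proteome_ms") {
  stopifnot(length(proteome) > 0L, !is.null(names(proteome)),
            all(c("peptide", "tissue") %in% names(observed)))
  theo <- lapply(proteome, function(s) unique(tryptic_digest(s, max_missed)$peptide))
  pep2gene <- data.frame(
    peptide = unlist(theo, use.names = FALSE),
    gene = rep(names(theo), lengths(theo)),
    stringsAsFactors = FALSE)
  ngene <- tapply(pep2gene$gene, pep2gene$peptide, function(g) length(unique(g)))
  unique_pep <- names(ngene)[ngene == 1L]
  pep2gene <- pep2gene[pep2gene$peptide %in% unique_pep, , drop = FALSE]
  gene_of <- pep2gene$gene[match(pep2gene$peptide, pep2gene$peptide)]
  names(gene_of) <- pep2gene$peptide

  obs <- unique(observed[, c("peptide", "tissue")])
  obs$gene <- unname(gene_of[obs$peptide])
  obs <- obs[!is.na(obs$gene), , drop = FALSE]
  if (!nrow(obs))
    return(association_table(dataset, character(), character(), numeric(),
                             score_family = "peptide_count"))
  cnt <- stats::aggregate(list(score = obs$peptide),
                          by = list(gene = obs$gene, tissue = obs$tissue),
                          FUN = length)
  association_table(dataset, cnt$gene, cnt$tissue, cnt$score,
                    score_family = "peptide_count")
}

#' Dataset scoring profile
#'
#' Bundles a dataset's score family, aggregation rule, confidence cutoffs
#' and star transform.
#'
#' @param name Dataset name.
#' @param score_family See \code{\link{association_table}}.
#' @param aggregation \code{"mean"} or \code{"sum"}.
#' @param cutoffs Numeric vector \code{c(low, medium, high)},
#'   non-decreasing, on the raw score scale.
#' @param transform A \code{star_transform} (see
#'   \code{\link{star_transform}}), or \code{NULL}.
#' @param probe_filter Apply \code{\link{filter_probe_sets}} to
#'   \code{source_id} before scoring (three-prime microarray platforms).
#' @return A list of class \code{dataset_profile}.
#' @export
dataset_profile <- function(name, score_family, aggregation = "mean",
                            cutoffs, transform = NULL, probe_filter = FALSE) {
  stopifnot(length(cutoffs) == 3L, !is.unsorted(cutoffs))
  structure(list(name = name, score_family = score_family,
                 aggregation = match.arg(aggregation, c("mean", "sum")),
                 cutoffs = stats::setNames(as.numeric(cutoffs),
                                           c("low", "medium", "high")),
                 transform = transform, probe_filter = probe_filter),
            class = "dataset_profile")
}

#' Build an association table from raw measurements
#'
#' Composes the per-dataset pipeline: probe-set filtering (where the profile
#' requests it), alias mapping, tissue-name resolution onto the major-tissue
#' set, then aggregation of all values landing on the same (gene, major)
#' with the profile's rule. RPKM/FPKM values pass through unchanged apart
#' from this aggregation.
#'
#' @param measurements data.frame with columns \code{source_id}, \code{gene},
#'   \code{tissue}, \code{value}.
#' @param aliases data.frame (\code{alias}, \code{target}), or \code{NULL}
#'   to skip alias mapping.
#' @param profile A \code{dataset_profile}.
#' @param dag An \code{ontology_dag}.
#' @param majors Character vector of major tissue term ids.
#' @return An \code{assoc_table}; empty (with a warning) if nothing survives.
#' @export
build_association_table <- function(measurements, aliases, profile, dag, majors) {
  stopifnot(inherits(profile, "dataset_profile"),
            all(c("gene", "tissue", "value") %in% names(measurements)))
  m <- measurements
  if (profile$probe_filter && "source_id" %in% names(m)) {
    keep <- m$source_id %in% filter_probe_sets(unique(m$source_id))
    m <- m[keep, , drop = FALSE]
  }
  if (!is.null(aliases)) m <- map_aliases(m, aliases, quiet = TRUE)
  if (nrow(m)) {
    hits <- resolve_to_majors(m$tissue, majors, dag)
    reps <- lengths(hits)
    m <- m[rep(seq_len(nrow(m)), reps), , drop = FALSE]
    m$tissue <- unlist(hits, use.names = FALSE)
  }
  if (!nrow(m)) {
    warning("no measurement survived mapping for dataset ", profile$name)
    return(association_table(profile$name, character(), character(),
                             numeric(), score_family = profile$score_family))
  }
  agg <- stats::aggregate(
    list(score = as.numeric(m$value)),
    by = list(gene = m$gene, tissue = m$tissue),
    FUN = if (profile$aggregation == "mean") mean else sum)
  association_table(profile$name, agg$gene, agg$tissue, agg$score,
                    score_family = profile$score_family)
}
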