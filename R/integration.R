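# Downstream analyses over scored association tables: expression breadth
# (how many genes are expressed in how many tissues), cross-dataset
# consistency (Venn overlap on the shared gene x tissue universe), a
# consensus mRNA reference set, pooled evidence-type comparison, and the
# integrated-vs-single-dataset benchmark.

assoc_key <- function(x) paste(x$gene, x$tissue, sep = "\r")

#' Expression breadth per gene
#'
#' Breadth of a gene is the number of tissues where its score classifies at
#' or above the requested confidence level.
#'
#' @param table An \code{assoc_table}.
#' @param cutoffs Numeric \code{c(low, medium, high)} on the table's score
#'   scale.
#' @param level \code{"low"}, \code{"medium"} or \code{"high"}.
#' @param n_tissues Total tissue count T for the histogram; defaults to the
#'   number of distinct tissues in the table.
#' @return List with \code{breadth} (named integer vector per gene, genes
#'   with breadth 0 included) and \code{histogram} (counts over breadth
#'   0..T, class \code{breadth_histogram} with attributes \code{level} and
#'   \code{n_tissues}).
#' @export
expression_breadth <- function(table, cutoffs,
                               level = c("low", "medium", "high"),
                               n_tissues = length(unique(table$tissue))) {
  level <- match.arg(level)
  cls <- classify_confidence(table$score, cutoffs)
  ok <- cls >= level
  genes <- sort(unique(table$gene))
  b <- table(factor(table$gene[ok], levels = genes))
  breadth <- stats::setNames(as.integer(b), genes)
  hist <- tabulate(breadth + 1L, nbins = n_tissues + 1L)
  names(hist) <- 0:n_tissues
  list(breadth = breadth,
       histogram = structure(hist, level = level, n_tissues = n_tissues,
                             class = "breadth_histogram"))
}

#' Two-tail mass of a breadth histogram
#'
#' Quantifies bimodality as the fraction of expressed genes (breadth >= 1)
#' found in the extreme bins: breadth <= k (tissue-specific) or breadth >=
#' T-k+1 (ubiquitous).
#'
#' @param hist A \code{breadth_histogram} (counts over breadth 0..T).
#' @param k Tail width, 1 <= k < T/2.
#' @return Fraction in [0, 1].
#' @export
bimodality_fraction <- function(hist, k = 3L) {
  T <- attr(hist, "n_tissues")
  if (is.null(T)) T <- length(hist) - 1L
  stopifnot(k >= 1L, k < T / 2)
  counts <- as.numeric(hist)
  breadth <- as.integer(names(hist))
  expressed <- breadth >= 1L
  tails <- expressed & (breadth <= k | breadth >= T - k + 1L)
  sum(counts[tails]) / sum(counts[expressed])
}

#' Genes and tissues covered by every table
#'
#' @param tables List of >= 2 \code{assoc_table}s.
#' @return List with \code{genes} and \code{tissues} (sorted intersections).
#' @export
shared_universe <- function(tables) {
  stopifnot(length(tables) >= 2L)
  genes <- Reduce(intersect, lapply(tables, function(t) unique(t$gene)))
  tissues <- Reduce(intersect, lapply(tables, function(t) unique(t$tissue)))
  if (!length(genes) || !length(tissues))
    stop("tables share no common ", if (length(genes)) "tissues" else "genes")
  list(genes = sort(genes), tissues = sort(tissues))
}

#' Exclusive membership-pattern counts of association sets
#'
#' Every association in the union is assigned to exactly one pattern: the
#' bitstring (in declared set order, '1' = member) of the sets containing
#' it.
#'
#' @param sets Named list of 1-5 association data.frames (\code{gene},
#'   \code{tissue}).
#' @return Named integer vector of counts per pattern, carrying the set
#'   names as attribute \code{sets}.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 1L, length(sets) <= 5L, !is.null(names(sets)))
  keys <- lapply(sets, function(s) unique(assoc_key(s)))
  universe <- unique(unlist(keys, use.names = FALSE))
  memb <- vapply(keys, function(k) universe %in% k, logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe))
  pattern <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(pattern)
  structure(stats::setNames(as.integer(counts), names(counts)),
            sets = names(sets))
}

pattern_size <- function(counts) {
  vapply(strsplit(names(counts), ""), function(b) sum(b == "1"), 0L)
}

#' Summarize a Venn count vector as percentages of the union
#'
#' Reports the percentage of the union shared by all sets, shared by at
#' least k sets for each k, and unique to each set. Percentages are rounded
#' to \code{digits} decimals; the exact values are kept alongside.
#'
#' @param counts Output of \code{\link{venn_counts}}.
#' @param digits Decimals in the rounded percentages (default 1).
#' @return List of class \code{overlap_report}: \code{union},
#'   \code{shared_by_all}, \code{shared_by_at_least} (per k),
#'   \code{unique_to} (per set), each a list with \code{count},
#'   \code{percent} (rounded) and \code{percent_exact}.
#' @export
overlap_report <- function(counts, digits = 1L) {
  union_n <- sum(counts)
  if (!union_n) stop("empty union")
  sets <- attr(counts, "sets")
  nset <- length(sets)
  size <- pattern_size(counts)
  pct <- function(n) list(count = n,
                          percent = round(100 * n / union_n, digits),
                          percent_exact = 100 * n / union_n)
  shared_ge <- lapply(seq_len(nset), function(k) pct(sum(counts[size >= k])))
  names(shared_ge) <- as.character(seq_len(nset))
  uniq <- lapply(seq_len(nset), function(i) {
    solo <- paste(as.integer(seq_len(nset) == i), collapse = "")
    pct(if (solo %in% names(counts)) counts[[solo]] else 0L)
  })
  names(uniq) <- sets
  structure(list(union = union_n,
                 shared_by_all = pct(sum(counts[size == nset])),
                 shared_by_at_least = shared_ge,
                 unique_to = uniq,
                 digits = digits),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap of", length(x$unique_to), "association sets; union =",
      x$union, "\n")
  cat(sprintf("  shared by all: %d (%.*f%%)\n", x$shared_by_all$count,
              x$digits, x$shared_by_all$percent))
  for (k in names(x$shared_by_at_least)) {
    s <- x$shared_by_at_least[[k]]
    cat(sprintf("  shared by >= %s: %d (%.*f%%)\n", k, s$count, x$digits,
                s$percent))
  }
  for (nm in names(x$unique_to)) {
    u <- x$unique_to[[nm]]
    cat(sprintf("  unique to %s: %d (%.*f%%)\n", nm, u$count, x$digits,
                u$percent))
  }
  invisible(x)
}

#' Count associations contained in a given combination of sets
#'
#' Sums the exclusive Venn patterns whose membership includes every set in
#' \code{within} and (optionally) excludes every other set.
#'
#' @param counts Output of \code{\link{venn_counts}}.
#' @param within Character vector of set names that must contain the
#'   association.
#' @param exclusive If \code{TRUE}, count only associations in exactly
#'   these sets.
#' @return Integer count.
#' @export
count_in_sets <- function(counts, within, exclusive = FALSE) {
  sets <- attr(counts, "sets")
  stopifnot(all(within %in% sets))
  need <- sets %in% within
  keep <- vapply(strsplit(names(counts), ""), function(b) {
    b <- b == "1"
    all(b[need]) && (!exclusive || !any(b[!need]))
  }, logical(1L))
  sum(counts[keep])
}

#' Consensus mRNA reference set
#'
#' Gene-tissue pairs classified high-confidence in at least
#' \code{min_support} of the given tables. The curated gold standard is
#' breadth-biased and incomplete; this consensus of independent
#' transcriptome datasets complements it.
#'
#' @param tables List of \code{assoc_table}s.
#' @param cutoffs_list List of per-table cutoff vectors, parallel to
#'   \code{tables}.
#' @param min_support Minimum number of supporting tables (default 3).
#' @return data.frame (\code{gene}, \code{tissue}), sorted.
#' @export
build_mrna_reference <- function(tables, cutoffs_list, min_support = 3L) {
  stopifnot(length(tables) == length(cutoffs_list),
            min_support <= length(tables))
  keys <- unlist(lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    hi <- classify_confidence(t$score, cutoffs_list[[i]]) == "high"
    unique(assoc_key(t[hi, , drop = FALSE]))
  }), use.names = FALSE)
  support <- table(keys)
  keep <- names(support)[support >= min_support]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[`, "", 1L),
                    tissue = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool associations at or above a confidence level
#'
#' @param tables List of \code{assoc_table}s.
#' @param cutoffs_list Per-table cutoff vectors, parallel to \code{tables}.
#' @param level Minimum confidence level.
#' @return data.frame (\code{gene}, \code{tissue}): the union, sorted.
#' @export
pool_evidence <- function(tables, cutoffs_list,
                          level = c("high", "medium", "low")) {
  level <- match.arg(level)
  stopifnot(length(tables) == length(cutoffs_list))
  keys <- unlist(lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    ok <- classify_confidence(t$score, cutoffs_list[[i]]) >= level
    unique(assoc_key(t[ok, , drop = FALSE]))
  }), use.names = FALSE)
  keys <- sort(unique(keys))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(gene = vapply(parts, `[`, "", 1L),
             tissue = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Benchmark an integrated set against one dataset's top scores
#'
#' Restricts the integrated association set to the universe shared by the
#' single dataset and the gold standard, takes the same number N of
#' top-scoring associations from the single dataset within that universe
#' (ties at rank N broken lexicographically by gene then tissue), and
#' reports the gold-standard fraction of each list plus how many integrated
#' associations the single dataset misses.
#'
#' @param integrated data.frame (\code{gene}, \code{tissue}).
#' @param single An \code{assoc_table}.
#' @param gold data.frame (\code{gene}, \code{tissue}).
#' @return List: \code{n} (list size), \code{fraction_integrated},
#'   \code{fraction_single}, \code{n_extra} (integrated associations not in
#'   the single dataset's records), \code{universe} (genes/tissues).
#' @export
integrated_vs_single <- function(integrated, single, gold) {
  genes <- intersect(unique(single$gene), unique(gold$gene))
  tissues <- intersect(unique(single$tissue), unique(gold$tissue))
  gl <- unique(gold[gold$gene %in% genes & gold$tissue %in% tissues,
                    c("gene", "tissue"), drop = FALSE])
  gkey <- assoc_key(gl)
  integ <- integrated[integrated$gene %in% genes &
                        integrated$tissue %in% tissues, , drop = FALSE]
  ikey <- unique(assoc_key(integ))
  n <- length(ikey)
  sing <- single[single$gene %in% genes & single$tissue %in% tissues, ,
                 drop = FALSE]
  if (n > nrow(sing))
    stop("integrated list (", n, ") exceeds the single dataset's ",
         nrow(sing), " associations in the universe")
  sing <- sing[order(-sing$score, sing$gene, sing$tissue), , drop = FALSE]
  skey <- assoc_key(sing)[seq_len(n)]
  list(n = n,
       fraction_integrated = mean(ikey %in% gkey),
       fraction_single = mean(skey %in% gkey),
       n_extra = sum(!ikey %in% assoc_key(sing)),
       universe = list(genes = genes, tissues = tissues))
}
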