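# Synthetic ground truth and platform-specific datasets.
#
# The generator emulates the statistical structure the analysis assumes:
# a bimodal distribution of expression breadth (most genes either
# tissue-specific or near-ubiquitous), platform-specific score families
# (log-normal for continuous expression units and RPKM/FPKM, negative
# binomial for EST and peptide counts), measurement dropout, partial
# gene/tissue coverage per dataset, ordinal antibody staining with a
# tunable error rate, and an incomplete gold standard biased toward
# tissue-specific genes. Cross-dataset correlation is induced solely
# through the shared truth matrix. One global seed drives named
# substreams, so adding a dataset never perturbs the others.

#' Derive a named substream seed from a global seed
#'
#' One global seed drives every simulation stage through named substreams
#' (e.g. \code{"gold"}, \code{"dataset:gnf"}), so adding or reordering
#' stages never perturbs the draws of the others. The derived seed is a
#' deterministic hash of the name folded into [0, 2^31), safe for
#' \code{set.seed}.
#'
#' @param seed Integer global seed.
#' @param name Stream name.
#' @return An integer seed.
#' @export
stream_seed <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147482951
  as.integer((seed + h) %% 2147482951)
}

#' Noise profile of a simulated dataset
#'
#' @param name Dataset name.
#' @param score_family Score family (see \code{\link{association_table}}).
#' @param expressed Parameters of the expressed-score distribution:
#'   \code{list(dist = "lognormal", meanlog, sdlog)} or
#'   \code{list(dist = "nbinom", mu, size)}, optionally with
#'   \code{specific_lift}: a multiplicative location lift applied to
#'   tissue-specific genes. Tissue-specific genes reach higher expression
#'   in their few tissues than housekeeping genes do anywhere, and this
#'   lift is what couples score to gold-standard membership (the gold
#'   standard being biased toward tissue-specific genes), reproducing the
#'   steady rise of fold enrichment with score seen in real data.
#' @param background \code{list(rate, dist, ...)}: an unexpressed pair
#'   emits a background score with probability \code{rate}, drawn from the
#'   given distribution (zero draws are not emitted).
#' @param dropout Probability an expressed pair goes unmeasured.
#' @param gene_coverage,tissue_coverage Fractions of genes/tissues the
#'   dataset covers.
#' @param cutoffs The dataset's (low, medium, high) cutoffs.
#' @return List of class \code{noise_profile}.
#' @export
noise_profile <- function(name, score_family, expressed, background,
                          dropout = 0.02, gene_coverage = 1,
                          tissue_coverage = 1, cutoffs) {
  stopifnot(dropout >= 0, dropout <= 1, background$rate >= 0,
            background$rate <= 1, gene_coverage > 0, gene_coverage <= 1,
            tissue_coverage > 0, tissue_coverage <= 1)
  structure(list(name = name, score_family = score_family,
                 expressed = expressed, background = background,
                 dropout = dropout, gene_coverage = gene_coverage,
                 tissue_coverage = tissue_coverage,
                 cutoffs = cutoffs),
            class = "noise_profile")
}

#' Default noise profiles for the five transcriptome-style datasets
#'
#' Expressed-score distributions are placed so that the published medium
#' cutoff of each platform detects a truly expressed pair with roughly
#' 0.95-0.99 sensitivity, while background noise rarely exceeds it --
#' mirroring the observation that the published cutoffs correspond to
#' comparable quality across platforms. Background distributions share the
#' log-scale spread of the expressed ones so that the likelihood ratio (and
#' hence fold enrichment) is monotone in the score. Tissue coverage varies
#' by platform (brain-focused exon arrays cover about half the major
#' tissues; the RNA-seq atlases cover few or all), so that the universe
#' shared by all five datasets is a handful of tissues.
#'
#' @return Named list of \code{noise_profile}s: \code{gnf},
#'   \code{exon_array}, \code{unigene}, \code{rnaseq_atlas},
#'   \code{hpa_rnaseq}.
#' @export
default_noise_profiles <- function() {
  list(
    gnf = noise_profile(
      "gnf", "expression_units",
      expressed = list(dist = "lognormal", meanlog = log(500), sdlog = 0.9,
                       specific_lift = 6),
      background = list(rate = 0.35, dist = "lognormal",
                        meanlog = log(20), sdlog = 0.9),
      dropout = 0.02, gene_coverage = 1, tissue_coverage = 1,
      cutoffs = c(50, 100, 250)),
    exon_array = noise_profile(
      "exon_array", "expression_units",
      expressed = list(dist = "lognormal", meanlog = log(550), sdlog = 0.9,
                       specific_lift = 6),
      background = list(rate = 0.30, dist = "lognormal",
                        meanlog = log(15), sdlog = 0.9),
      dropout = 0.03, gene_coverage = 0.75, tissue_coverage = 0.5,
      cutoffs = c(50, 100, 250)),
    unigene = noise_profile(
      "unigene", "est_count",
      expressed = list(dist = "nbinom", mu = 60, size = 0.8,
                       specific_lift = 8),
      background = list(rate = 0.35, dist = "nbinom", mu = 5, size = 0.8),
      dropout = 0.05, gene_coverage = 0.9, tissue_coverage = 0.9,
      cutoffs = c(1, 10, 20)),
    rnaseq_atlas = noise_profile(
      "rnaseq_atlas", "rpkm",
      expressed = list(dist = "lognormal", meanlog = log(20), sdlog = 1.0,
                       specific_lift = 6),
      background = list(rate = 0.30, dist = "lognormal",
                        meanlog = log(0.25), sdlog = 1.0),
      dropout = 0.02, gene_coverage = 0.85, tissue_coverage = 0.5,
      cutoffs = c(0.5, 1, 5)),
    hpa_rnaseq = noise_profile(
      "hpa_rnaseq", "fpkm",
      expressed = list(dist = "lognormal", meanlog = log(50), sdlog = 0.9,
                       specific_lift = 6),
      background = list(rate = 0.30, dist = "lognormal",
                        meanlog = log(1), sdlog = 0.9),
      dropout = 0.02, gene_coverage = 0.9, tissue_coverage = 1,
      cutoffs = c(1, 10, 20))
  )
}

#' Simulation configuration
#'
#' @param n_genes Number of genes (default 20000).
#' @param n_tissues Number of major tissues (default 21).
#' @param p_ubiquitous Probability a gene is ubiquitously expressed
#'   (default 0.4).
#' @param k_spec Tissue-specific genes express in 1..k_spec tissues
#'   (default 3).
#' @param k_ubiq Ubiquitous genes express in (T-k_ubiq)..T tissues
#'   (default 2).
#' @param profiles Named list of \code{noise_profile}s (default
#'   \code{\link{default_noise_profiles}()}).
#' @param gold_coverage Per-pair base inclusion probability of the gold
#'   standard (default 0.3).
#' @param gold_bias Breadth-bias exponent of the gold standard (default 1):
#'   annotation probability decays as breadth^-bias, emulating literature
#'   curation favouring tissue-specific proteins.
#' @param antibody_count_prob Distribution of antibodies per protein
#'   (probabilities for counts 1, 2, ...; default 0.5, 0.25, 0.15, 0.1).
#' @param antibody_error Per-antibody, per-tissue corruption probability
#'   (default 0.1).
#' @param seed Global seed (default 1).
#' @return List of class \code{sim_config}.
#' @export
simulation_config <- function(n_genes = 20000L, n_tissues = 21L,
                              p_ubiquitous = 0.4, k_spec = 3L, k_ubiq = 2L,
                              profiles = default_noise_profiles(),
                              gold_coverage = 0.3, gold_bias = 1,
                              antibody_count_prob = c(0.5, 0.25, 0.15, 0.1),
                              antibody_error = 0.1, seed = 1L) {
  stopifnot(p_ubiquitous >= 0, p_ubiquitous <= 1,
            k_spec >= 1, k_spec < n_tissues / 2,
            k_ubiq >= 0, k_ubiq < n_tissues / 2,
            gold_coverage >= 0, gold_coverage <= 1, gold_bias >= 0,
            antibody_error >= 0, antibody_error <= 1,
            abs(sum(antibody_count_prob) - 1) < 1e-8)
  structure(list(n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 p_ubiquitous = p_ubiquitous, k_spec = as.integer(k_spec),
                 k_ubiq = as.integer(k_ubiq), profiles = profiles,
                 gold_coverage = gold_coverage, gold_bias = gold_bias,
                 antibody_count_prob = antibody_count_prob,
                 antibody_error = antibody_error, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate the ground-truth expression matrix
#'
#' Each gene is independently ubiquitous with probability
#' \code{p_ubiquitous}; ubiquitous genes express in a uniform number of
#' tissues between T-k_ubiq and T, tissue-specific genes between 1 and
#' k_spec, with the expressed tissues drawn uniformly without replacement.
#' The resulting breadth distribution is bimodal.
#'
#' @param config A \code{sim_config}.
#' @return List of class \code{truth_matrix}: \code{expressed} (logical
#'   genes x tissues matrix), \code{class} (per-gene factor
#'   specific/ubiquitous), \code{breadth} (per-gene tissue count).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "truth"))
  n <- config$n_genes
  T <- config$n_tissues
  genes <- sprintf("g%05d", seq_len(n))
  tissues <- sprintf("t%02d", seq_len(T))
  ubiq <- stats::runif(n) < config$p_ubiquitous
  breadth <- integer(n)
  breadth[ubiq] <- sample.int(config$k_ubiq + 1L, sum(ubiq),
                              replace = TRUE) + T - config$k_ubiq - 1L
  breadth[!ubiq] <- sample.int(config$k_spec, sum(!ubiq), replace = TRUE)
  expressed <- matrix(FALSE, n, T, dimnames = list(genes, tissues))
  for (i in seq_len(n))
    expressed[i, sample.int(T, breadth[i])] <- TRUE
  structure(list(expressed = expressed,
                 class = factor(ifelse(ubiq, "ubiquitous", "specific")),
                 breadth = stats::setNames(breadth, genes)),
            class = "truth_matrix")
}

#' @export
print.truth_matrix <- function(x, ...) {
  cat("Truth matrix: ", nrow(x$expressed), " genes x ", ncol(x$expressed),
      " tissues; ", sum(x$class == "ubiquitous"), " ubiquitous, ",
      sum(x$class == "specific"), " tissue-specific\n", sep = "")
  invisible(x)
}

draw_scores <- function(n, d, specific = NULL) {
  if (n == 0L) return(numeric())
  lift <- d$specific_lift
  if (is.null(lift) || is.null(specific)) {
    lift <- 1
    specific <- rep(FALSE, n)
  }
  switch(d$dist,
    lognormal = stats::rlnorm(n, d$meanlog + log(lift) * specific, d$sdlog),
    nbinom = stats::rnbinom(n, size = d$size,
                            mu = d$mu * lift^as.numeric(specific)),
    stop("unknown distribution: ", d$dist))
}

#' Simulate one platform's association table from the truth
#'
#' Within the profile's gene/tissue coverage, expressed pairs that escape
#' dropout draw a score from the expressed distribution; unexpressed pairs
#' emit background noise with the profile's background rate. Only records
#' with score > 0 are emitted.
#'
#' @param truth A \code{truth_matrix}.
#' @param profile A \code{noise_profile}.
#' @param seed Stream seed (derive from the global seed).
#' @return An \code{assoc_table}.
#' @export
simulate_dataset <- function(truth, profile, seed) {
  stopifnot(inherits(truth, "truth_matrix"),
            inherits(profile, "noise_profile"))
  set.seed(seed)
  genes <- rownames(truth$expressed)
  tissues <- colnames(truth$expressed)
  g_keep <- sort(sample(genes, round(length(genes) * profile$gene_coverage)))
  t_keep <- sort(sample(tissues, max(1L, round(length(tissues) *
                                                 profile$tissue_coverage))))
  ex <- truth$expressed[g_keep, t_keep, drop = FALSE]

  idx_ex <- which(ex)
  idx_bg <- which(!ex)
  measured <- idx_ex[stats::runif(length(idx_ex)) >= profile$dropout]
  noisy <- idx_bg[stats::runif(length(idx_bg)) < profile$background$rate]

  spec_gene <- truth$class[match(g_keep, rownames(truth$expressed))] == "specific"
  spec_row <- spec_gene[(measured - 1L) %% nrow(ex) + 1L]
  score <- c(draw_scores(length(measured), profile$expressed, spec_row),
             draw_scores(length(noisy), profile$background))
  cell <- c(measured, noisy)
  keep <- score > 0
  cell <- cell[keep]
  score <- score[keep]
  row <- (cell - 1L) %% nrow(ex) + 1L
  col <- (cell - 1L) %/% nrow(ex) + 1L
  association_table(profile$name, g_keep[row], t_keep[col], score,
                    score_family = profile$score_family)
}

#' Simulate an incomplete, breadth-biased gold standard
#'
#' Each true pair of gene g enters the gold standard with probability
#' \code{coverage * w(g)}, where \code{w(g)} is proportional to
#' \code{breadth(g)^-bias} and normalized so the most tissue-specific genes
#' have weight 1. The output is always a subset of the truth.
#'
#' @param truth A \code{truth_matrix}.
#' @param coverage Base inclusion probability.
#' @param breadth_bias Bias exponent (0 = unbiased).
#' @param seed Stream seed.
#' @return data.frame (\code{gene}, \code{tissue}), sorted.
#' @export
simulate_gold <- function(truth, coverage = 0.3, breadth_bias = 1, seed) {
  stopifnot(coverage >= 0, coverage <= 1, breadth_bias >= 0)
  set.seed(seed)
  ex <- truth$expressed
  idx <- which(ex)
  row <- (idx - 1L) %% nrow(ex) + 1L
  col <- (idx - 1L) %/% nrow(ex) + 1L
  b <- truth$breadth[row]
  w <- (b / min(truth$breadth[truth$breadth >= 1L]))^(-breadth_bias)
  keep <- stats::runif(length(idx)) < coverage * w
  out <- data.frame(gene = rownames(ex)[row[keep]],
                    tissue = colnames(ex)[col[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate antibody staining tables
#'
#' Per protein, the antibody count is drawn from
#' \code{antibody_count_prob}; the true staining is 6 where the protein is
#' expressed and 0 elsewhere. With probability \code{error_rate} a protein
#' is a difficult antigen: every antibody raised against it is
#' non-specific and reports, independently in each tissue, a diffuse
#' background staining drawn uniformly from \{1, 3, 6\}. Antibody
#' reliability is correlated within a protein because the failure is a
#' property of the antigen (cross-reactive epitopes), not of individual
#' immunizations; the resulting between-antibody disagreement is what
#' flags proteins whose staining carries no signal, which is precisely
#' the information the consensus quality factor exploits.
#'
#' @param truth A \code{truth_matrix}.
#' @param antibody_count_prob Probabilities for 1, 2, ... antibodies.
#' @param error_rate Probability a protein's antibodies are non-specific.
#' @param seed Stream seed.
#' @param proteins Optional subset of gene ids to stain (default all).
#' @return Long-format data.frame (\code{protein}, \code{antibody},
#'   \code{tissue}, \code{value}) suitable for \code{\link{score_staining}}.
#' @export
simulate_staining <- function(truth, antibody_count_prob = c(0.5, 0.25, 0.15, 0.1),
                              error_rate = 0.1, seed, proteins = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  set.seed(seed)
  ex <- truth$expressed
  if (!is.null(proteins)) ex <- ex[proteins, , drop = FALSE]
  n <- nrow(ex)
  T <- ncol(ex)
  n_ab <- sample.int(length(antibody_count_prob), n, replace = TRUE,
                     prob = antibody_count_prob)
  rows <- rep(seq_len(n), n_ab * T)
  ab <- unlist(lapply(seq_len(n), function(i) rep(seq_len(n_ab[i]), each = T)),
               use.names = FALSE)
  tis <- unlist(lapply(n_ab, function(k) rep(seq_len(T), k)), use.names = FALSE)
  value <- ifelse(ex[cbind(rows, tis)], 6L, 0L)
  # difficult antigens: all antibodies stain diffusely at random intensity
  hard <- stats::runif(n) < error_rate
  corrupt <- hard[rows]
  value[corrupt] <- sample(c(1L, 3L, 6L), sum(corrupt), replace = TRUE)
  data.frame(protein = rownames(ex)[rows],
             antibody = sprintf("%s_ab%d", rownames(ex)[rows], ab),
             tissue = colnames(ex)[tis],
             value = value, stringsAsFactors = FALSE)
}
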