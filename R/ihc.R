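# Multi-antibody immunohistochemistry consensus scoring.
#
# Staining of one protein measured with several antibodies over a panel of
# tissues is combined into a single per-tissue score
#
#   score[p,t] = alpha * quality[p] * level[p,t]
#
# where quality[p] = exp(-beta * R2[p] / N[p]) penalizes disagreement among
# the N[p] antibodies (R2[p] sums, over antibodies and tissues, the squared
# deviation of each antibody's staining from the per-tissue antibody mean),
# and level[p,t] is a disagreement-weighted average of the staining values,
# with weight[a,t] = 1 - R2[a,t]/R2[p]. A protein measured with a single
# antibody keeps that antibody's staining values unchanged. The published
# operating point is alpha = 3.0, beta = 0.7.

#' Antibody disagreement of a staining table
#'
#' @param staining Numeric matrix, antibodies in rows and tissues in
#'   columns, values in \{0, 1, 3, 6\}.
#' @return A list of class \code{ihc_disagreement}: \code{R2_at} (matrix of
#'   per-antibody, per-tissue squared deviations from the tissue mean),
#'   \code{R2_p} (their total) and \code{N_p} (antibody count).
#' @export
ihc_disagreement <- function(staining) {
  staining <- as.matrix(staining)
  stopifnot(nrow(staining) >= 1L, all(staining %in% c(0, 1, 3, 6)))
  tissue_mean <- colMeans(staining)
  R2_at <- sweep(staining, 2L, tissue_mean)^2
  structure(list(R2_at = R2_at, R2_p = sum(R2_at), N_p = nrow(staining)),
            class = "ihc_disagreement")
}

#' Antibody-set quality factor
#'
#' \code{exp(-beta * R2_p / N_p)}: 1 for perfect agreement, decaying with
#' the per-antibody disagreement.
#'
#' @param summary An \code{ihc_disagreement}.
#' @param beta Decay rate (>= 0).
#' @return Quality in (0, 1].
#' @export
antibody_quality <- function(summary, beta = 0.7) {
  stopifnot(beta >= 0, summary$N_p >= 1L)
  exp(-beta * summary$R2_p / summary$N_p)
}

#' Disagreement-weighted consensus staining level per tissue
#'
#' Weighted average of the antibodies' staining with
#' \code{weight[a,t] = 1 - R2[a,t]/R2_p}. When \code{R2_p = 0} (perfect
#' agreement, or a single antibody) the weights are the 0/0 limit of the
#' definition and uniform weights are used, giving the plain mean. Should a
#' tissue's weights sum to zero while \code{R2_p > 0}, the unweighted mean
#' is used for that tissue with a warning.
#'
#' @param staining Antibody-by-tissue staining matrix.
#' @param summary The matching \code{ihc_disagreement}; recomputed when
#'   omitted.
#' @return Named numeric vector of per-tissue consensus levels.
#' @export
ihc_consensus_level <- function(staining, summary = ihc_disagreement(staining)) {
  staining <- as.matrix(staining)
  if (summary$R2_p == 0) return(colMeans(staining))
  w <- 1 - summary$R2_at / summary$R2_p
  wsum <- colSums(w)
  level <- colSums(w * staining) / wsum
  bad <- wsum == 0
  if (any(bad)) {
    warning("zero weight sum in ", sum(bad),
            " tissue(s); falling back to the unweighted mean")
    level[bad] <- colMeans(staining)[bad]
  }
  level
}

#' Immunohistochemistry consensus score per tissue
#'
#' Single-antibody proteins keep the raw staining values; multi-antibody
#' proteins are scored \code{alpha * quality * level}. Multi-antibody scores
#' may exceed 6 (perfect agreement at staining 6 with alpha = 3 gives 18);
#' the scale is left unclamped because the downstream calibration cutoffs
#' and star transform are defined on it.
#'
#' @param staining Antibody-by-tissue staining matrix.
#' @param alpha Scaling factor making multi-antibody scores comparable to
#'   single-antibody ones (published value 3.0).
#' @param beta Quality decay rate (published value 0.7).
#' @return Named numeric vector of per-tissue scores.
#' @export
ihc_score <- function(staining, alpha = 3.0, beta = 0.7) {
  staining <- as.matrix(staining)
  stopifnot(alpha > 0, beta >= 0)
  if (nrow(staining) == 1L) return(staining[1L, ])
  s <- ihc_disagreement(staining)
  alpha * antibody_quality(s, beta) * ihc_consensus_level(staining, s)
}

#' Score a long-format staining table for many proteins
#'
#' Vectorized equivalent of applying \code{\link{ihc_score}} to every
#' protein's antibody-by-tissue matrix. Tissues with a zero consensus score
#' yield no association record.
#'
#' @param staining data.frame with columns \code{protein}, \code{antibody},
#'   \code{tissue}, \code{value} (integers in \{0, 1, 3, 6\}); every
#'   antibody of a protein must be measured in every tissue of that protein.
#' @param alpha,beta Consensus parameters.
#' @param dataset Dataset name for the resulting table.
#' @return An \code{assoc_table} with score family \code{"ihc"}.
#' @export
score_staining <- function(staining, alpha = 3.0, beta = 0.7,
                           dataset = "ihc") {
  stopifnot(all(c("protein", "antibody", "tissue", "value") %in% names(staining)),
            all(staining$value %in% c(0, 1, 3, 6)))
  p <- staining$protein
  value <- as.numeric(staining$value)
  pt <- paste(p, staining$tissue, sep = "\r")
  p_id <- match(p, unique(p))
  pt_id <- match(pt, unique(pt))
  by_pt <- function(x) rowsum(x, pt_id)[, 1L][pt_id]
  by_p <- function(x) rowsum(x, p_id)[, 1L][p_id]

  # completeness: antibodies per protein constant across its tissues
  n_pt <- by_pt(rep(1, length(pt)))
  first_ab <- !duplicated(paste(p_id, staining$antibody, sep = "\r"))
  N_p <- by_p(as.numeric(first_ab))
  if (any(n_pt != N_p)) stop("incomplete staining matrix: every antibody ",
                             "must be measured in every tissue of its protein")

  mean_at <- by_pt(value) / n_pt
  R2_at <- (value - mean_at)^2
  R2_p <- by_p(R2_at)

  quality <- exp(-beta * R2_p / N_p)
  w <- ifelse(R2_p > 0, 1 - R2_at / R2_p, 1)
  wsum <- by_pt(w)
  wlev <- by_pt(w * value)
  level <- ifelse(wsum > 0, wlev / wsum, mean_at)
  score <- ifelse(N_p == 1, value, alpha * quality * level)

  one <- !duplicated(pt_id)
  out <- data.frame(gene = p[one], tissue = staining$tissue[one],
                    score = score[one], stringsAsFactors = FALSE)
  out <- out[out$score > 0, , drop = FALSE]
  association_table(dataset, out$gene, out$tissue, out$score,
                    score_family = "ihc")
}

#' Fit the consensus parameters against a gold standard
#'
#' Exhaustive grid search: each (alpha, beta) candidate scores the staining
#' data, the scored associations are windowed into an enrichment curve
#' against the gold standard, and the candidate maximizing the mean fold
#' enrichment of the top quarter of windows (highest scores) wins. Ties are
#' broken toward smaller beta, then smaller alpha.
#'
#' The objective is restricted to the top windows because the unrestricted
#' mean over full windows is invariant to the ranking: every full window
#' contributes its gold hits divided by the same window size and
#' background, so the mean telescopes to the total hit count of the scored
#' set, which the parameters do not change. Only the placement of reliable
#' evidence at the top of the ranking distinguishes candidates, and the
#' top-window mean measures exactly that.
#'
#' @param staining Long-format staining table (see
#'   \code{\link{score_staining}}).
#' @param gold A gold-standard data.frame (\code{gene}, \code{tissue}).
#' @param alpha_grid,beta_grid Candidate values; defaults
#'   \code{seq(0.5, 5, 0.5)} and \code{seq(0, 2, 0.1)}.
#' @param window Associations per enrichment window.
#' @param top_fraction Fraction of highest-score windows averaged by the
#'   objective (default 0.25).
#' @return A list of class \code{ihc_fit}: \code{alpha}, \code{beta},
#'   \code{objective} (mean fold enrichment of the top windows) and the
#'   full \code{grid} of objective values.
#' @export
fit_alpha_beta <- function(staining, gold,
                           alpha_grid = seq(0.5, 5, by = 0.5),
                           beta_grid = seq(0, 2, by = 0.1),
                           window = 100L, top_fraction = 0.25) {
  stopifnot(length(alpha_grid) > 0L, length(beta_grid) > 0L,
            top_fraction > 0, top_fraction <= 1)
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$objective <- NA_real_
  for (i in seq_len(nrow(grid))) {
    tab <- score_staining(staining, grid$alpha[i], grid$beta[i])
    genes <- intersect(tab$gene, gold$gene)
    if (!length(genes)) stop("gold standard does not overlap the staining data")
    curve <- enrichment_curve(tab, gold, window = window)
    top <- seq_len(max(1L, floor(nrow(curve) * top_fraction)))
    grid$objective[i] <- mean(curve$fold_enrichment[top])
  }
  best <- order(-grid$objective, grid$beta, grid$alpha)[1L]
  structure(list(alpha = grid$alpha[best], beta = grid$beta[best],
                 objective = grid$objective[best], grid = grid),
            class = "ihc_fit")
}

#' @export
print.ihc_fit <- function(x, ...) {
  cat("IHC consensus parameter fit: alpha =", x$alpha, ", beta =", x$beta,
      "\nmean window fold enrichment at optimum:",
      format(x$objective, digits = 4), "\n")
  invisible(x)
}
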