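# Calibration of raw dataset scores against a curated gold standard.
#
# Quality is quantified as fold enrichment: the fraction of a dataset's
# gene-tissue pairs found in the gold standard, divided by the fraction
# expected by chance over the gene x tissue universe shared by the dataset
# and the gold standard. Sorting a dataset's associations by score and
# computing fold enrichment in windows of 100 associations traces how
# reliability grows with the raw score; fitting a small parametric form to
# that curve yields a transform from any platform's native scale onto a
# unified 0-5 star confidence scale.

#' Fold enrichment of an association set in a gold standard
#'
#' Both the pairs and the gold standard are restricted to the given gene and
#' tissue universe before counting:
#' \code{FE = (hits/|pairs|) / (|gold in universe| / (|genes|*|tissues|))}.
#'
#' @param pairs data.frame (\code{gene}, \code{tissue}).
#' @param gold data.frame (\code{gene}, \code{tissue}).
#' @param genes,tissues Character vectors spanning the universe.
#' @return Fold enrichment (>= 0); 1 means chance agreement.
#' @export
fold_enrichment <- function(pairs, gold, genes, tissues) {
  pr <- pairs[pairs$gene %in% genes & pairs$tissue %in% tissues, , drop = FALSE]
  gl <- gold[gold$gene %in% genes & gold$tissue %in% tissues, , drop = FALSE]
  gl <- unique(gl[, c("gene", "tissue")])
  if (!nrow(pr)) stop("no association pairs inside the universe")
  if (!nrow(gl)) stop("no gold-standard pairs inside the universe")
  hits <- sum(paste(pr$gene, pr$tissue, sep = "\r") %in%
                paste(gl$gene, gl$tissue, sep = "\r"))
  background <- nrow(gl) / (length(unique(genes)) * length(unique(tissues)))
  (hits / nrow(pr)) / background
}

#' Score-window fold-enrichment curve
#'
#' Restricts a scored association table to the genes and tissues it shares
#' with the gold standard, sorts by descending score, partitions the records
#' into consecutive disjoint windows of \code{window} associations (a short
#' final window is kept when it holds at least half a window), and computes
#' the fold enrichment of each window against the shared universe. The
#' median score of a window represents it.
#'
#' @param scored An \code{assoc_table} (or data.frame with \code{gene},
#'   \code{tissue}, \code{score}).
#' @param gold data.frame (\code{gene}, \code{tissue}).
#' @param window Associations per window (default 100).
#' @return A data.frame of class \code{enrichment_curve} with columns
#'   \code{window_index}, \code{score} (median), \code{fold_enrichment},
#'   \code{n_gold}, \code{n_window}; the shared universe sizes are attached
#'   as attributes \code{genes} and \code{tissues}.
#' @export
enrichment_curve <- function(scored, gold, window = 100L) {
  stopifnot(window >= 1L)
  genes <- intersect(unique(scored$gene), unique(gold$gene))
  tissues <- intersect(unique(scored$tissue), unique(gold$tissue))
  rec <- scored[scored$gene %in% genes & scored$tissue %in% tissues, ,
                drop = FALSE]
  if (nrow(rec) < window / 2)
    stop("only ", nrow(rec), " associations in the shared universe; ",
         "need at least half a window (", window, ")")
  rec <- rec[order(-rec$score, rec$gene, rec$tissue), , drop = FALSE]

  gl <- unique(gold[gold$gene %in% genes & gold$tissue %in% tissues,
                    c("gene", "tissue"), drop = FALSE])
  background <- nrow(gl) / (length(genes) * length(tissues))
  in_gold <- paste(rec$gene, rec$tissue, sep = "\r") %in%
    paste(gl$gene, gl$tissue, sep = "\r")

  idx <- ceiling(seq_len(nrow(rec)) / window)
  last <- max(idx)
  n_last <- sum(idx == last)
  if (last > 1L && n_last < window / 2) {
    keep <- idx < last
    rec <- rec[keep, , drop = FALSE]
    in_gold <- in_gold[keep]
    idx <- idx[keep]
    last <- last - 1L
  }
  n_win <- tabulate(idx, last)
  hits <- vapply(seq_len(last), function(w) sum(in_gold[idx == w]), 0L)
  med <- vapply(seq_len(last), function(w) stats::median(rec$score[idx == w]), 0)
  out <- data.frame(window_index = seq_len(last), score = med,
                    fold_enrichment = (hits / n_win) / background,
                    n_gold = hits, n_window = n_win)
  structure(out, genes = length(genes), tissues = length(tissues),
            background = background,
            class = c("enrichment_curve", "data.frame"))
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat("Fold-enrichment curve: ", nrow(x), " windows over ",
      sum(x$n_window), " associations (universe ", attr(x, "genes"),
      " genes x ", attr(x, "tissues"), " tissues)\n", sep = "")
  cat("fold enrichment ", format(min(x$fold_enrichment), digits = 3), " - ",
      format(max(x$fold_enrichment), digits = 3), " across the score range\n",
      sep = "")
  invisible(x)
}

#' @export
plot.enrichment_curve <- function(x, log = "x", ...) {
  ok <- if (grepl("x", log)) x$score > 0 else rep(TRUE, nrow(x))
  plot(x$score[ok], x$fold_enrichment[ok], log = log,
       xlab = "quality score (window median)", ylab = "fold enrichment", ...)
  invisible(x)
}

#' Construct a score-to-star transform
#'
#' Parametric forms mapping a dataset's native score onto the unified star
#' confidence scale, evaluated by \code{\link{to_stars}} and clamped to
#' [\code{floor}, \code{ceiling}]:
#' \itemize{
#'   \item \code{log_linear}: \code{a * log10(s) + b}
#'   \item \code{sigmoid}: \code{A / (1 + B * s^C) + D}
#'   \item \code{linear}: \code{a * s + b}
#'   \item \code{capped_linear}: \code{min(a * s, cap)}
#' }
#'
#' @param form One of the four form names.
#' @param params Named numeric vector of the form's parameters.
#' @param floor,ceiling Star clamp bounds (default 0 and 5).
#' @return A list of class \code{star_transform}.
#' @export
star_transform <- function(form = c("log_linear", "sigmoid", "linear",
                                    "capped_linear"),
                           params, floor = 0, ceiling = 5) {
  form <- match.arg(form)
  need <- switch(form,
    log_linear = c("a", "b"), sigmoid = c("A", "B", "C", "D"),
    linear = c("a", "b"), capped_linear = c("a", "cap"))
  if (!all(need %in% names(params)))
    stop("form '", form, "' needs parameters ", paste(need, collapse = ", "))
  structure(list(form = form, params = params[need],
                 floor = floor, ceiling = ceiling),
            class = "star_transform")
}

#' @export
print.star_transform <- function(x, ...) {
  p <- x$params
  eq <- switch(x$form,
    log_linear = sprintf("%g * log10(score) + %g", p["a"], p["b"]),
    sigmoid = sprintf("%g / (1 + %g * score^%g) + %g",
                      p["A"], p["B"], p["C"], p["D"]),
    linear = sprintf("%g * score + %g", p["a"], p["b"]),
    capped_linear = sprintf("min(%g * score, %g)", p["a"], p["cap"]))
  cat("Star transform: stars =", eq, "\nclamped to [",
      x$floor, ",", x$ceiling, "]\n")
  invisible(x)
}

transform_eval <- function(spec, score) {
  p <- spec$params
  switch(spec$form,
    log_linear = p[["a"]] * log10(score) + p[["b"]],
    sigmoid = p[["A"]] / (1 + p[["B"]] * score^p[["C"]]) + p[["D"]],
    linear = p[["a"]] * score + p[["b"]],
    capped_linear = pmin(p[["a"]] * score, p[["cap"]]))
}

#' Transform raw scores to star confidences
#'
#' Evaluates the transform and clamps to its [floor, ceiling] range.
#' Non-positive scores under a log form map to floor stars (with a warning),
#' since the log-linear fits are only valid on positive scores.
#'
#' @param score Numeric vector on the dataset's native scale.
#' @param spec A \code{star_transform}.
#' @return Star confidences in [floor, ceiling].
#' @export
to_stars <- function(score, spec) {
  stopifnot(inherits(spec, "star_transform"))
  stars <- numeric(length(score))
  bad <- spec$form %in% c("log_linear", "sigmoid") & score <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive score(s) clamped to ", spec$floor,
            " stars")
    stars[bad] <- spec$floor
  }
  stars[!bad] <- transform_eval(spec, score[!bad])
  pmin(pmax(stars, spec$floor), spec$ceiling)
}

#' Fit a parametric transform to an enrichment curve
#'
#' Least-squares fit of the chosen form to the (score, fold enrichment)
#' points of a calibration curve. The log-linear and linear forms are
#' ordinary linear regressions; the sigmoid is a Levenberg-Marquardt fit
#' seeded from a logit-log regression; the capped-linear form is a direct
#' two-parameter optimization.
#'
#' @param curve An \code{enrichment_curve}, or any data.frame with
#'   \code{score} and \code{fold_enrichment} columns.
#' @param form Transform form (see \code{\link{star_transform}}).
#' @param floor,ceiling Clamp bounds stored in the result.
#' @return A \code{star_transform} carrying the fitted parameters, with the
#'   residual sum of squares as attribute \code{rss}.
#' @export
fit_transform <- function(curve, form = c("log_linear", "sigmoid", "linear",
                                          "capped_linear"),
                          floor = 0, ceiling = 5) {
  form <- match.arg(form)
  s <- curve$score
  y <- curve$fold_enrichment
  npar <- switch(form, log_linear = 2L, linear = 2L, capped_linear = 2L,
                 sigmoid = 4L)
  if (length(s) < 2L * npar)
    stop("need at least ", 2L * npar, " curve points to fit a ", form,
         " transform")
  if (form == "log_linear") {
    ok <- s > 0
    fit <- stats::lm(y[ok] ~ log10(s[ok]))
    params <- c(a = unname(stats::coef(fit)[2L]),
                b = unname(stats::coef(fit)[1L]))
    rss <- sum(stats::resid(fit)^2)
  } else if (form == "linear") {
    fit <- stats::lm(y ~ s)
    params <- c(a = unname(stats::coef(fit)[2L]),
                b = unname(stats::coef(fit)[1L]))
    rss <- sum(stats::resid(fit)^2)
  } else if (form == "capped_linear") {
    obj <- function(p) sum((pmin(p[1L] * s, p[2L]) - y)^2)
    start <- c(stats::median(y / pmax(s, .Machine$double.eps)), max(y))
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000L))
    params <- c(a = opt$par[1L], cap = opt$par[2L])
    rss <- opt$value
  } else {
    ok <- s > 0
    s1 <- s[ok]; y1 <- y[ok]
    D0 <- min(y1) - 0.05 * diff(range(y1)) - 1e-9
    A0 <- max(y1) - D0
    # interior points linearize: log(A/(y - D) - 1) = log(B) + C*log(s)
    frac <- A0 / (y1 - D0) - 1
    use <- frac > 1e-9
    lf <- stats::lm(log(frac[use]) ~ log(s1[use]))
    start <- list(A = A0, B = exp(unname(stats::coef(lf)[1L])),
                  C = unname(stats::coef(lf)[2L]), D = D0)
    fit <- minpack.lm::nlsLM(
      y1 ~ A / (1 + B * s1^C) + D, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200L))
    if (!fit$convInfo$isConv)
      stop("sigmoid fit did not converge after ",
           fit$convInfo$finIter, " iterations")
    params <- stats::coef(fit)[c("A", "B", "C", "D")]
    rss <- sum(stats::resid(fit)^2)
  }
  out <- star_transform(form, params, floor = floor, ceiling = ceiling)
  attr(out, "rss") <- rss
  out
}

#' Anchor a fitted enrichment transform onto the star scale
#'
#' Optional re-calibration for user data: rescales a transform fitted to a
#' fold-enrichment curve so that its value at a chosen anchor score (for
#' example the score attaining the enrichment of the medium-confidence text
#' mining cutoff) maps to a chosen star value (default 2.5).
#'
#' @param spec A fitted \code{star_transform} on the fold-enrichment scale.
#' @param anchor_score Score whose transformed value is pinned.
#' @param anchor_stars Star value assigned at the anchor (default 2.5).
#' @return A rescaled \code{star_transform}.
#' @export
anchor_transform <- function(spec, anchor_score, anchor_stars = 2.5) {
  fe <- transform_eval(spec, anchor_score)
  if (!is.finite(fe) || fe <= 0)
    stop("transform value at the anchor score must be positive")
  k <- anchor_stars / fe
  p <- spec$params
  p[] <- switch(spec$form,
    log_linear = c(p[["a"]] * k, p[["b"]] * k),
    linear = c(p[["a"]] * k, p[["b"]] * k),
    capped_linear = c(p[["a"]] * k, p[["cap"]] * k),
    sigmoid = c(p[["A"]] * k, p[["B"]], p[["C"]], p[["D"]] * k))
  star_transform(spec$form, p, floor = spec$floor, ceiling = spec$ceiling)
}

#' Classify a raw score into a confidence level
#'
#' Boundary-inclusive: a score equal to a cutoff qualifies at that cutoff's
#' level, so the published cutoffs themselves are low/medium/high.
#'
#' @param score Numeric vector on the dataset's native scale.
#' @param cutoffs Numeric \code{c(low, medium, high)}, non-decreasing.
#' @return Ordered factor with levels \code{below < low < medium < high}.
#' @export
classify_confidence <- function(score, cutoffs) {
  stopifnot(length(cutoffs) == 3L, !is.unsorted(cutoffs))
  lev <- c("below", "low", "medium", "high")
  idx <- 1L + (score >= cutoffs[1L]) + (score >= cutoffs[2L]) +
    (score >= cutoffs[3L])
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Published dataset profiles
#'
#' The shipped per-dataset configuration: score family, aggregation rule,
#' low/medium/high cutoffs on the native score scale, and the published
#' score-to-star transforms. The text-mining z-score transform is
#' \code{score/2.4} capped at 4 stars (text-mining evidence tops out at 4
#' stars on the unified scale); all other datasets clamp to [0, 5].
#'
#' @return Named list of \code{dataset_profile} objects with names
#'   \code{unigene}, \code{gnf}, \code{exon_array}, \code{rnaseq_atlas},
#'   \code{hpa_rnaseq}, \code{hpa_ihc}, \code{hpm}, \code{text_mining}.
#' @export
dataset_profiles <- function() {
  list(
    unigene = dataset_profile(
      "unigene", "est_count", "sum", c(1, 10, 20),
      star_transform("sigmoid", c(A = 6, B = 0.229, C = -7.898, D = -1))),
    gnf = dataset_profile(
      "gnf", "expression_units", "mean", c(50, 100, 250),
      star_transform("log_linear", c(a = 1, b = 0.7)), probe_filter = TRUE),
    exon_array = dataset_profile(
      "exon_array", "expression_units", "mean", c(50, 100, 250),
      star_transform("log_linear", c(a = 2, b = -3.56))),
    rnaseq_atlas = dataset_profile(
      "rnaseq_atlas", "rpkm", "mean", c(0.5, 1, 5),
      star_transform("log_linear", c(a = 1, b = 0.523))),
    hpa_rnaseq = dataset_profile(
      "hpa_rnaseq", "fpkm", "mean", c(1, 10, 20),
      star_transform("log_linear", c(a = 1, b = -0.176))),
    hpa_ihc = dataset_profile(
      "hpa_ihc", "ihc", "mean", c(0, 1.1, 1.9),
      star_transform("linear", c(a = 1 / 5.5, b = 0))),
    hpm = dataset_profile(
      "hpm", "peptide_count", "mean", c(1, 5, 10),
      star_transform("linear", c(a = 1 / 30, b = 0.5))),
    text_mining = dataset_profile(
      "text_mining", "zscore", "mean", c(0, 2.5, 3.5),
      star_transform("capped_linear", c(a = 1 / 2.4, cap = 4), ceiling = 4))
  )
}
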