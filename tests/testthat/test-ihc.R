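test_that("disagreement matches hand evaluation of the squared deviations", {
  # identical antibodies: zero everywhere
  st <- rbind(a1 = c(6, 3), a2 = c(6, 3))
  s <- ihc_disagreement(st)
  expect_equal(s$R2_p, 0)
  expect_true(all(s$R2_at == 0))

  # worked example: A1 = (6,0), A2 = (0,0) over (t1,t2)
  st2 <- rbind(A1 = c(6, 0), A2 = c(0, 0))
  s2 <- ihc_disagreement(st2)
  expect_equal(unname(s2$R2_at[, 1]), c(9, 9))
  expect_equal(unname(s2$R2_at[, 2]), c(0, 0))
  expect_equal(s2$R2_p, 18)
  expect_equal(s2$N_p, 2L)

  # single antibody agrees with itself
  expect_equal(ihc_disagreement(rbind(a = c(6, 1, 0)))$R2_p, 0)
})

test_that("antibody quality decays exponentially with mean disagreement", {
  s0 <- ihc_disagreement(rbind(a = c(6, 6), b = c(6, 6)))
  expect_equal(antibody_quality(s0, 0.7), 1)
  s <- ihc_disagreement(rbind(A1 = c(6, 0), A2 = c(0, 0)))
  expect_equal(antibody_quality(s, 0), 1)
  expect_equal(antibody_quality(s, 0.7), exp(-0.7 * 18 / 2))
  expect_equal(antibody_quality(s, 0.7), 1.836305e-3, tolerance = 1e-6)
})

test_that("consensus level is the disagreement-weighted mean with uniform fallback", {
  st <- rbind(A1 = c(6, 0), A2 = c(0, 0))
  lv <- ihc_consensus_level(st)
  expect_equal(unname(lv), c(3, 0))   # weights 0.5/0.5 in t1
  # perfect agreement: plain mean by the continuity convention
  expect_equal(unname(ihc_consensus_level(rbind(a = c(6, 3), b = c(6, 3)))),
               c(6, 3))
  # single antibody: its own staining
  expect_equal(unname(ihc_consensus_level(rbind(a = c(1, 3)))), c(1, 3))
})

test_that("consensus scores follow score = alpha * quality * level", {
  # single antibody keeps raw staining
  expect_equal(unname(ihc_score(rbind(a = c(6, 0)), 3, 0.7)), c(6, 0))
  # two identical antibodies at 6: 3 * 1 * 6 = 18
  expect_equal(unname(ihc_score(rbind(a = c(6, 6), b = c(6, 6)), 3, 0.7)),
               c(18, 18))
  # full worked example
  sc <- ihc_score(rbind(A1 = c(6, 0), A2 = c(0, 0)), 3, 0.7)
  expect_equal(unname(sc), c(3 * exp(-6.3) * 3, 0), tolerance = 1e-12)
  expect_equal(unname(sc[1]), 1.652674e-2, tolerance = 1e-6)
})

test_that("vectorized staining scorer agrees with the per-protein matrix path", {
  set.seed(55)
  rows <- list()
  expected <- list()
  for (p in 1:40) {
    st <- random_staining_matrix(sample(1:5, 1), sample(3:10, 1))
    pid <- sprintf("P%02d", p)
    rows[[p]] <- data.frame(
      protein = pid,
      antibody = rep(rownames(st), ncol(st)),
      tissue = rep(colnames(st), each = nrow(st)),
      value = as.vector(st), stringsAsFactors = FALSE)
    sc <- ihc_score(st, 2.5, 0.4)
    expected[[p]] <- data.frame(gene = pid, tissue = colnames(st),
                                score = unname(sc), stringsAsFactors = FALSE)
  }
  tab <- score_staining(do.call(rbind, rows), 2.5, 0.4)
  exp_df <- do.call(rbind, expected)
  exp_df <- exp_df[exp_df$score > 0, ]
  exp_df <- exp_df[order(exp_df$gene, exp_df$tissue), ]
  expect_equal(tab$score, exp_df$score, tolerance = 1e-12)
  expect_equal(tab$gene, exp_df$gene)
})

test_that("implementation matches the literal equation transcription", {
  set.seed(77)
  worst <- 0
  for (i in 1:200) {
    st <- random_staining_matrix(sample(2:5, 1), sample(3:10, 1))
    a <- runif(1, 0.5, 5)
    b <- runif(1, 0, 2)
    worst <- max(worst, max(abs(ihc_score(st, a, b) - oracle_ihc(st, a, b))))
  }
  expect_lt(worst, 1e-9)
})

test_that("scores are monotone in staining and invariant to antibody order", {
  set.seed(88)
  for (i in 1:50) {
    st <- random_staining_matrix(sample(2:4, 1), sample(3:6, 1))
    # permutation invariance
    perm <- sample(nrow(st))
    expect_equal(ihc_score(st[perm, , drop = FALSE], 3, 0.7),
                 ihc_score(st, 3, 0.7), tolerance = 1e-12)
    # weights within [0, 1]; levels inside the per-tissue staining range
    s <- ihc_disagreement(st)
    if (s$R2_p > 0) {
      w <- 1 - s$R2_at / s$R2_p
      expect_true(all(w >= 0 & w <= 1))
    }
    lv <- ihc_consensus_level(st, s)
    expect_true(all(lv >= apply(st, 2, min) - 1e-12))
    expect_true(all(lv <= apply(st, 2, max) + 1e-12))
  }
  # raising one staining value never lowers that tissue's score under
  # a fixed disagreement pattern (quality recomputed, level increases)
  st <- rbind(a = c(3, 0, 1), b = c(3, 6, 1))
  for (lower in c(0, 1, 3)) {
    hi <- st
    hi["a", 1] <- 6
    lo <- st
    lo["a", 1] <- lower
    lv_hi <- ihc_consensus_level(hi)
    lv_lo <- ihc_consensus_level(lo)
    expect_gte(lv_hi[1], lv_lo[1])
  }
})

test_that("quality strictly decreases as total disagreement grows", {
  q <- sapply(c(0, 2, 8, 18), function(r2)
    antibody_quality(list(R2_p = r2, N_p = 2L), beta = 0.7))
  expect_true(all(diff(q) < 0))
})

test_that("grid search returns the sole candidate and breaks ties low", {
  gold <- data.frame(gene = sprintf("P%02d", 1:10), tissue = "t01",
                     stringsAsFactors = FALSE)
  set.seed(3)
  st <- do.call(rbind, lapply(1:30, function(p) {
    v <- ifelse(rep(p <= 10, 8), 6L, sample(c(0L, 6L), 8, TRUE))
    data.frame(protein = sprintf("P%02d", p),
               antibody = rep(c("a1", "a2"), each = 4),
               tissue = rep(sprintf("t%02d", 1:4), 2),
               value = rep(v[1:4], 2), stringsAsFactors = FALSE)
  }))
  one <- fit_alpha_beta(st, gold, alpha_grid = 2.5, beta_grid = 0.3,
                        window = 10)
  expect_equal(one$alpha, 2.5)
  expect_equal(one$beta, 0.3)

  # all proteins multi-antibody and concordant: alpha rescales without
  # reordering, so objectives tie and the smaller (beta, alpha) wins
  tie <- fit_alpha_beta(st, gold, alpha_grid = c(2, 3),
                        beta_grid = c(0, 0.5), window = 10)
  expect_equal(tie$beta, 0)
  expect_equal(tie$alpha, 2)
})

test_that("a beta separating concordant from discordant antibodies is chosen", {
  # Concordant proteins stain 'medium' (3) only in their annotated tissue,
  # so their records are all true. Discordant proteins stain (6, 1)
  # everywhere -> consensus level 3.5 in five unannotated tissues each.
  # With beta = 0 those false positives (score 10.5) outrank the truth
  # (score 9); beta = 0.7 collapses the discordant proteins, so the top
  # windows enrich and the nonzero beta wins strictly.
  tissues <- sprintf("t%02d", 1:5)
  concordant <- function(id, tissue) {
    v <- ifelse(tissues == tissue, 3L, 0L)
    data.frame(protein = id, antibody = rep(c("a1", "a2"), each = 5),
               tissue = rep(tissues, 2), value = rep(v, 2),
               stringsAsFactors = FALSE)
  }
  good <- do.call(rbind, lapply(1:40, function(i)
    concordant(sprintf("G%02d", i), "t01")))
  # extras keep every tissue inside the gold universe
  extra <- do.call(rbind, lapply(1:10, function(k)
    concordant(sprintf("E%02d", k), tissues[(k - 1L) %% 5L + 1L])))
  bad <- do.call(rbind, lapply(1:40, function(i) {
    data.frame(protein = sprintf("B%02d", i),
               antibody = rep(c("a1", "a2"), each = 5),
               tissue = rep(tissues, 2),
               value = c(rep(6L, 5), rep(1L, 5)),
               stringsAsFactors = FALSE)
  }))
  gold <- data.frame(
    gene = c(sprintf("G%02d", 1:40), sprintf("E%02d", 1:10),
             sprintf("B%02d", 1:40)),
    tissue = c(rep("t01", 40), tissues[(0:9) %% 5L + 1L], rep("t01", 40)),
    stringsAsFactors = FALSE)
  fit <- fit_alpha_beta(rbind(good, extra, bad), gold, alpha_grid = 3,
                        beta_grid = c(0, 0.7), window = 20)
  expect_equal(fit$beta, 0.7)
  obj0 <- fit$grid$objective[fit$grid$beta == 0]
  expect_gt(fit$objective, obj0)
})
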