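test_that("expression breadth counts tissues at or above the level", {
  # 3 genes x 3 tissues with hand-set scores; cutoffs (10, 50, 100)
  tab <- mk_table("d",
                  gene = rep(c("g1", "g2", "g3"), each = 3),
                  tissue = rep(c("t1", "t2", "t3"), 3),
                  score = c(120, 300, 101,   60, 9, 5,   1, 2, 3))
  eb <- expression_breadth(tab, c(10, 50, 100), "medium")
  expect_equal(unname(eb$breadth[c("g1", "g2", "g3")]), c(3L, 1L, 0L))
  expect_equal(unname(eb$histogram[c("0", "1", "3")]), c(1L, 1L, 1L))

  # per-gene breadth is antitone in the level
  lo <- expression_breadth(tab, c(10, 50, 100), "low")$breadth
  md <- expression_breadth(tab, c(10, 50, 100), "medium")$breadth
  hi <- expression_breadth(tab, c(10, 50, 100), "high")$breadth
  expect_true(all(hi <= md & md <= lo))
})

test_that("bimodality fraction is the two-tail mass of expressed genes", {
  h1 <- structure(c(0L, 100L, rep(0L, 20)), names = 0:21, n_tissues = 21L,
                  class = "breadth_histogram")
  expect_equal(bimodality_fraction(h1, 3), 1)
  # uniform over 1..21: fraction = 2k/21
  hu <- structure(c(0L, rep(10L, 21)), names = 0:21, n_tissues = 21L,
                  class = "breadth_histogram")
  expect_equal(bimodality_fraction(hu, 3), 6 / 21)
  # two spikes at 1 and T
  h2 <- structure(c(0L, 50L, rep(0L, 19), 50L), names = 0:21,
                  n_tissues = 21L, class = "breadth_histogram")
  expect_equal(bimodality_fraction(h2, 3), 1)
  expect_error(bimodality_fraction(hu, 11), "k")
})

test_that("shared universe intersects genes and tissues", {
  t1 <- mk_table("a", c("g1", "g2", "g3"), c("x", "y", "z"), 1:3)
  t2 <- mk_table("b", c("g2", "g3", "g4"), c("y", "z", "w"), 1:3)
  t3 <- mk_table("c", c("g2", "g3"), c("z", "y"), 1:2)
  u <- shared_universe(list(t1, t2, t3))
  expect_equal(u$genes, c("g2", "g3"))
  expect_equal(u$tissues, c("y", "z"))
  expect_equal(shared_universe(list(t1, t1))$genes, c("g1", "g2", "g3"))
  t4 <- mk_table("d", c("h1", "h2"), c("x", "y"), 1:2)
  expect_error(shared_universe(list(t1, t4)), "share no common")
})

test_that("venn patterns are exclusive and conserve the union", {
  s1 <- data.frame(gene = c("a", "b"), tissue = "t")
  s2 <- data.frame(gene = c("c", "d", "e"), tissue = "t")
  v <- venn_counts(list(A = s1, B = s2))
  expect_equal(unname(v[c("10", "01")]), c(2L, 3L))

  same <- data.frame(gene = sprintf("g%d", 1:7), tissue = "t")
  v5 <- venn_counts(list(a = same, b = same, c = same, d = same, e = same))
  expect_equal(unname(v5["11111"]), 7L)
  expect_equal(length(v5), 1L)

  # random 3-set fixture against per-element membership scan
  set.seed(12)
  pool <- expand.grid(gene = sprintf("g%d", 1:12),
                      tissue = c("x", "y"), stringsAsFactors = FALSE)
  sets <- lapply(1:3, function(i) pool[sample(24, sample(5:20, 1)), ])
  names(sets) <- c("A", "B", "C")
  v3 <- venn_counts(sets)
  key <- function(d) paste(d$gene, d$tissue)
  uni <- unique(unlist(lapply(sets, key)))
  brute <- table(sapply(uni, function(k)
    paste(as.integer(sapply(sets, function(s) k %in% key(s))),
          collapse = "")))
  expect_equal(sum(v3), length(uni))
  expect_equal(v3[sort(names(v3))],
               structure(as.integer(brute[sort(names(v3))]),
                         names = sort(names(v3))),
               ignore_attr = TRUE)
})

test_that("overlap reports convert counts to percentages of the union", {
  counts <- mk_counts(c("111" = 50, "110" = 20, "100" = 20, "010" = 10),
                      c("A", "B", "C"))
  rep <- overlap_report(counts)
  expect_equal(rep$union, 100L)
  expect_equal(rep$shared_by_all$percent, 50)
  expect_equal(rep$shared_by_at_least[["2"]]$percent, 70)
  expect_equal(rep$unique_to$A$percent, 20)
  expect_equal(rep$unique_to$C$percent, 0)
  # single set: everything unique
  single <- overlap_report(mk_counts(c("1" = 42), "A"))
  expect_equal(single$unique_to$A$percent, 100)
  # exclusive percentages add to 100
  pct <- 100 * counts / sum(counts)
  expect_equal(sum(pct), 100)
})

test_that("count_in_sets sums patterns containing the requested sets", {
  counts <- mk_counts(c("111" = 5, "110" = 3, "011" = 2, "001" = 7),
                      c("A", "B", "C"))
  expect_equal(count_in_sets(counts, c("A", "B")), 8L)
  expect_equal(count_in_sets(counts, c("A", "B"), exclusive = TRUE), 3L)
  expect_equal(count_in_sets(counts, "C"), 14L)
})

test_that("the mRNA reference set needs high confidence in enough tables", {
  cuts <- replicate(5, c(1, 5, 10), simplify = FALSE)
  mk <- function(score) mk_table("d", c("g1", "g2"), c("t1", "t1"),
                                 c(score, 2))
  tables <- list(mk(12), mk(11), mk(10), mk(3), mk(2))
  # g1 high in exactly 3 of 5 -> included; g2 never high -> excluded
  ref <- build_mrna_reference(tables, cuts, min_support = 3)
  expect_equal(ref$gene, "g1")
  expect_equal(nrow(build_mrna_reference(tables, cuts, min_support = 4)), 0L)
  # min_support 1 degenerates to the union of high-confidence sets
  ref1 <- build_mrna_reference(tables, cuts, min_support = 1)
  expect_equal(ref1$gene, "g1")
  # antitone in min_support
  sizes <- sapply(1:5, function(k)
    nrow(build_mrna_reference(tables, cuts, min_support = k)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("evidence pooling unions level-filtered associations", {
  cuts <- list(c(1, 5, 10), c(1, 5, 10))
  ta <- mk_table("a", c("g1", "g2"), c("t1", "t1"), c(12, 6))
  tb <- mk_table("b", c("g2", "g3"), c("t1", "t1"), c(12, 12))
  expect_equal(nrow(pool_evidence(list(ta), list(cuts[[1]]), "high")), 1L)
  hi <- pool_evidence(list(ta, tb), cuts, "high")
  expect_setequal(hi$gene, c("g1", "g2", "g3"))
  md <- pool_evidence(list(ta, tb), cuts, "medium")
  expect_equal(nrow(md), 3L)   # g2 medium in a, high in b: one record
})

test_that("integrated lists are benchmarked against equal-size top lists", {
  # universe 3 genes x 2 tissues; gold 3 pairs
  gold <- data.frame(gene = c("g1", "g2", "g3"),
                     tissue = c("t1", "t1", "t2"), stringsAsFactors = FALSE)
  single <- mk_table("gnf",
                     gene = rep(c("g1", "g2", "g3"), each = 2),
                     tissue = rep(c("t1", "t2"), 3),
                     score = c(100, 90, 80, 70, 60, 50))
  integrated <- data.frame(gene = c("g1", "g2", "g3"),
                           tissue = c("t1", "t1", "t1"),
                           stringsAsFactors = FALSE)
  out <- integrated_vs_single(integrated, single, gold)
  expect_equal(out$n, 3L)
  expect_equal(out$fraction_integrated, 2 / 3)
  # top-3 of single = (g1,t1), (g1,t2), (g2,t1): hits g1t1, g2t1
  expect_equal(out$fraction_single, 2 / 3)
  expect_equal(out$n_extra, 0L)

  # integrated equal to the single top-N: identical fractions
  topn <- single[order(-single$score), ][1:4, c("gene", "tissue")]
  out2 <- integrated_vs_single(topn, single, gold)
  expect_equal(out2$fraction_integrated, out2$fraction_single)

  # gold covering the whole universe: both fractions 1
  gold_all <- expand.grid(gene = c("g1", "g2", "g3"),
                          tissue = c("t1", "t2"), stringsAsFactors = FALSE)
  out3 <- integrated_vs_single(integrated, single, gold_all)
  expect_equal(out3$fraction_integrated, 1)
  expect_equal(out3$fraction_single, 1)

  # integrated list larger than the single table's records in the universe
  sparse <- mk_table("gnf", c("g1", "g2"), c("t1", "t2"), c(10, 5))
  expect_error(integrated_vs_single(rbind(integrated,
                                          data.frame(gene = "g1",
                                                     tissue = "t2")),
                                    sparse, gold),
               "exceeds")
})
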