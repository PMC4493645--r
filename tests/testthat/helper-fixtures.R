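# Shared fixtures and independent oracles used across the test files.

# Small tissue DAG:
#   root -> {nervous system, liver, kidney}
#   nervous system -> brain -> cerebellum
#   brain also is_a organ-like second parent (diamond via "head")
toy_obo <- function() {
  c("format-version: 1.2",
    "",
    "[Term]", "id: T:root", "name: tissue",
    "[Term]", "id: T:ns", "name: nervous system", "is_a: T:root",
    "[Term]", "id: T:head", "name: head", "is_a: T:root",
    "[Term]", "id: T:brain", "name: brain",
    "synonym: \"encephalon\" EXACT []",
    "is_a: T:ns", "is_a: T:head",
    "[Term]", "id: T:cereb", "name: cerebellum", "is_a: T:brain",
    "[Term]", "id: T:liver", "name: liver", "is_a: T:root",
    "[Term]", "id: T:kidney", "name: kidney", "is_a: T:root",
    "[Term]", "id: T:old", "name: obsolete thing", "is_obsolete: true")
}

toy_dag <- function() parse_obo(toy_obo())

# Independent ancestor closure by recursive parent lookup on the edge list.
oracle_ancestors <- function(term, edges) {
  direct <- edges$parent[edges$child == term]
  out <- direct
  for (p in direct) out <- c(out, oracle_ancestors(p, edges))
  unique(out)
}

# Random DAG built by attaching each node to parents among earlier nodes
# (guarantees acyclicity).
random_dag <- function(n_terms, p_edge = 0.3, tree = FALSE) {
  ids <- sprintf("N:%02d", seq_len(n_terms))
  edges <- do.call(rbind, lapply(2:n_terms, function(i) {
    pool <- ids[seq_len(i - 1L)]
    parents <- if (tree) sample(pool, 1L) else
      pool[runif(i - 1L) < p_edge]
    if (!length(parents)) parents <- sample(pool, 1L)
    data.frame(child = ids[i], parent = parents, stringsAsFactors = FALSE)
  }))
  structure(list(
    terms = data.frame(id = ids, name = ids, stringsAsFactors = FALSE),
    synonyms = data.frame(id = character(), synonym = character(),
                          stringsAsFactors = FALSE),
    edges = edges), class = "ontology_dag")
}

# Literal transcription of the five printed consensus equations, looped.
oracle_ihc <- function(staining, alpha, beta) {
  N <- nrow(staining)
  T <- ncol(staining)
  if (N == 1L) return(as.numeric(staining[1L, ]))
  R2at <- matrix(0, N, T)
  for (t in seq_len(T)) {
    m <- mean(staining[, t])
    for (a in seq_len(N)) R2at[a, t] <- (staining[a, t] - m)^2
  }
  R2p <- sum(R2at)
  quality <- exp(-beta * R2p / N)
  level <- numeric(T)
  for (t in seq_len(T)) {
    if (R2p == 0) {
      level[t] <- mean(staining[, t])
    } else {
      w <- 1 - R2at[, t] / R2p
      level[t] <- if (sum(w) > 0) sum(w * staining[, t]) / sum(w) else
        mean(staining[, t])
    }
  }
  alpha * quality * level
}

random_staining_matrix <- function(n_ab, n_tissue) {
  matrix(sample(c(0, 1, 3, 6), n_ab * n_tissue, replace = TRUE),
         nrow = n_ab,
         dimnames = list(sprintf("ab%d", seq_len(n_ab)),
                         sprintf("t%02d", seq_len(n_tissue))))
}

# Direct-counting fold enrichment on explicit pair sets.
oracle_fe <- function(pairs, gold, genes, tissues) {
  key <- function(d) paste(d$gene, d$tissue)
  pr <- pairs[pairs$gene %in% genes & pairs$tissue %in% tissues, ]
  gl <- unique(gold[gold$gene %in% genes & gold$tissue %in% tissues, ])
  (sum(key(pr) %in% key(gl)) / nrow(pr)) /
    (nrow(gl) / (length(genes) * length(tissues)))
}

# Build a tiny association table quickly.
mk_table <- function(dataset, gene, tissue, score, family = "expression_units") {
  association_table(dataset, gene, tissue, score, score_family = family)
}

# Exclusive Venn pattern counts with the given names, as venn_counts returns.
mk_counts <- function(counts, sets) {
  structure(as.integer(counts), names = names(counts), sets = sets)
}
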