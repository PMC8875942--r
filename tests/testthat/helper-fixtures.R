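# Shared small fixtures built in code.

# tiny heterogeneous graph: 3 lncRNA, 3 miRNA, 2 proteins, 1 disease
tiny_graph <- function() {
  build_graph(list(
    association_table(c("L1", "L1", "L2", "L3"), c("M1", "M2", "M2", "M3"),
                      "lncRNA-miRNA"),
    association_table(c("P1", "P2"), c("M1", "M3"), "protein-miRNA"),
    association_table("D1", "L2", "disease-lncRNA"),
    association_table("P1", "P2", "protein-protein")))
}

# write a headerless TSV edge list
write_edges <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

# small planted two-community graph over one node type
two_block_graph <- function(n_per_block = 30, p_within = 0.5,
                            p_between = 0.02, seed = 42) {
  n <- 2L * n_per_block
  ids <- sprintf("n%03d", seq_len(n))
  blk <- rep(1:2, each = n_per_block)
  set.seed(seed)
  src <- character(0); tgt <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- if (blk[i] == blk[j]) p_within else p_between
    if (stats::runif(1) < p) { src <- c(src, ids[i]); tgt <- c(tgt, ids[j]) }
  }
  g <- build_graph(list(association_table(src, tgt, "protein-protein")))
  attr(g, "blocks") <- stats::setNames(blk, normalize_id(ids))
  g
}

# O(n^2) pairwise ROC oracle: P(score_pos > score_neg) + 0.5 P(tie)
pairwise_auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

small_fixture_spec <- function(seed = 1L) {
  fixture_spec(n_lncrna = 12L, n_mirna = 12L, n_disease = 6L,
               n_protein = 8L, n_drug = 5L, n_blocks = 2L,
               lncrna_length = c(60L, 120L), protein_length = c(30L, 60L),
               seed = seed)
}
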