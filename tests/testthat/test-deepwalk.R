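test_that("single walks respect adjacency and truncate at isolated nodes", {
  g <- build_graph(list(association_table("A", "B", "lncRNA-miRNA")),
                   extra_nodes = data.frame(id = "z", type = "drug"))
  expect_equal(random_walk(g, "z", 5), "z")
  expect_equal(random_walk(g, "A", 4), c("a", "b", "a", "b"))
  expect_error(random_walk(g, "nope", 4), "unknown start")
})

test_that("walk steps are uniform over neighbours on a star graph", {
  # star: centre c, leaves x1..x5; from a leaf the second node is always c
  # and the third is uniform over all leaves (and back to c is impossible:
  # centre's neighbours are the leaves)
  tabs <- association_table(rep("c", 5), paste0("x", 1:5), "protein-protein")
  g <- build_graph(list(tabs))
  p <- deepwalk_params(gamma = 400, t = 3, seed = 11)
  corpus <- generate_corpus(g, p)
  from_leaf <- Filter(function(w) startsWith(w[1], "x"), corpus)
  expect_true(all(vapply(from_leaf, function(w) w[2] == "c", TRUE)))
  third <- table(vapply(from_leaf, function(w) w[3], ""))
  n <- length(from_leaf)
  # multinomial 3-sigma band around uniform 1/5
  sigma <- sqrt(n * 0.2 * 0.8)
  expect_true(all(abs(third - n * 0.2) < 3 * sigma))
})

test_that("the corpus has gamma walks per start node, every consecutive pair
           is an edge, and generation is reproducible", {
  fix <- gen_network(small_fixture_spec())
  g <- fix$graph
  p <- deepwalk_params(gamma = 10, t = 8, seed = 5)
  corpus <- generate_corpus(g, p)
  expect_length(corpus, 10 * nrow(g$nodes))
  starts <- table(vapply(corpus, `[[`, "", 1))
  expect_true(all(starts == 10))
  edge_key <- c(paste(g$edges$source, g$edges$target),
                paste(g$edges$target, g$edges$source))
  for (w in corpus) {
    if (length(w) > 1) {
      expect_true(all(paste(w[-length(w)], w[-1]) %in% edge_key))
    }
  }
  expect_identical(corpus, generate_corpus(g, p))
  expect_false(identical(corpus,
                         generate_corpus(g, deepwalk_params(gamma = 10,
                                                            t = 8,
                                                            seed = 6))))
})

test_that("skip-gram brings co-occurring nodes together and is bitwise
           reproducible", {
  # a and b always co-occur against a background vocabulary of independent
  # filler pairs; their vectors align far beyond any (a, filler) pair
  set.seed(3)
  fill <- sprintf("f%02d", 1:20)
  corpus <- c(rep(list(c("a", "b", "a", "b")), 200),
              replicate(400, sample(fill, 2), simplify = FALSE))
  p <- deepwalk_params(d = 16, w = 2, epochs = 5, seed = 3)
  ids <- c("a", "b", fill, "ghost")
  emb <- train_skipgram(corpus, p, node_ids = ids)
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_equal(emb["ghost", ], rep(0, 16))  # never in a pair -> fallback
  cos_fill <- vapply(fill, function(f) cos(emb["a", ], emb[f, ]), 0)
  expect_gt(cos(emb["a", ], emb["b", ]), max(cos_fill))
  expect_identical(emb, train_skipgram(corpus, p, node_ids = ids))
})

test_that("two disjoint cliques separate: within-clique cosine exceeds
           between-clique cosine", {
  ids <- c(paste0("u", 1:6), paste0("v", 1:6))
  pairs <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a < pairs$b &
                 substr(pairs$a, 1, 1) == substr(pairs$b, 1, 1), ]
  g <- build_graph(list(association_table(pairs$a, pairs$b,
                                          "protein-protein")))
  emb <- deepwalk_embed(g, deepwalk_params(d = 16, seed = 2))
  cs <- emb / sqrt(rowSums(emb^2))
  sim <- cs %*% t(cs)
  same <- outer(substr(rownames(sim), 1, 1), substr(rownames(sim), 1, 1),
                "==")
  ut <- upper.tri(sim)
  expect_gt(mean(sim[ut & same]), mean(sim[ut & !same]))
})

test_that("embeddings separate a planted two-block graph by cosine
           similarity", {
  g <- two_block_graph()
  blocks <- attr(g, "blocks")
  emb <- deepwalk_embed(g, deepwalk_params(seed = 7))
  expect_equal(dim(emb), c(60, 64))
  cs <- emb / sqrt(rowSums(emb^2) + 1e-12)
  sim <- cs %*% t(cs)
  ut <- upper.tri(sim)
  same <- outer(blocks[rownames(sim)], blocks[rownames(sim)], "==")
  auc <- roc_auc(sim[ut], as.integer(same[ut]))
  expect_gt(auc, 0.9)
})

test_that("behaviour vectors come from the embedding and exports round-trip", {
  g <- tiny_graph()
  emb <- deepwalk_embed(g, deepwalk_params(d = 8, seed = 1))
  expect_equal(behavior_vector(emb, "l1"), emb["l1", ])
  expect_error(behavior_vector(emb, "missing"), "unknown node")
  p <- tempfile()
  write_embedding(emb, p)
  back <- read_embedding(p)
  expect_equal(back[rownames(emb), ], emb, tolerance = 1e-6)
  pc <- tempfile()
  corpus <- generate_corpus(g, deepwalk_params(t = 4, gamma = 1, seed = 1))
  write_corpus(corpus, pc)
  expect_length(readLines(pc), length(corpus))
})
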