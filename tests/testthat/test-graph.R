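test_that("edge list reading de-duplicates and drops self-pairs", {
  p <- write_edges(list(c("L1", "M1"), c("L1", "M1"), c("L2", "M2")))
  tab <- suppressMessages(read_edge_list(p, "lncRNA-miRNA"))
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "n_dropped_dup"), 1L)

  p2 <- write_edges(list(c("L1", "L1")))
  tab2 <- suppressMessages(read_edge_list(p2, "lncRNA-miRNA"))
  expect_equal(nrow(tab2), 0L)
  expect_equal(attr(tab2, "n_dropped_self"), 1L)
})

test_that("a planted-duplicate file yields the set-distinct pair count", {
  set.seed(7)
  src <- sprintf("l%02d", sample(1:30, 50, replace = TRUE))
  tgt <- sprintf("m%02d", sample(1:30, 50, replace = TRUE))
  # oracle: distinct unordered pairs via a set
  key <- unique(paste(pmin(src, tgt), pmax(src, tgt)))
  p <- write_edges(Map(c, src, tgt))
  tab <- suppressMessages(read_edge_list(p, "lncRNA-miRNA"))
  expect_equal(nrow(tab), length(key))
})

test_that("malformed lines and type clashes are rejected", {
  p <- write_edges(list(c("L1", "M1"), "just_one_field"))
  expect_error(read_edge_list(p, "lncRNA-miRNA"), "line 2")
  # same id on both sides of a heterotypic relation
  expect_error(association_table(c("x1", "m1"), c("m1", "x2"),
                                 "lncRNA-miRNA"), "clash")
})

test_that("graph construction unions nodes and validates types", {
  g <- tiny_graph()
  expect_equal(sum(g$nodes$id == "m1"), 1L)  # shared node appears once
  s <- graph_summary(g)
  expect_equal(s$nodes$lncRNA, 3L)
  expect_equal(s$nodes$miRNA, 3L)
  expect_equal(s$edges$`lncRNA-miRNA`, 4L)
  expect_equal(s$edges$`protein-protein`, 1L)
  # empty input
  g0 <- build_graph(list())
  expect_equal(nrow(g0$nodes), 0L)
  expect_equal(sum(unlist(graph_summary(g0)$edges)), 0L)
  # id reused with a different type
  expect_error(build_graph(list(
    association_table("a1", "b1", "lncRNA-miRNA"),
    association_table("a1", "c1", "disease-lncRNA"))), "two different")
})

test_that("graph construction is idempotent through re-export", {
  g <- tiny_graph()
  dir <- tempfile()
  export_edge_lists(g, dir)
  files <- list.files(dir, full.names = TRUE)
  tabs <- lapply(files, function(f) {
    suppressMessages(
      read_edge_list(f, gsub("_", "-", sub("\\.tsv$", "", basename(f)))))
  })
  g2 <- build_graph(tabs)
  expect_setequal(g2$nodes$id, g$nodes$id)
  key <- function(gg) sort(paste(gg$edges$relation,
                                 pmin(gg$edges$source, gg$edges$target),
                                 pmax(gg$edges$source, gg$edges$target)))
  expect_equal(key(g2), key(g))
})

test_that("per-class edge counts survive multi-table dedup", {
  set.seed(11)
  mk <- function(n, rel, pre_a, pre_b) {
    a <- sprintf("%s%02d", pre_a, sample(1:10, n, replace = TRUE))
    b <- sprintf("%s%02d", pre_b, sample(1:10, n, replace = TRUE))
    suppressMessages(association_table(a, b, rel))
  }
  tabs <- list(mk(30, "lncRNA-miRNA", "l", "m"),
               mk(30, "disease-lncRNA", "d", "l"),
               mk(30, "protein-drug", "p", "g"))
  g <- build_graph(tabs)
  s <- graph_summary(g)
  for (tab in tabs) {
    expect_equal(s$edges[[attr(tab, "relation")]], nrow(tab))
  }
})

test_that("negative sampling avoids positives and respects capacity", {
  g <- tiny_graph()
  # capacity: complete bipartite positives leave no room
  gfull <- build_graph(list(association_table(
    rep(c("L1", "L2"), each = 2), rep(c("M1", "M2"), 2), "lncRNA-miRNA")))
  expect_error(sample_negative_pairs(gfull, 1, seed = 1), "capacity")
  # forced outcome: 2x2 with 1 positive edge -> exactly the 3 non-edges
  g1 <- build_graph(list(
    association_table("L1", "M1", "lncRNA-miRNA")),
    extra_nodes = data.frame(id = c("l2", "m2"),
                             type = c("lncRNA", "miRNA")))
  neg <- sample_negative_pairs(g1, 3, seed = 1)
  expect_setequal(paste(neg$lncRNA, neg$miRNA),
                  c("l1 m2", "l2 m1", "l2 m2"))
  # determinism and positive avoidance on a larger fixture
  fix <- gen_network(small_fixture_spec())
  n1 <- sample_negative_pairs(fix$graph, 100, seed = 5)
  n2 <- sample_negative_pairs(fix$graph, 100, seed = 5)
  n3 <- sample_negative_pairs(fix$graph, 100, seed = 6)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  pos <- lncmi_edges(fix$graph)
  expect_length(intersect(paste(n1$lncRNA, n1$miRNA),
                          paste(pos$lncRNA, pos$miRNA)), 0)
})

test_that("edge masking removes holdout, keeps the floor fraction, and never
           touches nodes or other relation classes", {
  # 10 lncRNA-miRNA edges, holdout 2, keep 0.8 -> floor(0.8 * 8) = 6 remain
  tab <- association_table(sprintf("l%02d", 1:10), sprintf("m%02d", 1:10),
                           "lncRNA-miRNA")
  oth <- association_table(c("p1", "p2"), c("p3", "p4"), "protein-protein")
  g <- build_graph(list(tab, oth))
  hold <- data.frame(lncRNA = c("l01", "l02"), miRNA = c("m01", "m02"))
  m <- mask_edges(g, hold, keep_fraction = 0.8, seed = 3)
  expect_equal(nrow(lncmi_edges(m)), 6L)
  expect_equal(sum(m$edges$relation == "protein-protein"), 2L)
  expect_identical(m$nodes, g$nodes)
  # identity when keep_fraction = 1 and no holdout
  m1 <- mask_edges(g, hold[0, ], keep_fraction = 1)
  expect_equal(nrow(m1$edges), nrow(g$edges))
  # holdout that is not an edge
  expect_error(mask_edges(g, data.frame(lncRNA = "l01", miRNA = "m02"),
                          0.8, 1), "not positive")
  # graph without lncRNA-miRNA edges unchanged under default scope
  g2 <- build_graph(list(oth))
  expect_equal(nrow(mask_edges(g2, NULL, keep_fraction = 0.5)$edges), 2L)
})
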