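test_that("fusion and pair features follow the concatenation layout", {
  expect_equal(fuse(rep(0, 64), rep(0, 64)), rep(0, 128))
  a <- stats::runif(64); b <- stats::runif(64)
  f <- fuse(a, b)
  expect_equal(f[10], a[10])
  expect_equal(f[64 + 7], b[7])
  # Pythagorean identity of concatenation
  expect_equal(sum(f^2), sum(a^2) + sum(b^2))
  expect_error(fuse(a, b[-1]), "dimension")

  rl <- stats::runif(128); rm <- stats::runif(128)
  pf <- pair_features(rl, rm)
  expect_length(pf, 256)
  expect_equal(pf[200], rm[72])
  expect_false(identical(pf, pair_features(rm, rl)))
})

test_that("the classifier separates separable data, is seed-reproducible,
           and is calibrated on pure noise", {
  set.seed(31)
  X <- rbind(matrix(stats::rnorm(100, 3), 50, 2),
             matrix(stats::rnorm(100, -3), 50, 2))
  y <- rep(c(1, 0), each = 50)
  m <- train_classifier(X, y, seed = 1)
  expect_equal(as.integer(predict_scores(m, X) >= 0.5), y)
  Xh <- matrix(stats::rnorm(40), 20, 2)
  expect_identical(predict_scores(train_classifier(X, y, seed = 2), Xh),
                   predict_scores(train_classifier(X, y, seed = 2), Xh))
  expect_error(train_classifier(X, rep(1, 100)), "both classes")
  # pure-noise labels: 5-fold AUC near chance
  set.seed(32)
  Xn <- matrix(stats::rnorm(300 * 8), 300, 8)
  yn <- stats::rbinom(300, 1, 0.5)
  fold <- sample(rep_len(1:5, 300))
  aucs <- vapply(1:5, function(f) {
    m <- train_classifier(Xn[fold != f, ], yn[fold != f], seed = f)
    roc_auc(predict_scores(m, Xn[fold == f, , drop = FALSE]), yn[fold == f])
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("cross-validation partitions pairs, balances classes, and leaks no
           test information", {
  fix <- gen_network(small_fixture_spec(seed = 2))
  res <- suppressWarnings(prepare_attribute_resources(
    fix$sequences, fix$dags, fix$drugs, seed = 1))
  rep_ <- suppressWarnings(
    kfold_cv(fix$graph, res, deepwalk_params(gamma = 5, t = 20, seed = 1),
             k = 5, seed = 1, n_trees = 50))
  expect_equal(nrow(rep_$folds), 5)
  for (col in c("Acc", "Sen", "Spec", "Prec", "AUC", "AUPR")) {
    expect_true(all(rep_$folds[[col]] >= 0 & rep_$folds[[col]] <= 1))
  }
  expect_true(all(abs(rep_$folds$MCC) <= 1))
  n_pos <- nrow(lncmi_edges(fix$graph))
  key <- function(df) paste(df$lncRNA, df$miRNA)
  all_test <- unlist(lapply(rep_$audit, function(a) key(a$test_pairs)))
  # disjoint folds covering all pairs once
  expect_equal(length(all_test), 2 * n_pos)
  expect_false(any(duplicated(all_test)))
  # near-equal fold sizes
  sizes <- vapply(rep_$audit, function(a) nrow(a$test_pairs), 0)
  expect_lte(max(sizes) - min(sizes), 2)
  # leakage audit: test pairs never in training pairs nor embedded edges
  for (a in rep_$audit) {
    expect_length(intersect(key(a$test_pairs), key(a$train_pairs)), 0)
    emb_key <- paste(a$embedded_lncmi$lncRNA, a$embedded_lncmi$miRNA)
    expect_length(intersect(key(a$test_pairs), emb_key), 0)
    # embedded edges are the masked fraction of training positives
    train_pos <- a$train_pairs[a$train_pairs$label == 1, ]
    expect_true(all(emb_key %in% key(train_pos)))
    expect_equal(length(emb_key), floor(0.8 * nrow(train_pos)))
  }
  # mean/sd computed over the fold values
  expect_equal(unname(rep_$mean["AUC"]), mean(rep_$folds$AUC))
  expect_equal(unname(rep_$sd["AUC"]), stats::sd(rep_$folds$AUC))
})

test_that("the CV report TSV mirrors the per-fold + average layout", {
  fix <- gen_network(small_fixture_spec(seed = 3))
  res <- suppressWarnings(prepare_attribute_resources(
    fix$sequences, fix$dags, fix$drugs, seed = 1))
  rep_ <- suppressWarnings(
    kfold_cv(fix$graph, res, deepwalk_params(gamma = 3, t = 15, seed = 1),
             k = 3, seed = 1, n_trees = 30))
  p <- tempfile(fileext = ".tsv")
  write_cv_report(rep_, p)
  tab <- utils::read.delim(p, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 4)  # 3 folds + Average
  expect_equal(tab$Fold[4], "Average")
  expect_match(tab$AUC[4], "\\+/-")
})

test_that("candidate ranking is ordered, excludes nothing of the opposite
           type, and is deterministic", {
  fix <- gen_network(small_fixture_spec(seed = 4))
  res <- suppressWarnings(prepare_attribute_resources(
    fix$sequences, fix$dags, fix$drugs, seed = 1))
  q <- nodes_of_type(fix$graph, "lncRNA")[1]
  p <- deepwalk_params(gamma = 5, t = 20, seed = 2)
  rk <- suppressWarnings(rank_candidates(fix$graph, q, res, p, seed = 1,
                                         n_trees = 50))
  expect_equal(sort(rk$candidate), sort(nodes_of_type(fix$graph, "miRNA")))
  expect_true(all(diff(rk$score) <= 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  rk2 <- suppressWarnings(rank_candidates(fix$graph, q, res, p, seed = 1,
                                          n_trees = 50))
  expect_identical(rk, rk2)
  top5 <- suppressWarnings(rank_candidates(fix$graph, q, res, p, seed = 1,
                                           n_trees = 50, top = 5))
  expect_equal(nrow(top5), 5)
  expect_error(rank_candidates(fix$graph, "nope", res, p), "unknown query")
})

test_that("held-out partners of a block-embedded query are enriched in the
           top half of its ranking", {
  fix <- gen_network(fixture_spec(n_lncrna = 20L, n_mirna = 20L,
                                  n_disease = 6L, n_protein = 10L,
                                  n_drug = 5L, n_blocks = 2L,
                                  p_within = 0.7, p_between = 0,
                                  lncrna_length = c(60L, 120L),
                                  protein_length = c(30L, 60L), seed = 8))
  res <- suppressWarnings(prepare_attribute_resources(
    fix$sequences, fix$dags, fix$drugs, seed = 1))
  pos <- lncmi_edges(fix$graph)
  deg <- table(pos$lncRNA)
  q <- names(which.max(deg))
  truth <- pos$miRNA[pos$lncRNA == q]
  rk <- suppressWarnings(rank_candidates(
    fix$graph, q, res, deepwalk_params(seed = 2), seed = 1))
  top_half <- rk$candidate[seq_len(ceiling(nrow(rk) / 2))]
  expect_gt(mean(truth %in% top_half), 0.5)
})
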