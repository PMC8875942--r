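# Fusion of attribute and behaviour vectors, pair features, random-forest
# scoring, the k-fold cross-validation protocol and leave-one-node-out
# candidate ranking.

#' Fuse attribute and behaviour vectors into a node representation
#'
#' @param attr attribute vector (64-d by default).
#' @param behavior behaviour vector of the same length.
#' @return concatenation attribute-first, typically 128-d.
#' @export
fuse <- function(attr, behavior) {
  if (length(attr) != length(behavior)) {
    stop("attribute and behaviour vectors must have the same dimension")
  }
  c(unname(attr), unname(behavior))
}

#' Pair feature of a candidate lncRNA-miRNA pair
#'
#' @param rep_l the lncRNA's node representation.
#' @param rep_m the miRNA's node representation.
#' @return concatenation with the lncRNA half first (typically 256-d).
#' @export
pair_features <- function(rep_l, rep_m) {
  if (length(rep_l) != length(rep_m)) {
    stop("node representations must have the same dimension")
  }
  c(unname(rep_l), unname(rep_m))
}

# Node representation matrix: attributes (rows over all nodes) fused with an
# embedding matrix over the same ids.
node_representations <- function(attributes, embedding) {
  stopifnot(identical(sort(rownames(attributes)), sort(rownames(embedding))))
  cbind(attributes, embedding[rownames(attributes), , drop = FALSE])
}

# Feature matrix for a data.frame of (lncRNA, miRNA) pairs.
pair_feature_matrix <- function(pairs, reps) {
  cbind(reps[pairs$lncRNA, , drop = FALSE],
        reps[pairs$miRNA, , drop = FALSE])
}

#' Train the random-forest pair classifier
#'
#' @param X numeric feature matrix, one pair per row.
#' @param y 0/1 labels.
#' @param n_trees number of trees.
#' @param seed integer seed; training and prediction are reproducible.
#' @return a fitted `randomForest` model.
#' @export
train_classifier <- function(X, y, n_trees = 100L, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("both classes required to train")
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  local_seed(seed,
    randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                               ntree = n_trees))
}

#' Positive-class probability scores
#'
#' The fraction of trees voting for the positive class.
#'
#' @param model a model from [train_classifier()].
#' @param X feature matrix.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  unname(stats::predict(model, X, type = "prob")[, "1"])
}

# Per-fold evaluation at the 0.5 threshold plus curve areas.
.fold_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  c(confusion_metrics(tp, tn, fp, fn),
    AUC = roc_auc(scores, labels),
    AUPR = pr_auc(scores, labels))
}

#' K-fold cross-validation of the full pipeline
#'
#' Protocol: positives are all lncRNA-miRNA edges and an equal number of
#' negatives is sampled once from the non-edges; pairs are split into k
#' near-equal disjoint folds; in each fold the test positives are removed
#' from the graph and only `keep_fraction` of the remaining lncRNA-miRNA
#' training edges is embedded (DeepWalk is re-trained per fold); the random
#' forest is trained on the training folds' pair features and scored on the
#' test fold; metrics are reported at threshold 0.5 plus AUC/AUPR, per fold
#' and as mean +/- sample standard deviation. Attributes are computed once
#' (they use no edge information).
#'
#' @param graph a `hetnet`.
#' @param resources an `attribute_resources` object.
#' @param params a `deepwalk_params` (its seed is re-derived per fold).
#' @param k number of folds.
#' @param seed integer master seed for negative sampling, fold assignment,
#'   masking, embedding and the classifier.
#' @param n_trees random-forest size.
#' @param keep_fraction fraction of training lncRNA-miRNA edges embedded.
#' @param mask_scope passed to [mask_edges()].
#' @return a `cv_report`: list with `folds` (data.frame of per-fold metrics),
#'   `mean`, `sd`, and an `audit` list per fold holding the test pairs,
#'   training pairs and embedded lncRNA-miRNA edges.
#' @export
kfold_cv <- function(graph, resources, params = deepwalk_params(), k = 5L,
                     seed = 1L, n_trees = 100L, keep_fraction = 0.8,
                     mask_scope = "lncmi") {
  pos <- lncmi_edges(graph)
  n_pos <- nrow(pos)
  if (n_pos < k) stop("need at least k positive lncRNA-miRNA edges")
  pos$label <- 1L
  neg <- sample_negative_pairs(graph, n_pos, seed = seed + 1000L)
  pairs <- rbind(pos, neg)
  fold_id <- local_seed(seed + 2000L, {
    c(sample(rep_len(seq_len(k), n_pos)),
      sample(rep_len(seq_len(k), n_pos)))
  })
  attributes <- build_attributes(graph, resources)
  fold_rows <- list(); audit <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    test <- pairs[test_idx, , drop = FALSE]
    train <- pairs[train_idx, , drop = FALSE]
    if (length(unique(train$label)) < 2L ||
        length(unique(test$label)) < 2L) {
      warning("fold ", f, " skipped: single-class fold")
      next
    }
    holdout <- test[test$label == 1L, c("lncRNA", "miRNA"), drop = FALSE]
    masked <- mask_edges(graph, holdout, keep_fraction = keep_fraction,
                         seed = seed + 3000L + f, scope = mask_scope)
    p_fold <- params
    p_fold$seed <- as.integer(params$seed + 4000L + f)
    embedding <- deepwalk_embed(masked, p_fold)
    reps <- node_representations(attributes, embedding)
    X_train <- pair_feature_matrix(train, reps)
    X_test <- pair_feature_matrix(test, reps)
    model <- train_classifier(X_train, train$label, n_trees = n_trees,
                              seed = seed + 5000L + f)
    scores <- predict_scores(model, X_test)
    fold_rows[[length(fold_rows) + 1L]] <-
      c(Fold = f - 1L, .fold_metrics(scores, test$label))
    audit[[length(audit) + 1L]] <- list(
      fold = f,
      test_pairs = test[, c("lncRNA", "miRNA", "label")],
      train_pairs = train[, c("lncRNA", "miRNA", "label")],
      embedded_lncmi = lncmi_edges(masked))
  }
  if (!length(fold_rows)) stop("no evaluable folds")
  folds <- as.data.frame(do.call(rbind, fold_rows))
  metric_cols <- setdiff(names(folds), "Fold")
  structure(list(folds = folds,
                 mean = colMeans(folds[metric_cols]),
                 sd = apply(folds[metric_cols], 2L, stats::sd),
                 audit = audit),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report (", nrow(x$folds), " folds)\n", sep = "")
  print(round(x$folds, 4), row.names = FALSE)
  cat("mean +/- sd:\n")
  print(paste0(round(x$mean, 4), " +/- ", round(x$sd, 4)) |>
          stats::setNames(names(x$mean)))
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus an `Average` row in `mean +/- sd` form.
#'
#' @param report a `cv_report`.
#' @param path output TSV.
#' @export
write_cv_report <- function(report, path) {
  folds <- report$folds
  out <- data.frame(Fold = as.character(folds$Fold))
  for (mcol in setdiff(names(folds), "Fold")) {
    out[[mcol]] <- sprintf("%.4f", folds[[mcol]])
  }
  avg <- c(Fold = "Average",
           vapply(setdiff(names(folds), "Fold"), function(mcol) {
             sprintf("%.4f +/- %.4f", report$mean[[mcol]], report$sd[[mcol]])
           }, ""))
  out <- rbind(out, as.list(avg))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Leave-one-node-out candidate ranking
#'
#' Case-study protocol: every edge incident to the query is removed, the
#' model is re-trained on the remaining positives plus an equal negative
#' sample (pairs involving the query excluded), every opposite-type node is
#' scored as a partner of the query, and candidates are returned in
#' descending score order.
#'
#' @param graph a `hetnet`.
#' @param query a lncRNA or miRNA id present in the graph.
#' @param resources an `attribute_resources`.
#' @param params a `deepwalk_params`.
#' @param seed integer seed.
#' @param n_trees random-forest size.
#' @param top optional: keep only the first `top` candidates.
#' @return a `ranking` data.frame (`rank`, `candidate`, `score`) with
#'   attribute `query`.
#' @export
rank_candidates <- function(graph, query, resources,
                            params = deepwalk_params(), seed = 1L,
                            n_trees = 100L, top = NULL) {
  query <- normalize_id(query)
  qtype <- graph$nodes$type[graph$nodes$id == query]
  if (!length(qtype)) stop("unknown query node '", query, "'")
  if (!qtype %in% c("lncRNA", "miRNA")) {
    stop("query must be a lncRNA or miRNA node")
  }
  other_type <- if (qtype == "lncRNA") "miRNA" else "lncRNA"
  candidates <- nodes_of_type(graph, other_type)
  if (!length(candidates)) {
    out <- data.frame(rank = integer(), candidate = character(),
                      score = numeric())
    attr(out, "query") <- query
    class(out) <- c("ranking", "data.frame")
    return(out)
  }
  # remove every edge incident to the query, keeping the node
  pruned <- graph
  touch <- pruned$edges$source == query | pruned$edges$target == query
  pruned$edges <- pruned$edges[!touch, , drop = FALSE]
  pos <- lncmi_edges(pruned)
  pos$label <- 1L
  neg <- sample_negative_pairs(pruned, nrow(pos), seed = seed + 1L)
  neg <- neg[neg$lncRNA != query & neg$miRNA != query, , drop = FALSE]
  train <- rbind(pos, neg)
  p_run <- params
  p_run$seed <- as.integer(params$seed + seed)
  embedding <- deepwalk_embed(pruned, p_run)
  attributes <- build_attributes(graph, resources)
  reps <- node_representations(attributes, embedding)
  model <- train_classifier(pair_feature_matrix(train, reps), train$label,
                            n_trees = n_trees, seed = seed + 2L)
  cand_pairs <- if (qtype == "lncRNA") {
    data.frame(lncRNA = query, miRNA = candidates, stringsAsFactors = FALSE)
  } else {
    data.frame(lncRNA = candidates, miRNA = query, stringsAsFactors = FALSE)
  }
  scores <- predict_scores(model, pair_feature_matrix(cand_pairs, reps))
  o <- order(scores, decreasing = TRUE)
  out <- data.frame(rank = seq_along(o), candidate = candidates[o],
                    score = scores[o], stringsAsFactors = FALSE)
  if (!is.null(top)) out <- utils::head(out, top)
  attr(out, "query") <- query
  class(out) <- c("ranking", "data.frame")
  out
}
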