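# DeepWalk behaviour vectors: truncated random walks over the heterogeneous
# graph (all edge types treated identically) feed a skip-gram model trained
# with negative sampling. Single-threaded and deterministic under the seed.

#' DeepWalk hyperparameters
#'
#' @param d embedding dimension (64, so attribute 64 + behaviour 64 gives the
#'   128-d node representation).
#' @param w skip-gram window size.
#' @param gamma walks started per vertex.
#' @param t walk length in nodes.
#' @param epochs training epochs over the walk corpus.
#' @param negative negative samples per centre-context pair.
#' @param alpha initial learning rate (linearly decayed).
#' @param seed integer seed for walk generation and training.
#' @return a `deepwalk_params` list.
#' @export
deepwalk_params <- function(d = 64L, w = 5L, gamma = 10L, t = 40L,
                            epochs = 5L, negative = 5L, alpha = 0.025,
                            seed = 1L) {
  stopifnot(d >= 1, w >= 1, gamma >= 1, t >= 1, epochs >= 1)
  structure(list(d = as.integer(d), w = as.integer(w),
                 gamma = as.integer(gamma), t = as.integer(t),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, seed = as.integer(seed)),
            class = "deepwalk_params")
}

# 1-based adjacency index lists for the C++ walk generator.
.adjacency_index <- function(graph) {
  ids <- graph$nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  adj <- lapply(ids, function(x) integer(0))
  if (nrow(graph$edges)) {
    ends <- c(graph$edges$source, graph$edges$target)
    nbrs <- c(graph$edges$target, graph$edges$source)
    sp <- split(unname(idx[nbrs]), ends)
    adj[idx[names(sp)]] <- lapply(sp, sort)
  }
  list(ids = ids, adj = adj)
}

#' A single truncated random walk
#'
#' Each step is a uniform choice among the current node's neighbours; the
#' walk truncates when it reaches an isolated node.
#'
#' @param graph a `hetnet`.
#' @param start starting node id.
#' @param t walk length in nodes.
#' @param seed integer seed.
#' @return character vector of node ids, length <= t.
#' @export
random_walk <- function(graph, start, t, seed = 1L) {
  start <- normalize_id(start)
  if (!start %in% graph$nodes$id) stop("unknown start node '", start, "'")
  adj <- adjacency_list(graph)
  local_seed(seed, {
    walk <- character(t)
    walk[1L] <- start
    cur <- start
    n <- 1L
    while (n < t) {
      nb <- adj[[cur]]
      if (!length(nb)) break
      cur <- nb[sample.int(length(nb), 1L)]
      n <- n + 1L
      walk[n] <- cur
    }
    walk[seq_len(n)]
  })
}

#' Generate the walk corpus
#'
#' `gamma` passes; each pass shuffles the vertex order and starts one walk
#' per vertex (isolated vertices yield length-1 walks, so every node appears
#' in the corpus). Reproducible under `params$seed`.
#'
#' @param graph a `hetnet`.
#' @param params a `deepwalk_params`.
#' @return a `walk_corpus`: list of character-vector walks, with attribute
#'   `node_ids` giving the graph's vertex order.
#' @export
generate_corpus <- function(graph, params = deepwalk_params()) {
  stopifnot(inherits(graph, "hetnet"), nrow(graph$nodes) > 0L)
  ai <- .adjacency_index(graph)
  walks <- cpp_generate_corpus(ai$adj, params$gamma, params$t,
                               as.double(params$seed))
  corpus <- lapply(walks, function(w) ai$ids[w])
  structure(corpus, node_ids = ai$ids, class = "walk_corpus")
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Negative-sampling skip-gram over window-`w` centre-context pairs of the
#' walks. Nodes never involved in a centre-context pair (isolated vertices'
#' length-1 walks produce none) receive the zero fallback vector, so every
#' node stays scoreable downstream.
#'
#' @param corpus a `walk_corpus` (or plain list of character walks).
#' @param params a `deepwalk_params`.
#' @param node_ids optional full node id universe; defaults to the corpus's
#'   `node_ids` attribute or the ids seen in the corpus.
#' @return numeric matrix (rows = node ids) of `params$d` columns.
#' @export
train_skipgram <- function(corpus, params = deepwalk_params(),
                           node_ids = NULL) {
  if (!length(corpus)) stop("empty walk corpus")
  if (is.null(node_ids)) node_ids <- attr(corpus, "node_ids")
  if (is.null(node_ids)) node_ids <- unique(unlist(corpus))
  idx <- stats::setNames(seq_along(node_ids), node_ids)
  walks <- lapply(corpus, function(w) unname(idx[w]))
  if (anyNA(unlist(walks))) stop("corpus contains ids outside node_ids")
  emb <- cpp_train_sgns(walks, length(node_ids), params$d, params$w,
                        params$epochs, params$negative, params$alpha,
                        as.double(params$seed))
  trained <- attr(emb, "trained") == 1L
  emb <- matrix(emb, nrow = length(node_ids), ncol = params$d,
                dimnames = list(node_ids, NULL))
  emb[!trained, ] <- 0
  emb
}

#' Walk corpus + skip-gram in one step
#'
#' @inheritParams generate_corpus
#' @return embedding matrix over all graph nodes (see [train_skipgram()]).
#' @export
deepwalk_embed <- function(graph, params = deepwalk_params()) {
  corpus <- generate_corpus(graph, params)
  train_skipgram(corpus, params)
}

#' Behaviour vector of a node
#'
#' @param embedding matrix from [train_skipgram()].
#' @param node node id.
#' @return the node's embedding row.
#' @export
behavior_vector <- function(embedding, node) {
  node <- normalize_id(node)
  if (!node %in% rownames(embedding)) stop("unknown node '", node, "'")
  embedding[node, ]
}

#' Export a walk corpus as word2vec-style sentences
#' @param corpus a `walk_corpus`.
#' @param path output text file (one walk per line, space-separated ids).
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, "", collapse = " "), path)
  invisible(path)
}

#' Export / import embeddings in word2vec text format
#'
#' Header line "N d", then one line per node: id followed by d values.
#'
#' @param embedding matrix with node id rownames.
#' @param path file path.
#' @return `read_embedding` returns the embedding matrix.
#' @export
write_embedding <- function(embedding, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(embedding), ncol(embedding)), con)
  writeLines(paste(rownames(embedding),
                   apply(embedding, 1L, paste, collapse = " ")), con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(vals) <- ids
  stopifnot(nrow(vals) == hdr[1L])
  vals
}
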