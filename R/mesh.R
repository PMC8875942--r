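#' Construct a disease DAG
#'
#' A disease's DAG holds the disease itself plus the ancestor closure of its
#' MeSH-style positions: `edges` are directed child -> parent links between
#' descriptor terms, and `delta` is the per-hop semantic decay factor.
#'
#' @param root the disease descriptor id (normalised like node ids).
#' @param edges data.frame with columns `child`, `parent` (descriptor ids).
#'   May have zero rows for a root-only DAG.
#' @param delta semantic contribution factor in (0, 1]; default 0.5.
#' @return a `disease_dag` object with elements `root`, `nodes`, `edges`,
#'   `delta`.
#' @export
disease_dag <- function(root, edges = NULL, delta = 0.5) {
  stopifnot(is.character(root), length(root) == 1L, delta > 0, delta <= 1)
  root <- normalize_id(root)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = normalize_id(edges$child),
                        parent = normalize_id(edges$parent),
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(paste(edges$child, edges$parent, sep = "\r")), ]
    if (any(edges$child == edges$parent)) stop("self-loop in disease DAG")
  }
  nodes <- unique(c(root, edges$child, edges$parent))
  structure(list(root = root, nodes = nodes, edges = edges, delta = delta),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("disease DAG of '", x$root, "': ", length(x$nodes), " node(s), ",
      nrow(x$edges), " child->parent link(s), delta = ", x$delta, "\n",
      sep = "")
  invisible(x)
}

#' Semantic contribution of every DAG node to the root disease
#'
#' The root contributes 1 to itself; every ancestor t contributes
#' `delta * max over children of t` — equivalently `delta^h` where h is the
#' shortest hop count from the root up to t. Computed as a fixpoint over the
#' child -> parent links; a cycle is an error.
#'
#' @param dag a `disease_dag`.
#' @return named numeric vector of contributions over `dag$nodes`; the root
#'   has value 1 and every value lies in (0, 1].
#' @export
semantic_contribution <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  # Kahn's algorithm over child -> parent links: acyclicity check and a
  # child-before-parent order in which one relaxation pass reaches the fixpoint.
  nodes <- dag$nodes
  n <- length(nodes)
  indeg <- stats::setNames(rep(0L, n), nodes)
  if (nrow(dag$edges)) {
    cnt <- table(dag$edges$parent)
    indeg[names(cnt)] <- as.integer(cnt)
  }
  order <- character(0)
  queue <- nodes[indeg == 0L]
  indeg_left <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    out <- dag$edges$parent[dag$edges$child == v]
    for (p in out) {
      indeg_left[p] <- indeg_left[p] - 1L
      if (indeg_left[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) < n) {
    stop("cycle detected in disease DAG of '", dag$root, "'")
  }
  contrib <- stats::setNames(rep(0, n), nodes)
  contrib[dag$root] <- 1
  for (v in order) {
    kids <- dag$edges$child[dag$edges$parent == v]
    if (length(kids)) {
      contrib[v] <- max(contrib[v], dag$delta * max(contrib[kids]))
    }
  }
  if (any(contrib <= 0)) {
    stop("disease DAG of '", dag$root,
         "' contains node(s) unreachable from the root: ",
         paste(names(contrib)[contrib <= 0], collapse = ", "))
  }
  contrib
}

#' Semantic value DV of a disease
#'
#' The sum of the decayed contributions of all nodes in the disease's DAG;
#' at least 1 (the root's own contribution).
#'
#' @param dag a `disease_dag`.
#' @return a single number.
#' @export
dv <- function(dag) {
  sum(semantic_contribution(dag))
}

#' Semantic similarity between two diseases
#'
#' Jaccard-style similarity: the contributions of the shared DAG nodes,
#' summed from both sides, over the sum of the two DV values. Symmetric, in
#' \[0, 1\], and 1 for a disease with itself.
#'
#' @param dag_i,dag_j `disease_dag` objects built with the same `delta`.
#' @return a single number in \[0, 1\].
#' @export
disease_similarity <- function(dag_i, dag_j) {
  stopifnot(inherits(dag_i, "disease_dag"), inherits(dag_j, "disease_dag"))
  if (dag_i$delta != dag_j$delta) {
    stop("disease DAGs were built with different delta values")
  }
  ci <- semantic_contribution(dag_i)
  cj <- semantic_contribution(dag_j)
  shared <- intersect(names(ci), names(cj))
  if (!length(shared)) return(0)
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

#' All pairwise disease similarities
#'
#' @param dags named (by root) or unnamed list of `disease_dag` objects.
#' @return symmetric matrix with unit diagonal, rows/columns named by the
#'   root disease ids.
#' @export
build_similarity_matrix <- function(dags) {
  stopifnot(length(dags) >= 1L)
  roots <- unname(vapply(dags, function(d) d$root, ""))
  n <- length(dags)
  contribs <- lapply(dags, semantic_contribution)
  dvs <- vapply(contribs, sum, 0)
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
      s <- if (length(shared)) {
        sum(contribs[[i]][shared] + contribs[[j]][shared]) / (dvs[i] + dvs[j])
      } else 0
      S[i, j] <- S[j, i] <- s
    }
  }
  dimnames(S) <- list(roots, roots)
  S
}

#' Read a MeSH-style descriptor hierarchy
#'
#' Expects a headerless TSV with columns `descriptor_id`, `tree_number`,
#' `parent_tree_number` (empty parent for top-level positions). A disease's
#' DAG is the ancestor closure of all its tree-number positions, with
#' child -> parent links between the descriptor terms the positions map to.
#'
#' @param path TSV file.
#' @param delta semantic contribution factor passed to every DAG.
#' @param diseases optional character vector restricting which descriptors
#'   get a DAG (default: every descriptor in the file).
#' @return named list of `disease_dag` objects.
#' @export
read_mesh_tsv <- function(path, delta = 0.5, diseases = NULL) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("descriptor_id", "tree_number",
                                         "parent_tree_number"))
  tab$descriptor_id <- normalize_id(tab$descriptor_id)
  desc_of <- stats::setNames(tab$descriptor_id, tab$tree_number)
  parent_of <- stats::setNames(tab$parent_tree_number, tab$tree_number)
  if (is.null(diseases)) diseases <- unique(tab$descriptor_id)
  diseases <- normalize_id(diseases)
  build_one <- function(d) {
    frontier <- tab$tree_number[tab$descriptor_id == d]
    if (!length(frontier)) stop("descriptor '", d, "' not in hierarchy file")
    kids <- character(); pars <- character()
    seen <- character()
    while (length(frontier)) {
      tn <- frontier[1L]; frontier <- frontier[-1L]
      if (tn %in% seen) next
      seen <- c(seen, tn)
      p <- parent_of[[tn]]
      if (is.null(p) || is.na(p) || !nzchar(p)) next
      if (!p %in% names(desc_of)) {
        stop("tree number '", p, "' referenced but not defined in ", path)
      }
      kids <- c(kids, desc_of[[tn]])
      pars <- c(pars, desc_of[[p]])
      frontier <- c(frontier, p)
    }
    disease_dag(d, data.frame(child = kids, parent = pars,
                              stringsAsFactors = FALSE), delta = delta)
  }
  stats::setNames(lapply(diseases, build_one), diseases)
}

#' Leaf descriptors of a MeSH-style hierarchy file
#'
#' Descriptors none of whose tree positions is a parent of another position —
#' the disease terms themselves, as opposed to ancestor category terms.
#'
#' @param path hierarchy TSV (see [read_mesh_tsv()]).
#' @return character vector of descriptor ids.
#' @export
mesh_leaf_descriptors <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("descriptor_id", "tree_number",
                                         "parent_tree_number"))
  tab$descriptor_id <- normalize_id(tab$descriptor_id)
  is_parent <- tab$tree_number %in% tab$parent_tree_number
  setdiff(unique(tab$descriptor_id), unique(tab$descriptor_id[is_parent]))
}

#' Write disease hierarchies in the MeSH-style TSV dialect
#'
#' @param rows data.frame with columns `descriptor_id`, `tree_number`,
#'   `parent_tree_number`.
#' @param path output TSV.
#' @export
write_mesh_tsv <- function(rows, path) {
  utils::write.table(rows[, c("descriptor_id", "tree_number",
                              "parent_tree_number")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
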