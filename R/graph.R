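#' @useDynLib dwlmi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The five entity classes and nine curated association classes of the
# heterogeneous molecular network. Each relation maps to the (source, target)
# node types its edge list columns carry.
.NODE_TYPES <- c("lncRNA", "miRNA", "disease", "protein", "drug")

.RELATIONS <- list(
  "lncRNA-miRNA"    = c("lncRNA",  "miRNA"),
  "protein-miRNA"   = c("protein", "miRNA"),
  "disease-miRNA"   = c("disease", "miRNA"),
  "disease-lncRNA"  = c("disease", "lncRNA"),
  "protein-lncRNA"  = c("protein", "lncRNA"),
  "disease-protein" = c("disease", "protein"),
  "protein-drug"    = c("protein", "drug"),
  "disease-drug"    = c("disease", "drug"),
  "protein-protein" = c("protein", "protein")
)

#' Node and relation classes of the heterogeneous network
#'
#' @return `node_types()` returns the five entity class labels;
#'   `relation_classes()` the nine association class names, each named after
#'   the (source, target) entity types of its edge lists.
#' @export
relation_classes <- function() names(.RELATIONS)

#' @rdname relation_classes
#' @export
node_types <- function() .NODE_TYPES

#' Endpoint types of a relation class
#' @param relation one of [relation_classes()].
#' @return character(2): source type, target type.
#' @export
relation_types <- function(relation) {
  relation <- match.arg(relation, names(.RELATIONS))
  .RELATIONS[[relation]]
}

# Uniform identifier normalisation: exact match after lowercasing and
# whitespace stripping (no fuzzy aliasing).
normalize_id <- function(x) tolower(trimws(x))

# Canonical unordered-pair key within a relation class.
.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read a typed association edge list
#'
#' Reads a headerless TSV with columns `source_id`, `target_id` and an
#' optional third `provenance` column, all interpreted under `relation`.
#' Identifiers are lowercased and whitespace-stripped; self-pairs and
#' duplicate unordered pairs are dropped with a message reporting the counts.
#'
#' @param path TSV file path.
#' @param relation one of [relation_classes()]; fixes the entity types of the
#'   two id columns.
#' @param provenance fallback database label used when the file has no third
#'   column.
#' @return an `association_table`: a data.frame with columns `source`,
#'   `target`, `relation`, `provenance` and attributes `relation`,
#'   `n_dropped_self`, `n_dropped_dup`.
#' @export
read_edge_list <- function(path, relation, provenance = NA_character_) {
  relation <- match.arg(relation, names(.RELATIONS))
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop("malformed edge list line ", bad[1L], " in ", path,
         ": expected >= 2 tab-separated fields")
  }
  src <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 2L)
  prov <- ifelse(nf >= 3L, vapply(fields, function(f) f[3L], ""), provenance)
  association_table(src, tgt, relation, prov)
}

#' Build an association table from id vectors
#'
#' @param source,target endpoint identifiers (normalised internally).
#' @param relation one of [relation_classes()].
#' @param provenance database label(s), recycled.
#' @return an `association_table` (see [read_edge_list()]).
#' @export
association_table <- function(source, target, relation,
                              provenance = NA_character_) {
  relation <- match.arg(relation, names(.RELATIONS))
  src <- normalize_id(source)
  tgt <- normalize_id(target)
  if (any(!nzchar(src)) || any(!nzchar(tgt))) {
    stop("empty identifier in ", relation, " associations")
  }
  prov <- rep_len(as.character(provenance), length(src))
  self <- src == tgt
  n_self <- sum(self)
  src <- src[!self]; tgt <- tgt[!self]; prov <- prov[!self]
  types <- .RELATIONS[[relation]]
  if (types[1L] != types[2L]) {
    clash <- intersect(src, tgt)
    if (length(clash)) {
      stop("endpoint type clash in ", relation, ": identifier(s) ",
           paste(utils::head(clash, 3L), collapse = ", "),
           " appear in both the ", types[1L], " and ", types[2L], " columns")
    }
  }
  dup <- duplicated(.pair_key(src, tgt))
  n_dup <- sum(dup)
  tab <- data.frame(source = src[!dup], target = tgt[!dup],
                    relation = rep_len(relation, sum(!dup)),
                    provenance = prov[!dup], stringsAsFactors = FALSE)
  if (n_self > 0L) message(relation, ": dropped ", n_self, " self-pair(s)")
  if (n_dup > 0L) message(relation, ": dropped ", n_dup, " duplicate pair(s)")
  structure(tab, relation = relation, n_dropped_self = n_self,
            n_dropped_dup = n_dup, class = c("association_table", "data.frame"))
}

#' Build the heterogeneous association graph
#'
#' Unions validated association tables into a simple undirected typed graph.
#' Node types are inferred from each table's relation class; the same
#' identifier used with two different types is an error. Parallel edges from
#' multiple tables collapse to one edge whose provenance labels are
#' concatenated.
#'
#' @param tables list of `association_table` objects.
#' @param extra_nodes optional data.frame (`id`, `type`) of nodes to include
#'   even if they touch no edge.
#' @return a `hetnet` object: list with data.frames `nodes` (`id`, `type`)
#'   and `edges` (`source`, `target`, `relation`, `provenance`).
#' @export
build_graph <- function(tables, extra_nodes = NULL) {
  stopifnot(is.list(tables))
  ids <- character(); types <- character()
  for (tab in tables) {
    if (!inherits(tab, "association_table")) {
      stop("build_graph expects association_table objects")
    }
    rel <- attr(tab, "relation")
    tt <- .RELATIONS[[rel]]
    ids <- c(ids, tab$source, tab$target)
    types <- c(types, rep(tt[1L], nrow(tab)), rep(tt[2L], nrow(tab)))
  }
  if (!is.null(extra_nodes)) {
    ids <- c(ids, normalize_id(extra_nodes$id))
    types <- c(types, as.character(extra_nodes$type))
  }
  keep <- !duplicated(ids)
  nodes <- data.frame(id = ids[keep], type = types[keep],
                      stringsAsFactors = FALSE)
  clash <- tapply(types, ids, function(x) length(unique(x)))
  if (length(clash) && any(clash > 1L)) {
    stop("identifier(s) used with two different node types: ",
         paste(utils::head(names(clash)[clash > 1L], 3L), collapse = ", "))
  }
  edges <- do.call(rbind, lapply(tables, function(tab) {
    as.data.frame(tab)[, c("source", "target", "relation", "provenance")]
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        relation = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  }
  # collapse parallel edges across tables of the same relation
  key <- paste(edges$relation, .pair_key(edges$source, edges$target))
  if (anyDuplicated(key)) {
    prov <- tapply(edges$provenance, key, function(p) {
      paste(unique(stats::na.omit(p)), collapse = ";")
    })
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$provenance <- as.character(prov[paste(edges$relation,
      .pair_key(edges$source, edges$target))])
  }
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  cat("Heterogeneous association network\n")
  s <- graph_summary(x)
  cat("  nodes:", sum(unlist(s$nodes)), "|",
      paste(names(s$nodes), unlist(s$nodes), collapse = ", "), "\n")
  cat("  edges:", sum(unlist(s$edges)), "\n")
  for (r in names(s$edges)) cat("    ", r, ": ", s$edges[[r]], "\n", sep = "")
  invisible(x)
}

#' Per-type node counts and per-class edge counts
#'
#' @param graph a `hetnet`.
#' @return list with named lists `nodes` (count per entity type) and `edges`
#'   (count per relation class), suitable for JSON export.
#' @export
graph_summary <- function(graph) {
  stopifnot(inherits(graph, "hetnet"))
  ncnt <- table(factor(graph$nodes$type, levels = .NODE_TYPES))
  ecnt <- table(factor(graph$edges$relation, levels = names(.RELATIONS)))
  list(nodes = as.list(as.integer(ncnt)) |> stats::setNames(.NODE_TYPES),
       edges = as.list(as.integer(ecnt)) |> stats::setNames(names(.RELATIONS)))
}

#' Re-export a graph as one TSV edge list per relation class
#'
#' @param graph a `hetnet`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths (named by relation class).
#' @export
export_edge_lists <- function(graph, dir) {
  stopifnot(inherits(graph, "hetnet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rels <- unique(graph$edges$relation)
  paths <- character(0)
  for (r in rels) {
    e <- graph$edges[graph$edges$relation == r, , drop = FALSE]
    p <- file.path(dir, paste0(gsub("-", "_", r), ".tsv"))
    utils::write.table(e[, c("source", "target", "provenance")], p,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths[r] <- p
  }
  invisible(paths)
}

#' Ids of nodes of a given type
#' @param graph a `hetnet`.
#' @param type one of [node_types()].
#' @export
nodes_of_type <- function(graph, type) {
  type <- match.arg(type, .NODE_TYPES)
  graph$nodes$id[graph$nodes$type == type]
}

#' The positive lncRNA-miRNA edges of a graph
#' @param graph a `hetnet`.
#' @return data.frame with columns `lncRNA`, `miRNA`.
#' @export
lncmi_edges <- function(graph) {
  e <- graph$edges[graph$edges$relation == "lncRNA-miRNA", , drop = FALSE]
  data.frame(lncRNA = e$source, miRNA = e$target, stringsAsFactors = FALSE)
}

#' Sample non-associated lncRNA-miRNA pairs
#'
#' Draws `n` distinct lncRNA-miRNA pairs uniformly from the pairs not present
#' as positive edges, labelled 0.
#'
#' @param graph a `hetnet`.
#' @param n number of negative pairs.
#' @param seed integer seed; the sample is reproducible under it.
#' @return data.frame `lncRNA`, `miRNA`, `label` (all 0).
#' @export
sample_negative_pairs <- function(graph, n, seed) {
  lnc <- nodes_of_type(graph, "lncRNA")
  mir <- nodes_of_type(graph, "miRNA")
  pos <- lncmi_edges(graph)
  pos_key <- .pair_key(pos$lncRNA, pos$miRNA)
  all_l <- rep(lnc, each = length(mir))
  all_m <- rep(mir, times = length(lnc))
  free <- !(.pair_key(all_l, all_m) %in% pos_key)
  avail <- sum(free)
  if (n > avail) {
    stop("capacity error: requested ", n, " negative pairs but only ",
         avail, " non-associated lncRNA-miRNA pairs exist")
  }
  idx <- which(free)
  pick <- local_seed(seed, sample(idx, n))
  data.frame(lncRNA = all_l[pick], miRNA = all_m[pick], label = 0L,
             stringsAsFactors = FALSE)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Remove held-out pairs and mask training edges before embedding
#'
#' Removes every `holdout` pair from the lncRNA-miRNA edge set, then retains
#' a uniformly random `keep_fraction` (rounded down) of the remaining
#' lncRNA-miRNA training edges. By default all other relation classes are
#' untouched; with `scope = "all"` the keep-fraction subsampling applies to
#' every relation class. The node set never changes, so nodes whose edges
#' were all masked persist as isolated vertices.
#'
#' @param graph a `hetnet`.
#' @param holdout data.frame (`lncRNA`, `miRNA`) of positive edges to remove;
#'   may be empty.
#' @param keep_fraction proportion of remaining training edges to embed, in
#'   (0, 1].
#' @param seed integer seed for the random retention.
#' @param scope `"lncmi"` (default) masks lncRNA-miRNA edges only; `"all"`
#'   subsamples every relation class.
#' @return a `hetnet` with the same node set.
#' @export
mask_edges <- function(graph, holdout, keep_fraction = 0.8, seed = 1L,
                       scope = c("lncmi", "all")) {
  stopifnot(inherits(graph, "hetnet"),
            keep_fraction > 0, keep_fraction <= 1)
  scope <- match.arg(scope)
  edges <- graph$edges
  is_lm <- edges$relation == "lncRNA-miRNA"
  if (NROW(holdout)) {
    hold_key <- .pair_key(normalize_id(holdout[[1L]]),
                          normalize_id(holdout[[2L]]))
    edge_key <- .pair_key(edges$source, edges$target)
    hit <- is_lm & (edge_key %in% hold_key)
    if (sum(hit) < length(unique(hold_key))) {
      stop("holdout contains pair(s) that are not positive lncRNA-miRNA edges")
    }
    edges <- edges[!hit, , drop = FALSE]
    is_lm <- edges$relation == "lncRNA-miRNA"
  }
  subsample <- function(idx, s) {
    n_keep <- floor(keep_fraction * length(idx))
    local_seed(s, sample(idx, n_keep))
  }
  if (keep_fraction < 1) {
    if (scope == "lncmi") {
      keep <- c(which(!is_lm), subsample(which(is_lm), seed))
    } else {
      keep <- unlist(lapply(seq_along(names(.RELATIONS)), function(i) {
        r <- names(.RELATIONS)[i]
        idx <- which(edges$relation == r)
        if (length(idx)) subsample(idx, seed + i) else integer(0)
      }))
    }
    edges <- edges[sort(keep), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(nodes = graph$nodes, edges = edges), class = "hetnet")
}

# Adjacency list (named list of character neighbour vectors) for walks.
adjacency_list <- function(graph) {
  ids <- graph$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  if (nrow(graph$edges)) {
    ends <- c(graph$edges$source, graph$edges$target)
    nbrs <- c(graph$edges$target, graph$edges$source)
    sp <- split(nbrs, ends)
    adj[names(sp)] <- sp
  }
  adj
}
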