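# Per-node attribute representation. Sequence-bearing nodes (lncRNA, miRNA,
# protein) get the 64-d 3-mer composition directly; diseases get their
# similarity-profile row and drugs their fingerprint, each unified to the
# attribute dimension by a stacked autoencoder trained on that resource.

#' Prepare the shared attribute resources
#'
#' Builds the disease similarity matrix, the drug fingerprint matrix and the
#' stacked autoencoders that bring both (and, optionally, the k-mer vectors)
#' to the common attribute dimension. Attributes use no edge information, so
#' the resources can be computed once per data set and reused across
#' cross-validation folds.
#'
#' @param sequences named character vector of sequences for lncRNA, miRNA and
#'   protein node ids.
#' @param dags named list of `disease_dag` objects (names = disease ids).
#' @param drugs data.frame with columns `id`, `smiles`.
#' @param config configuration list, see [default_config()].
#' @param seed integer seed for autoencoder training.
#' @return an `attribute_resources` list.
#' @export
prepare_attribute_resources <- function(sequences, dags, drugs,
                                        config = default_config(),
                                        seed = 1L) {
  names(sequences) <- normalize_id(names(sequences))
  sim <- if (length(dags)) build_similarity_matrix(dags) else NULL
  fps <- if (NROW(drugs)) {
    fingerprint_matrix(drugs, radius = config$fingerprint_radius,
                       nbits = config$fingerprint_nbits)
  } else NULL
  dim_out <- config$attribute_dim
  sae_disease <- if (!is.null(sim) && nrow(sim) >= 1L) {
    sae_train(sim, layer_dims = sae_layer_dims(ncol(sim), dim_out),
              epochs = config$sae_epochs,
              learning_rate = config$sae_learning_rate, seed = seed)
  } else NULL
  sae_drug <- if (!is.null(fps) && nrow(fps) >= 1L) {
    sae_train(fps, layer_dims = sae_layer_dims(ncol(fps), dim_out),
              epochs = config$sae_epochs,
              learning_rate = config$sae_learning_rate, seed = seed + 1L)
  } else NULL
  structure(list(sequences = sequences, similarity = sim,
                 fingerprints = fps, sae_disease = sae_disease,
                 sae_drug = sae_drug, config = config),
            class = "attribute_resources")
}

#' Attribute vector of a single node
#'
#' Dispatches on the node type: lncRNA/miRNA get the 3-mer composition of
#' their (U -> T normalised) sequence; proteins the 3-mer composition of
#' their class-reduced sequence; diseases their similarity-matrix row and
#' drugs their fingerprint, both encoded by the resource's stacked
#' autoencoder. A node whose raw resource is missing (or whose sequence is
#' too short for a 3-mer) keeps a zero vector, with a warning.
#'
#' @param id node identifier.
#' @param type one of [node_types()].
#' @param resources an `attribute_resources` object.
#' @return numeric vector of length `config$attribute_dim` (64 by default).
#' @export
attribute_vector <- function(id, type, resources) {
  stopifnot(inherits(resources, "attribute_resources"))
  id <- normalize_id(id)
  type <- match.arg(type, node_types())
  cfg <- resources$config
  d <- cfg$attribute_dim
  zero <- function(msg) {
    warning("node '", id, "': ", msg, "; using a zero attribute vector")
    rep(0, d)
  }
  if (type %in% c("lncRNA", "miRNA", "protein")) {
    seq <- resources$sequences[id]
    if (is.na(seq)) return(zero("no sequence"))
    if (type == "protein") seq <- reduce_protein_alphabet(seq)
    v <- tryCatch(kmer_frequency_vector(seq, k = cfg$kmer_k),
                  error = function(e) NULL)
    if (is.null(v)) return(zero("sequence shorter than the k-mer length"))
    if (isTRUE(cfg$sae_on_kmer) && !is.null(resources$sae_kmer)) {
      v <- sae_encode(resources$sae_kmer, v)
    }
    return(unname(v))
  }
  if (type == "disease") {
    sim <- resources$similarity
    if (is.null(sim) || !(id %in% rownames(sim))) {
      return(zero("no disease DAG"))
    }
    return(unname(sae_encode(resources$sae_disease, sim[id, ])))
  }
  fps <- resources$fingerprints
  if (is.null(fps) || !(id %in% rownames(fps))) {
    return(zero("no parseable structure"))
  }
  unname(sae_encode(resources$sae_drug, fps[id, ]))
}

#' Attribute matrix for every node of a graph
#'
#' @param graph a `hetnet`.
#' @param resources an `attribute_resources` object.
#' @return numeric matrix, one row per node (rownames = node ids),
#'   `config$attribute_dim` columns.
#' @export
build_attributes <- function(graph, resources) {
  stopifnot(inherits(graph, "hetnet"))
  n <- nrow(graph$nodes)
  A <- matrix(0, n, resources$config$attribute_dim,
              dimnames = list(graph$nodes$id, NULL))
  for (i in seq_len(n)) {
    A[i, ] <- attribute_vector(graph$nodes$id[i], graph$nodes$type[i],
                               resources)
  }
  A
}

#' Export an attribute (or embedding) matrix as TSV
#' @param A matrix with rownames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(A, path) {
  utils::write.table(cbind(id = rownames(A), as.data.frame(A)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
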