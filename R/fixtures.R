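# Synthetic input generator: every input kind the pipeline consumes
# (edge lists, sequences, disease hierarchies, drug structures) with planted
# block structure in the lncRNA-miRNA layer so association signal is
# recoverable end-to-end without any database download.

#' Specification of a synthetic fixture
#'
#' The lncRNA-miRNA layer follows a planted block model: lncRNAs and miRNAs
#' are assigned to `n_blocks` blocks and a pair is associated with
#' probability `p_within` inside a block and `p_between` across blocks. The
#' other eight relation classes are Erdos-Renyi at the given densities. With
#' `couple_attributes` the block label also biases nucleotide composition,
#' so attribute features carry block signal too.
#'
#' @param n_lncrna,n_mirna,n_disease,n_protein,n_drug node counts per type.
#' @param n_blocks planted block count for the lncRNA-miRNA layer.
#' @param p_within,p_between within/between-block association probabilities.
#' @param densities named numeric vector of edge densities for the other
#'   eight relation classes.
#' @param lncrna_length,mirna_length,protein_length sequence length ranges.
#' @param mesh_depth,mesh_branching disease hierarchy shape.
#' @param couple_attributes bias sequence composition by block label.
#' @param seed integer seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_lncrna = 40L, n_mirna = 40L, n_disease = 20L,
                         n_protein = 30L, n_drug = 15L, n_blocks = 4L,
                         p_within = 0.5, p_between = 0.02,
                         densities = c("protein-miRNA" = 0.05,
                                       "disease-miRNA" = 0.05,
                                       "disease-lncRNA" = 0.05,
                                       "protein-lncRNA" = 0.05,
                                       "disease-protein" = 0.05,
                                       "protein-drug" = 0.08,
                                       "disease-drug" = 0.05,
                                       "protein-protein" = 0.08),
                         lncrna_length = c(200L, 400L),
                         mirna_length = c(20L, 24L),
                         protein_length = c(100L, 200L),
                         mesh_depth = 3L, mesh_branching = 2L,
                         couple_attributes = TRUE, seed = 1L) {
  stopifnot(p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            all(densities >= 0), all(densities <= 1),
            n_lncrna >= 1, n_mirna >= 1, n_disease >= 1, n_protein >= 1,
            n_drug >= 1, n_blocks >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Random sequences
#'
#' @param n number of sequences.
#' @param length_range integer c(min, max), min >= 3.
#' @param alphabet `"nucleotide"` (ACGT) or `"protein"` (20 amino acids).
#' @param seed integer seed.
#' @param ids optional record ids (default seq1..seqn).
#' @param probs optional per-letter sampling probabilities (uniform default).
#' @return named character vector of sequences.
#' @export
gen_sequences <- function(n, length_range, alphabet = c("nucleotide",
                                                        "protein"),
                          seed = 1L, ids = NULL, probs = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(length_range[1L] >= 3L, length_range[2L] >= length_range[1L])
  letters_ <- if (alphabet == "nucleotide") c("A", "C", "G", "T") else
    names(.AA_CLASSES)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  local_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(letters_, L, replace = TRUE, prob = probs), collapse = "")
    }, "")
    stats::setNames(seqs, normalize_id(ids))
  })
}

# MeSH-style hierarchy rows of the two fixed worked-example diseases.
.worked_example_rows <- function() {
  data.frame(
    descriptor_id = c("skin and connective tissue diseases",
                      "connective tissue diseases",
                      "immune system diseases",
                      "autoimmune diseases",
                      "systemic lupus erythematosus",
                      "systemic lupus erythematosus",
                      "skin diseases",
                      "acneiform eruptions",
                      "sebaceous gland diseases",
                      "acne vulgaris",
                      "acne vulgaris"),
    tree_number = c("C17", "C17.300", "C20", "C20.111", "C17.300.480",
                    "C20.111.590", "C17.800", "C17.800.030", "C17.800.794",
                    "C17.800.030.150", "C17.800.794.111"),
    parent_tree_number = c("", "C17", "", "C20", "C17.300", "C20.111",
                           "C17", "C17.800", "C17.800", "C17.800.030",
                           "C17.800.794"),
    stringsAsFactors = FALSE)
}

#' The fixed worked-example disease DAG pair
#'
#' The reconstructed MeSH positions of systemic lupus erythematosus (root
#' plus parents Connective Tissue Diseases and Autoimmune Diseases, with
#' grandparents Skin and Connective Tissue Diseases and Immune System
#' Diseases) and acne vulgaris (root plus parents Acneiform Eruptions and
#' Sebaceous Gland Diseases, their shared parent Skin Diseases and its
#' parent Skin and Connective Tissue Diseases). At `delta` 0.5 their DV
#' values are 2.5 and 2.375 and their semantic similarity is 0.375/4.875.
#'
#' @param delta semantic contribution factor.
#' @return named list of two `disease_dag` objects.
#' @export
worked_example_dags <- function(delta = 0.5) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_mesh_tsv(.worked_example_rows(), path)
  read_mesh_tsv(path, delta = delta,
                diseases = c("systemic lupus erythematosus", "acne vulgaris"))
}

#' Random disease hierarchies plus the fixed worked-example pair
#'
#' Generates a random category forest (shared upper-level ancestors, so
#' pairwise similarities are non-trivial) and attaches each disease at one or
#' two random positions. The two fixed worked-example DAGs (see
#' [worked_example_dags()]) are always appended.
#'
#' @param n_diseases number of generated diseases.
#' @param max_depth category tree depth (>= 1).
#' @param branching children per category node.
#' @param seed integer seed.
#' @param ids optional disease ids (default disease01..).
#' @param delta semantic contribution factor.
#' @return named list of `disease_dag` objects with attribute `mesh_table`,
#'   the hierarchy rows in the MeSH TSV dialect.
#' @export
gen_mesh_forest <- function(n_diseases, max_depth = 3L, branching = 2L,
                            seed = 1L, ids = NULL, delta = 0.5) {
  stopifnot(max_depth >= 1L, branching >= 1L)
  if (is.null(ids)) ids <- sprintf("disease%02d", seq_len(n_diseases))
  ids <- normalize_id(ids)
  rows <- local_seed(seed, {
    # category forest: 3 roots, `branching` children per node, max_depth levels
    cat_rows <- data.frame(descriptor_id = character(),
                           tree_number = character(),
                           parent_tree_number = character(),
                           stringsAsFactors = FALSE)
    level <- data.frame(tn = sprintf("F%02d", 1:3), parent = "",
                        stringsAsFactors = FALSE)
    all_cats <- character(0)
    for (depth in seq_len(max_depth)) {
      cat_rows <- rbind(cat_rows, data.frame(
        descriptor_id = paste0("category ", tolower(level$tn)),
        tree_number = level$tn, parent_tree_number = level$parent,
        stringsAsFactors = FALSE))
      all_cats <- c(all_cats, level$tn)
      if (depth == max_depth) break
      level <- do.call(rbind, lapply(seq_len(nrow(level)), function(i) {
        data.frame(tn = paste0(level$tn[i], ".",
                               sprintf("%03d", seq_len(branching) * 100L)),
                   parent = level$tn[i], stringsAsFactors = FALSE)
      }))
    }
    dis_rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
      n_pos <- sample(1:2, 1L)
      anchors <- sample(all_cats, n_pos)
      data.frame(descriptor_id = ids[i],
                 tree_number = paste0(anchors, ".", sprintf("%03d", 500L + i)),
                 parent_tree_number = anchors, stringsAsFactors = FALSE)
    }))
    # keep only category positions on some disease's ancestor path, so the
    # leaf descriptors of the written hierarchy are exactly the disease terms
    closure <- character(0)
    frontier <- unique(dis_rows$parent_tree_number)
    while (length(frontier)) {
      closure <- union(closure, frontier)
      frontier <- setdiff(
        cat_rows$parent_tree_number[cat_rows$tree_number %in% frontier],
        c(closure, ""))
    }
    cat_rows <- cat_rows[cat_rows$tree_number %in% closure, , drop = FALSE]
    rbind(cat_rows, dis_rows, .worked_example_rows())
  })
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_mesh_tsv(rows, path)
  dags <- read_mesh_tsv(path, delta = delta,
                        diseases = c(ids, "systemic lupus erythematosus",
                                     "acne vulgaris"))
  attr(dags, "mesh_table") <- rows
  dags
}

# Curated pool of valid small-molecule SMILES for fixture drugs.
.SMILES_POOL <- c(
  "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  "CC(=O)Nc1ccc(O)cc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CCO", "CO",
  "CC(C)=O", "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "c1ccncc1", "OCC1OC(O)C(O)C(O)C1O", "NCC(=O)O", "CC(N)C(=O)O",
  "OCC(N)C(=O)O", "CC(O)C(=O)O", "OC(=O)CC(O)(CC(=O)O)C(=O)O", "NC(N)=O",
  "CN1CCCC1c1cccnc1", "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1", "c1c[nH]cn1",
  "c1ccoc1", "c1ccsc1", "C1COCCN1", "C1CCNCC1", "C1CCCCC1", "CCCCCC",
  "CCCCCCCCO", "CC(=O)O", "OC=O", "OC(=O)c1ccccc1", "OC(=O)c1ccccc1O",
  "COc1cc(C=O)ccc1O", "CC(C)C1CCC(C)CC1O", "CC(=C)C1CCC(C)=CC1",
  "C=Cc1ccccc1", "NC(=O)C=C", "ClC(Cl)Cl", "CS(C)=O", "OCC(O)CO", "OCCO",
  "NCCS(=O)(=O)O", "NCCc1ccc(O)c(O)c1", "NCCc1c[nH]c2ccc(O)cc12",
  "CNCC(O)c1ccc(O)c(O)c1", "NCCc1c[nH]cn1",
  "CC(=O)NCCc1c[nH]c2ccc(OC)cc12", "Nc1ncnc2[nH]cnc12",
  "Nc1nc2[nH]cnc2c(=O)[nH]1", "Nc1cc[nH]c(=O)n1", "Cc1c[nH]c(=O)[nH]c1=O",
  "O=c1cc[nH]c(=O)[nH]1", "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
  "c1ccc2ncccc2c1", "c1ccc2cc3ccccc3cc2c1", "Oc1ccccc1O",
  "Oc1cccc(O)c1", "Oc1ccc(O)cc1", "O=Cc1ccccc1")

#' Sample fixture drug structures
#'
#' Samples without replacement from an embedded pool of curated valid
#' small-molecule SMILES.
#'
#' @param n number of drugs (at most the pool size).
#' @param seed integer seed.
#' @param ids optional drug ids (default drug01..).
#' @return data.frame with columns `id`, `smiles`.
#' @export
gen_smiles <- function(n, seed = 1L, ids = NULL) {
  if (n > length(.SMILES_POOL)) {
    stop("capacity error: at most ", length(.SMILES_POOL),
         " fixture drugs available")
  }
  if (is.null(ids)) ids <- sprintf("drug%02d", seq_len(n))
  smi <- local_seed(seed, sample(.SMILES_POOL, n))
  data.frame(id = normalize_id(ids), smiles = smi, stringsAsFactors = FALSE)
}

# Bernoulli edge table over all cross pairs of two id sets; guarantees at
# least one edge so every relation class is populated.
.er_edges <- function(ids_a, ids_b, density, relation, seed) {
  pairs <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  if (relation == "protein-protein") {
    pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
  }
  keep <- local_seed(seed, stats::runif(nrow(pairs)) < density)
  if (!any(keep)) keep[1L] <- TRUE
  association_table(pairs$a[keep], pairs$b[keep], relation,
                    provenance = "synthetic")
}

#' Generate a full synthetic input bundle
#'
#' Produces a heterogeneous graph over all five node types with all nine
#' relation classes populated, sequences for every lncRNA/miRNA/protein, a
#' disease DAG for every disease, a SMILES for every drug, and the planted
#' block labels of the lncRNA-miRNA layer.
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `graph`, `sequences`, `dags`, `drugs`,
#'   `blocks` (named block label vector over lncRNA and miRNA ids), `spec`.
#' @export
gen_network <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  lnc <- sprintf("lnc%03d", seq_len(spec$n_lncrna))
  mir <- sprintf("mir%03d", seq_len(spec$n_mirna))
  dis <- sprintf("dis%03d", seq_len(spec$n_disease))
  prot <- sprintf("prot%03d", seq_len(spec$n_protein))
  drug <- sprintf("drug%02d", seq_len(spec$n_drug))
  blocks <- local_seed(spec$seed, {
    stats::setNames(c(sample(rep_len(seq_len(spec$n_blocks), spec$n_lncrna)),
                      sample(rep_len(seq_len(spec$n_blocks), spec$n_mirna))),
                    c(lnc, mir))
  })
  # planted-block lncRNA-miRNA layer
  pairs <- expand.grid(lncRNA = lnc, miRNA = mir, stringsAsFactors = FALSE)
  p <- ifelse(blocks[pairs$lncRNA] == blocks[pairs$miRNA],
              spec$p_within, spec$p_between)
  keep <- local_seed(spec$seed + 1L, stats::runif(nrow(pairs)) < p)
  if (!any(keep)) keep[1L] <- TRUE
  tabs <- list(association_table(pairs$lncRNA[keep], pairs$miRNA[keep],
                                 "lncRNA-miRNA", provenance = "synthetic"))
  ends <- list("protein-miRNA" = list(prot, mir),
               "disease-miRNA" = list(dis, mir),
               "disease-lncRNA" = list(dis, lnc),
               "protein-lncRNA" = list(prot, lnc),
               "disease-protein" = list(dis, prot),
               "protein-drug" = list(prot, drug),
               "disease-drug" = list(dis, drug),
               "protein-protein" = list(prot, prot))
  for (i in seq_along(ends)) {
    r <- names(ends)[i]
    tabs[[length(tabs) + 1L]] <-
      .er_edges(ends[[i]][[1L]], ends[[i]][[2L]], spec$densities[[r]], r,
                seed = spec$seed + 10L + i)
  }
  all_nodes <- data.frame(
    id = c(lnc, mir, dis, prot, drug),
    type = rep(c("lncRNA", "miRNA", "disease", "protein", "drug"),
               c(length(lnc), length(mir), length(dis), length(prot),
                 length(drug))),
    stringsAsFactors = FALSE)
  graph <- build_graph(tabs, extra_nodes = all_nodes)
  # sequences; with coupled attributes each block has a biased composition
  seq_of <- function(ids_, range_, off, probs_by_block = NULL) {
    if (is.null(probs_by_block)) {
      gen_sequences(length(ids_), range_, "nucleotide",
                    seed = spec$seed + off, ids = ids_)
    } else {
      out <- character(length(ids_))
      names(out) <- ids_
      for (b in seq_len(spec$n_blocks)) {
        sel <- ids_[blocks[ids_] == b]
        if (!length(sel)) next
        out[sel] <- gen_sequences(length(sel), range_, "nucleotide",
                                  seed = spec$seed + off + 100L * b,
                                  ids = sel, probs = probs_by_block[[b]])
      }
      out
    }
  }
  block_probs <- NULL
  if (isTRUE(spec$couple_attributes)) {
    block_probs <- lapply(seq_len(spec$n_blocks), function(b) {
      pr <- rep(0.15, 4)
      pr[(b - 1L) %% 4L + 1L] <- 0.55
      pr
    })
  }
  sequences <- c(
    seq_of(lnc, spec$lncrna_length, 20L, block_probs),
    seq_of(mir, spec$mirna_length, 40L, block_probs),
    gen_sequences(spec$n_protein, spec$protein_length, "protein",
                  seed = spec$seed + 60L, ids = prot))
  dags <- gen_mesh_forest(spec$n_disease, max_depth = spec$mesh_depth,
                          branching = spec$mesh_branching,
                          seed = spec$seed + 70L, ids = dis)
  drugs <- gen_smiles(spec$n_drug, seed = spec$seed + 80L, ids = drug)
  list(graph = graph, sequences = sequences, dags = dags, drugs = drugs,
       blocks = blocks, spec = spec)
}

#' Write a fixture bundle to disk in the pipeline's input formats
#'
#' Edge lists as one TSV per relation class under `edges/`, sequences as
#' FASTA, the disease hierarchy as MeSH-style TSV, drugs as a two-column
#' SMILES TSV, and the ground-truth block labels plus the spec as JSON.
#'
#' @param fixture output of [gen_network()].
#' @param dir target directory.
#' @return invisibly, `dir`.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  export_edge_lists(fixture$graph, file.path(dir, "edges"))
  write_fasta_sequences(fixture$sequences, file.path(dir, "sequences.fasta"))
  write_mesh_tsv(attr(fixture$dags, "mesh_table"), file.path(dir, "mesh.tsv"))
  utils::write.table(fixture$drugs, file.path(dir, "smiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(as.list(fixture$blocks), file.path(dir, "blocks.json"),
                       auto_unbox = TRUE)
  spec <- fixture$spec
  class(spec) <- NULL
  jsonlite::write_json(spec, file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir bundle directory.
#' @param delta semantic contribution factor for the disease DAGs.
#' @return list with `graph`, `sequences`, `dags`, `drugs`.
#' @export
read_fixture_bundle <- function(dir, delta = 0.5) {
  edge_dir <- file.path(dir, "edges")
  files <- list.files(edge_dir, pattern = "\\.tsv$", full.names = TRUE)
  tabs <- lapply(files, function(f) {
    rel <- gsub("_", "-", sub("\\.tsv$", "", basename(f)))
    read_edge_list(f, rel)
  })
  sequences <- read_fasta_sequences(file.path(dir, "sequences.fasta"))
  mesh_path <- file.path(dir, "mesh.tsv")
  dags <- read_mesh_tsv(mesh_path, delta = delta,
                        diseases = mesh_leaf_descriptors(mesh_path))
  drugs <- read_smiles_tsv(file.path(dir, "smiles.tsv"))
  graph <- build_graph(tabs)
  list(graph = graph, sequences = sequences, dags = dags, drugs = drugs)
}
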