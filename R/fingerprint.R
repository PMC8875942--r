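# Circular (Morgan-type / ECFP) fingerprints via OpenBabel. OpenBabel names
# the fingerprint by diameter (ECFP0/2/4/6...), i.e. 2 * radius.
.ecfp_name <- function(radius) {
  stopifnot(radius %in% 0:5)
  paste0("ECFP", 2L * radius)
}

#' Hashed circular fingerprint of a molecule
#'
#' Computes a Morgan-type (ECFP) binary fingerprint from a SMILES string and
#' OR-folds it to `nbits`. Canonical and non-canonical SMILES of the same
#' molecule yield identical vectors.
#'
#' @param smiles a single SMILES string.
#' @param radius circular neighbourhood radius (default 2, i.e. ECFP4).
#' @param nbits fingerprint length after folding (default 1024).
#' @return integer 0/1 vector of length `nbits`.
#' @export
drug_fingerprint <- function(smiles, radius = 2L, nbits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nbits >= 1)
  raw <- tryCatch({
    mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    as.numeric(ChemmineOB::fingerprint_OB(mol, .ecfp_name(radius)))
  }, error = function(e) {
    stop("structure error: could not parse SMILES '", smiles, "'")
  })
  if (length(raw) %% nbits == 0L) {
    folded <- as.integer(rowSums(matrix(raw, nrow = nbits)) > 0)
  } else {
    idx <- ((seq_along(raw) - 1L) %% nbits) + 1L
    folded <- as.integer(tapply(raw, idx, max))
  }
  folded
}

#' Read drug structures from a two-column TSV
#'
#' @param path headerless TSV with columns `drug_id`, `smiles`.
#' @return data.frame with columns `id` (normalised), `smiles`.
#' @export
read_smiles_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("id", "smiles"))
  tab$id <- normalize_id(tab$id)
  tab
}

#' Fingerprint matrix for a set of drugs
#'
#' Unparseable structures are dropped with a warning (the node keeps a zero
#' attribute vector downstream).
#'
#' @param drugs data.frame with columns `id`, `smiles`.
#' @inheritParams drug_fingerprint
#' @return 0/1 matrix, one row per successfully parsed drug, rownames = ids.
#' @export
fingerprint_matrix <- function(drugs, radius = 2L, nbits = 1024L) {
  rows <- list()
  for (i in seq_len(nrow(drugs))) {
    fp <- tryCatch(drug_fingerprint(drugs$smiles[i], radius, nbits),
                   error = function(e) NULL)
    if (is.null(fp)) {
      warning("dropping drug '", drugs$id[i], "': unparseable SMILES")
    } else {
      rows[[drugs$id[i]]] <- fp
    }
  }
  if (!length(rows)) return(matrix(0L, 0L, nbits))
  do.call(rbind, rows)
}
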