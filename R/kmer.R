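#' Enumerate the k-mers of a sequence
#'
#' Sliding-window substrings of length `k` in sequence order; a sequence of
#' length L yields L - k + 1 of them (none when k > L).
#'
#' @param seq a single character string.
#' @param k substring length, >= 1.
#' @return character vector of k-mers.
#' @export
enumerate_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1)
  L <- nchar(seq)
  if (k > L) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# The 64 possible 3-mers over ACGT in lexicographic order.
kmer_names <- function(k = 3L) {
  mkAllStrings <- Biostrings::mkAllStrings
  mkAllStrings(c("A", "C", "G", "T"), k)
}

# Normalise a nucleotide string to the DNA alphabet: uppercase, U -> T.
normalize_nucleotide <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

#' Normalised 3-mer frequency vector of a sequence
#'
#' Counts overlapping k-mers over the 4-letter alphabet ACGT (RNA is mapped
#' U -> T first; proteins must be reduced with [reduce_protein_alphabet()])
#' and divides by L - k + 1, so the 4^k entries sum to 1.
#'
#' @param seq a single character string over ACGT/ACGU.
#' @param k k-mer length (default 3, giving the 64-dimensional feature space).
#' @return named numeric vector of length 4^k in lexicographic k-mer order.
#' @export
kmer_frequency_vector <- function(seq, k = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- normalize_nucleotide(seq)
  L <- nchar(seq)
  if (L < k) {
    stop("degenerate input: sequence of length ", L,
         " cannot form a ", k, "-mer")
  }
  bad <- gsub("[ACGT]", "", seq)
  if (nzchar(bad)) {
    stop("sequence contains non-ACGT/ACGU character(s): ",
         paste(unique(strsplit(bad, "")[[1L]]), collapse = ""))
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  counts / (L - k + 1L)
}

# Fixed 4-group physicochemical partition of the 20 amino acids, mapped onto
# the ACGT index space so protein sequences admit the same 64-d 3-mer vector.
.AA_CLASSES <- c(
  A = "A", G = "A", V = "A",
  I = "C", L = "C", F = "C", P = "C",
  Y = "G", M = "G", T = "G", S = "G", C = "G", W = "G",
  H = "T", N = "T", Q = "T", D = "T", E = "T", K = "T", R = "T"
)

#' Reduce a protein sequence to a 4-letter class alphabet
#'
#' Maps each residue to one of four physicochemical classes
#' \{(A,G,V), (I,L,F,P), (Y,M,T,S,C,W), (H,N,Q,D,E,K,R)\}, written as
#' A/C/G/T so the reduced sequence feeds the nucleotide 3-mer machinery.
#' Unknown residues map to the largest class (written T) with a warning.
#'
#' @param seq a single amino-acid string.
#' @return character string of the same length over ACGT.
#' @export
reduce_protein_alphabet <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  aa <- strsplit(toupper(seq), "")[[1L]]
  cls <- .AA_CLASSES[aa]
  if (anyNA(cls)) {
    warning("unknown residue(s) ",
            paste(unique(aa[is.na(cls)]), collapse = ""),
            " mapped to the largest class")
    cls[is.na(cls)] <- "T"
  }
  paste(cls, collapse = "")
}

#' Read node sequences from a FASTA file
#'
#' Record ids (first whitespace-delimited token of the header) are normalised
#' like graph identifiers so they match node ids.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- normalize_id(sub("\\s.*$", "", names(set)))
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
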