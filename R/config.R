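# Run configuration: one flat list of paths and hyperparameters, validated
# against documented ranges, with per-stage seeds derived from the master
# seed by stable hashing of the stage name.

#' Default run configuration
#'
#' @return named list of all pipeline settings: input paths (`edges_dir`,
#'   `fasta`, `mesh`, `smiles`), `delta` (semantic decay), `kmer_k`,
#'   `fingerprint_radius`/`fingerprint_nbits`, `attribute_dim`,
#'   `sae_epochs`/`sae_learning_rate`/`sae_on_kmer`, DeepWalk
#'   `d`/`w`/`gamma`/`t`/`epochs`, `n_trees`, `cv_k`, `keep_fraction`,
#'   `mask_scope`, `threshold`, and the master `seed`.
#' @export
default_config <- function() {
  list(
    edges_dir = NULL, fasta = NULL, mesh = NULL, smiles = NULL,
    delta = 0.5,
    kmer_k = 3L,
    fingerprint_radius = 2L, fingerprint_nbits = 1024L,
    attribute_dim = 64L,
    sae_epochs = 200L, sae_learning_rate = 0.05, sae_on_kmer = FALSE,
    d = 64L, w = 5L, gamma = 10L, t = 40L, epochs = 5L,
    n_trees = 100L, cv_k = 5L, keep_fraction = 0.8, mask_scope = "lncmi",
    threshold = 0.5,
    seed = 1L)
}

.CONFIG_RANGES <- list(
  delta = c(1e-6, 1), kmer_k = c(1, 8), fingerprint_radius = c(0, 5),
  fingerprint_nbits = c(8, 4096), attribute_dim = c(1, 1024),
  sae_epochs = c(1, 1e5), sae_learning_rate = c(1e-8, 10),
  d = c(1, 1024), w = c(1, 100), gamma = c(1, 1000), t = c(1, 1000),
  epochs = c(1, 1000), n_trees = c(1, 1e5), cv_k = c(2, 100),
  keep_fraction = c(1e-9, 1), threshold = c(0, 1))

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) file, fills unspecified keys with the defaults,
#' rejects unknown keys by name and out-of-range values with the allowed
#' range.
#'
#' @param path config file; an empty file yields all defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  for (key in names(.CONFIG_RANGES)) {
    rng <- .CONFIG_RANGES[[key]]
    val <- cfg[[key]]
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < rng[1L] || val > rng[2L]) {
      stop("configuration value '", key, "' = ", val,
           " outside allowed range [", rng[1L], ", ", rng[2L], "]")
    }
  }
  if (!cfg$mask_scope %in% c("lncmi", "all")) {
    stop("configuration value 'mask_scope' must be 'lncmi' or 'all'")
  }
  int_keys <- c("kmer_k", "fingerprint_radius", "fingerprint_nbits",
                "attribute_dim", "sae_epochs", "d", "w", "gamma", "t",
                "epochs", "n_trees", "cv_k", "seed")
  for (key in int_keys) cfg[[key]] <- as.integer(cfg[[key]])
  cfg
}

#' Canonical serialisation of a configuration
#' @param config a configuration list.
#' @param path output YAML file.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(config[order(names(config))], path)
  invisible(path)
}

#' Stage seed derived from the master seed
#'
#' Stable string hash of the stage name combined with the master seed, so
#' adding a stage never shifts another stage's random stream.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}
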