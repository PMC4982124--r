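# Shared fixtures: all test data is generated in code.

# A small but complete two-species dataset configuration.
small_cfg <- function(seed = 42, ...) {
  args <- list(n_families = 6L, members_per_family_range = c(2L, 2L),
               n_chromosomes = 4L, chromosome_length = 1.5e6,
               n_synteny_segments = 2L, n_decoy_kinase = 2L,
               n_decoy_tm_kinase = 2L, seed = seed)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(generator_config, args)
}

# Cache one small zero-noise dataset across tests within a run.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_rlk_dataset(small_cfg())
    cache
  }
})

# Random amino-acid sequence.
raa <- function(n) paste(sample(familyscope:::AA_ALPHABET, n, replace = TRUE),
                         collapse = "")

# Random nucleotide sequence.
rnt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                         collapse = "")

# Paths of a dataset written to a temporary directory.
dataset_paths <- function(dir) {
  list(species = list(
    spA = list(proteome = file.path(dir, "spA_proteins.fa"),
               gff = file.path(dir, "spA.gff3"),
               domains = file.path(dir, "spA_domains.tsv"),
               genome = file.path(dir, "spA_genome.fa")),
    spB = list(proteome = file.path(dir, "spB_proteins.fa"),
               gff = file.path(dir, "spB.gff3"),
               domains = file.path(dir, "spB_domains.tsv"),
               genome = file.path(dir, "spB_genome.fa"))),
    reference = list(proteome = file.path(dir, "reference_proteins.fa"),
                     domains = file.path(dir, "reference_domains.tsv"),
                     labels = file.path(dir, "reference_labels.tsv")))
}

# Independent global affine-gap alignment score (Needleman-Wunsch with
# affine gaps), written as a plain three-state DP over strings. Used as
# an oracle; shares no code with the package implementation.
nw_affine_score <- function(a, b, S, open, extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- open + (i - 1) * extend
  for (j in 2:(m + 1)) Y[1, j] <- open + (j - 1) * extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- S[ca[i - 1], cb[j - 1]] + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    X[i, j] <- max(M[i - 1, j] + open + extend, X[i - 1, j] + extend,
                   Y[i - 1, j] + open + extend)
    Y[i, j] <- max(M[i, j - 1] + open + extend, X[i, j - 1] + open + extend,
                   Y[i, j - 1] + extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Independent Smith-Waterman local alignment score with linear gap cost.
sw_local_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (ca[i - 1] == cb[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + s, H[i - 1, j] + gap, H[i, j - 1] + gap)
    best <- max(best, H[i, j])
  }
  best
}
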