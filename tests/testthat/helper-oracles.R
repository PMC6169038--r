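# Independent oracles used to verify the fast implementations. These are
# deliberately naive (full dynamic-programming matrices, direct counting)
# and stay independent of the code paths they check.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Exhaustive affine-gap Smith-Waterman score by full-matrix DP in R.
# Forward strand only; a gap of length L costs gap_open + L * gap_extend.
sw_oracle_score <- function(q, s, match = 1, mismatch = 2, gap_open = 2,
                            gap_extend = 1) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qv); n <- length(sv)
  go <- gap_open + gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  acgt <- c("A", "C", "G", "T")
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - gap_extend)
      sub <- if (qv[i - 1] == sv[j - 1] && qv[i - 1] %in% acgt) match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Hamming distance between two equal-length sequences, by direct byte
# comparison.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# Identity between two co-aligned equal-length sequences.
hamming_identity <- function(a, b) 1 - hamming(a, b) / nchar(a)

# Clustering identity oracle: Biostrings local alignment, identical columns
# over the shorter sequence -- an implementation independent of the package's
# engine.
biostrings_cluster_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1,
                                       type = "local")
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# A small reference database used by several classifier tests.
make_test_db <- function(seed = 11, n_classes = 4, per_class = 0.02,
                         seqs_per_class = 4, root_length = 800,
                         between = 0.2) {
  evolve_reference_db(root_length, n_classes, per_class, seqs_per_class,
                      seed = seed, between_class_divergence = between)
}

# A reference_db wrapper around a single genome so reads can be simulated
# from it.
single_genome_db <- function(genome, cluster = "SIM") {
  structure(list(
    sequences = Biostrings::DNAStringSet(stats::setNames(genome$sequence,
                                                         genome$id)),
    lineage = data.frame(id = genome$id, domain = "Bacteria",
                         phylum = "SimPhylum", class = "SimClass",
                         cluster = cluster, stringsAsFactors = FALSE),
    seed = NA_integer_, params = list()), class = "reference_db")
}
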