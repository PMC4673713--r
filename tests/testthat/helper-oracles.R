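# Independent oracles used only by the tests.

# Nearest-neighbor Tm oracle: a second, independently written summation of
# the published unified duplex parameters (matrix-indexed walk rather than
# the package's named-vector lookup).
oracle_tm_nn <- function(seq, salt_molar = 0.05, oligo_molar = 5e-7) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  #           A      C      G      T   (columns = 3' base)
  dH <- matrix(c(-7.9,  -8.4,  -7.8,  -7.2,   # A-
                 -8.5,  -8.0, -10.6,  -7.8,   # C-
                 -8.2,  -9.8,  -8.0,  -8.4,   # G-
                 -7.2,  -8.2,  -8.5,  -7.9),  # T-
               nrow = 4, byrow = TRUE)
  dS <- matrix(c(-22.2, -22.4, -21.0, -20.4,
                 -22.7, -19.9, -27.2, -21.0,
                 -22.2, -24.4, -19.9, -22.4,
                 -21.3, -22.2, -22.7, -22.2),
               nrow = 4, byrow = TRUE)
  b <- code[strsplit(toupper(seq), "")[[1]]]
  n <- length(b)
  H <- 0; S <- 0
  for (i in seq_len(n - 1L)) {
    H <- H + dH[b[i], b[i + 1L]]
    S <- S + dS[b[i], b[i + 1L]]
  }
  for (term in c(b[1L], b[n])) {
    if (term %in% c(2L, 3L)) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (n - 1L) * log(salt_molar)
  H * 1000 / (S + 1.987 * log(oligo_molar / 4)) - 273.15
}

# Exhaustive local-alignment oracle: best-scoring reference per read using
# full (unbanded) Smith-Waterman via Biostrings, vectorized over reads.
oracle_best_targets <- function(reads, refs) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pat <- Biostrings::DNAStringSet(reads)
  scores <- vapply(refs, function(rf) {
    Biostrings::pairwiseAlignment(pat, Biostrings::DNAString(rf),
                                  type = "local",
                                  substitutionMatrix = submat,
                                  gapOpening = 2, gapExtension = 1,
                                  scoreOnly = TRUE)
  }, numeric(length(reads)))
  if (length(reads) == 1L) scores <- matrix(scores, nrow = 1)
  names(refs)[apply(scores, 1L, which.max)]
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_subs <- function(seq, n_subs) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(length(b), n_subs)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}
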