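# Shared in-code fixtures for the test suite.

rnaSet <- function(...) {
  x <- c(...)
  Biostrings::RNAStringSet(x)
}

# Uniform random RNA string of length n (uses current RNG state).
randomRna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Random Pssm with standard-normal cells.
randomPssm <- function(m, id = "rnd") {
  Pssm(matrix(rnorm(4 * m), 4, m,
              dimnames = list(c("A", "C", "G", "U"), NULL)),
       motifId = id, kind = "log-odds")
}

# Independent brute-force oracle for the window-score sum: an explicit double
# loop over windows and motif positions, no shared code with scanPssm().
bruteForceScan <- function(seqChar, mat) {
  ch <- strsplit(seqChar, "")[[1]]
  n <- length(ch)
  m <- ncol(mat)
  scores <- rep(NA_real_, n - m + 1L)
  for (i in seq_len(n - m + 1L)) {
    total <- 0
    defined <- TRUE
    for (k in seq_len(m)) {
      b <- ch[i + k - 1L]
      if (!b %in% rownames(mat)) { defined <- FALSE; break }
      total <- total + mat[b, k]
    }
    if (defined) scores[i] <- total
  }
  scores
}

# Brute-force AUC oracle: all positive/negative pairs, ties counted 1/2.
bruteForceAuc <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == -1]
  total <- 0
  for (p in ps) for (q in ns)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(ps) * length(ns))
}

# A tiny MEME minimal file with the given motif blocks, written to a temp path.
writeMemeFixture <- function(blocks, alphabet = "ACGT") {
  path <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", paste0("ALPHABET= ", alphabet), "",
               blocks), path)
  path
}
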