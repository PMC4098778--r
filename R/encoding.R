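#' Tetranucleotide composition of an RNA sequence
#'
#' Counts every width-4 window (step 1) of the sequence; windows containing a
#' non-ACGU symbol are skipped. By default raw counts are returned: on the
#' datasets this method targets, dividing by sequence length did not help the
#' classifier, so normalization is off unless requested (then counts are
#' divided by \code{max(n - 3, 1)}).
#'
#' @param seq a single RNA string, an \code{RNAString} or an
#'   \code{RNAStringSet} of length 1.
#' @param normalize divide counts by the number of window positions.
#' @return Named numeric vector of length 256 (lexicographic AAAA..UUUU).
#' @examples
#' tetraCounts("AAAAA")[["AAAA"]]   # 2
#' @export
tetraCounts <- function(seq, normalize = FALSE) {
  s <- asRnaString(seq)
  n <- length(s)
  if (n < 4L) {
    warning("sequence shorter than 4 nt: all tetranucleotide counts are zero")
    return(setNames(numeric(256L), tetranucleotides()))
  }
  # windows containing ambiguity codes match none of the 256 words and are
  # thereby skipped, which is the intended handling
  counts <- Biostrings::oligonucleotideFrequency(s, width = 4L, step = 1L)
  out <- setNames(as.numeric(counts), names(counts))[tetranucleotides()]
  if (normalize) out <- out / max(n - 3L, 1L)
  out
}

#' Scan a sequence with a PSSM
#'
#' For every window offset i in 0..(n - m), the score is the sum over
#' k = 1..m of the matrix cell for the base at window position k. Windows
#' containing a non-ACGU base get score \code{NA} and are excluded from
#' top-k selection downstream. Matrix cells are used as stored
#' (log-odds scoring is the default produced by \code{\link{pssmFromSites}};
#' probability matrices can be converted with \code{\link{toLogOdds}}).
#'
#' @param seq a single RNA string (or \code{RNAString(Set)}).
#' @param pssm a \linkS4class{Pssm}.
#' @return data.frame with columns \code{offset} (0-based window start) and
#'   \code{score}; \code{n - m + 1} rows, or zero rows (with a warning) when
#'   the sequence is shorter than the motif.
#' @export
scanPssm <- function(seq, pssm) {
  stopifnot(is(pssm, "Pssm"))
  s <- asRnaString(seq)
  n <- length(s)
  m <- motifLength(pssm)
  if (n < m) {
    warning("sequence shorter than motif: no windows to score")
    return(data.frame(offset = integer(0), score = numeric(0)))
  }
  baseIdx <- match(strsplit(as.character(s), "")[[1]], RNA_BASES)  # NA for non-ACGU
  nw <- n - m + 1L
  v <- pssmMatrix(pssm)
  scores <- numeric(nw)
  ok <- rep(TRUE, nw)
  for (k in seq_len(m)) {
    bi <- baseIdx[k:(k + nw - 1L)]
    miss <- is.na(bi)
    ok <- ok & !miss
    bi[miss] <- 1L
    scores <- scores + v[bi + (k - 1L) * 4L]
  }
  scores[!ok] <- NA_real_
  data.frame(offset = 0:(nw - 1L), score = scores)
}

#' Top motif scores of a sequence
#'
#' Pools the defined window scores of all supplied PSSMs, sorts them in
#' decreasing order and returns the k highest — the representation of a
#' sequence's candidate binding sites by its strongest motif matches. Ties
#' break deterministically by (PSSM order, window offset). When fewer than k
#' defined windows exist, the output is padded by repeating the minimum
#' observed score (0 when no window exists at all), keeping the feature scale
#' bounded for the linear kernel. With \code{perMotif = TRUE} the single best
#' score of each PSSM is taken (in order) before pooling fills the remainder.
#'
#' @param seq a single RNA string (or \code{RNAString(Set)}).
#' @param pssms list of \linkS4class{Pssm}.
#' @param k number of scores to return (default 10).
#' @param perMotif take each motif's best score first instead of pure pooling.
#' @return Numeric vector of length k, non-increasing in the pooled mode.
#' @export
topMotifScores <- function(seq, pssms, k = 10L, perMotif = FALSE) {
  stopifnot(k >= 1L)
  if (is(pssms, "Pssm")) pssms <- list(pssms)
  if (length(pssms) == 0L) {
    warning("no PSSMs supplied: motif scores are all zero")
    return(numeric(k))
  }
  all <- lapply(seq_along(pssms), function(i) {
    ws <- suppressWarnings(scanPssm(seq, pssms[[i]]))
    ws <- ws[!is.na(ws$score), , drop = FALSE]
    if (nrow(ws)) data.frame(pssm = i, offset = ws$offset, score = ws$score)
    else NULL
  })
  all <- do.call(rbind, all)
  if (is.null(all) || nrow(all) == 0L) return(numeric(k))
  ord <- order(-all$score, all$pssm, all$offset)
  pooled <- all$score[ord]
  if (perMotif) {
    best <- vapply(split(all$score, all$pssm), max, 0)
    lead <- unname(best[order(as.integer(names(best)))])
    rest <- sort(pooled, decreasing = TRUE)
    out <- c(lead, rest)[seq_len(min(k, length(lead) + length(rest)))]
  } else {
    out <- pooled[seq_len(min(k, length(pooled)))]
  }
  if (length(out) < k) out <- c(out, rep(min(out), k - length(out)))
  out
}

#' Tetranucleotide accessibility indicators
#'
#' For each of the 256 tetranucleotides t, the indicator is 1 iff some
#' width-4 window of the sequence equal to t lies entirely inside a maximal
#' single-stranded run of length >= 4 of the structure, else 0.
#'
#' @param seq a single RNA string (or \code{RNAString(Set)}).
#' @param dotbracket dot-bracket string of the same length.
#' @return Named 0/1 numeric vector of length 256 (names \code{acc_AAAA}..).
#' @export
accessibilityFeatures <- function(seq, dotbracket) {
  s <- as.character(asRnaString(seq))
  if (nchar(dotbracket) != nchar(s))
    stop("structure/sequence length mismatch (", nchar(dotbracket), " vs ",
         nchar(s), ")")
  tet <- tetranucleotides()
  out <- setNames(numeric(256L), paste0("acc_", tet))
  runs <- accessibleRuns(parsePairing(dotbracket))
  for (i in seq_len(nrow(runs))) {
    sub <- substr(s, runs$start[i], runs$start[i] + runs$length[i] - 1L)
    words <- substring(sub, 1:(nchar(sub) - 3L), 4:nchar(sub))
    words <- words[words %in% tet]   # windows with ambiguity codes are skipped
    out[paste0("acc_", unique(words))] <- 1
  }
  out
}

#' Encode sequences into oli / olimo / olimoss feature matrices
#'
#' Builds the fixed-order feature vector of each sequence under the given
#' schema: \code{oli} is the 256 tetranucleotide counts; \code{olimo}
#' appends the 10 highest PSSM window scores; \code{olimoss} further appends
#' the folding energy, stem density and stem count, then 256 accessibility
#' indicators.
#'
#' @param seqs an \code{RNAStringSet} (or single string / \code{RNAString}).
#' @param schema a \linkS4class{FeatureSchema} or schema name.
#' @param pssms list of \linkS4class{Pssm} (required for olimo / olimoss).
#' @param structures data.frame as from \code{\link{readDotBracket}}
#'   (required for olimoss); matched to sequences by id.
#' @param normalize normalize tetranucleotide counts (see
#'   \code{\link{tetraCounts}}).
#' @param perMotif see \code{\link{topMotifScores}}.
#' @return Numeric matrix, one row per sequence (rownames = ids), columns the
#'   schema's feature names.
#' @examples
#' x <- Biostrings::RNAStringSet(c(s1 = "AUGGCUACGUAG"))
#' dim(encodeFeatures(x, "oli"))
#' @export
encodeFeatures <- function(seqs, schema = "oli", pssms = NULL,
                           structures = NULL, normalize = FALSE,
                           perMotif = FALSE) {
  if (is.character(schema)) schema <- featureSchema(schema)
  if (is.character(seqs) || is(seqs, "RNAString"))
    seqs <- Biostrings::RNAStringSet(setNames(as.character(seqs), "seq"))
  name <- schemaName(schema)
  if (name %in% c("olimo", "olimoss") && (is.null(pssms) || length(pssms) == 0L))
    stop("configuration error: schema '", name, "' requires PSSMs")
  if (name == "olimoss" && is.null(structures))
    stop("configuration error: schema 'olimoss' requires secondary structures")

  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  out <- matrix(0, nrow = length(seqs), ncol = schemaDim(schema),
                dimnames = list(ids, featureNames(schema)))
  if (name == "olimoss") {
    si <- match(ids, structures$id)
    if (anyNA(si))
      stop("configuration error: missing structure for sequence(s): ",
           paste(head(ids[is.na(si)], 3L), collapse = ", "))
  }
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    row <- suppressWarnings(tetraCounts(s, normalize = normalize))
    if (name %in% c("olimo", "olimoss"))
      row <- c(row, suppressWarnings(topMotifScores(s, pssms, k = 10L,
                                                    perMotif = perMotif)))
    if (name == "olimoss") {
      st <- structures[si[i], ]
      sf <- structureFeatures(st$dotbracket, st$energy)
      row <- c(row,
               ifelse(is.na(sf$energy), 0, sf$energy),
               sf$stemDensity, sf$nStems,
               accessibilityFeatures(s, st$dotbracket))
    }
    out[i, ] <- row
  }
  attr(out, "schema") <- schemaName(schema)
  out
}

asRnaString <- function(seq) {
  if (is(seq, "RNAString")) return(seq)
  if (is(seq, "RNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(seq[[1]])
  }
  Biostrings::RNAString(chartr("Tt", "Uu", toupper(as.character(seq))))
}
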