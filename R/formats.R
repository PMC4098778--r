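#' Read RNA sequences from a FASTA file
#'
#' Sequences are canonicalized to the RNA alphabet: lowercase letters are
#' uppercased, internal whitespace is stripped and T is mapped to U, so DNA
#' convention inputs (UCSC / Ensembl 3'UTRs) load unchanged. Record ids are
#' the header up to the first whitespace, in file order. Sequences containing
#' IUPAC ambiguity codes (N, R, Y, ...) are loaded but flagged in
#' \code{mcols(x)$ambiguous}; the encoders skip windows overlapping them.
#'
#' @param path path to a FASTA file.
#' @return An \code{RNAStringSet}; metadata column \code{ambiguous} marks
#'   records with non-ACGU residues.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' as.character(readFasta(f))
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  txt <- toupper(gsub("[[:space:]]+", "", as.character(raw)))
  txt <- chartr("T", "U", txt)
  bad <- grepl("[^ACGUNRYSWKMBDHV-]", txt)
  if (any(bad)) {
    stop("non-IUPAC residue in record(s): ",
         paste(head(names(raw)[bad], 3L), collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(raw))
  out <- Biostrings::RNAStringSet(txt)
  names(out) <- ids
  S4Vectors::mcols(out)$ambiguous <- grepl("[^ACGU]", txt)
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param x an \code{RNAStringSet}.
#' @param path output path.
#' @param width line width for wrapping.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(x, path, width = 70L) {
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read PSSMs from a MEME minimal motif file
#'
#' Parses the MEME minimal interchange format: a \code{MEME version} header,
#' an \code{ALPHABET=} line, and one or more \code{MOTIF} blocks each holding
#' a \code{letter-probability matrix} or \code{log-odds matrix} section with
#' one whitespace-separated row of 4 values per motif position. DNA alphabets
#' are mapped onto RNA (column T becomes U). The matrix kind is recorded in
#' the returned \code{Pssm} objects.
#'
#' @param path path to a MEME minimal file.
#' @return A list of \linkS4class{Pssm} objects, one per MOTIF block, in file
#'   order.
#' @export
readMemeMinimal <- function(path) {
  if (!file.exists(path)) stop("MEME file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  alphaLine <- grep("^\\s*ALPHABET\\s*=", lines, value = TRUE)
  if (length(alphaLine) == 0L)
    stop("MEME minimal parse error: missing ALPHABET= line in ", path)
  alphabet <- strsplit(gsub("^\\s*ALPHABET\\s*=\\s*|\\s+$", "", alphaLine[1]), "")[[1]]
  alphabet[alphabet == "T"] <- "U"
  if (length(alphabet) != 4L || !setequal(alphabet, RNA_BASES))
    stop("MEME minimal parse error: alphabet must be ACGT or ACGU")

  motifStarts <- grep("^MOTIF\\b", lines)
  if (length(motifStarts) == 0L) stop("MEME minimal parse error: no MOTIF block")
  pssms <- vector("list", length(motifStarts))
  bounds <- c(motifStarts, length(lines) + 1L)
  for (i in seq_along(motifStarts)) {
    block <- lines[motifStarts[i]:(bounds[i + 1L] - 1L)]
    id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    if (is.na(id) || !nzchar(id))
      stop("MEME minimal parse error: MOTIF line without identifier")
    hdr <- grep("(letter-probability|log-odds) matrix", block)
    if (length(hdr) == 0L)
      stop("MEME minimal parse error: motif '", id, "' has no matrix section")
    kind <- if (grepl("log-odds", block[hdr[1]])) "log-odds" else "probability"
    rows <- character(0)
    for (ln in block[-seq_len(hdr[1])]) {
      if (grepl("^\\s*$", ln) || grepl("^(MOTIF|URL)\\b", ln)) break
      rows <- c(rows, trimws(ln))
    }
    vals <- lapply(strsplit(rows, "\\s+"), as.numeric)
    if (any(lengths(vals) != 4L))
      stop("MEME minimal parse error: motif '", id,
           "' has a matrix row without exactly 4 values")
    m <- t(do.call(cbind, vals))        # positions x bases
    mat <- t(m)                          # bases x positions
    rownames(mat) <- alphabet
    pssms[[i]] <- Pssm(mat[RNA_BASES, , drop = FALSE], motifId = id, kind = kind)
  }
  pssms
}

#' Write PSSMs to a MEME minimal motif file
#'
#' Inverse of \code{\link{readMemeMinimal}}; cells are written with six
#' decimals so that a read/write round trip reproduces them to that
#' precision.
#'
#' @param pssms list of \linkS4class{Pssm} (all the same kind).
#' @param path output path.
#' @param background length-4 background frequencies written to the header.
#' @return Invisibly, \code{path}.
#' @export
writeMemeMinimal <- function(pssms, path, background = rep(0.25, 4)) {
  if (is(pssms, "Pssm")) pssms <- list(pssms)
  kinds <- unique(vapply(pssms, pssmKind, ""))
  if (length(kinds) != 1L) stop("all PSSMs must share one matrix kind")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "Background letter frequencies", paste(
                 sprintf("%s %.6f", RNA_BASES, background), collapse = " "),
               ""), con)
  for (p in pssms) {
    v <- pssmMatrix(p)
    hdr <- if (kinds == "probability")
      sprintf("letter-probability matrix: alength= 4 w= %d", ncol(v))
    else
      sprintf("log-odds matrix: alength= 4 w= %d", ncol(v))
    writeLines(c(sprintf("MOTIF %s", motifId(p)), hdr), con)
    writeLines(apply(v, 2L, function(col) paste(sprintf("%10.6f", col),
                                                collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read dot-bracket secondary structures
#'
#' Reads RNAfold-style output: per record a FASTA-like header line, the
#' sequence line, and the structure line, optionally ending in the predicted
#' minimum free energy in parentheses, e.g. \code{"(((...))) (-1.20)"}.
#' Every structure is checked for balanced, properly nested parentheses and
#' for matching the sequence length.
#'
#' @param path path to a dot-bracket text file.
#' @return data.frame with columns \code{id}, \code{sequence},
#'   \code{dotbracket} and \code{energy} (kcal/mol; \code{NA} when absent).
#' @export
readDotBracket <- function(path) {
  if (!file.exists(path)) stop("dot-bracket file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("dot-bracket parse error: records must be header/sequence/structure triples")
  n <- length(lines) %/% 3L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- lines[3L * i - 2L]
    if (!startsWith(hdr, ">"))
      stop("dot-bracket parse error: expected header at record ", i)
    id <- sub("\\s.*$", "", sub("^>", "", hdr))
    seq <- chartr("Tt", "Uu", toupper(trimws(lines[3L * i - 1L])))
    sline <- trimws(lines[3L * i])
    em <- regmatches(sline, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", sline))
    energy <- NA_real_
    db <- sline
    if (length(em) == 1L && grepl("[0-9]", em)) {
      energy <- as.numeric(gsub("[() \t]", "", em))
      db <- trimws(sub("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", sline))
    }
    if (grepl("[^.()]", db))
      stop("dot-bracket parse error: invalid character in structure of '", id, "'")
    if (nchar(db) != nchar(seq))
      stop("structure error: structure/sequence length mismatch for '", id, "'")
    parsePairing(db)  # errors if unbalanced
    out[[i]] <- data.frame(id = id, sequence = seq, dotbracket = db,
                           energy = energy, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write dot-bracket secondary structures
#'
#' @param structures data.frame as returned by \code{\link{readDotBracket}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDotBracket <- function(structures, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(structures))) {
    sline <- structures$dotbracket[i]
    if (!is.na(structures$energy[i]))
      sline <- sprintf("%s (%.2f)", sline, structures$energy[i])
    writeLines(c(paste0(">", structures$id[i]), structures$sequence[i], sline), con)
  }
  invisible(path)
}

#' Write a prediction table
#'
#' Tab-separated with a header row (\code{id}, \code{score}, \code{label}),
#' rows in input order.
#'
#' @param predictions data.frame with columns \code{id}, \code{score} (in
#'   \code{[0, 1]}) and \code{label} (+1/-1).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writePredictions <- function(predictions, path) {
  stopifnot(all(c("id", "score", "label") %in% names(predictions)))
  if (nrow(predictions) && (any(predictions$score < 0) || any(predictions$score > 1)))
    stop("prediction scores must lie in [0, 1]")
  write.table(predictions[, c("id", "score", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by \code{\link{writePredictions}}
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{id}, \code{score}, \code{label}.
#' @export
readPredictions <- function(path) {
  read.table(path, sep = "\t", header = TRUE, colClasses =
               c(id = "character", score = "numeric", label = "integer"))
}

#' Write / read a dataset manifest (id, label TSV)
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeManifest <- function(dataset, path) {
  write.table(data.frame(id = names(sequences(dataset)),
                         label = dataset@labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @return For \code{readManifest}, a data.frame with columns \code{id} and
#'   \code{label}.
#' @export
readManifest <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = c(id = "character", label = "integer"))
}

#' Export a feature matrix as TSV
#'
#' Rows are sequence ids, columns the schema's feature names.
#'
#' @param x numeric feature matrix with rownames and colnames.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
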