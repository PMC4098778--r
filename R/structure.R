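#' Parse a dot-bracket string into a pairing table
#'
#' Stack-based matching of a pseudoknot-free structure over \code{.}, \code{(}
#' and \code{)}. Other bracket types are rejected: minimum-free-energy output
#' of standard folders is nested.
#'
#' @param dotbracket a dot-bracket string.
#' @return Integer vector of length \code{nchar(dotbracket)}: entry i is the
#'   1-based index of the partner of position i, or \code{NA} if unpaired.
#' @examples
#' parsePairing("(())")   # 4 3 2 1
#' parsePairing("(.)")    # 3 NA 1
#' @export
parsePairing <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  if (length(ch) && any(!ch %in% c(".", "(", ")")))
    stop("structure error: only '.', '(' and ')' are allowed")
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L)
        stop("structure error: unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack))
    stop("structure error: unmatched '(' at position ", stack[1])
  partner
}

#' Number of stems in a structure
#'
#' A stem is a maximal helix: a maximal run of consecutive base pairs
#' \code{(i, j), (i+1, j-1), ...}. Bulges and interior loops break stems.
#'
#' @param pairing integer pairing table from \code{\link{parsePairing}} (a
#'   dot-bracket string is also accepted).
#' @return Integer stem count.
#' @examples
#' countStems("((((....))))")      # 1
#' countStems("((..((...))..))")   # 2
#' @export
countStems <- function(pairing) {
  p <- asPairing(pairing)
  n <- length(p)
  if (n == 0L) return(0L)
  stems <- 0L
  for (i in seq_len(n)) {
    j <- p[i]
    if (is.na(j) || j <= i) next      # consider each pair once, from its 5' side
    # pair (i, j) starts a stem unless (i-1, j+1) is also a pair
    if (i == 1L || is.na(p[i - 1L]) || p[i - 1L] != j + 1L) stems <- stems + 1L
  }
  stems
}

#' Stem density of a structure
#'
#' The proportion of paired positions: (number of paired bases) / n.
#'
#' @inheritParams countStems
#' @return Numeric in \code{[0, 1]}.
#' @export
stemDensity <- function(pairing) {
  p <- asPairing(pairing)
  if (length(p) == 0L) stop("stem density undefined for an empty structure")
  sum(!is.na(p)) / length(p)
}

#' Maximal single-stranded runs of length >= 4
#'
#' Accessibility in this method's sense: a region is accessible when at least
#' four consecutive nucleotides are unpaired. Returns all maximal such runs,
#' left to right.
#'
#' @inheritParams countStems
#' @param minLength minimum run length (default 4).
#' @return data.frame with columns \code{start} (1-based) and \code{length}.
#' @examples
#' accessibleRuns(".....(())....")   # runs at 1 (len 5) and 10 (len 4)
#' @export
accessibleRuns <- function(pairing, minLength = 4L) {
  p <- asPairing(pairing)
  if (length(p) == 0L)
    return(data.frame(start = integer(0), length = integer(0)))
  r <- rle(is.na(p))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLength
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' The four secondary-structure features of one sequence
#'
#' @param dotbracket dot-bracket string.
#' @param energy predicted folding energy in kcal/mol (taken from the input,
#'   never recomputed).
#' @return List with \code{energy}, \code{stemDensity}, \code{nStems} and
#'   \code{accessibleRuns}.
#' @export
structureFeatures <- function(dotbracket, energy = NA_real_) {
  p <- parsePairing(dotbracket)
  list(energy = as.numeric(energy),
       stemDensity = if (length(p)) stemDensity(p) else NA_real_,
       nStems = countStems(p),
       accessibleRuns = accessibleRuns(p))
}

asPairing <- function(pairing) {
  if (is.character(pairing)) parsePairing(pairing) else as.integer(pairing)
}

#' Fold a sequence with an external structure-prediction program
#'
#' Thin adapter around an RNAfold-compatible executable: the program receives
#' FASTA on standard input and must print the sequence, then a line with the
#' dot-bracket structure followed by the energy in parentheses. No folding
#' logic lives in this package; when no program is available, precomputed
#' structures read with \code{\link{readDotBracket}} serve instead.
#'
#' @param seq an \code{RNAStringSet} of length 1, or a single RNA string.
#' @param program name or path of the folding executable (default
#'   \code{"RNAfold"}).
#' @param args extra command-line arguments (default \code{"--noPS"} is
#'   passed only to programs named RNAfold).
#' @return One-row data.frame as from \code{\link{readDotBracket}}.
#' @export
foldExternal <- function(seq, program = "RNAfold", args = NULL) {
  if (is.character(seq)) seq <- Biostrings::RNAStringSet(setNames(seq, "seq"))
  stopifnot(length(seq) == 1L)
  exe <- Sys.which(program)
  if (!nzchar(exe))
    stop("environment error: folding program '", program, "' not found; ",
         "supply precomputed structures via readDotBracket() instead")
  if (is.null(args) && grepl("RNAfold$", program)) args <- "--noPS"
  fa <- tempfile(fileext = ".fa"); on.exit(unlink(fa))
  writeFasta(seq, fa)
  out <- suppressWarnings(system2(exe, args, stdout = TRUE,
                                  stdin = fa))
  id <- names(seq)[1]
  sline <- grep("^[.()]+(\\s*\\(\\s*-?[0-9.]+\\s*\\))?$", trimws(out), value = TRUE)
  if (length(sline) == 0L)
    stop("adapter error: no dot-bracket line in output of '", program, "'")
  tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
  writeLines(c(paste0(">", id), as.character(seq[[1]]), sline[1]), tmp)
  readDotBracket(tmp)
}
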