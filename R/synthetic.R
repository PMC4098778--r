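#' Synthetic planted-motif benchmark dataset
#'
#' Generates a desk-scale labeled dataset with the statistical structure the
#' predictor assumes: negatives are i.i.d. sequences from a background base
#' composition; positives are background sequences into which one instance
#' of a binding motif is planted at a uniformly random position (with
#' independent per-base mutation), for a fraction \code{plantProb} of the
#' positive set. Defaults emulate a PUM2-like PAR-CLIP experiment: the
#' UGUAUAUA consensus family planted into 3'UTR-length sequences of 200-1500
#' nt. With \code{structureMode = "hairpin-toy"} each sequence also gets a
#' schematic dot-bracket structure of hairpins dropped onto unpaired
#' background, placed so that a planted motif sits in a single-stranded run
#' of at least its own length — enough to give accessibility features
#' signal, without any thermodynamics.
#'
#' Bound 3'UTRs in CLIP-style experiments typically carry several binding
#' sites, which is also what motivates summarising a sequence by its ten
#' best motif scores. A positive that carries the motif therefore receives
#' \code{1 + Poisson(meanExtraSites)} non-overlapping instances, each
#' independently mutated.
#'
#' @param nPos,nNeg number of positive / negative sequences.
#' @param lengthRange integer range of sequence lengths.
#' @param motif consensus string planted into positives.
#' @param plantProb fraction of positives carrying at least one motif
#'   instance.
#' @param meanExtraSites Poisson mean of additional instances beyond the
#'   first (default 1.5, about 2.5 sites per bound sequence on average).
#' @param mutationRate per-base mutation probability of planted instances.
#' @param background length-4 base composition (A, C, G, U), summing to 1.
#' @param structureMode \code{"none"} or \code{"hairpin-toy"}.
#' @param protein RBP name for the dataset.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return List with \code{dataset} (a \linkS4class{LabeledDataset};
#'   positives first, ids \code{pos_1..}, \code{neg_1..}), \code{sites}
#'   (data.frame of planted instances: id, start, site string as planted),
#'   and \code{structures} (data.frame as from \code{\link{readDotBracket}},
#'   or \code{NULL}).
#' @examples
#' d <- generateDataset(nPos = 5, nNeg = 5, lengthRange = c(50, 80), seed = 1)
#' d$dataset
#' @export
generateDataset <- function(nPos = 400L, nNeg = 800L,
                            lengthRange = c(200L, 1500L),
                            motif = "UGUAUAUA", plantProb = 0.9,
                            meanExtraSites = 1.5, mutationRate = 0.05,
                            background = c(0.25, 0.25, 0.25, 0.25),
                            structureMode = c("none", "hairpin-toy"),
                            protein = "synthRBP", seed = 1L) {
  structureMode <- match.arg(structureMode)
  stopifnot(nPos >= 1L, nNeg >= 1L, plantProb >= 0, plantProb <= 1,
            mutationRate >= 0, mutationRate <= 1,
            abs(sum(background) - 1) < 1e-8, all(background >= 0))
  motif <- chartr("Tt", "Uu", toupper(motif))
  m <- nchar(motif)
  if (m > lengthRange[1])
    stop("spec error: motif longer than the minimum sequence length")
  motifCh <- strsplit(motif, "")[[1]]

  withSeed(seed, {
    randSeq <- function(n) paste(sample(RNA_BASES, n, replace = TRUE,
                                        prob = background), collapse = "")
    lens <- sample(lengthRange[1]:lengthRange[2], nPos + nNeg, replace = TRUE)
    seqs <- vapply(lens, randSeq, "")
    ids <- c(sprintf("pos_%d", seq_len(nPos)), sprintf("neg_%d", seq_len(nNeg)))
    labels <- c(rep(1L, nPos), rep(-1L, nNeg))

    siteRows <- list()
    planted <- runif(nPos) < plantProb
    for (i in which(planted)) {
      n <- lens[i]
      nInst <- 1L + stats::rpois(1L, meanExtraSites)
      taken <- rep(FALSE, n)
      for (inst in seq_len(nInst)) {
        # non-overlapping placement; give up quietly when the sequence is full
        start <- NA_integer_
        for (try in 1:25) {
          cand <- sample.int(n - m + 1L, 1L)
          if (!any(taken[cand:(cand + m - 1L)])) { start <- cand; break }
        }
        if (is.na(start)) break
        taken[start:(start + m - 1L)] <- TRUE
        instCh <- motifCh
        mut <- runif(m) < mutationRate
        for (k in which(mut))
          instCh[k] <- sample(setdiff(RNA_BASES, instCh[k]), 1L)
        instStr <- paste(instCh, collapse = "")
        substr(seqs[i], start, start + m - 1L) <- instStr
        siteRows[[length(siteRows) + 1L]] <-
          data.frame(id = ids[i], start = start, site = instStr,
                     stringsAsFactors = FALSE)
      }
    }
    sites <- if (length(siteRows)) do.call(rbind, siteRows) else NULL

    structures <- NULL
    if (structureMode == "hairpin-toy") {
      structures <- do.call(rbind, lapply(seq_along(seqs), function(i) {
        n <- lens[i]
        keepFree <- if (labels[i] == 1L && !is.null(sites) &&
                        ids[i] %in% sites$id) {
          st <- sites$start[sites$id == ids[i]]
          cbind(st, st + m - 1L)
        } else NULL
        db <- toyHairpinStructure(n, keepFree)
        data.frame(id = ids[i], sequence = seqs[i], dotbracket = db,
                   # toy energy: a fixed stabilization per paired base
                   energy = -0.5 * sum(strsplit(db, "")[[1]] != "."),
                   stringsAsFactors = FALSE)
      }))
    }

    ss <- Biostrings::RNAStringSet(setNames(seqs, ids))
    list(dataset = LabeledDataset(ss, labels, protein = protein),
         sites = sites, structures = structures)
  })
}

# Schematic structure: scatter hairpins "((((....))))"-style (random stem
# 3..6, loop 4) onto an unpaired background, avoiding the protected regions
# (a 2-column matrix of 1-based start/end pairs).
toyHairpinStructure <- function(n, keepFree = NULL) {
  db <- rep(".", n)
  nHairpins <- max(1L, n %/% 60L)
  occupied <- rep(FALSE, n)
  if (!is.null(keepFree)) {
    keepFree <- matrix(keepFree, ncol = 2L)
    for (r in seq_len(nrow(keepFree)))
      occupied[max(1L, keepFree[r, 1] - 1L):min(n, keepFree[r, 2] + 1L)] <- TRUE
  }
  for (h in seq_len(nHairpins)) {
    stem <- sample(3:6, 1L)
    width <- 2L * stem + 4L
    if (n < width) break
    for (try in 1:20) {
      at <- sample.int(n - width + 1L, 1L)
      span <- at:(at + width - 1L)
      if (!any(occupied[span])) {
        db[at:(at + stem - 1L)] <- "("
        db[(at + stem + 4L):(at + width - 1L)] <- ")"
        occupied[span] <- TRUE
        break
      }
    }
  }
  paste(db, collapse = "")
}

#' Build a PSSM from aligned binding sites
#'
#' Position-wise base frequencies with pseudocounts over a set of
#' equal-length aligned sites, optionally converted to log-odds against a
#' background composition. This is the in-package stand-in for de novo motif
#' discovery when benchmarking: in cross-validated runs it is applied to the
#' planted sites of the training-fold positives only.
#'
#' @param sites character vector of equal-length site strings.
#' @param pseudocount added per base and position (default 0.5).
#' @param background length-4 background composition (A, C, G, U).
#' @param kind \code{"log-odds"} (default; base-2 log of probability over
#'   background) or \code{"probability"}.
#' @param motifId motif identifier.
#' @return A \linkS4class{Pssm}.
#' @examples
#' pssmFromSites(c("UGUA", "UGUA", "UGAA"))
#' @export
pssmFromSites <- function(sites, pseudocount = 0.5,
                          background = rep(0.25, 4),
                          kind = c("log-odds", "probability"),
                          motifId = "sites") {
  kind <- match.arg(kind)
  stopifnot(length(sites) >= 1L)
  sites <- chartr("Tt", "Uu", toupper(sites))
  m <- unique(nchar(sites))
  if (length(m) != 1L) stop("all sites must have equal length")
  mat <- matrix(0, 4L, m, dimnames = list(RNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(sites, ""))
  for (k in seq_len(m)) {
    tab <- table(factor(chars[, k], levels = RNA_BASES))
    mat[, k] <- as.numeric(tab)
  }
  prob <- sweep(mat + pseudocount, 2L, colSums(mat + pseudocount), "/")
  if (kind == "probability")
    return(Pssm(prob, motifId = motifId, kind = "probability"))
  lo <- log2(prob / background)
  Pssm(lo, motifId = motifId, kind = "log-odds")
}

#' PSSM provider over known planted sites
#'
#' Returns a provider function for \code{\link{runCV}}: given the positive
#' training sequences of a fold, it builds one PSSM from the planted sites
#' of exactly those sequences (ids looked up in \code{sites}), so no test
#' sequence ever informs motif construction.
#'
#' @param sites data.frame with columns \code{id} and \code{site} (as
#'   returned by \code{\link{generateDataset}}).
#' @param pseudocount,background passed to \code{\link{pssmFromSites}}.
#' @return Function mapping an \code{RNAStringSet} to a list of one
#'   \linkS4class{Pssm}.
#' @export
pssmProviderFromSites <- function(sites, pseudocount = 0.5,
                                  background = rep(0.25, 4)) {
  force(sites); force(pseudocount); force(background)
  function(posTrainSeqs) {
    s <- sites$site[sites$id %in% names(posTrainSeqs)]
    if (length(s) == 0L)
      stop("no planted sites among the supplied training positives")
    list(pssmFromSites(s, pseudocount = pseudocount, background = background))
  }
}
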