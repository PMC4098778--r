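#' Confusion counts at a decision threshold
#'
#' @param truth vector of +1 / -1 true labels.
#' @param predicted vector of +1 / -1 predicted labels.
#' @return Named list with \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
confusionCounts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(tp = sum(truth == 1 & predicted == 1),
       fp = sum(truth == -1 & predicted == 1),
       tn = sum(truth == -1 & predicted == -1),
       fn = sum(truth == 1 & predicted == -1))
}

#' Matthews correlation coefficient
#'
#' Standard MCC; a zero denominator (any empty margin) yields 0, the usual
#' convention that keeps grid search total.
#'
#' @param counts list with \code{tp}, \code{fp}, \code{tn}, \code{fn} (as
#'   from \code{\link{confusionCounts}}).
#' @return Numeric in \code{[-1, 1]}.
#' @export
mcc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a uniformly random positive outscores a
#' uniformly random negative, with ties counted 1/2 (computed via midranks).
#'
#' @param scores numeric prediction scores.
#' @param labels vector of +1 / -1 true labels.
#' @return Numeric in \code{[0, 1]}.
#' @export
aucScore <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision at a score threshold
#'
#' \code{tp / (tp + fp)} with predictions positive at \code{score >=
#' threshold}. When nothing is predicted positive the precision is defined
#' as 0 and the result carries attribute \code{noPositivePredictions = TRUE}.
#'
#' @param scores numeric prediction scores in \code{[0, 1]}.
#' @param labels vector of +1 / -1 true labels.
#' @param threshold decision threshold (default 0.5).
#' @return Numeric precision.
#' @export
precisionAt <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  predPos <- scores >= threshold
  if (!any(predPos)) {
    out <- 0
    attr(out, "noPositivePredictions") <- TRUE
    return(out)
  }
  sum(predPos & labels == 1) / sum(predPos)
}

#' ROC and precision-recall curves
#'
#' Threshold sweep over the unique scores (plus sentinels), predictions
#' positive at \code{score >= t}. The trapezoidal area under the returned
#' ROC equals \code{\link{aucScore}} exactly (ties handled by midranks there
#' and by shared thresholds here).
#'
#' @param scores numeric prediction scores.
#' @param labels vector of +1 / -1 true labels.
#' @return List of two data.frames: \code{roc} (\code{threshold},
#'   \code{fpr}, \code{tpr}) and \code{pr} (\code{threshold}, \code{recall},
#'   \code{precision}).
#' @export
curves <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == -1)
  if (n1 == 0L || n0 == 0L) stop("curves undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cumTp <- cumsum(y == 1); cumFp <- cumsum(y == -1)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct score
  thr <- s[last]
  tp <- cumTp[last]; fp <- cumFp[last]
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fp / n0),
                    tpr = c(0, tp / n1))
  pr <- data.frame(threshold = thr, recall = tp / n1,
                   precision = tp / (tp + fp))
  list(roc = roc, pr = pr)
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided Wilcoxon signed-rank test on paired per-protein performance
#' values (typically AUCs); zero differences are dropped per the standard
#' convention.
#'
#' @param a,b paired numeric vectors (one entry per protein), equal length.
#' @param alpha significance level (default 0.01).
#' @return List with \code{statistic}, \code{p}, \code{significant}.
#' @export
compareMethods <- function(a, b, alpha = 0.01) {
  stopifnot(length(a) == length(b), length(a) >= 5L)
  d <- b - a
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = NA_real_, p = 1, significant = FALSE))
  ht <- suppressWarnings(wilcox.test(d, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha)
}

#' Information-gain ranking of features
#'
#' Each feature is discretized by its best single binary split: thresholds
#' are the midpoints of consecutive distinct sorted values, and the split
#' maximizing the information gain \code{H(label) - H(label | split)} (base-2
#' entropy) is kept. Features are returned sorted by decreasing gain, ties
#' broken by name. Constant features have gain 0.
#'
#' @param x numeric feature matrix (columns named).
#' @param y vector of +1 / -1 labels.
#' @return data.frame with columns \code{feature}, \code{gain} (bits) and
#'   \code{threshold}, in decreasing gain order.
#' @export
informationGainRanking <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  y1 <- y == 1
  n <- length(y)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h0 <- ent(c(mean(y1), 1 - mean(y1)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]; ys <- y1[ord]
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0L)
      return(c(gain = 0, threshold = NA_real_))
    cumPos <- cumsum(ys)
    nl <- distinct
    posl <- cumPos[distinct]
    nr <- n - nl
    posr <- sum(ys) - posl
    hl <- vapply(seq_along(nl), function(i)
      ent(c(posl[i] / nl[i], 1 - posl[i] / nl[i])), 0)
    hr <- vapply(seq_along(nr), function(i)
      ent(c(posr[i] / nr[i], 1 - posr[i] / nr[i])), 0)
    gains <- h0 - (nl / n * hl + nr / n * hr)
    k <- which.max(gains)
    c(gain = gains[k], threshold = (vs[distinct[k]] + vs[distinct[k] + 1L]) / 2)
  })
  out <- data.frame(feature = colnames(x),
                    gain = vapply(res, `[[`, 0, "gain"),
                    threshold = vapply(res, `[[`, 0, "threshold"),
                    stringsAsFactors = FALSE)
  out[order(-out$gain, out$feature), , drop = FALSE]
}

#' Leakage-safe stratified k-fold cross-validated evaluation
#'
#' The full training protocol inside every fold: motif matrices are rebuilt
#' from the fold's positive training sequences only (via
#' \code{pssmProvider}), SMOTE balances the training fold only, the cost C is
#' grid-searched by inner-CV MCC, and the untouched test fold is scored with
#' the calibrated model. The report carries a per-fold audit of which
#' sequence ids contributed to PSSM construction and SMOTE, so leakage is
#' checkable after the fact.
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param schema schema name or \linkS4class{FeatureSchema}.
#' @param pssmProvider \code{NULL} (oli) or a function taking the
#'   \code{RNAStringSet} of a fold's positive training sequences and
#'   returning a list of \linkS4class{Pssm} (see
#'   \code{\link{pssmProviderFromSites}}).
#' @param structures data.frame of dot-bracket structures (olimoss only).
#' @param folds number of folds (default 10).
#' @param cValues,innerFolds,tolerance passed to \code{\link{trainModel}}.
#' @param smoteK,targetRatio passed to \code{\link{balanceTrainingFold}}.
#' @param normalize normalize tetranucleotide counts.
#' @param permuteLabels permute the labels before fold assignment (null
#'   benchmark).
#' @param seed integer seed for fold assignment, SMOTE and any permutation.
#' @return A \linkS4class{CvReport}.
#' @export
runCV <- function(dataset, schema = "oli", pssmProvider = NULL,
                  structures = NULL, folds = 10L,
                  cValues = defaultCostGrid(), innerFolds = 5L,
                  smoteK = 5L, targetRatio = 1, normalize = FALSE,
                  permuteLabels = FALSE, seed = 1L, tolerance = 0.001) {
  if (is.character(schema)) schema <- featureSchema(schema)
  name <- schemaName(schema)
  seqs <- sequences(dataset)
  ids <- names(seqs)
  y <- dataset@labels
  if (sum(y == 1) < folds || sum(y == -1) < folds)
    stop("need at least one sequence of each class per fold")
  if (name %in% c("olimo", "olimoss") && is.null(pssmProvider))
    stop("configuration error: schema '", name, "' requires a pssmProvider")

  withSeed(seed, {
    if (permuteLabels) y <- sample(y)
    foldId <- stratifiedFolds(y, folds)
  })

  # tetranucleotide (and structure) blocks do not depend on the fold
  tetra <- encodeFeatures(seqs, "oli", normalize = normalize)
  foldRows <- vector("list", folds)
  scoreRows <- vector("list", folds)
  audit <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- foldId == f
    train <- !test
    pssms <- NULL
    pssmIds <- character(0)
    if (!is.null(pssmProvider) && name %in% c("olimo", "olimoss")) {
      posTrain <- seqs[train & y == 1]
      pssms <- pssmProvider(posTrain)
      pssmIds <- names(posTrain)
    }
    x <- buildSchemaMatrix(tetra, seqs, schema, pssms, structures)
    bal <- balanceTrainingFold(x[train, , drop = FALSE], y[train],
                               targetRatio = targetRatio, k = smoteK,
                               seed = seed + f)
    model <- trainModel(bal$x, bal$y, schema = schema, cValues = cValues,
                        innerFolds = innerFolds, seed = seed + f,
                        protein = datasetProtein(dataset),
                        tolerance = tolerance)
    pred <- predict(model, x[test, , drop = FALSE])
    cc <- confusionCounts(y[test], pred$label)
    foldRows[[f]] <- data.frame(fold = f, n_test = sum(test),
                                tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                                auc = aucScore(pred$score, y[test]),
                                precision = as.numeric(
                                  precisionAt(pred$score, y[test])),
                                mcc = mcc(cc), C = modelCost(model))
    scoreRows[[f]] <- data.frame(id = ids[test], fold = f, label = y[test],
                                 score = pred$score, predicted = pred$label,
                                 stringsAsFactors = FALSE)
    audit[[f]] <- list(testIds = ids[test], pssmIds = pssmIds,
                       smoteIds = ids[train])
  }
  new("CvReport", protein = datasetProtein(dataset), schemaName = name,
      folds = do.call(rbind, foldRows), scores = do.call(rbind, scoreRows),
      meta = list(seed = seed, foldId = foldId, permuted = permuteLabels,
                  audit = audit))
}

# Assemble the full schema matrix from the precomputed tetra block plus
# fold-dependent motif and static structure blocks.
buildSchemaMatrix <- function(tetra, seqs, schema, pssms, structures) {
  name <- schemaName(schema)
  if (name == "oli") return(tetra)
  motif <- t(vapply(seq_along(seqs), function(i)
    suppressWarnings(topMotifScores(seqs[[i]], pssms, k = 10L)),
    numeric(10L)))
  x <- cbind(tetra, motif)
  if (name == "olimoss") {
    si <- match(names(seqs), structures$id)
    if (anyNA(si)) stop("missing structure for sequence(s): ",
                        paste(head(names(seqs)[is.na(si)], 3L), collapse = ", "))
    sblock <- t(vapply(seq_along(seqs), function(i) {
      st <- structures[si[i], ]
      sf <- structureFeatures(st$dotbracket, st$energy)
      c(ifelse(is.na(sf$energy), 0, sf$energy), sf$stemDensity, sf$nStems,
        accessibilityFeatures(seqs[[i]], st$dotbracket))
    }, numeric(259L)))
    x <- cbind(x, sblock)
  }
  colnames(x) <- featureNames(schema)
  rownames(x) <- names(seqs)
  x
}

#' Check a CvReport for train/test leakage
#'
#' Verifies, from the report's per-fold audit, that no test-fold sequence id
#' contributed to PSSM construction or to the SMOTE pool of its own fold,
#' and that every record was scored exactly once out of fold.
#'
#' @param report a \linkS4class{CvReport}.
#' @return \code{TRUE} invisibly; errors with a protocol violation message
#'   otherwise.
#' @export
assertNoLeakage <- function(report) {
  audit <- report@meta$audit
  for (a in audit) {
    if (length(intersect(a$testIds, a$pssmIds)))
      stop("protocol error: test id used for PSSM construction")
    if (length(intersect(a$testIds, a$smoteIds)))
      stop("protocol error: test id present in the SMOTE training pool")
  }
  ids <- report@scores$id
  if (anyDuplicated(ids))
    stop("protocol error: a record was scored in more than one test fold")
  invisible(TRUE)
}

#' Confidence interval of the AUC under negative-set resampling
#'
#' Repeats the full cross-validated evaluation with the negative class
#' exchanged: the negative pool is split into \code{draws} disjoint sets of
#' \code{drawSize} sequences (sampled without replacement per draw, with a
#' warning, when the pool is too small for disjoint draws), and a Student-t
#' confidence interval at level \code{1 - alpha} is formed over the per-draw
#' mean AUCs.
#'
#' @param positives \code{RNAStringSet} of bound sequences.
#' @param negativePool \code{RNAStringSet} of candidate unbound sequences.
#' @param drawSize negatives per draw.
#' @param draws number of draws (default 10).
#' @param alpha significance level of the interval (default 0.01).
#' @param protein RBP name.
#' @param seed integer seed.
#' @param ... passed to \code{\link{runCV}} (schema, folds, grid, ...).
#' @return List with \code{meanAuc}, \code{ci} (length 2), \code{aucs} and
#'   \code{degenerate} (TRUE when draws < 2, where no interval exists).
#' @export
negativeResamplingCI <- function(positives, negativePool, drawSize,
                                 draws = 10L, alpha = 0.01, protein = "RBP",
                                 seed = 1L, ...) {
  nPool <- length(negativePool)
  if (nPool < drawSize) stop("negative pool smaller than drawSize")
  disjoint <- nPool >= draws * drawSize
  if (!disjoint)
    warning("negative pool too small for disjoint draws; ",
            "sampling without replacement per draw")
  drawsIdx <- withSeed(seed, {
    if (disjoint) {
      perm <- sample.int(nPool)
      lapply(seq_len(draws), function(d)
        perm[((d - 1L) * drawSize + 1L):(d * drawSize)])
    } else {
      lapply(seq_len(draws), function(d) sample.int(nPool, drawSize))
    }
  })
  aucs <- vapply(seq_len(draws), function(d) {
    neg <- negativePool[drawsIdx[[d]]]
    ds <- LabeledDataset(c(positives, neg),
                         c(rep(1L, length(positives)), rep(-1L, length(neg))),
                         protein = protein)
    cvMeanAuc(runCV(ds, seed = seed + d, ...))
  }, 0)
  m <- mean(aucs)
  if (draws < 2L)
    return(list(meanAuc = m, ci = c(m, m), aucs = aucs, degenerate = TRUE))
  half <- qt(1 - alpha / 2, draws - 1L) * sd(aucs) / sqrt(draws)
  list(meanAuc = m, ci = c(m - half, m + half), aucs = aucs,
       degenerate = FALSE)
}

#' Cross-protein sensitivity matrix
#'
#' Applies each protein's model to every protein's bound set: entry (i, j)
#' is the fraction of protein j's positives labeled +1 by model i. Diagonal
#' entries are resubstitution sensitivities unless out-of-fold values (from
#' each model's own cross-validation) are supplied, which is the honest
#' choice since resubstitution is optimistic.
#'
#' @param models named list of \linkS4class{TrainedModel} (one per protein).
#' @param positiveFeatures named list of feature matrices, one per protein,
#'   encoding that protein's positives under each model's schema.
#' @param oofSensitivity optional named numeric vector of out-of-fold
#'   sensitivities replacing the diagonal.
#' @return Numeric matrix, rows = models, columns = positive sets.
#' @export
crossRbpSensitivity <- function(models, positiveFeatures,
                                oofSensitivity = NULL) {
  stopifnot(length(models) >= 1L, length(positiveFeatures) >= 1L)
  dims <- vapply(models, function(m) schemaDim(modelSchema(m)), 0L)
  out <- matrix(NA_real_, length(models), length(positiveFeatures),
                dimnames = list(names(models), names(positiveFeatures)))
  for (i in seq_along(models)) {
    for (j in seq_along(positiveFeatures)) {
      x <- positiveFeatures[[j]]
      if (ncol(x) != dims[i])
        stop("contract error: feature matrix '", names(positiveFeatures)[j],
             "' does not match schema of model '", names(models)[i], "'")
      out[i, j] <- mean(predict(models[[i]], x)$label == 1L)
    }
  }
  if (!is.null(oofSensitivity)) {
    common <- intersect(names(oofSensitivity),
                        intersect(rownames(out), colnames(out)))
    for (p in common) out[p, p] <- oofSensitivity[[p]]
  }
  out
}

#' Plain-text summary files of a CvReport
#'
#' Writes the per-fold table and the pooled out-of-fold scores as TSV next
#' to a short text summary.
#'
#' @param report a \linkS4class{CvReport}.
#' @param prefix output path prefix; files \code{<prefix>_folds.tsv},
#'   \code{<prefix>_scores.tsv} and \code{<prefix>_summary.txt} are written.
#' @return Invisibly, the three paths.
#' @export
writeCvReport <- function(report, prefix) {
  fp <- paste0(prefix, "_folds.tsv")
  sp <- paste0(prefix, "_scores.tsv")
  tp <- paste0(prefix, "_summary.txt")
  write.table(report@folds, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report@scores, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    sprintf("protein: %s", report@protein),
    sprintf("schema: %s", report@schemaName),
    sprintf("folds: %d", nrow(report@folds)),
    sprintf("mean AUC: %.4f (sd %.4f)", mean(report@folds$auc),
            sd(report@folds$auc)),
    sprintf("mean precision@0.5: %.4f", mean(report@folds$precision)),
    sprintf("mean MCC: %.4f", mean(report@folds$mcc)),
    sprintf("chosen C per fold: %s", paste(report@folds$C, collapse = " "))),
    tp)
  invisible(c(fp, sp, tp))
}
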