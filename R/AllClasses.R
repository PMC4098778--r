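#' Position-specific scoring matrix
#'
#' A 4 x m matrix of per-base, per-position scores. Rows are the RNA bases
#' A, C, G, U; columns are motif positions 1..m. A window score is the sum,
#' over positions k = 1..m, of the cell for the base observed at that window
#' position (see \code{\link{scanPssm}}). The \code{kind} slot records
#' whether the cells are letter probabilities or log-odds scores; scanning
#' uses the cells as stored.
#'
#' @slot motifId single string identifying the motif.
#' @slot values numeric 4 x m matrix, rownames \code{c("A","C","G","U")}.
#' @slot kind \code{"probability"} or \code{"log-odds"}.
#' @exportClass Pssm
setClass("Pssm", representation(
  motifId = "character",
  values = "matrix",
  kind = "character"
))

setValidity("Pssm", function(object) {
  v <- object@values
  if (length(object@motifId) != 1L) return("motifId must be a single string")
  if (!is.numeric(v) || nrow(v) != 4L) return("values must be a numeric 4 x m matrix")
  if (!identical(rownames(v), RNA_BASES))
    return("values rownames must be A, C, G, U")
  if (ncol(v) < 1L) return("motif length m must be >= 1")
  if (!all(is.finite(v))) return("all PSSM cells must be finite")
  if (!object@kind %in% c("probability", "log-odds"))
    return("kind must be 'probability' or 'log-odds'")
  TRUE
})

#' Construct a Pssm
#'
#' @param values numeric 4 x m matrix with rownames A, C, G, U (a T row name
#'   is accepted and mapped to U).
#' @param motifId motif identifier.
#' @param kind \code{"probability"} or \code{"log-odds"}.
#' @return A \linkS4class{Pssm}.
#' @examples
#' m <- matrix(0.25, 4, 5, dimnames = list(c("A","C","G","U"), NULL))
#' Pssm(m, "uniform", kind = "probability")
#' @export
Pssm <- function(values, motifId = "motif", kind = c("log-odds", "probability")) {
  kind <- match.arg(kind)
  rn <- rownames(values)
  if (!is.null(rn)) {
    rn[rn == "T"] <- "U"
    rownames(values) <- rn
    if (setequal(rn, RNA_BASES)) values <- values[RNA_BASES, , drop = FALSE]
  } else if (nrow(values) == 4L) {
    rownames(values) <- RNA_BASES
  }
  new("Pssm", motifId = as.character(motifId), values = values, kind = kind)
}

#' @describeIn Pssm motif length m (number of columns).
#' @param object,x a \code{Pssm}.
#' @export
motifLength <- function(x) ncol(x@values)

#' @describeIn Pssm motif identifier.
#' @export
motifId <- function(x) x@motifId

#' @describeIn Pssm the score matrix (4 x m, rows A, C, G, U).
#' @export
pssmMatrix <- function(x) x@values

#' @describeIn Pssm matrix kind ("probability" or "log-odds").
#' @export
pssmKind <- function(x) x@kind

setMethod("show", "Pssm", function(object) {
  cat(sprintf("Pssm '%s' (%s), m = %d\n", object@motifId, object@kind,
              ncol(object@values)))
  print(round(object@values, 3))
})

#' Convert a probability PSSM to log-odds
#'
#' Cells become \code{log2((p + pseudocount) / background)} where \code{p} is
#' the letter probability. A \code{Pssm} already of kind log-odds is returned
#' unchanged.
#'
#' @param x a \linkS4class{Pssm}.
#' @param background length-4 background base composition (A, C, G, U).
#' @param pseudocount small value added to probabilities before the log,
#'   preventing minus infinity on zero cells.
#' @return A log-odds \linkS4class{Pssm}.
#' @export
toLogOdds <- function(x, background = rep(0.25, 4), pseudocount = 1e-4) {
  stopifnot(is(x, "Pssm"))
  if (x@kind == "log-odds") return(x)
  stopifnot(length(background) == 4L, all(background > 0))
  v <- log2((x@values + pseudocount) / background)
  Pssm(v, motifId = x@motifId, kind = "log-odds")
}

#' Feature schema for the three encodings
#'
#' Fixes the name, order and dimension of the features of one encoding:
#' \code{oli} (256 tetranucleotide counts, lexicographic AAAA..UUUU over
#' A < C < G < U), \code{olimo} (oli plus \code{motif_top01..motif_top10}),
#' \code{olimoss} (olimo plus \code{energy}, \code{stem_density},
#' \code{n_stems} and 256 accessibility bits \code{acc_AAAA..acc_UUUU}).
#' The order is frozen so that saved models remain valid.
#'
#' @slot name schema name, one of \code{"oli"}, \code{"olimo"}, \code{"olimoss"}.
#' @slot featureNames ordered character vector of feature names.
#' @slot dim integer dimension (256, 266 or 525).
#' @exportClass FeatureSchema
setClass("FeatureSchema", representation(
  name = "character",
  featureNames = "character",
  dim = "integer"
))

setValidity("FeatureSchema", function(object) {
  want <- c(oli = 256L, olimo = 266L, olimoss = 525L)
  if (!object@name %in% names(want)) return("unknown schema name")
  if (object@dim != want[[object@name]])
    return(sprintf("schema '%s' must have dim %d", object@name, want[[object@name]]))
  if (length(object@featureNames) != object@dim) return("featureNames length != dim")
  if (anyDuplicated(object@featureNames)) return("featureNames must be unique")
  if (!identical(object@featureNames[1:256], tetranucleotides()))
    return("first 256 features must be the lexicographic tetranucleotides")
  TRUE
})

#' All 256 tetranucleotides in lexicographic order
#'
#' @return Character vector \code{"AAAA", "AAAC", ..., "UUUU"} (A < C < G < U).
#' @export
tetranucleotides <- function() {
  g <- expand.grid(RNA_BASES, RNA_BASES, RNA_BASES, RNA_BASES,
                   stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  sort(apply(g, 1L, paste0, collapse = ""))
}

#' Construct a FeatureSchema
#'
#' @param name \code{"oli"}, \code{"olimo"} or \code{"olimoss"}.
#' @return A \linkS4class{FeatureSchema}.
#' @examples
#' featureSchema("olimo")
#' @export
featureSchema <- function(name = c("oli", "olimo", "olimoss")) {
  name <- match.arg(name)
  tet <- tetranucleotides()
  fn <- switch(name,
    oli = tet,
    olimo = c(tet, sprintf("motif_top%02d", 1:10)),
    olimoss = c(tet, sprintf("motif_top%02d", 1:10),
                "energy", "stem_density", "n_stems", paste0("acc_", tet)))
  new("FeatureSchema", name = name, featureNames = fn, dim = length(fn))
}

#' @describeIn featureSchema schema name.
#' @param x a \code{FeatureSchema}.
#' @export
schemaName <- function(x) x@name

#' @describeIn featureSchema ordered feature names.
#' @export
featureNames <- function(x) x@featureNames

#' @describeIn featureSchema schema dimension.
#' @export
schemaDim <- function(x) x@dim

setMethod("show", "FeatureSchema", function(object) {
  cat(sprintf("FeatureSchema '%s': %d features (%s, ..., %s)\n", object@name,
              object@dim, object@featureNames[1],
              object@featureNames[object@dim]))
})

#' Labeled RNA sequence dataset for one RBP
#'
#' Binds an \code{RNAStringSet} of 3'UTR (or other RNA) sequences to
#' per-sequence labels +1 (bound by the protein) / -1 (not bound).
#'
#' @slot protein RBP name.
#' @slot sequences \code{Biostrings::RNAStringSet}, uniquely named.
#' @slot labels integer vector of +1 / -1, one per sequence.
#' @exportClass LabeledDataset
setClass("LabeledDataset", representation(
  protein = "character",
  sequences = "RNAStringSet",
  labels = "integer"
))

setValidity("LabeledDataset", function(object) {
  n <- length(object@sequences)
  if (length(object@labels) != n) return("one label per sequence required")
  if (!all(object@labels %in% c(-1L, 1L))) return("labels must be +1 or -1")
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids)) return("sequence ids must be unique")
  TRUE
})

#' Construct a LabeledDataset
#'
#' @param sequences an \code{RNAStringSet} with unique names.
#' @param labels vector of +1 / -1 labels, one per sequence.
#' @param protein RBP name.
#' @return A \linkS4class{LabeledDataset}.
#' @export
LabeledDataset <- function(sequences, labels, protein = "RBP") {
  new("LabeledDataset", protein = as.character(protein),
      sequences = sequences, labels = as.integer(labels))
}

#' @describeIn LabeledDataset the sequences.
#' @param object,x a \code{LabeledDataset}.
#' @export
sequences <- function(x) x@sequences

#' @describeIn LabeledDataset the +1/-1 label vector, named by sequence id.
#' @export
datasetLabels <- function(x) setNames(x@labels, names(x@sequences))

#' @describeIn LabeledDataset the RBP name.
#' @export
datasetProtein <- function(x) x@protein

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset '%s': %d sequences (%d bound, %d unbound)\n",
              object@protein, length(object@sequences),
              sum(object@labels == 1L), sum(object@labels == -1L)))
})

setMethod("length", "LabeledDataset", function(x) length(x@sequences))

#' Trained per-protein linear SVM
#'
#' The decision function is \code{d(x) = w . x + b} in the original feature
#' space; reported scores are \code{plogis(a + c * d(x))} with \code{(a, c)}
#' the Platt calibration fitted on inner cross-validation decision values.
#'
#' @slot protein RBP the model was trained for.
#' @slot schema the \linkS4class{FeatureSchema} of the inputs.
#' @slot weights numeric weight vector, one per feature.
#' @slot bias intercept of the decision function.
#' @slot cost the selected cost parameter C.
#' @slot calibration numeric \code{c(intercept, slope)} of the logistic map.
#' @slot trainingMeta list: seed, grid, inner-fold count, per-C mean MCC.
#' @exportClass TrainedModel
setClass("TrainedModel", representation(
  protein = "character",
  schema = "FeatureSchema",
  weights = "numeric",
  bias = "numeric",
  cost = "numeric",
  calibration = "numeric",
  trainingMeta = "list"
))

setValidity("TrainedModel", function(object) {
  if (length(object@weights) != object@schema@dim)
    return("weights length must equal schema dim")
  if (length(object@bias) != 1L || !is.finite(object@bias))
    return("bias must be a single finite number")
  if (length(object@cost) != 1L || object@cost <= 0) return("C must be a single positive number")
  if (length(object@calibration) != 2L || !all(is.finite(object@calibration)))
    return("calibration must be finite c(intercept, slope)")
  TRUE
})

#' @describeIn TrainedModel the selected cost parameter C.
#' @param object,x a \code{TrainedModel}.
#' @export
modelCost <- function(x) x@cost

#' @describeIn TrainedModel the decision-function weights.
#' @export
modelWeights <- function(x) x@weights

#' @describeIn TrainedModel the decision-function intercept.
#' @export
modelBias <- function(x) x@bias

#' @describeIn TrainedModel the schema the model expects.
#' @export
modelSchema <- function(x) x@schema

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel '%s' (%s, %d features), C = %g\n", object@protein,
              object@schema@name, object@schema@dim, object@cost))
})

#' Cross-validation report
#'
#' @slot protein RBP name.
#' @slot schemaName encoding used.
#' @slot folds data.frame with one row per fold: fold, n_test, tp, fp, tn,
#'   fn, auc, precision, mcc, C.
#' @slot scores data.frame of pooled out-of-fold scores: id, fold, label,
#'   score, predicted.
#' @slot meta list: seed, fold assignment, and per-fold leakage audit
#'   (test ids, ids used for PSSM construction, ids used by SMOTE).
#' @exportClass CvReport
setClass("CvReport", representation(
  protein = "character",
  schemaName = "character",
  folds = "data.frame",
  scores = "data.frame",
  meta = "list"
))

#' @describeIn CvReport per-fold metric table.
#' @param object,x a \code{CvReport}.
#' @export
cvFolds <- function(x) x@folds

#' @describeIn CvReport pooled out-of-fold score table.
#' @export
cvScores <- function(x) x@scores

#' @describeIn CvReport mean out-of-fold AUC across folds.
#' @export
cvMeanAuc <- function(x) mean(x@folds$auc)

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport '%s' (%s): %d folds\n", object@protein,
              object@schemaName, nrow(object@folds)))
  cat(sprintf("  AUC  %.3f +/- %.3f   precision@0.5  %.3f   MCC  %.3f\n",
              mean(object@folds$auc), sd(object@folds$auc),
              mean(object@folds$precision), mean(object@folds$mcc)))
})
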