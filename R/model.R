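#' Default cost grid for the linear-kernel grid search
#'
#' The conventional coarse LIBSVM-style grid 2^-5, 2^-3, ..., 2^15.
#'
#' @return Numeric vector of candidate C values.
#' @export
defaultCostGrid <- function() 2 ^ seq(-5L, 15L, by = 2L)

#' Train a per-protein linear SVM with grid search on C by MCC
#'
#' For every candidate cost C, an inner stratified cross-validation on the
#' (already balanced) training data estimates the mean Matthews correlation
#' coefficient; the C with the highest mean MCC wins, ties going to the
#' smallest C. The final model is refit on all training data at the winning C
#' (linear kernel only). A Platt-style logistic calibration mapping decision
#' values to \code{[0, 1]} scores is fitted on the winning C's inner
#' out-of-fold decision values.
#'
#' @param x numeric feature matrix (rows = samples, columns ordered per the
#'   schema).
#' @param y vector of +1 / -1 labels.
#' @param schema \linkS4class{FeatureSchema} or schema name matching
#'   \code{ncol(x)}.
#' @param cValues candidate C values (default \code{\link{defaultCostGrid}}).
#' @param innerFolds inner CV fold count (default 5).
#' @param seed integer seed controlling inner fold assignment.
#' @param protein RBP name stored in the model.
#' @param tolerance LIBSVM termination tolerance, passed through to the
#'   optimizer.
#' @return A \linkS4class{TrainedModel}.
#' @export
trainModel <- function(x, y, schema = NULL, cValues = defaultCostGrid(),
                       innerFolds = 5L, seed = 1L, protein = "RBP",
                       tolerance = 0.001) {
  x <- as.matrix(x)
  if (is.null(schema))
    schema <- switch(as.character(ncol(x)), "256" = "oli", "266" = "olimo",
                     "525" = "olimoss",
                     stop("cannot infer schema from ", ncol(x), " columns"))
  if (is.character(schema)) schema <- featureSchema(schema)
  if (schemaDim(schema) != ncol(x))
    stop("contract error: feature matrix has ", ncol(x),
         " columns but schema '", schemaName(schema), "' expects ",
         schemaDim(schema))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training error: both classes must be present")
  if (!all(is.finite(x))) {
    bad <- rownames(x)[!apply(is.finite(x), 1L, all)]
    stop("validation error: non-finite feature value in: ",
         paste(head(bad, 3L), collapse = ", "))
  }
  stopifnot(all(cValues > 0), length(cValues) >= 1L)

  foldId <- withSeed(seed, stratifiedFolds(y, innerFolds))
  nf <- max(foldId)
  meanMcc <- numeric(length(cValues))
  dvByC <- vector("list", length(cValues))
  for (ci in seq_along(cValues)) {
    mccs <- numeric(nf)
    dv <- rep(NA_real_, length(y))
    for (f in seq_len(nf)) {
      tr <- foldId != f
      if (length(unique(y[tr])) < 2L) { mccs[f] <- 0; next }
      fit <- svmFit(x[tr, , drop = FALSE], y[tr], cValues[ci], tolerance)
      d <- decisionValues(fit, x[!tr, , drop = FALSE])
      dv[!tr] <- d
      pred <- ifelse(d >= 0, 1L, -1L)
      mccs[f] <- mcc(confusionCounts(y[!tr], pred))
    }
    meanMcc[ci] <- mean(mccs)
    dvByC[[ci]] <- dv
  }
  best <- which(meanMcc == max(meanMcc))
  winner <- best[which.min(cValues[best])]
  C <- cValues[winner]

  fit <- svmFit(x, y, C, tolerance)
  cal <- plattCalibration(dvByC[[winner]], y)
  new("TrainedModel", protein = protein, schema = schema,
      weights = fit$w, bias = fit$b, cost = C, calibration = cal,
      trainingMeta = list(seed = seed, cValues = cValues,
                          innerFolds = innerFolds, meanMcc = meanMcc,
                          formatVersion = MODEL_FORMAT_VERSION))
}

MODEL_FORMAT_VERSION <- "olimoss-model-1"

# Fit a linear SVM and return the decision function in the original feature
# space, oriented so that larger values favour the +1 class.
svmFit <- function(x, y, C, tolerance = 0.001) {
  fy <- factor(y, levels = c("1", "-1"))
  fit <- e1071::svm(x, fy, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  # align to column order of x (SV keeps colnames)
  if (!is.null(colnames(x))) w <- w[colnames(x)]
  b <- -fit$rho
  d <- drop(x %*% w) + b
  if (mean(d[y == 1]) < mean(d[y == -1])) { w <- -w; b <- -b }
  list(w = unname(w), b = b)
}

decisionValues <- function(fit, x) drop(as.matrix(x) %*% fit$w) + fit$b

# Logistic map from decision values to probabilities. Degenerate cases
# (separable folds, missing values) fall back to a unit-slope logistic.
plattCalibration <- function(dv, y) {
  keep <- is.finite(dv)
  dv <- dv[keep]; y01 <- as.integer(y[keep] == 1L)
  if (length(unique(y01)) < 2L || length(dv) < 4L) return(c(0, 1))
  fit <- suppressWarnings(glm(y01 ~ dv, family = binomial()))
  cf <- unname(coef(fit))
  if (any(!is.finite(cf)) || cf[2] <= 0) cf <- c(0, 1)
  # cap extreme slopes from quasi-separable calibration sets
  if (cf[2] > 50) cf <- cf * (50 / cf[2])
  cf
}

# Stratified fold assignment: shuffles within each class, then deals folds
# round-robin. Uses the current RNG state (wrap in withSeed for determinism).
stratifiedFolds <- function(y, k) {
  foldId <- integer(length(y))
  for (lab in unique(y)) {
    idx <- sample(which(y == lab))
    foldId[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldId
}

#' Predict binding scores with a trained model
#'
#' Scores are \code{plogis(a + c * (w . x + b))} with \code{(a, c)} the
#' model's Platt calibration; the predicted label is +1 iff the score is at
#' least 0.5.
#'
#' @param object a \linkS4class{TrainedModel}.
#' @param x feature matrix with the model's schema dimension and column
#'   order.
#' @return data.frame with columns \code{id}, \code{decision}, \code{score}
#'   and \code{label}.
#' @export
setMethod("predict", "TrainedModel", function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != schemaDim(object@schema))
    stop("contract error: feature matrix has ", ncol(x),
         " columns but model expects ", schemaDim(object@schema))
  d <- drop(x %*% object@weights) + object@bias
  score <- plogis(object@calibration[1] + object@calibration[2] * d)
  data.frame(id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
             else rownames(x),
             decision = d, score = score,
             label = ifelse(score >= 0.5, 1L, -1L),
             stringsAsFactors = FALSE)
})

#' Save / load a trained model
#'
#' Versioned flat JSON serialization of all model fields (weights at full
#' precision). Loading verifies the format version and the schema's feature
#' names and errors on mismatch.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param path file path.
#' @return \code{loadModel} returns the \linkS4class{TrainedModel};
#'   \code{saveModel} returns \code{path} invisibly.
#' @export
saveModel <- function(model, path) {
  obj <- list(formatVersion = MODEL_FORMAT_VERSION,
              protein = model@protein,
              schema = schemaName(model@schema),
              featureNames = featureNames(model@schema),
              weights = model@weights, bias = model@bias, C = model@cost,
              calibration = model@calibration,
              trainingMeta = model@trainingMeta)
  # 17 significant digits: exact round trip for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$formatVersion, MODEL_FORMAT_VERSION))
    stop("incompatible model file: format version '", obj$formatVersion,
         "' (expected '", MODEL_FORMAT_VERSION, "')")
  schema <- featureSchema(obj$schema)
  if (!identical(as.character(obj$featureNames), featureNames(schema)))
    stop("incompatible model file: feature names do not match schema '",
         obj$schema, "'")
  new("TrainedModel", protein = obj$protein, schema = schema,
      weights = as.numeric(obj$weights), bias = as.numeric(obj$bias),
      cost = as.numeric(obj$C), calibration = as.numeric(obj$calibration),
      trainingMeta = as.list(obj$trainingMeta))
}
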