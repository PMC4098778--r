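#' SMOTE: synthetic minority oversampling
#'
#' Generates synthetic minority-class samples by interpolation: each
#' synthetic point is \code{x + u * (x_nn - x)} with \code{u ~ Uniform(0,1)},
#' \code{x} a minority sample and \code{x_nn} one of its k nearest minority
#' neighbours under Euclidean distance on the raw feature scale. Parent
#' samples are drawn uniformly with replacement. Interpolated values of
#' binary features are left fractional: balancing operates in the input
#' space, which is also why downstream training is restricted to the linear
#' kernel.
#'
#' @param minority numeric matrix of minority-class feature vectors (rows =
#'   samples).
#' @param nSynthetic number of synthetic samples to generate.
#' @param k number of nearest neighbours considered (default 5, the value of
#'   the original SMOTE formulation); clamped to \code{nrow(minority) - 1}
#'   with a warning when too large.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return Numeric matrix with \code{nSynthetic} rows (0 rows allowed) and
#'   the same columns as \code{minority}.
#' @examples
#' x <- matrix(c(0, 1), ncol = 1)
#' smote(x, nSynthetic = 3, k = 1, seed = 7)   # values in [0, 1]
#' @export
smote <- function(minority, nSynthetic, k = 5L, seed = NULL) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  if (n < 2L) stop("balance error: SMOTE needs at least 2 minority samples")
  if (nSynthetic <= 0L)
    return(minority[integer(0), , drop = FALSE])
  if (k >= n) {
    warning("k >= number of minority samples; clamping k to ", n - 1L)
    k <- n - 1L
  }
  d <- as.matrix(dist(minority))
  diag(d) <- Inf
  # k nearest neighbour indices per sample, ties broken by row order
  # (apply() collapses to a vector when k == 1, hence the explicit matrix)
  nn <- t(matrix(apply(d, 1L, function(r) order(r)[seq_len(k)]), nrow = k))
  withSeed(seed, {
    parents <- sample.int(n, nSynthetic, replace = TRUE)
    whichNn <- sample.int(k, nSynthetic, replace = TRUE)
    u <- runif(nSynthetic)
    x <- minority[parents, , drop = FALSE]
    xnn <- minority[nn[cbind(parents, whichNn)], , drop = FALSE]
    out <- x + u * (xnn - x)
    rownames(out) <- sprintf("synthetic_%d", seq_len(nSynthetic))
    out
  })
}

#' Balance a training fold by oversampling the minority class
#'
#' Augments the minority class (the bound sequences, in the intended use) of
#' a training fold with SMOTE samples until it reaches
#' \code{targetRatio * majority} samples. Synthetic rows are flagged so the
#' cross-validation driver can prove they never reach a test fold. Must only
#' be applied to training folds; the CV driver enforces this.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y vector of +1 / -1 labels.
#' @param targetRatio desired minority/majority ratio after augmentation
#'   (default 1 = parity).
#' @param k SMOTE neighbourhood size.
#' @param seed integer seed.
#' @return List with \code{x} (original rows first, then synthetic),
#'   \code{y}, and logical \code{synthetic} flags.
#' @export
balanceTrainingFold <- function(x, y, targetRatio = 1, k = 5L, seed = NULL) {
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  nPos <- sum(y == 1); nNeg <- sum(y == -1)
  minLab <- if (nPos <= nNeg) 1 else -1
  nMin <- min(nPos, nNeg); nMaj <- max(nPos, nNeg)
  target <- round(targetRatio * nMaj)
  nSyn <- max(0L, as.integer(target - nMin))
  if (nSyn == 0L)
    return(list(x = x, y = y, synthetic = rep(FALSE, length(y))))
  syn <- smote(x[y == minLab, , drop = FALSE], nSynthetic = nSyn, k = k,
               seed = seed)
  list(x = rbind(x, syn),
       y = c(y, rep(minLab, nSyn)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, nSyn)))
}
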