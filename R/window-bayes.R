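# The two-class per-position categorical ("naive Bayes") window model.
#
# All likelihood arithmetic is in log space, so products over window columns
# never underflow (safe far beyond W = 500). Internal fast paths operate on
# integer-coded window matrices (rows = windows, columns = positions).

# counts: 20 x W residue counts per column; 'X' (code 21) is skipped
.columnCounts <- function(M) {
  W <- ncol(M)
  out <- matrix(0L, nrow = 20L, ncol = W)
  for (j in seq_len(W)) {
    v <- M[, j]
    out[, j] <- tabulate(v[v <= 20L], nbins = 20L)
  }
  out
}

.trainWM <- function(posMat, negMat, alpha) {
  W <- ncol(posMat)
  ll <- array(0, dim = c(21L, W, 2L),
              dimnames = list(.AAX, NULL, c("motif", "background")))
  for (k in 1:2) {
    cnt <- .columnCounts(if (k == 1L) posMat else negMat)
    p <- sweep(cnt + alpha, 2L, colSums(cnt) + 20 * alpha, "/")
    ll[1:20, , k] <- log(p)
    ll[21L, , k] <- log(1 / 20)
  }
  npos <- nrow(posMat); nneg <- nrow(negMat)
  methods::new("WindowModel", W = as.integer(W), logLik = ll,
               logPriors = log(c(npos, nneg) / (npos + nneg)),
               alpha = alpha, nTrain = c(as.integer(npos), as.integer(nneg)))
}

# log-likelihood difference (motif - background), including priors
.scoreWMRaw <- function(model, M) {
  d <- numeric(nrow(M))
  ll <- model@logLik
  for (j in seq_len(model@W)) d <- d + ll[M[, j], j, 1L] - ll[M[, j], j, 2L]
  d + model@logPriors[1L] - model@logPriors[2L]
}

.scoreWM <- function(model, M) stats::plogis(.scoreWMRaw(model, M))

.windowsToMatrix <- function(x, W = NULL) {
  x <- .asCharacterSeqs(x)
  if (is.matrix(x)) return(x)
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("windows must all have the same width")
  if (!is.null(W) && w != W)
    stop("window width ", w, " does not match the model width ", W)
  matrix(unlist(lapply(x, .encodeResidues), use.names = FALSE),
         nrow = length(x), ncol = w, byrow = TRUE)
}

#' Train the two-class window model
#'
#' Fits an independent categorical distribution over the 20 residues at every
#' window column, per class, with Laplace smoothing: the probability of
#' residue \eqn{i} at column \eqn{j} is \eqn{(c_{ij} + \alpha) / (N_j + 20\alpha)}
#' where \eqn{N_j} is the column's non-'X' observation count. Class priors
#' come from the training counts.
#'
#' @param motif,background training windows of one common width: character
#'   vectors (or \code{AAStringSet}s); each class needs at least one window
#' @param alpha Laplace pseudocount (default 1; a 20-letter alphabet with a
#'   few hundred samples needs smoothing)
#' @return a \code{\link{WindowModel}}
#' @export
#' @examples
#' m <- trainWindowModel(rep("AA", 3), rep("CC", 3))
#' exp(m@logLik["A", 1, "motif"])   # (3 + 1) / (3 + 20)
trainWindowModel <- function(motif, background, alpha = 1) {
  motif <- .asCharacterSeqs(motif); background <- .asCharacterSeqs(background)
  if (length(motif) == 0L || length(background) == 0L)
    stop("training requires at least one window per class")
  if (alpha <= 0) stop("alpha must be positive")
  posMat <- .windowsToMatrix(motif)
  negMat <- .windowsToMatrix(background, W = ncol(posMat))
  .trainWM(posMat, negMat, alpha)
}

#' Posterior probability of the motif class for a window
#'
#' Combines the class priors with the per-column likelihood products (in log
#' space) and normalizes. An 'X' at any position contributes a flat 1/20
#' likelihood to both classes, so an all-'X' window returns the motif prior.
#'
#' @param model a \code{\link{WindowModel}}
#' @param windows one or more windows of the model's width
#' @return numeric vector of posteriors in [0, 1]
#' @export
windowPosterior <- function(model, windows) {
  stopifnot(methods::is(model, "WindowModel"))
  .scoreWM(model, .windowsToMatrix(windows, W = model@W))
}

# Stratified fold assignment + pooled precision/recall. Callers must seed.
.cvScoreInt <- function(posMat, negMat, folds, alpha) {
  np <- nrow(posMat); nn <- nrow(negMat)
  foldP <- sample(rep_len(seq_len(folds), np))
  foldN <- sample(rep_len(seq_len(folds), nn))
  tp <- fp <- fn <- 0L
  for (k in seq_len(folds)) {
    model <- .trainWM(posMat[foldP != k, , drop = FALSE],
                      negMat[foldN != k, , drop = FALSE], alpha)
    predP <- .scoreWMRaw(model, posMat[foldP == k, , drop = FALSE]) >= 0
    predN <- .scoreWMRaw(model, negMat[foldN == k, , drop = FALSE]) >= 0
    tp <- tp + sum(predP); fn <- fn + sum(!predP); fp <- fp + sum(predN)
  }
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  methods::new("CVScore", precision = precision, recall = recall,
               minPR = min(precision, recall), folds = as.integer(folds))
}

#' Cross-validated window classification score
#'
#' Stratified k-fold cross-validation of the window model: each held-out
#' window is classified as motif when its posterior is >= 0.5, and precision
#' and recall of the motif class are pooled over folds (micro-averaged, which
#' is stable for small classes). The returned \code{minPR},
#' min(precision, recall), is the package's motif score — a chance-level
#' problem scores about 0.5, a perfectly separable one 1.0.
#'
#' @inheritParams trainWindowModel
#' @param folds number of folds (default 5); each class must have at least
#'   \code{folds} windows
#' @param seed integer seed for the fold shuffle (same inputs, alpha, folds
#'   and seed give an identical result)
#' @return a \code{\link{CVScore}}
#' @export
crossValidatedScore <- function(motif, background, folds = 5L, alpha = 1,
                                seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2")
  motif <- .asCharacterSeqs(motif); background <- .asCharacterSeqs(background)
  if (length(motif) < folds || length(background) < folds)
    stop("each class needs at least `folds` windows")
  posMat <- .windowsToMatrix(motif)
  negMat <- .windowsToMatrix(background, W = ncol(posMat))
  set.seed(as.integer(seed))
  .cvScoreInt(posMat, negMat, folds, alpha)
}
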