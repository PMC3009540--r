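#' Configuration for motif boundary determination
#'
#' @param W sliding-window width in residues (default 10)
#' @param accuracyThreshold cross-validated min(precision, recall) below
#'   which the window is judged to have left the motif region (default 0.5,
#'   i.e. chance level)
#' @param folds cross-validation folds (default 5)
#' @param alpha Laplace pseudocount
#' @param maxExtension cap on the extension beyond the anchor, per side
#'   (default 50 residues)
#' @param centerCorrection boundary bias correction in residues (default
#'   half a window, \code{W \%/\% 2 + 1}): a window can stay discriminative
#'   while only its edge overlaps the conserved region, so the outermost
#'   passing window overstates the boundary by up to a window width; the
#'   boundary is placed at the center of that window instead of its outer
#'   edge. Set to 0 to report the raw outer edge.
#' @param seed integer seed (fold shuffles and random background windows)
#' @return validated configuration list
#' @export
boundaryConfig <- function(W = 10L, accuracyThreshold = 0.5, folds = 5L,
                           alpha = 1, maxExtension = 50L,
                           centerCorrection = W %/% 2L + 1L, seed = 1L) {
  if (accuracyThreshold <= 0 || accuracyThreshold >= 1)
    stop("accuracyThreshold must lie in (0, 1)")
  if (folds < 2L) stop("folds must be >= 2")
  if (maxExtension < 0L) stop("maxExtension must be >= 0")
  if (centerCorrection < 0L || centerCorrection >= W)
    stop("centerCorrection must lie in [0, W)")
  list(W = as.integer(W), accuracyThreshold = accuracyThreshold,
       folds = as.integer(folds), alpha = alpha,
       maxExtension = as.integer(maxExtension),
       centerCorrection = as.integer(centerCorrection),
       seed = as.integer(seed))
}

# CV score of the offset's window problem, or NULL when a class has fewer
# than `folds` windows.
.offsetCV <- function(prob, posEnc, seats, spans, o, dir, cfg) {
  posStart <- if (dir == "left") seats - o else seats + spans + o - cfg$W
  pw <- .winMat(posEnc, posStart, cfg$W)
  negMat <- .negWindowMatrix(prob, o, dir, cfg$W)
  if (nrow(pw$mat) < cfg$folds || nrow(negMat) < cfg$folds) return(NULL)
  .cvScoreInt(pw$mat, negMat, cfg$folds, cfg$alpha)
}

#' Determine motif boundaries around an anchor
#'
#' Starting from the anchor seat, a width-\code{W} window slides outward one
#' residue at a time — leftward (window start moving away from the anchor
#' start), then rightward (window end moving away from the anchor end). At
#' every offset a window model is trained (positives: anchor-aligned windows
#' of the purified set; background: anchor-aligned windows of negatives
#' containing the anchor, randomly placed windows otherwise) and scored by
#' stratified cross-validation. The farther the window leaves the true motif
#' region the more irrelevant residues it contains and the lower the score,
#' so the extension in a direction ends at the first offset whose
#' min(precision, recall) falls below \code{accuracyThreshold}; the last
#' passing offsets are the boundary extents. An anchor whose seat window
#' already scores below the threshold is rejected (no motif).
#'
#' @param positives terminal segments of the (purified) positive set; every
#'   one must contain the anchor
#' @param negatives terminal segments of the background set
#' @param anchor an \code{\link{AnchorPattern}}
#' @param config see \code{\link{boundaryConfig}}
#' @param seats optional named vector of anchor-occurrence starts per
#'   positive (as returned by \code{\link{purifyPositives}}); when absent the
#'   leftmost occurrence is used and refined under a seat-trained model
#' @param spans matched anchor spans accompanying \code{seats}
#' @return list with \code{found}, \code{leftExt}, \code{rightExt},
#'   \code{seatScore}, \code{scores} (per-offset CV table), \code{seats},
#'   \code{spans}
#' @export
determineBoundaries <- function(positives, negatives, anchor,
                                config = boundaryConfig(), seats = NULL,
                                spans = NULL) {
  prob <- .prepareAnchorProblem(positives, negatives, anchor)
  posEnc <- prob$pos
  set.seed(config$seed)
  if (is.null(seats)) {
    s0 <- vapply(prob$posHits, function(h) h$start[1L], integer(1))
    p0 <- vapply(prob$posHits, function(h) h$span[1L], integer(1))
    rf <- .refineSeats(prob, seq_along(posEnc$ids), s0, p0, config$W,
                       config$alpha)
    seats <- rf$starts; spans <- rf$spans
  } else {
    seats <- unname(seats[posEnc$ids]); spans <- unname(spans[posEnc$ids])
    if (anyNA(seats)) stop("seats must cover every positive sequence")
  }
  rows <- list()
  seatCV <- .offsetCV(prob, posEnc, seats, spans, 0L, "left", config)
  if (is.null(seatCV))
    stop("too few valid windows at the anchor seat for cross-validation")
  rows[[1]] <- data.frame(direction = "left", offset = 0L,
                          minPR = seatCV@minPR)
  if (seatCV@minPR < config$accuracyThreshold) {
    return(list(found = FALSE, leftExt = 0L, rightExt = 0L,
                seatScore = seatCV@minPR, scores = do.call(rbind, rows),
                seats = stats::setNames(seats, posEnc$ids),
                spans = stats::setNames(spans, posEnc$ids)))
  }
  ext <- c(left = 0L, right = 0L)
  for (dir in c("left", "right")) {
    for (o in seq_len(config$maxExtension)) {
      cv <- .offsetCV(prob, posEnc, seats, spans, o, dir, config)
      if (is.null(cv)) break
      rows[[length(rows) + 1L]] <- data.frame(direction = dir, offset = o,
                                              minPR = cv@minPR)
      if (cv@minPR < config$accuracyThreshold) break
      ext[dir] <- o
    }
    # boundary = center of the outermost passing window, not its outer edge
    ext[dir] <- max(0L, ext[dir] - config$centerCorrection)
  }
  list(found = TRUE, leftExt = unname(ext["left"]),
       rightExt = unname(ext["right"]), seatScore = seatCV@minPR,
       scores = do.call(rbind, rows),
       seats = stats::setNames(seats, posEnc$ids),
       spans = stats::setNames(spans, posEnc$ids))
}

#' Cross-validated discrimination score of a motif region
#'
#' Scores how well the boundary-delimited motif region separates the
#' positive set from background: the aligned positive instances are
#' classified against equal-width windows from the negative segments
#' (anchor-aligned at the same relative position when the negative contains
#' the anchor, randomly placed otherwise) with stratified cross-validation,
#' and min(precision, recall) is returned — the minimum avoids the pitfall
#' of unbalanced datasets. This is exactly the
#' \code{\link{crossValidatedScore}} contract applied to the motif region.
#'
#' @param instances aligned boundary-delimited subsequences of the positive
#'   set (equal width, at least \code{folds})
#' @param negatives terminal segments of the background set
#' @param anchor optional \code{\link{AnchorPattern}} used to anchor-align
#'   background windows
#' @param leftExt residues between the instance start and the anchor start
#'   (used for the alignment of background windows)
#' @param folds,alpha,seed as in \code{\link{crossValidatedScore}}
#' @return a \code{\link{CVScore}}
#' @export
motifRegionScore <- function(instances, negatives, anchor = NULL,
                             leftExt = 0L, folds = 5L, alpha = 1,
                             seed = 1L) {
  instances <- .asCharacterSeqs(instances)
  if (length(instances) < folds)
    stop("need at least `folds` motif instances")
  L <- unique(nchar(instances))
  if (length(L) != 1L) stop("instances must be aligned to one length")
  set.seed(as.integer(seed))
  neg <- .asCharacterSeqs(negatives)
  negEnc <- .encodeSet(neg)
  starts <- rep(NA_integer_, length(neg))
  if (!is.null(anchor)) {
    hits <- matchAnchor(anchor, neg)
    first <- hits[!duplicated(hits$id), , drop = FALSE]
    starts[match(first$id, negEnc$ids)] <- first$start - as.integer(leftExt)
  }
  bad <- is.na(starts) | starts < 1L | starts + L - 1L > negEnc$len
  room <- negEnc$len - L + 1L
  if (all(room[bad] <= 1L)) {
    # segments exactly motif-width: placement is forced, no randomness
    starts[bad] <- ifelse(room[bad] == 1L, 1L, NA_integer_)
  } else {
    starts[bad] <- .randomStarts(negEnc$len, L)[bad]
  }
  negMat <- .winMat(negEnc, starts, L)$mat
  if (nrow(negMat) < folds)
    stop("too few background windows of the motif width")
  posMat <- .windowsToMatrix(instances)
  .cvScoreInt(posMat, negMat, folds, alpha)
}

.instanceCounts <- function(x) {
  x <- .asCharacterSeqs(x)
  if (length(x) < 2L) stop("need at least 2 aligned instances")
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("instances must all have the same length")
  M <- .windowsToMatrix(x)
  .columnCounts(M)  # 20 x L, 'X' excluded
}

setMethod("informationContent", "character", function(x) {
  cnt <- .instanceCounts(x)
  tot <- colSums(cnt)
  H <- vapply(seq_len(ncol(cnt)), function(j) {
    if (tot[j] == 0L) return(log2(20))  # all-'X' column: no information
    p <- cnt[, j] / tot[j]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  sum(log2(20) - H)
})

setMethod("informationContent", "AAStringSet",
          function(x) informationContent(as.character(x)))

#' Position weight matrix and consensus of aligned instances
#'
#' Column residue frequencies over the 20-letter alphabet ('X' excluded from
#' a column's counts) plus a consensus string: the modal residue where its
#' frequency reaches 0.5 (ties broken alphabetically), otherwise 'x' for a
#' weakly conserved column — the conventional rendering of anchored sorting
#' motifs such as NPxY.
#'
#' @param instances aligned equal-length subsequences (>= 2)
#' @return list with \code{pwm} (20 x L column-stochastic matrix, rows named
#'   by residue) and \code{consensus}
#' @export
#' @examples
#' buildPWM(c("NPAY", "NPCY", "NPGY"))$consensus   # "NPxY"
buildPWM <- function(instances) {
  cnt <- .instanceCounts(instances)
  tot <- colSums(cnt)
  pwm <- sweep(cnt, 2L, pmax(tot, 1L), "/")
  # renormalize all-'X' columns to uniform so columns stay stochastic
  uni <- tot == 0L
  if (any(uni)) pwm[, uni] <- 1 / 20
  rownames(pwm) <- .AA20
  consensus <- vapply(seq_len(ncol(pwm)), function(j) {
    f <- pwm[, j]
    if (max(f) < 0.5) "x" else .AA20[which.max(f)]
  }, character(1))
  list(pwm = pwm, consensus = paste(consensus, collapse = ""))
}

#' Write motifs in MEME minimal format
#'
#' Emits the discovered PWMs as a MEME minimal motif file (version line,
#' protein alphabet, background frequencies, one letter-probability matrix
#' per motif) so downstream logo and scanning tools can consume them.
#'
#' @param motifs a \code{\link{MotifModel}} or list of them
#' @param path output path
#' @param background named background residue frequencies (defaults to the
#'   shipped composition table)
#' @return \code{path}, invisibly
#' @export
writeMemeMotif <- function(motifs, path, background = aaComposition()) {
  if (methods::is(motifs, "MotifModel")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               sprintf("ALPHABET= %s", paste(.AA20, collapse = "")), "",
               "Background letter frequencies", paste(
                 sprintf("%s %.5f", .AA20, background[.AA20]),
                 collapse = " "), ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF %s_%d %s", anchorLiteral(m@anchor), i,
                       m@consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
      motifLength(m), length(m@instances)), con)
    apply(m@pwm, 2L, function(col) {
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con)
    })
    writeLines("", con)
  }
  invisible(path)
}
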