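# Iterative false-positive removal (dataset purification).
#
# For a given anchor, positive sequences that are unlikely to carry a true
# motif instance around their anchor occurrence are removed in rounds: a
# window model is trained at the anchor seat and at successive offsets to the
# left and right, each sequence's window posteriors are tracked until it
# accumulates `consecutiveLow` successive sub-threshold scores (or the
# segment edge is reached), and a sequence whose average pre-run score falls
# below the threshold is dropped. The loop repeats on the reduced set until
# nothing is removed or `maxIterations` is reached.

#' Configuration for iterative false-positive removal
#'
#' @param W sliding-window width in residues (default 10)
#' @param scoreThreshold window-posterior threshold (default 0.85): sequences
#'   whose average window score falls below it are removed; 0 disables
#'   removal entirely
#' @param consecutiveLow how many successive sub-threshold scores end a
#'   sequence's scan in one direction (default 3)
#' @param maxIterations cap on removal rounds (default 10)
#' @param alpha Laplace pseudocount for window-model training
#' @param seed integer seed: identical inputs and configuration give an
#'   identical audit
#' @return validated configuration list
#' @export
fpRemovalConfig <- function(W = 10L, scoreThreshold = 0.85,
                            consecutiveLow = 3L, maxIterations = 10L,
                            alpha = 1, seed = 1L) {
  W <- as.integer(W)
  if (W < 2L) stop("W must be >= 2")
  if (scoreThreshold < 0 || scoreThreshold >= 1)
    stop("scoreThreshold must lie in [0, 1)")
  if (consecutiveLow < 1L) stop("consecutiveLow must be >= 1")
  if (maxIterations < 1L) stop("maxIterations must be >= 1")
  list(W = W, scoreThreshold = scoreThreshold,
       consecutiveLow = as.integer(consecutiveLow),
       maxIterations = as.integer(maxIterations), alpha = alpha,
       seed = as.integer(seed))
}

# Bundle everything the per-anchor procedures need: encoded segments, the
# per-positive anchor hit lists (every positive must have >= 1), and the
# leftmost anchor seat of each negative (NA when absent).
.prepareAnchorProblem <- function(positives, negatives, anchor) {
  pos <- .asCharacterSeqs(positives); neg <- .asCharacterSeqs(negatives)
  if (is.null(names(pos))) names(pos) <- paste0("pos", seq_along(pos))
  if (is.null(names(neg))) names(neg) <- paste0("neg", seq_along(neg))
  posHitsDf <- matchAnchor(anchor, pos)
  posHits <- split(posHitsDf[c("start", "gap", "span")],
                   factor(posHitsDf$id, levels = names(pos)))
  miss <- names(pos)[vapply(posHits, nrow, integer(1)) == 0L]
  if (length(miss))
    stop("positive segment(s) without an anchor occurrence: ",
         paste(utils::head(miss, 3), collapse = ", "),
         if (length(miss) > 3) sprintf(" (and %d more)", length(miss) - 3))
  negHitsDf <- matchAnchor(anchor, neg)
  negFirst <- negHitsDf[!duplicated(negHitsDf$id), , drop = FALSE]
  negSeat <- rep(NA_integer_, length(neg))
  negSpan <- rep(NA_integer_, length(neg))
  idx <- match(negFirst$id, names(neg))
  negSeat[idx] <- negFirst$start
  negSpan[idx] <- negFirst$span
  list(pos = .encodeSet(pos), neg = .encodeSet(neg),
       posHits = posHits, negSeat = negSeat, negSpan = negSpan)
}

# Window matrix at per-sequence starts; invalid (NA / out-of-bounds) starts
# are dropped rather than padded.
.winMat <- function(enc, starts, W) {
  valid <- !is.na(starts) & starts >= 1L & starts + W - 1L <= enc$len
  idx <- which(valid)
  mat <- if (length(idx)) {
    t(vapply(idx, function(i) enc$seq[[i]][starts[i] + 0:(W - 1L)],
             integer(W)))
  } else matrix(integer(0), 0L, W)
  list(mat = mat, valid = valid, idx = idx)
}

.randomStarts <- function(len, W) {
  room <- len - W + 1L
  out <- 1L + as.integer(floor(stats::runif(length(len)) * pmax(room, 0L)))
  out[room < 1L] <- NA_integer_
  out
}

# Background window matrix at a signed offset from each negative's anchor
# seat (anchor-free or out-of-bounds negatives get a fresh random placement).
.negWindowMatrix <- function(prob, offset, dir, W) {
  starts <- if (dir == "left") prob$negSeat - offset
            else prob$negSeat + prob$negSpan + offset - W
  bad <- is.na(starts) | starts < 1L | starts + W - 1L > prob$neg$len
  starts[bad] <- .randomStarts(prob$neg$len, W)[bad]
  .winMat(prob$neg, starts, W)$mat
}

#' Choose one anchor occurrence per sequence
#'
#' When a sequence contains several anchor occurrences, the occurrence whose
#' anchor-seated window scores highest under the current window model is
#' used; without a model (the first purification round) the leftmost
#' occurrence is used. Ties go to the leftmost.
#'
#' @param hits data.frame of occurrences for one sequence
#'   (\code{\link{matchAnchor}} columns \code{start}, \code{gap},
#'   \code{span})
#' @param segment the sequence the hits belong to (residue string)
#' @param model a \code{\link{WindowModel}} or \code{NULL}
#' @return the chosen row of \code{hits}
#' @export
chooseOccurrence <- function(hits, segment, model = NULL) {
  if (nrow(hits) == 0L) stop("hits must be non-empty")
  hits <- hits[order(hits$start, hits$gap), , drop = FALSE]
  if (is.null(model) || nrow(hits) == 1L) return(hits[1L, , drop = FALSE])
  segment <- .asCharacterSeqs(segment)
  enc <- .encodeResidues(segment)
  W <- model@W
  ok <- hits$start + W - 1L <= length(enc) & hits$start >= 1L
  if (!any(ok)) return(hits[1L, , drop = FALSE])
  cand <- hits[ok, , drop = FALSE]
  M <- t(vapply(cand$start, function(s) enc[s + 0:(W - 1L)], integer(W)))
  post <- .scoreWM(model, M)
  cand[which.max(post), , drop = FALSE]
}

# Seat refinement: train a seat-window model from the current seating, then
# re-choose each positive's occurrence by seat-window posterior (ties ->
# leftmost). `sel` indexes the retained positives.
.refineSeats <- function(prob, sel, seats, spans, W, alpha, rounds = 2L) {
  multi <- vapply(prob$posHits[sel], nrow, integer(1)) > 1L
  if (!any(multi)) return(list(starts = seats, spans = spans))
  posEnc <- list(ids = prob$pos$ids[sel], seq = prob$pos$seq[sel],
                 len = prob$pos$len[sel])
  for (r in seq_len(rounds)) {
    pw <- .winMat(posEnc, seats, W)
    negMat <- .negWindowMatrix(prob, 0L, "left", W)
    if (nrow(pw$mat) == 0L || nrow(negMat) == 0L) break
    model <- .trainWM(pw$mat, negMat, alpha)
    newSeats <- seats; newSpans <- spans
    for (j in which(multi)) {
      hits <- prob$posHits[sel][[j]]
      ok <- hits$start >= 1L & hits$start + W - 1L <= posEnc$len[j]
      if (!any(ok)) next
      cand <- hits[ok, , drop = FALSE]
      M <- t(vapply(cand$start, function(s) posEnc$seq[[j]][s + 0:(W - 1L)],
                    integer(W)))
      post <- .scoreWM(model, M)
      best <- which.max(post)
      newSeats[j] <- cand$start[best]
      newSpans[j] <- cand$span[best]
    }
    if (all(newSeats == seats)) break
    seats <- newSeats; spans <- newSpans
  }
  list(starts = seats, spans = spans)
}

# One full two-direction scan from the current seats. Returns each retained
# positive's removal mean: the average of its window scores before its first
# run of `consecutiveLow` sub-threshold scores (pooled over directions); a
# sequence whose scan starts inside such a run falls back to the run scores
# themselves.
.scanRemovalMeans <- function(prob, sel, seats, spans, cfg) {
  posEnc <- list(ids = prob$pos$ids[sel], seq = prob$pos$seq[sel],
                 len = prob$pos$len[sel])
  np <- length(sel)
  W <- cfg$W; thr <- cfg$scoreThreshold; k <- cfg$consecutiveLow
  preSum <- preN <- runSum <- runN <- rep(0, np)
  for (dir in c("left", "right")) {
    finished <- rep(FALSE, np)
    runLen <- rep(0L, np)
    dRunSum <- dRunN <- rep(0, np)
    o <- if (dir == "left") 0L else 1L
    maxOff <- max(posEnc$len)
    while (o <= maxOff) {
      posStart <- if (dir == "left") seats - o else seats + spans + o - W
      pw <- .winMat(posEnc, posStart, W)
      negMat <- .negWindowMatrix(prob, o, dir, W)
      if (nrow(pw$mat) == 0L || nrow(negMat) == 0L) break
      model <- .trainWM(pw$mat, negMat, cfg$alpha)
      post <- .scoreWM(model, pw$mat)
      act <- intersect(pw$idx, which(!finished))
      if (length(act)) {
        s <- post[match(act, pw$idx)]
        low <- s < thr
        hi <- act[!low]; lo <- act[low]
        if (length(hi)) {
          preSum[hi] <- preSum[hi] + dRunSum[hi] + s[!low]
          preN[hi] <- preN[hi] + dRunN[hi] + 1
          dRunSum[hi] <- 0; dRunN[hi] <- 0; runLen[hi] <- 0L
        }
        if (length(lo)) {
          dRunSum[lo] <- dRunSum[lo] + s[low]
          dRunN[lo] <- dRunN[lo] + 1
          runLen[lo] <- runLen[lo] + 1L
          done <- lo[runLen[lo] >= k]
          finished[done] <- TRUE
        }
      }
      # sequences whose window ran off the segment edge stop here; their
      # accumulated run (if any) was not a terminating run, so it counts
      bnd <- which(!pw$valid & !finished)
      if (length(bnd)) {
        preSum[bnd] <- preSum[bnd] + dRunSum[bnd]
        preN[bnd] <- preN[bnd] + dRunN[bnd]
        dRunSum[bnd] <- 0; dRunN[bnd] <- 0
        finished[bnd] <- TRUE
      }
      if (all(finished)) break
      o <- o + 1L
    }
    # terminating runs kept as fallback for sequences with no pre-run scores
    runSum <- runSum + dRunSum
    runN <- runN + dRunN
  }
  means <- ifelse(preN > 0, preSum / preN,
                  ifelse(runN > 0, runSum / runN, NA_real_))
  means
}

#' Iteratively remove false-positive sequences
#'
#' Implements the purification loop for one anchor: (1) seat a window at each
#' positive's chosen anchor occurrence (background windows come from the
#' negative set — anchor-aligned when the negative contains the anchor,
#' randomly placed otherwise); (2) train the window model; (3) score every
#' positive's window; (4) advance the window one residue at a time, first
#' leftward then rightward from the seat, retraining at every offset, until
#' each sequence has had \code{consecutiveLow} successive scores below
#' \code{scoreThreshold} (or its segment edge is reached); (5) average each
#' sequence's scores accumulated before its terminating run and remove
#' sequences with mean below the threshold; (6) repeat on the reduced set
#' until no sequence is removed or \code{maxIterations} is reached.
#'
#' Occurrence seating is re-chosen each round under the current model (see
#' \code{\link{chooseOccurrence}}); round one starts from the leftmost
#' occurrence and refines.
#'
#' @param positives terminal segments of the positive set; every one must
#'   contain the anchor (at least 10 sequences)
#' @param negatives terminal segments of the background set (at least 10)
#' @param anchor an \code{\link{AnchorPattern}}
#' @param config see \code{\link{fpRemovalConfig}}
#' @return list with \code{retainedIds}, \code{audit} (data.frame: iteration,
#'   id, meanScore, action), \code{seats}/\code{spans} (chosen anchor
#'   occurrence per retained sequence), and \code{iterations}
#' @export
purifyPositives <- function(positives, negatives, anchor,
                            config = fpRemovalConfig()) {
  prob <- .prepareAnchorProblem(positives, negatives, anchor)
  np <- length(prob$pos$ids); nn <- length(prob$neg$ids)
  if (np < 10L || nn < 10L)
    stop("purification needs at least 10 sequences per class")
  set.seed(config$seed)
  retained <- rep(TRUE, np)
  seatsAll <- vapply(prob$posHits, function(h) h$start[1L], integer(1))
  spansAll <- vapply(prob$posHits, function(h) h$span[1L], integer(1))
  audit <- vector("list", config$maxIterations)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sel <- which(retained)
    rf <- .refineSeats(prob, sel, seatsAll[sel], spansAll[sel], config$W,
                       config$alpha)
    seatsAll[sel] <- rf$starts; spansAll[sel] <- rf$spans
    means <- .scanRemovalMeans(prob, sel, rf$starts, rf$spans, config)
    remove <- !is.na(means) & means < config$scoreThreshold
    audit[[iter]] <- data.frame(
      iteration = iter, id = prob$pos$ids[sel], meanScore = means,
      action = ifelse(remove, "removed", "retained"),
      stringsAsFactors = FALSE)
    if (all(remove))
      stop("all positive sequences were removed; consider a lower ",
           "scoreThreshold")
    retained[sel[remove]] <- FALSE
    if (!any(remove) || iter >= config$maxIterations) break
  }
  sel <- which(retained)
  list(retainedIds = prob$pos$ids[sel],
       audit = do.call(rbind, audit[seq_len(iter)]),
       seats = stats::setNames(seatsAll[sel], prob$pos$ids[sel]),
       spans = stats::setNames(spansAll[sel], prob$pos$ids[sel]),
       iterations = iter)
}
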