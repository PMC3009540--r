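#' Find all occurrences of an anchor pattern
#'
#' Scans sequences for a gap-tolerant anchor
#' (\code{left . gap(gapMin..gapMax) . right}). All occurrences are reported,
#' overlaps included; when the gap length varies, each distinct
#' (start, gap) combination is one hit. Literal positions never match 'X';
#' gap positions match anything.
#'
#' @param pattern an \code{\link{AnchorPattern}}
#' @param x sequences: character vector or \code{AAStringSet} (named)
#' @return data.frame with columns \code{id}, \code{start} (1-based),
#'   \code{gap}, \code{span} (matched length including the gap)
#' @export
#' @examples
#' matchAnchor(AnchorPattern("RR"), c(s = "ARRRA"))
#' matchAnchor(AnchorPattern("NP", "Y", 1), c(s = "ANPAYC"))
matchAnchor <- function(pattern, x) {
  stopifnot(methods::is(pattern, "AnchorPattern"))
  x <- .asCharacterSeqs(x)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  n <- nchar(pattern@leftLiteral); m <- nchar(pattern@rightLiteral)
  out <- vector("list", (pattern@gapMax - pattern@gapMin + 1L))
  k <- 0L
  for (g in pattern@gapMin:pattern@gapMax) {
    k <- k + 1L
    rx <- if (m == 0L) sprintf("(?=%s)", pattern@leftLiteral)
          else sprintf("(?=%s.{%d}%s)", pattern@leftLiteral, g,
                       pattern@rightLiteral)
    hits <- gregexpr(rx, x, perl = TRUE)
    starts <- lapply(hits, function(h) h[h > 0L])
    nh <- lengths(starts)
    out[[k]] <- data.frame(id = rep(ids, nh),
                           start = unlist(starts, use.names = FALSE),
                           gap = rep(g, sum(nh)),
                           span = rep(n + g + m, sum(nh)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L)
    return(data.frame(id = character(0), start = integer(0),
                      gap = integer(0), span = integer(0)))
  res <- res[order(match(res$id, ids), res$start, res$gap), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enumerate frequent anchors
#'
#' Exhaustively instantiates the anchor template
#' \code{<residues>{n} <gap>{gapMin,gapMax} <residues>{m}} over the given
#' alphabets, counts occurrences in the positive terminal segments, and keeps
#' instantiations supported by at least \code{minSupport} of the positive
#' sequences. Support is the number of distinct positive sequences with at
#' least one hit (a sorting signal occurs at most a few times per protein, so
#' per-sequence support resists repeat-rich outliers); total occurrence
#' counts are also reported, as is the fraction of negative sequences with a
#' hit, for context. The table is sorted by support (descending), ties broken
#' lexicographically by the pattern label.
#'
#' @param positives,negatives terminal segments (character vector or
#'   \code{AAStringSet}); negatives may be \code{NULL}
#' @param n,m left/right literal lengths (\code{m = 0} for a plain anchor)
#' @param gapMin,gapMax gap-length bounds
#' @param leftAlphabet,rightAlphabet candidate residues for each literal
#' @param minSupport minimum fraction of positive sequences with a hit
#' @param maxSpace resource cap on the number of literal instantiations
#' @return data.frame with columns \code{label}, \code{left}, \code{right},
#'   \code{gapMin}, \code{gapMax}, \code{support} (sequences with >= 1 hit),
#'   \code{totalHits}, \code{posFreq}, \code{negFreq}
#' @export
#' @examples
#' enumerateAnchors(c(a = "RRAR"), NULL, n = 2, minSupport = 0)
enumerateAnchors <- function(positives, negatives = NULL, n = 2L, m = 0L,
                             gapMin = 0L, gapMax = 0L,
                             leftAlphabet = aminoAcidAlphabet(),
                             rightAlphabet = aminoAcidAlphabet(),
                             minSupport = 0.3, maxSpace = 1e7) {
  n <- as.integer(n); m <- as.integer(m)
  gapMin <- as.integer(gapMin); gapMax <- as.integer(gapMax)
  if (n < 1L || m < 0L || gapMin < 0L || gapMax < gapMin)
    stop("need n >= 1, m >= 0, 0 <= gapMin <= gapMax")
  space <- length(leftAlphabet)^n * max(1, length(rightAlphabet))^m *
    (gapMax - gapMin + 1)
  if (space > maxSpace)
    stop("anchor instantiation space (", format(space, big.mark = ","),
         ") exceeds the cap; shrink the alphabets or literal lengths")
  pos <- .asCharacterSeqs(positives)
  nPos <- length(pos)
  if (nPos == 0L) stop("no positive sequences")
  counts <- .countAnchorKeys(pos, n, m, gapMin, gapMax,
                             leftAlphabet, rightAlphabet)
  if (nrow(counts) == 0L || minSupport > 1) {
    empty <- counts[0, , drop = FALSE]
    empty$negFreq <- numeric(0)
    return(empty)
  }
  counts$posFreq <- counts$support / nPos
  counts <- counts[counts$posFreq >= minSupport, , drop = FALSE]
  counts$negFreq <- 0
  if (!is.null(negatives) && length(negatives) && nrow(counts)) {
    neg <- .asCharacterSeqs(negatives)
    negCounts <- .countAnchorKeys(neg, n, m, gapMin, gapMax,
                                  leftAlphabet, rightAlphabet)
    idx <- match(counts$label, negCounts$label)
    counts$negFreq <- ifelse(is.na(idx), 0,
                             negCounts$support[idx] / length(neg))
  }
  counts <- counts[order(-counts$support, counts$label), , drop = FALSE]
  rownames(counts) <- NULL
  counts
}

# Count per-sequence support and total hits for every literal instantiation
# by direct substring extraction (equivalent to, and tested against, a
# brute-force regex scan). Keys containing 'X' or residues outside the
# declared alphabets are dropped.
.countAnchorKeys <- function(seqs, n, m, gapMin, gapMax, leftAlphabet,
                             rightAlphabet) {
  perSeqAll <- vector("list", length(seqs))
  perSeqUnique <- vector("list", length(seqs))
  leftOK <- function(v) !grepl(sprintf("[^%s]", paste(leftAlphabet, collapse = "")), v)
  rightOK <- function(v) !grepl(sprintf("[^%s]", paste(rightAlphabet, collapse = "")), v)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]; L <- nchar(s)
    keys <- character(0)
    for (g in gapMin:gapMax) {
      span <- n + g + m
      np <- L - span + 1L
      if (np < 1L) next
      starts <- seq_len(np)
      left <- substring(s, starts, starts + n - 1L)
      ok <- leftOK(left)
      if (m > 0L) {
        right <- substring(s, starts + n + g, starts + span - 1L)
        ok <- ok & rightOK(right)
        keys <- c(keys, paste0(left[ok], "|", right[ok]))
      } else {
        keys <- c(keys, left[ok])
      }
    }
    perSeqAll[[i]] <- keys
    perSeqUnique[[i]] <- unique(keys)
  }
  tot <- table(unlist(perSeqAll, use.names = FALSE))
  sup <- table(unlist(perSeqUnique, use.names = FALSE))
  if (length(sup) == 0L)
    return(data.frame(label = character(0), left = character(0),
                      right = character(0), gapMin = integer(0),
                      gapMax = integer(0), support = integer(0),
                      totalHits = integer(0), posFreq = numeric(0),
                      stringsAsFactors = FALSE))
  key <- names(sup)
  left <- sub("\\|.*$", "", key)
  right <- ifelse(grepl("|", key, fixed = TRUE), sub("^.*\\|", "", key), "")
  label <- ifelse(right == "", left,
                  paste0(left,
                         if (gapMin == gapMax) {
                           if (gapMin == 0L) "" else sprintf("x{%d}", gapMin)
                         } else sprintf("x{%d,%d}", gapMin, gapMax),
                         right))
  data.frame(label = label, left = left, right = right,
             gapMin = gapMin, gapMax = gapMax,
             support = as.integer(sup),
             totalHits = as.integer(tot[key]),
             stringsAsFactors = FALSE)
}

#' Rank frequent anchors
#'
#' @param table an anchor table from \code{\link{enumerateAnchors}}
#'   (non-empty)
#' @param topK how many patterns to return (>= 1)
#' @return list of instantiated \code{\link{AnchorPattern}} objects in table
#'   order (support descending, ties lexicographic)
#' @export
rankAnchors <- function(table, topK = 5L) {
  if (topK <= 0L) stop("topK must be >= 1")
  if (is.null(table) || nrow(table) == 0L) stop("anchor table is empty")
  rows <- utils::head(table, topK)
  lapply(seq_len(nrow(rows)), function(i) {
    AnchorPattern(rows$left[i], rows$right[i], rows$gapMin[i], rows$gapMax[i])
  })
}
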