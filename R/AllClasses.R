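#' Labeled protein sequence sets
#'
#' A \code{SortingDataset} bundles a positive set (proteins presumed to share
#' a sorting destination) and a negative/background set as a single sanitized
#' \code{\link[Biostrings]{AAStringSet}} with a per-record label. Residues
#' outside the 20-letter alphabet are represented as 'X'. Record ids must be
#' unique across both classes.
#'
#' @slot sequences an \code{AAStringSet} (named, sanitized)
#' @slot label character vector, one of \code{"positive"}/\code{"negative"}
#'   per record
#'
#' @param positive,negative named character vectors or \code{AAStringSet}s
#' @param x a \code{SortingDataset}
#' @return \code{SortingDataset()} returns a validated object;
#'   \code{positiveSet}/\code{negativeSet} return \code{AAStringSet}s;
#'   \code{nPositive}/\code{nNegative} return counts.
#' @export
#' @examples
#' ds <- SortingDataset(positive = c(p1 = "MKRAA", p2 = "MKLVV"),
#'                      negative = c(n1 = "MSSSS"))
#' nPositive(ds)
#' positiveSet(ds)
setClass("SortingDataset",
         representation(sequences = "AAStringSet", label = "character"))

setValidity("SortingDataset", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n == 0L) msg <- c(msg, "dataset contains no records")
  if (length(object@label) != n)
    msg <- c(msg, "label length must match the number of records")
  if (!all(object@label %in% c("positive", "negative")))
    msg <- c(msg, "labels must be 'positive' or 'negative'")
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "every record needs a non-empty id")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate record id: %s",
                          ids[duplicated(ids)][1L]))
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "records with empty residues are not allowed")
  chars <- unique(unlist(strsplit(as.character(object@sequences), "")))
  if (length(chars) && !all(chars %in% .AAX))
    msg <- c(msg, "residues outside the 21-letter extended alphabet; sanitize first")
  if (length(msg)) msg else TRUE
})

#' @rdname SortingDataset-class
#' @export
SortingDataset <- function(positive, negative) {
  toSet <- function(x, prefix) {
    x <- .asCharacterSeqs(x)
    if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
    san <- .sanitizeResidues(x)
    out <- san$residues
    names(out) <- names(x)
    out
  }
  pos <- toSet(positive, "pos")
  neg <- toSet(negative, "neg")
  methods::new("SortingDataset",
               sequences = Biostrings::AAStringSet(c(pos, neg)),
               label = c(rep("positive", length(pos)),
                         rep("negative", length(neg))))
}

setMethod("positiveSet", "SortingDataset",
          function(x) x@sequences[x@label == "positive"])
setMethod("negativeSet", "SortingDataset",
          function(x) x@sequences[x@label == "negative"])
setMethod("nPositive", "SortingDataset",
          function(x) sum(x@label == "positive"))
setMethod("nNegative", "SortingDataset",
          function(x) sum(x@label == "negative"))

setMethod("show", "SortingDataset", function(object) {
  cat(sprintf("SortingDataset: %d positive, %d negative records (widths %d..%d)\n",
              nPositive(object), nNegative(object),
              min(Biostrings::width(object@sequences)),
              max(Biostrings::width(object@sequences))))
})

#' Gap-tolerant anchor patterns
#'
#' An anchor is the short, highly conserved core of an anchored sorting motif
#' (e.g. the twin-arginine "RR", or "NPxY" written as left literal "NP", gap
#' exactly 1, right literal "Y"). The pattern matches
#' \code{left . gap(gapMin..gapMax) . right}; gap positions match any residue
#' (including 'X'), literal positions match only their own letter, so 'X' in a
#' sequence never satisfies a literal.
#'
#' @slot leftLiteral,rightLiteral concrete residue strings (right may be "")
#' @slot gapMin,gapMax gap-length bounds, \code{0 <= gapMin <= gapMax}
#'
#' @param leftLiteral,rightLiteral,gapMin,gapMax see slots
#' @param x an \code{AnchorPattern}
#' @return \code{AnchorPattern()} returns a validated object;
#'   \code{anchorLiteral} a display string such as \code{"RR"} or
#'   \code{"NPx{1}Y"}.
#' @export
#' @examples
#' AnchorPattern("NP", "Y", gapMin = 1, gapMax = 1)
setClass("AnchorPattern",
         representation(leftLiteral = "character", rightLiteral = "character",
                        gapMin = "integer", gapMax = "integer"))

setValidity("AnchorPattern", function(object) {
  msg <- character()
  if (nchar(object@leftLiteral) < 1L)
    msg <- c(msg, "left literal must have at least one residue")
  lits <- unlist(strsplit(c(object@leftLiteral, object@rightLiteral), ""))
  if (length(lits) && !all(lits %in% .AA20))
    msg <- c(msg, "literals must use the 20 standard residue letters")
  if (object@gapMin < 0L || object@gapMax < object@gapMin)
    msg <- c(msg, "need 0 <= gapMin <= gapMax")
  if (nchar(object@rightLiteral) == 0L && object@gapMax > 0L)
    msg <- c(msg, "a gap requires a right literal")
  if (length(msg)) msg else TRUE
})

#' @rdname AnchorPattern-class
#' @export
AnchorPattern <- function(leftLiteral, rightLiteral = "", gapMin = 0L,
                          gapMax = gapMin) {
  methods::new("AnchorPattern", leftLiteral = toupper(leftLiteral),
               rightLiteral = toupper(rightLiteral),
               gapMin = as.integer(gapMin), gapMax = as.integer(gapMax))
}

setMethod("anchorLiteral", "AnchorPattern", function(x) {
  if (nchar(x@rightLiteral) == 0L) return(x@leftLiteral)
  gap <- if (x@gapMin == x@gapMax) {
    if (x@gapMin == 0L) "" else sprintf("x{%d}", x@gapMin)
  } else sprintf("x{%d,%d}", x@gapMin, x@gapMax)
  paste0(x@leftLiteral, gap, x@rightLiteral)
})

setMethod("show", "AnchorPattern", function(object) {
  cat(sprintf("AnchorPattern: %s (span %d..%d)\n", anchorLiteral(object),
              .minSpan(object), .maxSpan(object)))
})

.minSpan <- function(p) nchar(p@leftLiteral) + p@gapMin + nchar(p@rightLiteral)
.maxSpan <- function(p) nchar(p@leftLiteral) + p@gapMax + nchar(p@rightLiteral)

#' Two-class per-position categorical window model
#'
#' A naive Bayes model over fixed-width residue windows: for each class
#' (\code{motif}, \code{background}) and each window column an independent
#' categorical distribution over the 20 residues, estimated with Laplace
#' smoothing \eqn{\alpha} (an 'X' observation is excluded from counts and
#' contributes a flat 1/20 likelihood to both classes at scoring time).
#'
#' @slot W window width
#' @slot logLik 21 x W x 2 array of per-residue log likelihoods (row 21 is
#'   'X'); classes along the third dimension are \code{motif},
#'   \code{background}
#' @slot logPriors log class priors (from training counts)
#' @slot alpha the pseudocount used
#' @slot nTrain training sample counts per class
#' @export
setClass("WindowModel",
         representation(W = "integer", logLik = "array",
                        logPriors = "numeric", alpha = "numeric",
                        nTrain = "integer"))

setValidity("WindowModel", function(object) {
  msg <- character()
  d <- dim(object@logLik)
  if (length(d) != 3L || d[1] != 21L || d[2] != object@W || d[3] != 2L)
    msg <- c(msg, "logLik must be a 21 x W x 2 array")
  else {
    sums <- apply(exp(object@logLik[1:20, , , drop = FALSE]), c(2, 3), sum)
    if (any(abs(sums - 1) > 1e-9))
      msg <- c(msg, "residue probabilities must sum to 1 per class and column")
  }
  if (abs(sum(exp(object@logPriors)) - 1) > 1e-9)
    msg <- c(msg, "class priors must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WindowModel", function(object) {
  cat(sprintf(
    "WindowModel: width %d, alpha %.3g, trained on %d motif / %d background windows\n",
    object@W, object@alpha, object@nTrain[1], object@nTrain[2]))
})

#' Cross-validated window classification score
#'
#' Precision and recall of the motif class pooled over stratified CV folds,
#' plus their minimum — the motif score used throughout the package, chosen
#' to be robust to class imbalance.
#'
#' @slot precision,recall,minPR fractions in [0, 1]
#' @slot folds number of folds used
#' @export
setClass("CVScore",
         representation(precision = "numeric", recall = "numeric",
                        minPR = "numeric", folds = "integer"))

setValidity("CVScore", function(object) {
  v <- c(object@precision, object@recall, object@minPR)
  msg <- character()
  if (any(v < 0 | v > 1)) msg <- c(msg, "scores must lie in [0, 1]")
  if (abs(object@minPR - min(object@precision, object@recall)) > 1e-12)
    msg <- c(msg, "minPR must equal min(precision, recall)")
  if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CVScore", function(object) {
  cat(sprintf("CVScore (%d-fold): precision %.3f, recall %.3f, min %.3f\n",
              object@folds, object@precision, object@recall, object@minPR))
})

#' Discovered anchored motif
#'
#' The final representation of one discovered motif: the anchor, the flanking
#' extents determined by the sliding-window boundary search, the aligned
#' instances extracted from the (purified) positive set, their position
#' weight matrix and consensus, the cross-validated motif score
#' (min(precision, recall)) and the Shannon information content in bits.
#'
#' @slot anchor the \code{AnchorPattern}
#' @slot anchorSpan matched anchor span (residues, including any gap)
#' @slot leftExt,rightExt residues extending beyond the anchor on each side
#' @slot instances aligned equal-length instances (\code{AAStringSet})
#' @slot pwm 20 x L column-stochastic residue frequency matrix
#' @slot consensus consensus string; weak columns (max frequency < 0.5)
#'   rendered as 'x'
#' @slot motifScore min(precision, recall) of the cross-validated classifier
#' @slot informationContent bits
#' @param x a \code{MotifModel}
#' @export
setClass("MotifModel",
         representation(anchor = "AnchorPattern", anchorSpan = "integer",
                        leftExt = "integer", rightExt = "integer",
                        instances = "AAStringSet", pwm = "matrix",
                        consensus = "character", motifScore = "numeric",
                        informationContent = "numeric"))

setValidity("MotifModel", function(object) {
  msg <- character()
  L <- object@leftExt + object@anchorSpan + object@rightExt
  if (length(object@instances) &&
      !all(Biostrings::width(object@instances) == L))
    msg <- c(msg, "instances must all have length leftExt + anchorSpan + rightExt")
  if (ncol(object@pwm) != L || nrow(object@pwm) != 20L)
    msg <- c(msg, "pwm must be a 20 x L matrix")
  else if (any(abs(colSums(object@pwm) - 1) > 1e-6))
    msg <- c(msg, "pwm columns must sum to 1")
  if (object@motifScore < 0 || object@motifScore > 1)
    msg <- c(msg, "motifScore must lie in [0, 1]")
  if (object@informationContent < -1e-9 ||
      object@informationContent > L * log2(20) + 1e-9)
    msg <- c(msg, "informationContent must lie in [0, L * log2(20)]")
  if (length(msg)) msg else TRUE
})

setMethod("motifLength", "MotifModel",
          function(x) x@leftExt + x@anchorSpan + x@rightExt)
setMethod("motifConsensus", "MotifModel", function(x) x@consensus)
setMethod("motifScore", "MotifModel", function(x) x@motifScore)
setMethod("informationContent", "MotifModel",
          function(x) x@informationContent)
setMethod("motifInstances", "MotifModel", function(x) x@instances)
setMethod("motifPWM", "MotifModel", function(x) x@pwm)

setMethod("show", "MotifModel", function(object) {
  cat(sprintf(
    "MotifModel: anchor %s, length %d (+%d/+%d around the anchor)\n",
    anchorLiteral(object@anchor), motifLength(object), object@leftExt,
    object@rightExt))
  cat(sprintf("  consensus %s\n", object@consensus))
  cat(sprintf("  motif score %.3f, information content %.1f bits, %d instances\n",
              object@motifScore, object@informationContent,
              length(object@instances)))
})

#' Implanted-motif design for the synthetic benchmark
#'
#' Describes the artificial motif implanted into synthetic positive sets: a
#' conserved anchor (default "AA") flanked on both sides by residues drawn
#' i.i.d. from a restricted alphabet whose frequencies are the background
#' composition renormalized to that alphabet. The motif overwrites
#' \code{totalLength} residues at a uniformly random start within
#' \code{positionRange} of the N-terminal segment, in a random subset of
#' \code{round(trueRatio * n)} sequences.
#'
#' @slot anchorLiteral the conserved core (default "AA")
#' @slot totalLength total implant length including the anchor (default 20)
#' @slot flankAlphabet residue subset for the flanks
#' @slot flankProbs sampling frequencies over \code{flankAlphabet} (sum 1)
#' @slot positionRange 1-based closed interval of allowed implant starts'
#'   region (default residues 1..100)
#' @slot trueRatio fraction of positive sequences that receive an implant
#' @export
setClass("ImplantSpec",
         representation(anchorLiteral = "character", totalLength = "integer",
                        flankAlphabet = "character", flankProbs = "numeric",
                        positionRange = "integer", trueRatio = "numeric"))

setValidity("ImplantSpec", function(object) {
  msg <- character()
  if (object@totalLength < nchar(object@anchorLiteral))
    msg <- c(msg, "totalLength must be at least the anchor length")
  if ((object@totalLength - nchar(object@anchorLiteral)) %% 2L != 0L)
    msg <- c(msg, "flanks must have equal lengths: totalLength - anchor length must be even")
  if (!all(object@flankAlphabet %in% .AA20))
    msg <- c(msg, "flank alphabet must use the 20 standard residues")
  if (length(object@flankProbs) != length(object@flankAlphabet) ||
      abs(sum(object@flankProbs) - 1) > 1e-6)
    msg <- c(msg, "flankProbs must match flankAlphabet and sum to 1")
  if (object@trueRatio <= 0 || object@trueRatio > 1)
    msg <- c(msg, "trueRatio must lie in (0, 1]")
  if (length(object@positionRange) != 2L ||
      object@positionRange[1] < 1L ||
      diff(object@positionRange) + 1L < object@totalLength)
    msg <- c(msg, "positionRange must be a 1-based interval wide enough for the implant")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImplantSpec", function(object) {
  cat(sprintf(
    "ImplantSpec: %d-residue motif, anchor %s, flanks over {%s}, true ratio %.0f%%\n",
    object@totalLength, object@anchorLiteral,
    paste(object@flankAlphabet, collapse = ","), 100 * object@trueRatio))
})
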