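# Synthetic implanted-motif benchmark: i.i.d. background proteins with an
# artificial anchored motif written into a controlled fraction of the
# positive set, so anchor recovery, boundary placement, scoring and the
# false-positive-removal procedure can be validated against ground truth.

.hydrophobicSet <- c("V", "I", "L", "M", "F", "W", "C")
.chargedSet <- c("K", "R", "D", "E")

#' Background amino-acid composition
#'
#' The average residue composition of UniProtKB/Swiss-Prot proteins, shipped
#' as a plain-text fixture. It is the default composition of synthetic
#' background sequences and the default MEME background.
#'
#' @return named numeric vector over the 20 residues, summing to 1
#' @export
aaComposition <- function() {
  path <- system.file("extdata", "aa_composition.tsv",
                      package = "AnchorMotif", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  p <- stats::setNames(tab$frequency, tab$residue)[.AA20]
  p / sum(p)
}

#' Generate i.i.d. background protein sequences
#'
#' @param n number of sequences
#' @param length residues per sequence (default 200, a terminal segment)
#' @param composition named residue frequencies (must sum to 1)
#' @param seed integer seed; the same seed reproduces the same set
#' @param prefix id prefix
#' @return named character vector of sequences
#' @export
#' @examples
#' generateBackground(2, length = 30, seed = 7)
generateBackground <- function(n, length = 200L,
                               composition = aaComposition(), seed = 1L,
                               prefix = "bg") {
  if (n < 1L) stop("n must be >= 1")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition must sum to 1")
  letters20 <- names(composition)
  if (is.null(letters20) || !all(letters20 %in% .AA20))
    stop("composition must be named by the 20 standard residues")
  set.seed(as.integer(seed))
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(letters20, length, replace = TRUE, prob = composition),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0(prefix, seq_len(n)))
}

#' Construct an implant design
#'
#' Builds the \code{\link{ImplantSpec}} for the synthetic benchmark: a
#' 20-residue artificial motif whose conserved core is the anchor "AA" and
#' whose flanks are drawn i.i.d. from a restricted residue set, with
#' frequencies equal to the background composition renormalized to that set
#' — \code{"hydrophobic"} uses {V,I,L,M,F,W,C}, \code{"hydrophobicCharged"}
#' adds the charged residues {K,R,D,E}, and \code{"random"} draws flanks from
#' the full background (no conserved flank, only the anchor).
#'
#' @param flank flank residue class (see above), or a custom character
#'   vector of residues
#' @param trueRatio fraction of positive sequences that receive an implant
#' @param anchorLiteral conserved core (default "AA")
#' @param totalLength implant length including the anchor (default 20;
#'   the flanks must split evenly around the anchor)
#' @param positionRange region of allowed implant locations, 1-based closed
#'   (default the first 100 residues)
#' @param composition background composition used to derive flank
#'   frequencies
#' @return an \code{\link{ImplantSpec}}
#' @export
implantSpec <- function(flank = c("hydrophobic", "hydrophobicCharged",
                                  "random"),
                        trueRatio = 1, anchorLiteral = "AA",
                        totalLength = 20L, positionRange = c(1L, 100L),
                        composition = aaComposition()) {
  alphabet <- if (is.character(flank) && length(flank) > 1L &&
                  all(flank %in% .AA20)) {
    flank
  } else {
    switch(match.arg(flank),
           hydrophobic = .hydrophobicSet,
           hydrophobicCharged = c(.hydrophobicSet, .chargedSet),
           random = .AA20)
  }
  probs <- composition[alphabet]
  probs <- probs / sum(probs)
  methods::new("ImplantSpec", anchorLiteral = toupper(anchorLiteral),
               totalLength = as.integer(totalLength),
               flankAlphabet = alphabet, flankProbs = unname(probs),
               positionRange = as.integer(positionRange),
               trueRatio = trueRatio)
}

#' Implant an artificial motif into a sequence set
#'
#' Exactly \code{round(trueRatio * n)} sequences (chosen uniformly at
#' random) receive one motif: equal-length flanks sampled i.i.d. from the
#' spec's flank distribution on both sides of the anchor, written into the
#' sequence by substitution (overwriting residues, so lengths and terminal
#' coordinates stay fixed) at a uniform start within the allowed position
#' range.
#'
#' @param x named character vector or \code{AAStringSet} of sequences, each
#'   at least as long as the position range
#' @param spec an \code{\link{ImplantSpec}}
#' @param seed integer seed
#' @return list with \code{sequences} (character, modified) and
#'   \code{truth}, a data.frame with \code{id}, \code{implanted},
#'   \code{start}, \code{end} (1-based closed interval of the implant, NA
#'   when not implanted)
#' @export
implantMotifs <- function(x, spec, seed = 1L) {
  seqs <- .asCharacterSeqs(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("pos", seq_along(seqs))
  n <- length(seqs)
  nImplant <- round(spec@trueRatio * n)
  if (nImplant < 1L) stop("trueRatio * n is below 1: nothing to implant")
  if (any(nchar(seqs) < spec@positionRange[2]))
    stop("sequences must span the implant position range")
  set.seed(as.integer(seed))
  chosen <- sort(sample.int(n, nImplant))
  flankLen <- (spec@totalLength - nchar(spec@anchorLiteral)) %/% 2L
  maxStart <- spec@positionRange[2] - spec@totalLength + 1L
  starts <- sample(seq.int(spec@positionRange[1], maxStart), nImplant,
                   replace = TRUE)
  for (k in seq_along(chosen)) {
    i <- chosen[k]
    motif <- paste0(
      paste(sample(spec@flankAlphabet, flankLen, replace = TRUE,
                   prob = spec@flankProbs), collapse = ""),
      spec@anchorLiteral,
      paste(sample(spec@flankAlphabet, flankLen, replace = TRUE,
                   prob = spec@flankProbs), collapse = ""))
    substr(seqs[i], starts[k], starts[k] + spec@totalLength - 1L) <- motif
  }
  truth <- data.frame(id = names(seqs),
                      implanted = seq_len(n) %in% chosen,
                      start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  truth$start[chosen] <- starts
  truth$end[chosen] <- starts + spec@totalLength - 1L
  list(sequences = seqs, truth = truth)
}

#' Run the implanted-motif benchmark
#'
#' For each condition (implant design plus removal on/off) and each
#' replicate, generates a fresh synthetic dataset (positives with implants,
#' i.i.d. background negatives of identical composition), runs the full
#' discovery pipeline for the implanted anchor, and records the detected
#' motif length, motif score, information content, the retained fraction of
#' the positive set and the overlap (Jaccard) between the detected interval
#' and the ground-truth implant. Dataset seeds derive from the global seed,
#' the flank class, the true ratio and the replicate index only, so a
#' with-removal condition and its without-removal contrast run on identical
#' datasets.
#'
#' @param conditions list of conditions; each a list with elements
#'   \code{flank} (see \code{\link{implantSpec}}), \code{trueRatio} and
#'   \code{removal} (logical)
#' @param replicates datasets per condition (default 3; 10 mirrors a full
#'   benchmark protocol)
#' @param seed global integer seed
#' @param nPos,nNeg positive/background set sizes (defaults 219/220)
#' @param seqLength sequence length (default 200)
#' @param fpConfig,boundConfig configuration templates (seeds are overridden
#'   per run)
#' @param minSupport anchor support threshold used to verify the implanted
#'   anchor is recoverable at all
#' @return list with \code{details} (one row per condition x replicate) and
#'   \code{summary} (mean and sd per condition)
#' @export
runBenchmark <- function(conditions, replicates = 3L, seed = 1L,
                         nPos = 219L, nNeg = 220L, seqLength = 200L,
                         fpConfig = fpRemovalConfig(),
                         boundConfig = boundaryConfig(),
                         minSupport = 0.3) {
  if (replicates < 1L) stop("replicates must be >= 1")
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    if (is.null(cond$flank) || is.null(cond$trueRatio) ||
        is.null(cond$removal))
      stop("each condition needs flank, trueRatio and removal")
    condName <- if (!is.null(cond$name)) cond$name else
      sprintf("%s_%d%%_%s", cond$flank, round(100 * cond$trueRatio),
              if (cond$removal) "removal" else "basic")
    spec <- implantSpec(flank = cond$flank, trueRatio = cond$trueRatio)
    for (r in seq_len(replicates)) {
      dataSeed <- .deriveSeed(seed, sprintf("data|%s|%d|%d", cond$flank,
                                            round(1000 * cond$trueRatio), r))
      pos <- generateBackground(nPos, seqLength, seed = dataSeed,
                                prefix = "pos")
      neg <- generateBackground(nNeg, seqLength,
                                seed = .deriveSeed(dataSeed, "neg"),
                                prefix = "neg")
      imp <- implantMotifs(pos, spec, seed = .deriveSeed(dataSeed, "implant"))
      anchor <- AnchorPattern(spec@anchorLiteral)
      res <- .runAnchorPipeline(
        imp$sequences, neg, anchor, removal = cond$removal,
        fpConfig = fpConfig, boundConfig = boundConfig,
        seed = .deriveSeed(dataSeed, sprintf("pipeline|%d", cond$removal)))
      jac <- .meanTruthJaccard(res, imp$truth)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condName, flank = cond$flank,
        trueRatio = cond$trueRatio, removal = cond$removal, replicate = r,
        seed = dataSeed, found = res$found,
        detectedLength = if (res$found) res$length else NA_integer_,
        motifScore = if (res$found) res$score else NA_real_,
        informationContent = if (res$found) res$ic else NA_real_,
        retainedFraction = res$retainedFraction,
        meanJaccard = jac, stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE)
                            else 0)
  summary <- do.call(rbind, lapply(split(details, details$condition), function(d) {
    data.frame(condition = d$condition[1], flank = d$flank[1],
               trueRatio = d$trueRatio[1], removal = d$removal[1],
               nFound = sum(d$found),
               meanLength = mean(d$detectedLength, na.rm = TRUE),
               sdLength = agg(d$detectedLength)[["sd"]],
               meanScore = mean(d$motifScore, na.rm = TRUE),
               sdScore = agg(d$motifScore)[["sd"]],
               meanIC = mean(d$informationContent, na.rm = TRUE),
               sdIC = agg(d$informationContent)[["sd"]],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(details = details, summary = summary)
}

# Mean per-sequence Jaccard between the detected interval and the
# ground-truth implant, over implanted sequences present in the final
# instance set.
.meanTruthJaccard <- function(res, truth) {
  if (!res$found) return(NA_real_)
  ids <- intersect(names(res$seats), truth$id[truth$implanted])
  if (!length(ids)) return(NA_real_)
  ti <- truth[match(ids, truth$id), ]
  detStart <- res$seats[ids] - res$leftExt
  detEnd <- res$seats[ids] + res$spans[ids] + res$rightExt - 1L
  inter <- pmax(0L, pmin(detEnd, ti$end) - pmax(detStart, ti$start) + 1L)
  union <- (detEnd - detStart + 1L) + (ti$end - ti$start + 1L) - inter
  mean(inter / union)
}
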