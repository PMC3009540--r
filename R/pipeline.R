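# End-to-end orchestration: preprocessing -> frequent anchors -> (optional)
# false-positive removal -> boundary determination -> motif scoring.

# Deterministic derivation of stage seeds from one global seed, so each
# stage is independently reproducible. Plain 31-ary string hash mod 2^31-1.
.deriveSeed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer(max(h, 1))
}

#' Pipeline configuration
#'
#' Collects every tunable of the discovery pipeline. A single global seed
#' deterministically derives all stage seeds.
#'
#' @param K terminal segment length (default 200)
#' @param ends which terminals to scan: \code{"N"}, \code{"C"} or both
#' @param anchorN,anchorM left/right anchor literal lengths
#' @param gapMin,gapMax anchor gap bounds
#' @param minSupport minimum fraction of positive sequences containing an
#'   anchor for it to be considered (default 0.3: the removal procedure
#'   tolerates substantial impurity, but anchors below ~30\% support are
#'   rarely recoverable)
#' @param redundancyThreshold identity threshold for redundancy reduction,
#'   or \code{NA} to skip (synthetic i.i.d. sets are non-redundant by
#'   construction)
#' @param topK how many ranked anchors to examine in depth
#' @param removal run iterative false-positive removal (default TRUE)
#' @param fpConfig see \code{\link{fpRemovalConfig}}
#' @param boundConfig see \code{\link{boundaryConfig}}
#' @param seed global integer seed
#' @return configuration list
#' @export
pipelineConfig <- function(K = 200L, ends = "N", anchorN = 2L, anchorM = 0L,
                           gapMin = 0L, gapMax = 0L, minSupport = 0.3,
                           redundancyThreshold = NA, topK = 5L,
                           removal = TRUE, fpConfig = fpRemovalConfig(),
                           boundConfig = boundaryConfig(), seed = 1L) {
  stopifnot(all(ends %in% c("N", "C")), topK >= 1L)
  list(K = as.integer(K), ends = ends, anchorN = as.integer(anchorN),
       anchorM = as.integer(anchorM), gapMin = as.integer(gapMin),
       gapMax = as.integer(gapMax), minSupport = minSupport,
       redundancyThreshold = redundancyThreshold, topK = as.integer(topK),
       removal = isTRUE(removal), fpConfig = fpConfig,
       boundConfig = boundConfig, seed = as.integer(seed))
}

# Run purification + boundary determination + scoring for one anchor on one
# pair of segment sets. Returns a flat result list (found, score, ic,
# length, extents, seats, instances, audit, retainedFraction).
.runAnchorPipeline <- function(posSegs, negSegs, anchor, removal, fpConfig,
                               boundConfig, seed, minClass = 10L) {
  posSegs <- .asCharacterSeqs(posSegs); negSegs <- .asCharacterSeqs(negSegs)
  if (is.null(names(posSegs))) names(posSegs) <- paste0("pos", seq_along(posSegs))
  hitIds <- unique(matchAnchor(anchor, posSegs)$id)
  notFound <- function(reason, retainedFraction = NA_real_, audit = NULL) {
    list(found = FALSE, reason = reason, score = NA_real_, ic = NA_real_,
         length = NA_integer_, leftExt = NA_integer_,
         rightExt = NA_integer_, seats = NULL, spans = NULL,
         instances = NULL, audit = audit,
         retainedFraction = retainedFraction)
  }
  if (length(hitIds) < max(minClass, boundConfig$folds))
    return(notFound("too few positive sequences contain the anchor"))
  posWith <- posSegs[hitIds]
  audit <- NULL
  seats <- NULL; spans <- NULL
  retainedFraction <- 1
  if (removal) {
    pur <- tryCatch(
      purifyPositives(posWith, negSegs, anchor,
                      config = utils::modifyList(
                        fpConfig, list(seed = .deriveSeed(seed, "purify")))),
      error = function(e) e)
    if (methods::is(pur, "error"))
      return(notFound(conditionMessage(pur), retainedFraction = 0))
    audit <- pur$audit
    retainedFraction <- length(pur$retainedIds) / length(posSegs)
    if (length(pur$retainedIds) < max(minClass, boundConfig$folds))
      return(notFound("purification removed too many sequences",
                      retainedFraction, audit))
    posWith <- posWith[pur$retainedIds]
    seats <- pur$seats; spans <- pur$spans
  }
  bd <- determineBoundaries(
    posWith, negSegs, anchor,
    config = utils::modifyList(boundConfig,
                               list(seed = .deriveSeed(seed, "boundary"))),
    seats = seats, spans = spans)
  if (!bd$found)
    return(notFound(sprintf("seat score %.3f below the boundary threshold",
                            bd$seatScore), retainedFraction, audit))
  spanUse <- as.integer(names(which.max(table(bd$spans))))
  useIds <- names(bd$spans)[bd$spans == spanUse]
  starts <- bd$seats[useIds] - bd$leftExt
  L <- bd$leftExt + spanUse + bd$rightExt
  lens <- nchar(posWith[useIds])
  ok <- starts >= 1L & starts + L - 1L <= lens
  useIds <- useIds[ok]
  if (length(useIds) < boundConfig$folds)
    return(notFound("too few full-length motif instances",
                    retainedFraction, audit))
  instances <- substring(posWith[useIds], starts[ok], starts[ok] + L - 1L)
  names(instances) <- useIds
  sc <- motifRegionScore(instances, negSegs, anchor = anchor,
                         leftExt = bd$leftExt,
                         folds = boundConfig$folds,
                         alpha = boundConfig$alpha,
                         seed = .deriveSeed(seed, "score"))
  ic <- informationContent(instances)
  pw <- buildPWM(instances)
  motif <- methods::new(
    "MotifModel", anchor = anchor, anchorSpan = spanUse,
    leftExt = as.integer(bd$leftExt), rightExt = as.integer(bd$rightExt),
    instances = Biostrings::AAStringSet(instances), pwm = pw$pwm,
    consensus = pw$consensus, motifScore = sc@minPR,
    informationContent = ic)
  list(found = TRUE, reason = NA_character_, score = sc@minPR, ic = ic,
       length = L, leftExt = bd$leftExt, rightExt = bd$rightExt,
       seats = bd$seats[useIds], spans = bd$spans[useIds],
       instances = instances, audit = audit, cv = sc, motif = motif,
       retainedFraction = retainedFraction, boundary = bd)
}

#' Discover anchored sorting motifs
#'
#' The full pipeline: (optional) redundancy reduction, terminal-segment
#' extraction, exhaustive frequent-anchor enumeration, and — per top-ranked
#' anchor — iterative false-positive removal, sliding-window boundary
#' determination and cross-validated motif scoring. Motifs are returned
#' ranked by motif score.
#'
#' @param dataset a \code{\link{SortingDataset}}
#' @param config see \code{\link{pipelineConfig}}
#' @return list with \code{status} (\code{"ok"} or \code{"no-motif"}),
#'   \code{motifs} (list of \code{\link{MotifModel}}, score-ranked),
#'   \code{anchors} (per-terminal anchor tables), \code{audits}
#'   (removal audits per anchor), and \code{config}
#' @export
#' @examples
#' \donttest{
#' pos <- generateBackground(30, 120, seed = 1, prefix = "p")
#' imp <- implantMotifs(pos, implantSpec("hydrophobic"), seed = 2)
#' neg <- generateBackground(30, 120, seed = 3, prefix = "n")
#' ds <- SortingDataset(positive = imp$sequences, negative = neg)
#' res <- discoverMotifs(ds, pipelineConfig(K = 120, removal = FALSE))
#' res$motifs[[1]]
#' }
discoverMotifs <- function(dataset, config = pipelineConfig()) {
  stopifnot(methods::is(dataset, "SortingDataset"))
  if (!is.na(config$redundancyThreshold))
    dataset <- reduceRedundancy(dataset, config$redundancyThreshold)$sequences
  motifs <- list(); audits <- list(); anchorTables <- list()
  for (end in config$ends) {
    posSegs <- as.character(extractTerminal(positiveSet(dataset), end,
                                            config$K))
    negSegs <- as.character(extractTerminal(negativeSet(dataset), end,
                                            config$K))
    tab <- enumerateAnchors(posSegs, negSegs, n = config$anchorN,
                            m = config$anchorM, gapMin = config$gapMin,
                            gapMax = config$gapMax,
                            minSupport = config$minSupport)
    anchorTables[[end]] <- tab
    if (nrow(tab) == 0L) next
    anchors <- rankAnchors(tab, config$topK)
    for (anchor in anchors) {
      lab <- paste0(end, ":", anchorLiteral(anchor))
      res <- .runAnchorPipeline(
        posSegs, negSegs, anchor, removal = config$removal,
        fpConfig = config$fpConfig, boundConfig = config$boundConfig,
        seed = .deriveSeed(config$seed, lab))
      if (!is.null(res$audit)) audits[[lab]] <- res$audit
      if (res$found) motifs[[lab]] <- res$motif
    }
  }
  if (length(motifs)) {
    motifs <- motifs[order(-vapply(motifs, motifScore, numeric(1)))]
  }
  list(status = if (length(motifs)) "ok" else "no-motif", motifs = motifs,
       anchors = anchorTables, audits = audits, config = config)
}

#' Serialize discovered motifs to JSON
#'
#' Writes anchor literal, extents, length, motif score, information content,
#' consensus and the PWM for each motif. Numeric values are rounded to 9
#' digits so reruns with the same seed produce byte-identical files.
#'
#' @param motifs list of \code{\link{MotifModel}}s (or one)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
motifsToJson <- function(motifs, path) {
  if (methods::is(motifs, "MotifModel")) motifs <- list(motifs)
  payload <- lapply(motifs, function(m) {
    list(anchor = anchorLiteral(m@anchor),
         anchorSpan = m@anchorSpan,
         leftExt = m@leftExt, rightExt = m@rightExt,
         length = motifLength(m),
         motifScore = round(m@motifScore, 9),
         informationContent = round(m@informationContent, 9),
         consensus = m@consensus,
         nInstances = length(m@instances),
         pwm = round(unname(m@pwm), 9))
  })
  names(payload) <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an anchor table as TSV
#'
#' @param table an anchor table from \code{\link{enumerateAnchors}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeAnchorTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a removal audit as TSV
#'
#' @param audit an audit data.frame from \code{\link{purifyPositives}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeRemovalAudit <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
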