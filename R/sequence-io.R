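#' Read a labeled FASTA file
#'
#' Reads protein sequences from FASTA, takes the first whitespace-delimited
#' token of each header as the record id, and sanitizes residues: every
#' letter outside the 20-letter standard alphabet (B, J, O, U, Z and any
#' other ambiguity code) is mapped to 'X'. The number of substituted residues
#' is reported with a message.
#'
#' @param path path to a FASTA file
#' @param label class label for every record in the file, \code{"positive"}
#'   or \code{"negative"}
#' @return a named sanitized \code{AAStringSet} with a \code{"label"}
#'   attribute; combine a positive and a negative set into a
#'   \code{\link{SortingDataset}} with \code{SortingDataset()}.
#' @seealso [SortingDataset()]
#' @export
readFastaDataset <- function(path, label = c("positive", "negative")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("cannot parse FASTA file ", path,
                                            ": ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("no parseable records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("record with an empty header in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate record id: ", dup[1L])
  chr <- as.character(seqs)
  if (any(nchar(chr) == 0L))
    stop("record '", ids[which(nchar(chr) == 0L)[1L]], "' has empty residues")
  san <- .sanitizeResidues(chr)
  if (san$nSubstituted > 0L)
    message(sprintf("sanitized %d non-standard residue(s) to 'X' in %s",
                    san$nSubstituted, path))
  out <- Biostrings::AAStringSet(san$residues)
  names(out) <- ids
  attr(out, "label") <- label
  out
}

#' Extract N- or C-terminal segments
#'
#' Most sorting signals lie within the terminal 200 residues, so discovery
#' runs on terminal segments: the first (N) or last (C) \code{K} residues of
#' each sequence, or the whole sequence when shorter than \code{K}.
#'
#' @param x an \code{AAStringSet}, character vector, or
#'   \code{\link{SortingDataset}}
#' @param end which terminal, \code{"N"} (prefix) or \code{"C"} (suffix)
#' @param K segment length in residues (default 200)
#' @return object of the same class as \code{x} with truncated sequences
#' @export
#' @examples
#' extractTerminal(c(a = "MKRILLAGDE"), end = "C", K = 3)
extractTerminal <- function(x, end = c("N", "C"), K = 200L) {
  end <- match.arg(end)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (methods::is(x, "SortingDataset")) {
    out <- x
    out@sequences <- extractTerminal(x@sequences, end = end, K = K)
    methods::validObject(out)
    return(out)
  }
  chr <- is.character(x)
  if (chr) x <- Biostrings::AAStringSet(x)
  w <- Biostrings::width(x)
  keep <- pmin(w, K)
  out <- if (end == "N") Biostrings::subseq(x, start = 1L, width = keep)
         else Biostrings::subseq(x, start = w - keep + 1L, width = keep)
  if (chr) as.character(out) else out
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match score 1, mismatch 0 and
#' linear gap penalty -1 (identity, not similarity, is what a redundancy
#' threshold means). Identity is the number of identical aligned positions
#' divided by the alignment length including gap columns; with
#' \code{denominator = "shorter"} the CD-HIT convention (length of the
#' shorter sequence) is used instead.
#'
#' @param a,b residue strings (or \code{AAString}s), non-empty
#' @param denominator \code{"alignment"} (default) or \code{"shorter"}
#' @return identity fraction in [0, 1]
#' @export
#' @examples
#' pairwiseIdentity("AAAA", "AAAC")  # 0.75
#' pairwiseIdentity("AA", "AAAA")    # 0.5: alignment length 4, 2 matches
pairwiseIdentity <- function(a, b, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = .identityMatrix(),
    gapOpening = 0, gapExtension = 1)
  den <- switch(denominator,
                alignment = nchar(as.character(Biostrings::alignedPattern(aln))),
                shorter = min(nchar(a), nchar(b)))
  Biostrings::nmatch(aln) / den
}

.identityMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- diag(1, length(.AAX))
      dimnames(m) <- list(.AAX, .AAX)
      cache <<- m
    }
    cache
  }
})

#' Greedy redundancy reduction
#'
#' CD-HIT-style greedy clustering: sequences are visited in order of
#' decreasing length (ties broken by id); each sequence joins the first
#' existing cluster whose representative it matches at identity >=
#' \code{threshold}, otherwise it founds a new cluster. Only representatives
#' ("pivots") are kept, so retained sequences are pairwise below the
#' threshold by construction. Redundant training sequences bias classifiers
#' and inflate cross-validation estimates, hence this preprocessing step.
#'
#' @param x an \code{AAStringSet}, named character vector, or
#'   \code{\link{SortingDataset}} (clustered jointly across both classes)
#' @param threshold identity threshold in (0, 1]; the conventional value for
#'   protein sets is 0.8
#' @param denominator identity denominator convention, see
#'   \code{\link{pairwiseIdentity}}
#' @return a list with \code{sequences} (same class as \code{x}, only
#'   representatives) and \code{report}, a data.frame with columns
#'   \code{removed_id}, \code{representative_id}, \code{identity}
#' @export
#' @examples
#' r <- reduceRedundancy(c(a = "MKRILK", b = "MKRILK", c = "GGGGGG"),
#'                       threshold = 0.8)
#' names(r$sequences); r$report
reduceRedundancy <- function(x, threshold = 0.8,
                             denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  isDS <- methods::is(x, "SortingDataset")
  seqs <- if (isDS) as.character(x@sequences) else .asCharacterSeqs(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  reps <- integer(0)                      # indices into seqs
  removed <- character(0); repOf <- character(0); ident <- numeric(0)
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      pid <- pairwiseIdentity(seqs[[i]], seqs[[r]], denominator = denominator)
      if (pid >= threshold) {
        removed <- c(removed, names(seqs)[i])
        repOf <- c(repOf, names(seqs)[r])
        ident <- c(ident, pid)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) reps <- c(reps, i)
  }
  keep <- sort(reps)
  report <- data.frame(removed_id = removed, representative_id = repOf,
                       identity = ident, stringsAsFactors = FALSE)
  sequences <- if (isDS) {
    methods::new("SortingDataset", sequences = x@sequences[keep],
                 label = x@label[keep])
  } else if (methods::is(x, "XStringSet")) x[keep] else seqs[keep]
  list(sequences = sequences, report = report)
}

#' Write a redundancy-reduction cluster report as TSV
#'
#' @param report the \code{report} component of
#'   \code{\link{reduceRedundancy}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeClusterReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
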