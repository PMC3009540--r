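#' @import methods
NULL

#' @rdname SortingDataset-class
#' @param x a \code{SortingDataset}
#' @export
setGeneric("positiveSet", function(x) standardGeneric("positiveSet"))

#' @rdname SortingDataset-class
#' @export
setGeneric("negativeSet", function(x) standardGeneric("negativeSet"))

#' @rdname SortingDataset-class
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))

#' @rdname SortingDataset-class
#' @export
setGeneric("nNegative", function(x) standardGeneric("nNegative"))

#' @rdname AnchorPattern-class
#' @param x an \code{AnchorPattern}
#' @export
setGeneric("anchorLiteral", function(x) standardGeneric("anchorLiteral"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifScore", function(x) standardGeneric("motifScore"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifInstances", function(x) standardGeneric("motifInstances"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifPWM", function(x) standardGeneric("motifPWM"))

#' Motif conservation as Shannon information content
#'
#' For a set of aligned, equal-length motif instances the information content
#' is \deqn{IC = \sum_{j=1}^{L} (\log_2 20 - H_j),\qquad
#'   H_j = -\sum_{i} p_j(i)\log_2 p_j(i),}
#' where \eqn{p_j(i)} is the observed frequency of residue \eqn{i} at column
#' \eqn{j} (no pseudocount; \eqn{0\log 0 = 0}); 'X' residues are excluded from
#' a column's counts. A fully conserved column contributes
#' \eqn{\log_2 20 \approx 4.32} bits. For a \code{MotifModel} the stored value
#' is returned.
#'
#' @param x aligned instances (character vector or \code{AAStringSet} of equal
#'   widths, at least 2 of them), or a \code{MotifModel}
#' @return information content in bits
#' @export
#' @examples
#' informationContent(c("AA", "AA", "AA"))   # two conserved columns
setGeneric("informationContent", function(x) standardGeneric("informationContent"))
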