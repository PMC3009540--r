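# Residue alphabet and integer encoding shared by every module.
#
# The 20 standard amino acids plus 'X' for any ambiguity code (B, J, O, U, Z
# and anything else non-standard is collapsed to 'X' on input). Internally a
# sequence is an integer vector with codes 1..20 for the standard residues
# and 21 for 'X'; code 21 is excluded from counts when models are trained and
# contributes a flat 1/20 likelihood to both classes when windows are scored.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AAX <- c(.AA20, "X")
.XCODE <- 21L

# byte lookup table: ASCII code -> residue code (0 for anything unexpected)
.AALUT <- local({
  lut <- integer(256)
  lut[utf8ToInt(paste(.AAX, collapse = ""))] <- seq_along(.AAX)
  lut
})

#' Standard amino-acid alphabet
#'
#' @return Character vector of the 20 standard one-letter residue codes
#'   (alphabetical order); this is the column order of every PWM produced by
#'   the package.
#' @export
#' @examples
#' aminoAcidAlphabet()
aminoAcidAlphabet <- function() .AA20

# Sanitize raw residue strings: uppercase, map every character outside the
# 20-letter alphabet (B, J, O, U, Z, ambiguity codes, ...) to 'X'.
# Returns list(residues = character vector, nSubstituted = total count).
.sanitizeResidues <- function(x) {
  x <- toupper(x)
  nonstd <- sprintf("[^%sX]", paste(.AA20, collapse = ""))
  hits <- gregexpr(nonstd, x)
  nSub <- sum(vapply(hits, function(m) sum(m > 0L), integer(1)))
  list(residues = gsub(nonstd, "X", x), nSubstituted = nSub)
}

.encodeResidues <- function(s) {
  code <- .AALUT[utf8ToInt(s)]
  code[code == 0L] <- .XCODE
  code
}

.decodeResidues <- function(code) {
  paste(.AAX[code], collapse = "")
}

# Encode a character vector / AAStringSet into the internal segment-set
# representation used by the classifier loops.
.encodeSet <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  list(ids = ids,
       seq = lapply(unname(x), .encodeResidues),
       len = unname(nchar(x)))
}

.asCharacterSeqs <- function(x) {
  if (methods::is(x, "XStringSet")) as.character(x) else x
}
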