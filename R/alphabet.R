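#' The 20 canonical amino acids
#'
#' Single-letter codes, in the conventional alphabetical order used for all
#' emission tables in this package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Encode an amino-acid string as alphabet indices
#'
#' Rejects any character outside the 20 canonical residues, naming the
#' offending character and its position.
#'
#' @param seq Single amino-acid string.
#' @return Integer vector of indices into [AA_ALPHABET].
#' @keywords internal
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad], bad))
  }
  idx
}

split_seq <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]
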