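#' Read a multi-FASTA file
#'
#' Identifiers are preserved (first whitespace-delimited token of the
#' header). Residue validation is deferred to the consumers, so records with
#' non-canonical characters parse fine here and fail only where the alphabet
#' matters.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA record at line ", nonblank[1L],
         ": expected a '>' header")
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write sequences as multi-FASTA
#'
#' Sequence lines are wrapped at 60 columns.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

.model_format_version <- "1.0"

#' Serialize an HMM to versioned JSON
#'
#' @param hmm An [hmm_spec()].
#' @param path Output path.
#' @param provenance Optional named list recorded verbatim (seeds,
#'   thresholds, build parameters...).
#' @export
write_hmm_json <- function(hmm, path, provenance = NULL) {
  states <- lapply(seq_along(hmm$id), function(i) {
    tr <- hmm$transitions[i, ]
    tr <- tr[tr > 0]
    st <- list(id = hmm$id[i], kind = hmm$kind[i],
               transitions = as.list(tr))
    if (!(hmm$kind[i] %in% c("START", "END")))
      st$emissions <- as.list(stats::setNames(hmm$emissions[i, ], AA_ALPHABET))
    if (!is.na(hmm$template_position[i]))
      st$template_position <- hmm$template_position[i]
    st
  })
  jsonlite::write_json(
    list(format = "fibrilHMM-model", version = .model_format_version,
         template_id = hmm$template_id,
         start_state = hmm$start_state, end_state = hmm$end_state,
         states = states, provenance = provenance),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read an HMM from versioned JSON
#'
#' Refuses files whose major format version differs from the current one.
#'
#' @param path Path written by [write_hmm_json()].
#' @return A validated [hmm_spec()].
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "fibrilHMM-model"))
    stop("not a fibrilHMM model file: ", path)
  if (major_version(x$version) != major_version(.model_format_version))
    stop("model format version ", x$version,
         " is incompatible with this package (expected major ",
         major_version(.model_format_version), ")")
  ids <- vapply(x$states, `[[`, character(1), "id")
  kinds <- vapply(x$states, `[[`, character(1), "kind")
  n <- length(ids)
  em <- matrix(0, n, 20L)
  tr <- matrix(0, n, n)
  tpos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    st <- x$states[[i]]
    if (!is.null(st$emissions))
      em[i, ] <- unlist(st$emissions)[AA_ALPHABET]
    if (length(st$transitions))
      tr[i, match(names(st$transitions), ids)] <- unlist(st$transitions)
    if (!is.null(st$template_position))
      tpos[i] <- as.integer(st$template_position)
  }
  validate_hmm(hmm_spec(ids, kinds, em, tr, x$start_state, x$end_state,
                        tpos, template_id = x$template_id))
}
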