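#' Template definition
#'
#' Describes one amyloid fibril template: the consensus sequence of
#' structurally resolved residues on one chain of one fibril layer, the
#' author-numbered residue intervals present in the structure, the numbering
#' gaps between them (structurally unresolved segments), and the
#' complementarity-determining-region (CDR) intervals in consensus
#' coordinates. CDR intervals are never inferred from the structure; they are
#' part of the per-template annotation.
#'
#' @param template_id Template identifier (e.g. a PDB id).
#' @param consensus Amino-acid string of the resolved residues, in order.
#' @param segments Data frame with columns `start`, `end`: disjoint, ordered
#'   author-residue-number intervals whose total length equals
#'   `nchar(consensus)`.
#' @param missing_segments Data frame with columns `after` (consensus position
#'   after which the gap opens) and `length` (number of unresolved residues,
#'   `NA` when unknown). May have zero rows.
#' @param cdr_intervals Data frame with columns `start`, `end` in 1-based
#'   consensus coordinates; non-overlapping. May have zero rows.
#' @param structure_path Path of the source coordinate file (may be `NA`).
#' @param chain Chain identifier the consensus was read from.
#' @return An object of class `template_definition`.
#' @export
template_definition <- function(template_id, consensus, segments,
                                missing_segments = empty_missing(),
                                cdr_intervals = empty_intervals(),
                                structure_path = NA_character_,
                                chain = NA_character_) {
  stopifnot(is.character(consensus), length(consensus) == 1L, nzchar(consensus))
  encode_seq(consensus)  # canonical alphabet only
  segments <- as.data.frame(segments)
  missing_segments <- as.data.frame(missing_segments)
  cdr_intervals <- as.data.frame(cdr_intervals)
  L <- nchar(consensus)
  if (nrow(segments) == 0L) stop("at least one segment is required")
  if (any(segments$end < segments$start))
    stop("segment end before start")
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)]))
    stop("segments must be ordered and disjoint")
  if (sum(segments$end - segments$start + 1L) != L)
    stop("segments must concatenate to the consensus length (",
         sum(segments$end - segments$start + 1L), " vs ", L, ")")
  seg_len <- segments$end - segments$start + 1L
  seg_last_cons <- cumsum(seg_len)          # consensus position ending each segment
  if (nrow(missing_segments)) {
    if (!all(missing_segments$after %in% seg_last_cons[-length(seg_last_cons)]))
      stop("missing_segments$after must be the consensus position ending a segment")
  }
  if (nrow(cdr_intervals)) {
    if (any(cdr_intervals$start < 1L) || any(cdr_intervals$end > L) ||
        any(cdr_intervals$end < cdr_intervals$start))
      stop("cdr_intervals must lie within the consensus")
    o <- order(cdr_intervals$start)
    cdr_intervals <- cdr_intervals[o, , drop = FALSE]
    if (nrow(cdr_intervals) > 1L &&
        any(cdr_intervals$start[-1L] <= cdr_intervals$end[-nrow(cdr_intervals)]))
      stop("cdr_intervals must not overlap")
  }
  structure(
    list(template_id = template_id, consensus = consensus,
         segments = segments, missing_segments = missing_segments,
         cdr_intervals = cdr_intervals,
         structure_path = structure_path, chain = chain),
    class = "template_definition")
}

#' @export
print.template_definition <- function(x, ...) {
  cat(sprintf("<template_definition> %s: %d residues, %d segment(s), %d missing, %d CDR(s)\n",
              x$template_id, nchar(x$consensus), nrow(x$segments),
              nrow(x$missing_segments), nrow(x$cdr_intervals)))
  invisible(x)
}

empty_intervals <- function() data.frame(start = integer(0), end = integer(0))
empty_missing <- function() data.frame(after = integer(0), length = integer(0))

#' Map consensus positions to author residue numbers
#'
#' @param template A [template_definition()].
#' @return Integer vector of length `nchar(consensus)`; element `k` is the
#'   author residue number of consensus position `k`.
#' @export
consensus_to_resno <- function(template) {
  with(template$segments, unlist(Map(seq.int, start, end), use.names = FALSE))
}

#' Parse a fibril template structure into a template definition
#'
#' Reads a PDB file, selects one chain of one fibril layer, and builds the
#' consensus from residues that have backbone (C-alpha) coordinates. A jump
#' greater than one in author residue numbering opens a missing segment whose
#' length is the numbering gap. CDR intervals are not inferred here; attach
#' them from the template annotation (see [read_template_config()]).
#'
#' @param structure_path Path to a PDB file.
#' @param chain_selector Chain identifier.
#' @param template_id Template identifier; defaults to the file stem.
#' @return A [template_definition()] with empty `cdr_intervals`.
#' @export
parse_template_structure <- function(structure_path, chain_selector,
                                     template_id = NULL) {
  if (is.null(template_id))
    template_id <- tools::file_path_sans_ext(basename(structure_path))
  pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
  atoms <- pdb$atom
  ca <- atoms[atoms$type %in% c("ATOM", "HETATM") & atoms$elety == "CA" &
                atoms$chain == chain_selector, , drop = FALSE]
  if (nrow(ca) == 0L) {
    have <- sort(unique(atoms$chain))
    stop("chain '", chain_selector, "' not found in ", structure_path,
         " (available: ", paste(have, collapse = ", "), ")")
  }
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  aa1 <- bio3d::aa321(ca$resid)
  bad <- !(aa1 %in% AA_ALPHABET)
  if (any(bad))
    stop("non-standard residues without a canonical mapping: ",
         paste(unique(ca$resid[bad]), collapse = ", "))
  resno <- ca$resno
  breaks <- which(diff(resno) > 1L)
  seg_start <- resno[c(1L, breaks + 1L)]
  seg_end <- resno[c(breaks, length(resno))]
  segments <- data.frame(start = seg_start, end = seg_end)
  if (length(breaks)) {
    missing <- data.frame(
      after = cumsum(seg_end - seg_start + 1L)[seq_along(breaks)],
      length = resno[breaks + 1L] - resno[breaks] - 1L)
  } else missing <- empty_missing()
  template_definition(template_id, paste(aa1, collapse = ""), segments,
                      missing, empty_intervals(), structure_path,
                      chain_selector)
}

#' Read a template annotation config and build its template definition
#'
#' The annotation is a JSON object with fields `template_id`,
#' `structure_path` (resolved relative to the config file), `chain`,
#' `cdr_intervals` (array of `[start, end]` pairs, 1-based inclusive,
#' consensus coordinates) and optional `segments` overrides (array of
#' `[start, end]` author-numbering pairs).
#'
#' @param config_path Path to the JSON annotation.
#' @return A [template_definition()] with CDR intervals attached.
#' @export
read_template_config <- function(config_path) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (f in c("template_id", "structure_path", "chain"))
    if (is.null(cfg[[f]])) stop("template config misses field '", f, "'")
  spath <- cfg$structure_path
  if (!file.exists(spath))
    spath <- file.path(dirname(config_path), cfg$structure_path)
  tmpl <- parse_template_structure(spath, cfg$chain, cfg$template_id)
  if (!is.null(cfg$segments) && length(cfg$segments)) {
    seg <- as.data.frame(cfg$segments)
    names(seg) <- c("start", "end")
    tmpl$segments <- seg
  }
  if (!is.null(cfg$cdr_intervals) && length(cfg$cdr_intervals)) {
    cdr <- cfg$cdr_intervals
    if (is.matrix(cdr)) cdr <- data.frame(start = cdr[, 1], end = cdr[, 2])
    else cdr <- data.frame(start = vapply(cdr, `[[`, numeric(1), 1),
                           end = vapply(cdr, `[[`, numeric(1), 2))
    tmpl <- template_definition(tmpl$template_id, tmpl$consensus,
                                tmpl$segments, tmpl$missing_segments,
                                cdr, tmpl$structure_path, tmpl$chain)
  }
  tmpl
}
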