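#' Prune a template backbone to the aligned region
#'
#' Removes, on every chain of the fibril stack, all atoms of template
#' residues whose consensus positions are not covered by the alignment's
#' MATCH pairs. Retained ATOM/HETATM records are copied verbatim from the
#' input file, so coordinates (and every other field) of kept residues are
#' unchanged byte for byte.
#'
#' @param structure_path Path of the template PDB file.
#' @param alignment An `alignment_result` (see [align_to_template()]) against
#'   this template; must be non-degenerate.
#' @param template The [template_definition()] of the template.
#' @param chains Optional character vector restricting which chains are kept
#'   in the output; default keeps every chain.
#' @return An object of class `pruned_structure`: `lines` (pruned PDB text),
#'   `mapping` (data frame `chain`, `resno`, `consensus_position`,
#'   `query_position`, `template_res`), `kept_resno`, `removed_per_chain`.
#' @export
prune_backbone <- function(structure_path, alignment, template, chains = NULL) {
  stopifnot(inherits(alignment, "alignment_result"))
  if (!nrow(alignment$pairs))
    stop("degenerate alignment: nothing to prune against")
  resno_map <- consensus_to_resno(template)
  L <- nchar(template$consensus)
  if (any(alignment$pairs$template_position < 1L |
            alignment$pairs$template_position > L))
    stop("alignment references consensus positions outside the template")
  keep_cons <- alignment$pairs$template_position
  keep_resno <- resno_map[keep_cons]

  pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
  atoms <- pdb$atom
  all_chains <- unique(atoms$chain)
  if (is.null(chains)) chains <- all_chains
  missing_chain <- setdiff(chains, all_chains)
  if (length(missing_chain))
    stop("chains not in structure: ", paste(missing_chain, collapse = ", "))
  for (ch in chains) {
    have <- unique(atoms$resno[atoms$chain == ch])
    absent <- setdiff(keep_resno, have)
    if (length(absent))
      stop("alignment references residues absent from chain ", ch, ": ",
           paste(absent, collapse = ", "))
  }

  lines <- readLines(structure_path)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  line_chain <- substr(lines, 22L, 22L)
  line_resno <- suppressWarnings(as.integer(substr(lines, 23L, 26L)))
  keep_line <- !is_atom |
    (line_chain %in% chains & line_resno %in% keep_resno)
  drop_other_chain <- is_atom & !(line_chain %in% chains)
  keep_line[drop_other_chain] <- FALSE
  pruned <- lines[keep_line]

  cons_chars <- split_seq(template$consensus)
  qpos <- alignment$pairs$sequence_position
  mapping <- do.call(rbind, lapply(chains, function(ch)
    data.frame(chain = ch, resno = keep_resno,
               consensus_position = keep_cons, query_position = qpos,
               template_res = cons_chars[keep_cons])))
  removed <- vapply(chains, function(ch) {
    have <- unique(atoms$resno[atoms$chain == ch])
    length(setdiff(have, keep_resno))
  }, integer(1))
  structure(list(lines = pruned, mapping = mapping,
                 kept_resno = keep_resno, removed_per_chain = removed,
                 structure_path = structure_path, chains = chains),
            class = "pruned_structure")
}

#' @export
print.pruned_structure <- function(x, ...) {
  cat(sprintf("<pruned_structure> %d residues kept on %d chain(s), removed per chain: %s\n",
              length(x$kept_resno), length(x$chains),
              paste(x$removed_per_chain, collapse = ", ")))
  invisible(x)
}

#' Write a pruned structure to a PDB file
#' @param pruned A [prune_backbone()] result.
#' @param path Output path.
#' @export
write_pruned_pdb <- function(pruned, path) {
  writeLines(pruned$lines, path)
  invisible(path)
}

#' Emit a side-chain modeling job
#'
#' Prepares the inputs for an external force field's model-building command:
#' the pruned backbone in PDB format, a mutation list in the
#' individual-list dialect (semicolon-terminated tokens
#' `<wt-residue><chain><residue-number><mutant-residue>`, one list per
#' line), and a JSON job manifest. Positions where the query residue equals
#' the template residue are omitted; mutations are applied symmetrically to
#' every retained chain of the fibril stack.
#'
#' @param pruned A [prune_backbone()] result.
#' @param alignment The `alignment_result` used for the pruning.
#' @param query_seq Query amino-acid string.
#' @param out_prefix Path prefix; writes `<prefix>_pruned.pdb`,
#'   `<prefix>_individual_list.txt` and `<prefix>_job.json`.
#' @return An object of class `sidechain_job`: `mutations` (data frame
#'   `wt`, `chain`, `resno`, `mut`), `files`, `job_type`.
#' @export
emit_sidechain_job <- function(pruned, alignment, query_seq, out_prefix) {
  stopifnot(inherits(pruned, "pruned_structure"))
  encode_seq(query_seq)  # reject non-canonical residues
  qchars <- split_seq(query_seq)
  if (max(alignment$pairs$sequence_position) > length(qchars))
    stop("alignment references positions beyond the query length")
  map <- pruned$mapping
  map$query_res <- qchars[map$query_position]
  mut <- map[map$query_res != map$template_res, , drop = FALSE]
  mutations <- data.frame(wt = mut$template_res, chain = mut$chain,
                          resno = mut$resno, mut = mut$query_res,
                          stringsAsFactors = FALSE)

  pdb_path <- paste0(out_prefix, "_pruned.pdb")
  list_path <- paste0(out_prefix, "_individual_list.txt")
  manifest_path <- paste0(out_prefix, "_job.json")
  write_pruned_pdb(pruned, pdb_path)
  tokens <- sprintf("%s%s%d%s", mutations$wt, mutations$chain,
                    mutations$resno, mutations$mut)
  writeLines(if (length(tokens)) paste0(paste(tokens, collapse = ";"), ";")
             else "", list_path)
  jsonlite::write_json(
    list(job_type = "BuildModel", pdb = basename(pdb_path),
         mutant_file = basename(list_path),
         n_mutations = nrow(mutations),
         chains = pruned$chains),
    manifest_path, auto_unbox = TRUE, digits = NA)
  structure(list(mutations = mutations, job_type = "BuildModel",
                 files = c(pdb = pdb_path, mutant_file = list_path,
                           manifest = manifest_path)),
            class = "sidechain_job")
}

#' Read an individual-list mutation file
#'
#' Parses the semicolon-terminated `<wt><chain><number><mutant>` tokens
#' written by [emit_sidechain_job()].
#'
#' @param path Path of the mutation list.
#' @return Data frame with columns `wt`, `chain`, `resno`, `mut` (zero rows
#'   for an empty list).
#' @export
read_mutation_list <- function(path) {
  lines <- readLines(path)
  tokens <- unlist(strsplit(lines[nzchar(lines)], ";", fixed = TRUE))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    return(data.frame(wt = character(0), chain = character(0),
                      resno = integer(0), mut = character(0)))
  m <- regmatches(tokens, regexec("^([A-Z])([A-Za-z0-9])([0-9]+)([A-Z])$", tokens))
  bad <- lengths(m) != 5L
  if (any(bad)) stop("malformed mutation token: ", tokens[which(bad)[1L]])
  data.frame(wt = vapply(m, `[[`, character(1), 2L),
             chain = vapply(m, `[[`, character(1), 3L),
             resno = as.integer(vapply(m, `[[`, character(1), 4L)),
             mut = vapply(m, `[[`, character(1), 5L))
}
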