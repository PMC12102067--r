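#' Decode a Viterbi path into an alignment result
#'
#' Maps MATCH states of the best state path to `(template_position,
#' sequence_position)` pairs, tabulates insertion/deletion events inside
#' CDRs and residues absorbed over missing structural segments, counts the
#' unaligned terminal flanks, and computes gapless coverage.
#'
#' Coverage is the number of template consensus positions aligned through
#' MATCH states divided by the template consensus length (positions skipped
#' by the local entry/exit transitions or by CDR deletions are not covered;
#' CDR indels do not break the constant, structure-bearing segments). Set
#' `coverage_denominator = "sequence"` for the alternative convention that
#' divides by the query length.
#'
#' @param model An [hmm_spec()] built from `template`.
#' @param calibrator A fitted [fit_calibrator()] result, or `NULL` to skip
#'   calibration.
#' @param template The [template_definition()] the model was built from.
#' @param seq Query amino-acid string.
#' @param n_shuffles,rng_seed Passed to [raw_score()].
#' @param coverage_denominator `"template"` (default) or `"sequence"`.
#' @return A list with `alignment` (class `alignment_result`: `template_id`,
#'   `pairs`, `cdr_indels`, `segment_gap_residues`, `flank_lengths`,
#'   `coverage`, `logprob`) and `report` (a [score_report()]).
#' @export
align_to_template <- function(model, calibrator, template, seq,
                              n_shuffles = 100L, rng_seed = 1L,
                              coverage_denominator = c("template", "sequence")) {
  coverage_denominator <- match.arg(coverage_denominator)
  vt <- hmm_viterbi(model, seq)
  report <- raw_score(model, seq, n_shuffles, rng_seed)
  if (!is.null(calibrator)) report <- calibrated_score(calibrator, report)
  aln <- decode_alignment(vt, template, nchar(seq), coverage_denominator)
  list(alignment = aln, report = report)
}

decode_alignment <- function(vt, template, seq_len, coverage_denominator) {
  L <- nchar(template$consensus)
  if (!length(vt$path)) {
    return(structure(list(template_id = template$template_id,
                          pairs = data.frame(template_position = integer(0),
                                             sequence_position = integer(0)),
                          cdr_indels = empty_indels(),
                          segment_gap_residues = integer(0),
                          flank_lengths = c(n = 0L, c = 0L),
                          coverage = 0, logprob = -Inf),
                     class = "alignment_result"))
  }
  kind <- vt$kind
  tpos <- vt$template_position
  t_idx <- seq_along(kind)        # emission index = sequence position
  is_m <- kind == "MATCH"
  pairs <- data.frame(template_position = tpos[is_m],
                      sequence_position = t_idx[is_m])
  id <- vt$path
  nfl <- sum(id == "NFLANK")
  cfl <- sum(id == "CFLANK")
  seg_gap <- t_idx[startsWith(id, "DSEG")]

  # group consecutive CDR indel states into events
  indels <- empty_indels()
  is_ins <- kind == "INSERT"
  is_del <- kind == "DELETE_EMIT" & !startsWith(id, "DSEG")
  for (ev in split_runs(which(is_ins))) {
    after <- as.integer(sub("^I", "", id[ev[1L]]))
    indels <- rbind(indels, data.frame(
      type = "insertion", template_after = after,
      seq_start = ev[1L], seq_end = ev[length(ev)], length = length(ev)))
  }
  for (ev in split_runs(which(is_del))) {
    del_tpos <- as.integer(sub("^D", "", id[ev]))
    indels <- rbind(indels, data.frame(
      type = "deletion", template_after = min(del_tpos) - 1L,
      seq_start = ev[1L], seq_end = ev[length(ev)], length = length(ev)))
  }

  denom <- if (coverage_denominator == "template") L else seq_len
  structure(list(template_id = template$template_id, pairs = pairs,
                 cdr_indels = indels, segment_gap_residues = seg_gap,
                 flank_lengths = c(n = nfl, c = cfl),
                 coverage = nrow(pairs) / denom, logprob = vt$logprob),
            class = "alignment_result")
}

empty_indels <- function() {
  data.frame(type = character(0), template_after = integer(0),
             seq_start = integer(0), seq_end = integer(0), length = integer(0))
}

split_runs <- function(idx) {
  if (!length(idx)) return(list())
  unname(split(idx, cumsum(c(1L, diff(idx) != 1L))))
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s: %d matched positions, coverage %.3f, %d CDR indel event(s), flanks %d/%d\n",
              x$template_id, nrow(x$pairs), x$coverage, nrow(x$cdr_indels),
              x$flank_lengths[["n"]], x$flank_lengths[["c"]]))
  invisible(x)
}

#' Register a trained template model
#'
#' Bundles a trained model, its calibrator and its template definition for
#' use with [select_template()] and [export_score_matrix()].
#'
#' @param model Trained [hmm_spec()].
#' @param calibrator Fitted [fit_calibrator()] result.
#' @param template The [template_definition()].
#' @return An object of class `template_model`.
#' @export
template_model <- function(model, calibrator, template) {
  structure(list(model = model, calibrator = calibrator, template = template,
                 template_id = template$template_id),
            class = "template_model")
}

#' Select the best template and decide modelability
#'
#' Scores the query against every registered template model and applies the
#' two-rule decision: the sequence is reliably modelable by homology only
#' when the best calibrated score strictly exceeds `score_threshold` (default
#' 0.5, the median of the training corpus) and the best template's gapless
#' alignment coverage is at least `coverage_threshold` (default 0.8). Ties
#' on the calibrated score are resolved by lexicographic template id.
#'
#' @param registry Named list of [template_model()] objects.
#' @param seq Query amino-acid string.
#' @param query_id Identifier recorded in the result.
#' @param score_threshold Strict lower bound on the best calibrated score.
#' @param coverage_threshold Non-strict lower bound on coverage.
#' @param n_shuffles,rng_seed Passed to [raw_score()].
#' @param coverage_denominator See [align_to_template()].
#' @return An object of class `selection_result`: `query_id`,
#'   `score_vector` (named calibrated scores), `degenerate` (named flags),
#'   `best_template`, `best_coverage`, `modelable`, `reasons` (named logical
#'   rule outcomes), and `alignments` (per-template `alignment_result`s).
#' @export
select_template <- function(registry, seq, query_id = "query",
                            score_threshold = 0.5, coverage_threshold = 0.8,
                            n_shuffles = 100L, rng_seed = 1L,
                            coverage_denominator = "template") {
  stopifnot(length(registry) >= 1L)
  ids <- vapply(registry, function(m) m$template_id, character(1))
  names(registry) <- ids
  out <- lapply(registry, function(m)
    align_to_template(m$model, m$calibrator, m$template, seq,
                      n_shuffles, rng_seed,
                      coverage_denominator = coverage_denominator))
  scores <- vapply(out, function(o) o$report$calibrated_score, numeric(1))
  degen <- vapply(out, function(o) isTRUE(o$report$degenerate), logical(1))
  best <- ids[order(-scores, ids)][1L]
  best_cov <- out[[best]]$alignment$coverage
  score_ok <- scores[[best]] > score_threshold
  cov_ok <- best_cov >= coverage_threshold
  structure(list(query_id = query_id, score_vector = scores,
                 degenerate = degen, best_template = best,
                 best_coverage = best_cov,
                 modelable = score_ok && cov_ok,
                 reasons = c(score = score_ok, coverage = cov_ok),
                 alignments = lapply(out, `[[`, "alignment")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: best %s (score %.3f, coverage %.3f) -> %s\n",
              x$query_id, x$best_template, x$score_vector[[x$best_template]],
              x$best_coverage,
              if (x$modelable) "modelable" else
                paste("not modelable:",
                      paste(names(x$reasons)[!x$reasons], collapse = "+"))))
  invisible(x)
}

#' Per-query score matrix across all templates
#'
#' One row per query with its calibrated score against every registered
#' template, per-template degeneracy flags, the best template and the
#' modelability verdict. Queries degenerate on at least one template are
#' flagged `excluded` for downstream landscape analyses.
#'
#' @inheritParams select_template
#' @param seqs Named character vector of query sequences.
#' @return A data frame with columns `query_id`, `score_<template>`,
#'   `degenerate_<template>`, `best_template`, `modelable`, `excluded`.
#' @export
export_score_matrix <- function(registry, seqs, score_threshold = 0.5,
                                coverage_threshold = 0.8, n_shuffles = 100L,
                                rng_seed = 1L) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    sel <- select_template(registry, seqs[[i]], names(seqs)[i],
                           score_threshold, coverage_threshold,
                           n_shuffles,
                           derive_seed(rng_seed, 0L, i))
    row <- data.frame(query_id = sel$query_id)
    for (tid in names(sel$score_vector)) {
      row[[paste0("score_", tid)]] <- sel$score_vector[[tid]]
      row[[paste0("degenerate_", tid)]] <- sel$degenerate[[tid]]
    }
    row$best_template <- sel$best_template
    row$modelable <- sel$modelable
    row$excluded <- any(sel$degenerate)
    row
  })
  do.call(rbind, rows)
}

#' Write a score matrix as TSV
#' @param mat An [export_score_matrix()] result.
#' @param path Output path.
#' @export
write_score_matrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
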