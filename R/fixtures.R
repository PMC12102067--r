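#' Synthetic fixture specification
#'
#' Describes the synthetic study system the generator emulates: a template
#' consensus with declared CDR intervals and missing structural segments,
#' plus a family of sequences sampled from the template HMM with controlled
#' per-position mutation and CDR indel rates. Everything downstream
#' (training, selection, structure building) is testable offline from these
#' fixtures.
#'
#' @param template_length Consensus length (resolved residues).
#' @param cdr_intervals Data frame (`start`, `end`) or list of length-2
#'   vectors, consensus coordinates; `NULL` (default) places one CDR-like
#'   interval spanning roughly 30-45% of the consensus, `list()` disables
#'   CDRs entirely.
#' @param missing_segments Data frame (`after`, `length`) or list of
#'   length-2 vectors: a numbering gap of `length` unresolved residues after
#'   consensus position `after`.
#' @param mutation_rate Per-position probability that a constant/CDR match
#'   position emits a non-consensus residue.
#' @param cdr_indel_rate Per-CDR probability of one insertion event and,
#'   independently, one deletion event.
#' @param corpus_size Number of sampled sequences.
#' @param rng_seed Integer seed.
#' @param n_chains Number of chains in the synthetic fibril stack PDB.
#' @param flank_prob Probability of attaching a random unaligned flank at
#'   each terminus.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(template_length = 100L,
                         cdr_intervals = NULL,
                         missing_segments = list(),
                         mutation_rate = 0.1, cdr_indel_rate = 0.1,
                         corpus_size = 50L, rng_seed = 1L,
                         n_chains = 2L, flank_prob = 0.3) {
  as_iv <- function(x, nms) {
    if (is.data.frame(x)) return(stats::setNames(x, nms))
    if (!length(x)) return(stats::setNames(data.frame(integer(0), integer(0)), nms))
    stats::setNames(as.data.frame(do.call(rbind, lapply(x, as.integer))), nms)
  }
  stopifnot(template_length >= 1L, corpus_size >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            cdr_indel_rate >= 0, cdr_indel_rate <= 1)
  if (is.null(cdr_intervals)) {
    # default: one CDR-like interval around 30-45% of the consensus
    L <- as.integer(template_length)
    cdr_intervals <- if (L >= 10L)
      list(c(max(2L, round(0.3 * L)), min(L - 1L, round(0.45 * L))))
    else list()
  }
  structure(list(template_length = as.integer(template_length),
                 cdr_intervals = as_iv(cdr_intervals, c("start", "end")),
                 missing_segments = as_iv(missing_segments, c("after", "length")),
                 mutation_rate = mutation_rate,
                 cdr_indel_rate = cdr_indel_rate,
                 corpus_size = as.integer(corpus_size),
                 rng_seed = as.integer(rng_seed),
                 n_chains = as.integer(n_chains),
                 flank_prob = flank_prob),
            class = "fixture_spec")
}

# minimal but standard-conforming backbone PDB text for the synthetic fibril
.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z, elem) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, x, y, z, 1, 0, elem)
}

write_synthetic_pdb <- function(consensus, resno, n_chains, path) {
  chars <- split_seq(consensus)
  res3 <- bio3d::aa123(chars)
  atoms <- data.frame(name = c("N", "CA", "C", "O"),
                      dz = c(-0.5, 0, 0.5, 1.2),
                      elem = c("N", "C", "C", "O"))
  lines <- character(0)
  serial <- 0L
  for (c_i in seq_len(n_chains)) {
    chain <- LETTERS[c_i]
    for (k in seq_along(chars)) {
      for (a in seq_len(nrow(atoms))) {
        serial <- serial + 1L
        lines <- c(lines, .pdb_atom_line(
          serial, atoms$name[a], res3[k], chain, resno[k],
          3.8 * k, 4.8 * (c_i - 1L), atoms$dz[a], atoms$elem[a]))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial + 1L, res3[length(chars)], chain,
                              resno[length(chars)]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a complete synthetic fixture
#'
#' Builds a random template consensus consistent with the declared CDR
#' intervals and missing segments, writes a minimal multi-chain backbone PDB
#' with matching author numbering (gaps where segments are missing), and
#' samples a corpus from the template HMM: constant and CDR match positions
#' emit the consensus residue or, with the mutation rate, a random other
#' residue; CDR indel events insert extra residues or replace a block of CDR
#' match emissions by skip-state emissions; missing segments always emit
#' their unresolved residues; random unaligned flanks are attached with
#' `flank_prob`. Ground-truth match alignments are recorded for every
#' sampled sequence.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory for the synthetic PDB (created if absent).
#' @return A list: `template` (a [template_definition()]),
#'   `structure_path`, `corpus` (named character), `truth` (per-sequence
#'   data frames of ground-truth `(template_position, sequence_position)`
#'   pairs), `labels` (per-sequence event counts).
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$rng_seed, {
    L <- spec$template_length
    consensus <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")

    # author numbering with gaps at the missing segments
    gap_after <- spec$missing_segments$after
    gap_len <- spec$missing_segments$length
    stopifnot(all(gap_after >= 1L), all(gap_after < L), all(gap_len >= 1L))
    resno <- integer(L)
    r <- 0L
    for (k in seq_len(L)) {
      r <- r + 1L
      resno[k] <- r
      if (k %in% gap_after) r <- r + gap_len[match(k, gap_after)]
    }
    breaks <- which(seq_len(L) %in% gap_after)
    seg_start <- resno[c(1L, breaks + 1L)]
    seg_end <- resno[c(breaks, L)]
    structure_path <- file.path(dir, "synthetic_template.pdb")
    write_synthetic_pdb(consensus, resno, spec$n_chains, structure_path)

    template <- template_definition(
      "SYNTH1", consensus,
      data.frame(start = seg_start, end = seg_end),
      if (length(gap_after)) data.frame(after = gap_after, length = gap_len)
      else empty_missing(),
      spec$cdr_intervals, structure_path, "A")

    sampled <- lapply(seq_len(spec$corpus_size), function(i)
      sample_corpus_sequence(template, spec))
    corpus <- vapply(sampled, `[[`, character(1), "seq")
    names(corpus) <- sprintf("synth%04d", seq_len(spec$corpus_size))
    truth <- lapply(sampled, `[[`, "pairs")
    names(truth) <- names(corpus)
    labels <- do.call(rbind, lapply(sampled, `[[`, "label"))
    labels$id <- names(corpus)
    list(template = template, structure_path = structure_path,
         corpus = corpus, truth = truth, labels = labels)
  })
}

rand_aa <- function(n) sample(AA_ALPHABET, n, replace = TRUE)

# sample one element of x (safe for length-1 x, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

sample_corpus_sequence <- function(template, spec) {
  L <- nchar(template$consensus)
  cons <- split_seq(template$consensus)
  cdr <- template$cdr_intervals
  gap_after <- template$missing_segments$after
  gap_len <- template$missing_segments$length

  # per-CDR indel events
  ins_after <- integer(0); ins_len <- integer(0); del_set <- integer(0)
  if (nrow(cdr)) {
    for (r in seq_len(nrow(cdr))) {
      a <- cdr$start[r]; b <- cdr$end[r]
      if (b > a && stats::runif(1) < spec$cdr_indel_rate) {
        ins_after <- c(ins_after, sample1(a:(b - 1L)))
        ins_len <- c(ins_len, 1L + stats::rgeom(1L, 0.5))
      }
      if (b > a && stats::runif(1) < spec$cdr_indel_rate) {
        len <- min(1L + stats::rgeom(1L, 0.5), b - a)
        st <- sample1((a + 1L):(b - len + 1L))
        del_set <- c(del_set, st:(st + len - 1L))
      }
    }
  }

  chars <- character(0); tpos <- integer(0)
  emit <- function(ch, tp) { chars <<- c(chars, ch); tpos <<- c(tpos, tp) }
  flank_n <- 0L; flank_c <- 0L
  if (stats::runif(1) < spec$flank_prob) {
    flank_n <- 1L + stats::rgeom(1L, 0.4)
    emit(rand_aa(flank_n), rep(NA_integer_, flank_n))
  }
  n_mut <- 0L
  for (k in seq_len(L)) {
    if (k %in% del_set) {
      emit(rand_aa(1L), NA_integer_)   # skip-state emission replaces the match
    } else {
      if (stats::runif(1) < spec$mutation_rate) {
        emit(sample(setdiff(AA_ALPHABET, cons[k]), 1L), k)
        n_mut <- n_mut + 1L
      } else emit(cons[k], k)
    }
    if (k %in% ins_after) {
      nl <- ins_len[match(k, ins_after)]
      emit(rand_aa(nl), rep(NA_integer_, nl))
    }
    if (k %in% gap_after) {
      gl <- gap_len[match(k, gap_after)]
      emit(rand_aa(gl), rep(NA_integer_, gl))
    }
  }
  if (stats::runif(1) < spec$flank_prob) {
    flank_c <- 1L + stats::rgeom(1L, 0.4)
    emit(rand_aa(flank_c), rep(NA_integer_, flank_c))
  }
  matched <- !is.na(tpos)
  # deleted CDR positions carry no pair; mutated positions still align
  list(seq = paste(chars, collapse = ""),
       pairs = data.frame(template_position = tpos[matched],
                          sequence_position = which(matched)),
       label = data.frame(n_mut = n_mut, n_ins = length(ins_after),
                          ins_res = sum(ins_len), n_del = length(del_set),
                          flank_n = flank_n, flank_c = flank_c))
}
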