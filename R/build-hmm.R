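#' Initial HMM parameterization
#'
#' The untrained ("dummy") parameter set the constrained profile HMM starts
#' from, before Baum-Welch refinement. Match states put `match_emit` on the
#' template residue and spread `mismatch_total` equally over the 19 other
#' residues; skip ("deletion"), insert and flank states emit uniformly at
#' `skip_emit` per residue. Within CDRs the total gap-open probability is
#' `cdr_gap_open`, split evenly between match-to-delete and match-to-insert,
#' and gaps extend with probability `gap_extend`; the same extension applies
#' to the inter-segment skip states that absorb residues spanning
#' structurally unresolved segments. Terminal flank states self-loop with
#' `flank_self` so unaligned termini are absorbed.
#'
#' Two parameters control local entry/exit into the match chain, so that a
#' query may leave leading or trailing template positions unaligned (their
#' residues being absorbed by the flanks): `entry_open` is the probability
#' mass of entering the chain after position one (spread uniformly over
#' positions 2..L), and `exit_open` is each interior match state's
#' probability of exiting to the C-flank/END before the chain end. Interior
#' match states therefore pass all non-terminal mass, `1 - exit_open`, to
#' their unique chain successor.
#'
#' @param match_emit Emission probability of the template residue in a match
#'   state (default 0.8).
#' @param mismatch_total Probability mass spread over the other 19 residues
#'   (default 0.2); `match_emit + mismatch_total` must equal 1.
#' @param skip_emit Per-residue emission in skip/insert/flank states
#'   (default 0.05, i.e. uniform).
#' @param cdr_gap_open Total CDR gap-open probability (default 0.1, split
#'   0.05 match-to-delete and 0.05 match-to-insert).
#' @param gap_extend Gap extension probability for CDR indel states and
#'   inter-segment skip states (default 0.9).
#' @param flank_self Self-transition of the terminal flank states
#'   (default 0.9).
#' @param entry_open Probability mass for entering the match chain after
#'   position 1 (default 0.1).
#' @param exit_open Per-interior-match probability of early exit to the
#'   C-terminal flank/END (default 0.01).
#' @param flank_open Probability that a path visits the N-terminal flank at
#'   all, i.e. the START-to-N-flank transition (default 0.1).
#' @return An object of class `hmm_build_params`.
#' @export
hmm_build_params <- function(match_emit = 0.8, mismatch_total = 0.2,
                             skip_emit = 0.05, cdr_gap_open = 0.1,
                             gap_extend = 0.9, flank_self = 0.9,
                             entry_open = 0.1, exit_open = 0.01,
                             flank_open = 0.1) {
  p <- list(match_emit = match_emit, mismatch_total = mismatch_total,
            skip_emit = skip_emit, cdr_gap_open = cdr_gap_open,
            gap_extend = gap_extend, flank_self = flank_self,
            entry_open = entry_open, exit_open = exit_open,
            flank_open = flank_open)
  if (any(unlist(p) < 0) || any(unlist(p) > 1))
    stop("all build parameters must lie in [0, 1]")
  if (abs(match_emit + mismatch_total - 1) > 1e-12)
    stop("match_emit + mismatch_total must equal 1")
  structure(p, class = "hmm_build_params")
}

#' Build the constrained initial HMM for a template
#'
#' Topology: one MATCH state per consensus position. In constant regions
#' match states chain directly (no insert or delete neighbours). Between
#' consecutive resolved segments a single self-looping DELETE_EMIT state
#' absorbs the residues spanning the unresolved segment (geometric length,
#' extension `gap_extend`). Within each declared CDR interval the standard
#' profile wiring applies: match-to-delete and match-to-insert openings of
#' `cdr_gap_open / 2` each, insert self-loops and delete chains extending
#' with `gap_extend`. Uniform-emission N- and C-terminal FLANK states absorb
#' unaligned termini, and local entry/exit transitions (see
#' [hmm_build_params()]) let leading or trailing template positions go
#' unaligned.
#'
#' @param template A [template_definition()].
#' @param params An [hmm_build_params()].
#' @return A validated [hmm_spec()] whose MATCH states carry
#'   `template_position` 1..`nchar(consensus)`.
#' @export
build_initial_hmm <- function(template, params = hmm_build_params()) {
  stopifnot(inherits(template, "template_definition"))
  if (!inherits(params, "hmm_build_params")) params <- do.call(hmm_build_params, params)
  L <- nchar(template$consensus)
  cons <- split_seq(template$consensus)
  cdr <- template$cdr_intervals
  miss_after <- template$missing_segments$after

  # a missing-segment boundary inside a CDR makes the wiring ambiguous
  if (nrow(cdr)) {
    for (r in seq_len(nrow(cdr))) {
      if (any(miss_after >= cdr$start[r] & miss_after < cdr$end[r]))
        stop("CDR interval [", cdr$start[r], ", ", cdr$end[r],
             "] overlaps a missing-segment boundary: wiring is ambiguous")
    }
  }

  in_cdr <- rep(FALSE, L)
  if (nrow(cdr))
    for (r in seq_len(nrow(cdr))) in_cdr[cdr$start[r]:cdr$end[r]] <- TRUE
  cdr_of <- rep(NA_integer_, L)
  if (nrow(cdr))
    for (r in seq_len(nrow(cdr))) cdr_of[cdr$start[r]:cdr$end[r]] <- r
  # gap-open positions: CDR matches that are not the last position of their CDR;
  # deletable positions: CDR matches that are not the first of their CDR
  cdr_rows <- seq_len(nrow(cdr))
  ins_pos <- sort(unlist(lapply(cdr_rows, function(r)
    if (cdr$end[r] > cdr$start[r]) cdr$start[r]:(cdr$end[r] - 1L) else integer(0))))
  del_pos <- sort(unlist(lapply(cdr_rows, function(r)
    if (cdr$end[r] > cdr$start[r]) (cdr$start[r] + 1L):cdr$end[r] else integer(0))))
  ins_pos <- as.integer(ins_pos); del_pos <- as.integer(del_pos)
  opens_gap <- seq_len(L) %in% ins_pos

  ids <- c("START", "NFLANK", paste0("M", seq_len(L)))
  kinds <- c("START", "FLANK", rep("MATCH", L))
  tpos <- c(NA_integer_, NA_integer_, seq_len(L))
  p0 <- function(pre, v) if (length(v)) paste0(pre, v) else character(0)
  ids <- c(ids, p0("I", ins_pos), p0("D", del_pos),
           p0("DSEG", miss_after), "CFLANK", "END")
  kinds <- c(kinds, rep("INSERT", length(ins_pos)),
             rep("DELETE_EMIT", length(del_pos)),
             rep("DELETE_EMIT", length(miss_after)), "FLANK", "END")
  tpos <- c(tpos, rep(NA_integer_, length(ins_pos) + length(del_pos) +
                        length(miss_after) + 2L))
  n <- length(ids)
  ix <- function(id) match(id, ids)

  em <- matrix(0, n, 20L)
  uniform <- rep(params$skip_emit, 20L)
  uniform <- uniform / sum(uniform)
  for (k in seq_len(L)) {
    row <- rep(params$mismatch_total / 19, 20L)
    row[match(cons[k], AA_ALPHABET)] <- params$match_emit
    em[ix(paste0("M", k)), ] <- row
  }
  for (id in c(p0("I", ins_pos), p0("D", del_pos),
               p0("DSEG", miss_after), "NFLANK", "CFLANK"))
    em[ix(id), ] <- uniform

  tr <- matrix(0, n, n, dimnames = list(ids, ids))
  gap_half <- params$cdr_gap_open / 2

  # entry distribution over match positions
  entry <- if (L == 1L) 1 else {
    e <- rep(params$entry_open / (L - 1L), L)
    e[1L] <- 1 - params$entry_open
    e
  }
  tr[ix("START"), ix("NFLANK")] <- params$flank_open
  tr[ix("START"), ix(paste0("M", seq_len(L)))] <- (1 - params$flank_open) * entry
  tr[ix("NFLANK"), ix("NFLANK")] <- params$flank_self
  tr[ix("NFLANK"), ix(paste0("M", seq_len(L)))] <- (1 - params$flank_self) * entry

  # chain successor of consensus position k (as a state id), NA at k = L
  chain_next <- function(k) {
    if (k == L) return(NA_character_)
    if (k %in% miss_after) paste0("DSEG", k) else paste0("M", k + 1L)
  }
  terminal <- function(i, mass) {
    tr[i, ix("CFLANK")] <<- tr[i, ix("CFLANK")] + mass / 2
    tr[i, ix("END")] <<- tr[i, ix("END")] + mass / 2
  }

  for (k in seq_len(L)) {
    i <- ix(paste0("M", k))
    if (k == L) { terminal(i, 1); next }
    gap <- if (opens_gap[k]) params$cdr_gap_open else 0
    chain_mass <- 1 - params$exit_open - gap
    tr[i, ix(chain_next(k))] <- chain_mass
    if (opens_gap[k]) {
      tr[i, ix(paste0("D", k + 1L))] <- gap_half
      tr[i, ix(paste0("I", k))] <- gap_half
    }
    terminal(i, params$exit_open)
  }
  for (k in ins_pos) {
    i <- ix(paste0("I", k))
    tr[i, i] <- params$gap_extend
    tr[i, ix(paste0("M", k + 1L))] <- 1 - params$gap_extend
  }
  for (k in del_pos) {
    i <- ix(paste0("D", k))
    cdr_end <- cdr$end[cdr_of[k]]
    if (k < cdr_end) {
      tr[i, ix(paste0("D", k + 1L))] <- params$gap_extend
      tr[i, ix(paste0("M", k + 1L))] <- 1 - params$gap_extend
    } else if (k == L) {
      terminal(i, 1)
    } else {
      tr[i, ix(chain_next(k))] <- 1
    }
  }
  for (k in miss_after) {
    i <- ix(paste0("DSEG", k))
    tr[i, i] <- params$gap_extend
    tr[i, ix(paste0("M", k + 1L))] <- 1 - params$gap_extend
  }
  tr[ix("CFLANK"), ix("CFLANK")] <- params$flank_self
  tr[ix("CFLANK"), ix("END")] <- 1 - params$flank_self

  hmm <- hmm_spec(ids, kinds, em, tr, "START", "END", tpos,
                  template_id = template$template_id)
  validate_hmm(hmm)
}
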