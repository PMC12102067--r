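#' Construct an HMM specification
#'
#' An `hmm_spec` is the in-memory description of one template's hidden Markov
#' model: an ordered set of states with emission distributions over the 20
#' canonical amino acids and a row-stochastic transition matrix. The only
#' silent states are the START and END bookends; every other state (including
#' the skip/"deletion" states, which absorb residues spanning structurally
#' unresolved segments) emits one residue per visit.
#'
#' @param id Character vector of unique state identifiers.
#' @param kind Character vector, one of `"MATCH"`, `"INSERT"`, `"DELETE_EMIT"`,
#'   `"FLANK"`, `"START"`, `"END"` per state.
#' @param emissions Numeric matrix, `length(id)` x 20 with columns in
#'   [AA_ALPHABET] order; rows for silent states are ignored (set them to 0).
#' @param transitions Numeric square matrix of transition probabilities,
#'   `transitions[i, j] = P(state j | state i)`.
#' @param start_state,end_state Identifiers of the silent START and END states.
#' @param template_position Integer vector giving, for MATCH states, the
#'   1-based position in the template consensus; `NA` elsewhere.
#' @param template_id Optional template identifier carried through scoring.
#' @return An object of class `hmm_spec`.
#' @seealso [validate_hmm()], [build_initial_hmm()]
#' @export
hmm_spec <- function(id, kind, emissions, transitions, start_state, end_state,
                     template_position = rep(NA_integer_, length(id)),
                     template_id = NULL) {
  n <- length(id)
  stopifnot(length(kind) == n, nrow(emissions) == n, ncol(emissions) == 20L,
            nrow(transitions) == n, ncol(transitions) == n,
            length(template_position) == n)
  if (anyDuplicated(id)) stop("state ids must be unique")
  kinds <- c("MATCH", "INSERT", "DELETE_EMIT", "FLANK", "START", "END")
  if (!all(kind %in% kinds))
    stop("unknown state kind: ", paste(setdiff(kind, kinds), collapse = ", "))
  if (!start_state %in% id || !end_state %in% id)
    stop("start_state/end_state must name states")
  dimnames(emissions) <- list(id, AA_ALPHABET)
  dimnames(transitions) <- list(id, id)
  structure(
    list(id = id, kind = kind,
         emissions = emissions, transitions = transitions,
         start_state = start_state, end_state = end_state,
         template_position = as.integer(template_position),
         template_id = template_id),
    class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  tab <- table(factor(x$kind, levels = unique(x$kind)))
  cat(sprintf("<hmm_spec> %d states (%s)%s\n",
              length(x$id),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              if (is.null(x$template_id)) "" else paste0(" template ", x$template_id)))
  invisible(x)
}

#' Validate HMM invariants
#'
#' Checks that every non-END state's outgoing transition probabilities sum to
#' one (within `tol`), that every emitting state's emission distribution sums
#' to one, that MATCH states carry unique template positions, and that END is
#' reachable from START through the transition graph.
#'
#' @param hmm An [hmm_spec()].
#' @param tol Numeric tolerance on probability sums.
#' @return `hmm`, invisibly; errors describe the first violated invariant.
#' @export
validate_hmm <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "hmm_spec"))
  si <- match(hmm$start_state, hmm$id)
  ei <- match(hmm$end_state, hmm$id)
  if (hmm$kind[si] != "START" || hmm$kind[ei] != "END")
    stop("start/end states must have kinds START and END")
  if (any(hmm$transitions < 0) || any(hmm$transitions > 1))
    stop("transition probabilities must lie in [0, 1]")
  rs <- rowSums(hmm$transitions)
  bad <- which(abs(rs - 1) > tol & seq_along(rs) != ei)
  if (length(bad))
    stop("outgoing transitions of state '", hmm$id[bad[1L]],
         "' sum to ", format(rs[bad[1L]]), ", not 1")
  emitting <- !(hmm$kind %in% c("START", "END"))
  if (any(hmm$emissions[emitting, , drop = FALSE] < 0))
    stop("emission probabilities must be non-negative")
  es <- rowSums(hmm$emissions)
  bade <- which(emitting & abs(es - 1) > tol)
  if (length(bade))
    stop("emissions of state '", hmm$id[bade[1L]],
         "' sum to ", format(es[bade[1L]]), ", not 1")
  tp <- hmm$template_position
  is_match <- hmm$kind == "MATCH"
  if (any(is.na(tp[is_match])))
    stop("every MATCH state needs a template_position")
  if (anyDuplicated(tp[is_match]))
    stop("template_position values must be unique across MATCH states")
  if (any(!is.na(tp[!is_match])))
    stop("only MATCH states may carry a template_position")
  # reachability start -> end by BFS over positive transitions
  n <- length(hmm$id)
  seen <- logical(n); seen[si] <- TRUE
  frontier <- si
  while (length(frontier)) {
    nxt <- which(colSums(hmm$transitions[frontier, , drop = FALSE] > 0) > 0)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!seen[ei]) stop("END state is not reachable from START")
  invisible(hmm)
}

# Tie-break priority used by Viterbi decoding: favour template coverage.
.kind_priority <- c(MATCH = 0, DELETE_EMIT = 1, INSERT = 2, FLANK = 3,
                    START = 4, END = 4)

#' Compile an hmm_spec for the C++ recursions
#'
#' Extracts the sparse positive-probability edge list between emitting states,
#' CSR indexes by target and by source, per-state START-entry and END-exit
#' log probabilities, and the log emission table. Edges incoming to each state
#' are ordered MATCH < DELETE_EMIT < INSERT < FLANK, then by state index, so
#' the C++ first-maximum scan realizes the documented deterministic tie-break.
#'
#' @keywords internal
hmm_compile <- function(hmm) {
  n <- length(hmm$id)
  si <- match(hmm$start_state, hmm$id)
  ei <- match(hmm$end_state, hmm$id)
  emit_idx <- setdiff(seq_len(n), c(si, ei))
  ne <- length(emit_idx)
  # remap emitting states to 1..ne
  remap <- integer(n); remap[emit_idx] <- seq_len(ne)

  tr <- hmm$transitions
  pos <- which(tr > 0, arr.ind = TRUE)
  inner <- pos[pos[, 1] != si & pos[, 1] != ei & pos[, 2] != si & pos[, 2] != ei, , drop = FALSE]
  efrom <- remap[inner[, 1]]
  eto <- remap[inner[, 2]]
  elogp <- log(tr[inner])
  prio <- .kind_priority[hmm$kind][emit_idx]
  ord <- order(eto, prio[efrom], efrom)
  efrom <- efrom[ord]; eto <- eto[ord]; elogp <- elogp[ord]
  tptr <- c(0L, cumsum(tabulate(eto, nbins = ne)))
  fo <- order(efrom, eto)
  fidx <- fo
  fptr <- c(0L, cumsum(tabulate(efrom, nbins = ne)))

  startlogp <- rep(-Inf, ne)
  sj <- which(tr[si, ] > 0)
  sj <- sj[sj != ei & sj != si]
  startlogp[remap[sj]] <- log(tr[si, sj])
  endlogp <- rep(-Inf, ne)
  ej <- which(tr[, ei] > 0)
  ej <- ej[ej != si & ej != ei]
  endlogp[remap[ej]] <- log(tr[ej, ei])

  logemit <- log(hmm$emissions[emit_idx, , drop = FALSE])

  list(n = ne,
       state_index = emit_idx,          # emitting-state row -> hmm state row
       kind = hmm$kind[emit_idx],
       template_position = hmm$template_position[emit_idx],
       logemit = logemit,
       efrom = as.integer(efrom - 1L), eto = as.integer(eto - 1L),
       elogp = elogp, tptr = as.integer(tptr),
       fidx = as.integer(fidx - 1L), fptr = as.integer(fptr),
       startlogp = startlogp, endlogp = endlogp,
       init_order = as.integer(order(prio, seq_len(ne)) - 1L),
       edge_from_full = inner[ord, 1L], edge_to_full = inner[ord, 2L])
}
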