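#' Forward log-likelihood of a sequence
#'
#' Computes `log P(seq | hmm)` summed over all state paths by the forward
#' recursion in natural-log space. Returns `-Inf` when no path can emit the
#' sequence.
#'
#' @param hmm An [hmm_spec()].
#' @param seq Amino-acid string over the 20 canonical residues.
#' @return Log probability (numeric scalar, `-Inf` allowed).
#' @export
hmm_forward <- function(hmm, seq) {
  cm <- hmm_compile(hmm)
  obs <- encode_seq(seq) - 1L
  hmm_forward_cpp(cm$logemit, obs, cm$efrom, cm$elogp, cm$tptr,
                  cm$startlogp, cm$endlogp, FALSE)$loglik
}

#' Backward log-likelihood of a sequence
#'
#' Same total probability as [hmm_forward()] computed by the backward
#' recursion; the two agree within numerical tolerance and their agreement is
#' a standing self-check of the engine.
#'
#' @inheritParams hmm_forward
#' @return Log probability (numeric scalar, `-Inf` allowed).
#' @export
hmm_backward <- function(hmm, seq) {
  cm <- hmm_compile(hmm)
  obs <- encode_seq(seq) - 1L
  hmm_backward_cpp(cm$logemit, obs, cm$eto, cm$elogp, cm$fidx, cm$fptr,
                   cm$startlogp, cm$endlogp, FALSE)$loglik
}

#' Maximum-probability state path
#'
#' Viterbi decoding. Ties are broken deterministically, preferring MATCH over
#' DELETE_EMIT over INSERT over FLANK predecessors and then the lower state
#' index, which favours maximal template coverage.
#'
#' @inheritParams hmm_forward
#' @return List with `path` (character vector of state ids, empty when no
#'   path has positive probability), `kind` and `template_position` along the
#'   path, and `logprob` (`-Inf` sentinel when degenerate).
#' @export
hmm_viterbi <- function(hmm, seq) {
  cm <- hmm_compile(hmm)
  obs <- encode_seq(seq) - 1L
  vt <- hmm_viterbi_cpp(cm$logemit, obs, cm$efrom, cm$elogp, cm$tptr,
                        cm$startlogp, cm$endlogp, cm$init_order)
  if (!length(vt$path))
    return(list(path = character(0), kind = character(0),
                template_position = integer(0), logprob = -Inf))
  full <- cm$state_index[vt$path]
  list(path = hmm$id[full], kind = hmm$kind[full],
       template_position = hmm$template_position[full],
       logprob = vt$logprob)
}

#' Corpus log-likelihood
#'
#' Sum of forward log-likelihoods over a set of sequences (degenerate
#' sequences contribute `-Inf`).
#'
#' @param hmm An [hmm_spec()].
#' @param seqs Character vector of sequences.
#' @return Numeric scalar.
#' @export
hmm_loglik <- function(hmm, seqs) {
  cm <- hmm_compile(hmm)
  sum(vapply(seqs, function(s) {
    obs <- encode_seq(s) - 1L
    hmm_forward_cpp(cm$logemit, obs, cm$efrom, cm$elogp, cm$tptr,
                    cm$startlogp, cm$endlogp, FALSE)$loglik
  }, numeric(1)))
}

#' Baum-Welch training with inertia
#'
#' Expectation-maximization over a sequence corpus where each accepted update
#' is the convex combination `new = inertia * old + (1 - inertia) *
#' expected-count estimate`, applied to every emission row and to every
#' structurally allowed transition row (zero transitions stay zero, so the
#' constrained topology is preserved). A floor of `emit_floor` is applied to
#' the expected-count estimates before renormalization so finite corpora
#' cannot create permanent zeros. Iteration stops when the improvement in
#' total corpus log-likelihood falls below `stop_threshold` or after
#' `max_iterations` updates.
#'
#' @param hmm Initial [hmm_spec()].
#' @param seqs Non-empty character vector of training sequences.
#' @param inertia Weight on the old parameters, in `[0, 1]`; the adopted
#'   default is 0.9.
#' @param stop_threshold Absolute improvement in total corpus log-likelihood
#'   below which training stops; the adopted default is 50.
#' @param max_iterations Upper bound on the number of updates.
#' @param emit_floor Probability floor applied to count estimates.
#' @return The trained [hmm_spec()], with an attribute `training_log`: a
#'   data frame of per-iteration corpus log-likelihoods.
#' @export
hmm_baum_welch <- function(hmm, seqs, inertia = 0.9, stop_threshold = 50,
                           max_iterations = 500L, emit_floor = 1e-10) {
  stopifnot(length(seqs) >= 1L, inertia >= 0, inertia <= 1,
            stop_threshold > 0)
  validate_hmm(hmm)
  obs_list <- lapply(seqs, function(s) encode_seq(s) - 1L)

  lls <- numeric(0)
  ll_prev <- NA_real_
  for (iter in seq_len(max_iterations)) {
    cm <- hmm_compile(hmm)
    ne <- cm$n
    emitc <- matrix(0, ne, 20L)
    edgec <- numeric(length(cm$elogp))
    startc <- numeric(ne)
    endc <- numeric(ne)
    ll <- 0
    n_finite <- 0L
    for (obs in obs_list) {
      ct <- hmm_counts_cpp(cm$logemit, obs, cm$efrom, cm$eto, cm$elogp,
                           cm$tptr, cm$fidx, cm$fptr, cm$startlogp, cm$endlogp)
      if (is.infinite(ct$loglik)) next
      n_finite <- n_finite + 1L
      ll <- ll + ct$loglik
      emitc <- emitc + ct$emit
      edgec <- edgec + ct$edge
      startc <- startc + ct$start
      endc <- endc + ct$end
    }
    if (n_finite == 0L)
      stop("every training sequence has -Inf likelihood under this model: ",
           "the topology and the corpus are incompatible")
    lls <- c(lls, ll)
    if (iter > 1L && (ll - ll_prev) < stop_threshold) break
    ll_prev <- ll

    hmm <- .bw_update(hmm, cm, emitc, edgec, startc, endc,
                      inertia, emit_floor)
  }
  attr(hmm, "training_log") <- data.frame(iteration = seq_along(lls),
                                          loglik = lls)
  hmm
}

# One inertial M-step. Estimates are per-row normalized expected counts,
# floored and renormalized over the structurally allowed support only.
.bw_update <- function(hmm, cm, emitc, edgec, startc, endc,
                       inertia, emit_floor) {
  n <- length(hmm$id)
  si <- match(hmm$start_state, hmm$id)
  ei <- match(hmm$end_state, hmm$id)

  counts <- matrix(0, n, n)
  counts[cbind(cm$edge_from_full, cm$edge_to_full)] <- edgec
  counts[si, cm$state_index] <- startc
  counts[cm$state_index, ei] <- endc

  tr <- hmm$transitions
  for (i in setdiff(seq_len(n), ei)) {
    sup <- which(tr[i, ] > 0)
    tot <- sum(counts[i, sup])
    if (tot <= 0) next  # state never visited: keep old row
    est <- counts[i, sup] / tot
    est <- pmax(est, emit_floor)
    est <- est / sum(est)
    tr[i, sup] <- inertia * tr[i, sup] + (1 - inertia) * est
    tr[i, sup] <- tr[i, sup] / sum(tr[i, sup])
  }

  em <- hmm$emissions
  for (k in seq_len(cm$n)) {
    i <- cm$state_index[k]
    tot <- sum(emitc[k, ])
    if (tot <= 0) next
    est <- emitc[k, ] / tot
    est <- pmax(est, emit_floor)
    est <- est / sum(est)
    em[i, ] <- inertia * em[i, ] + (1 - inertia) * est
    em[i, ] <- em[i, ] / sum(em[i, ])
  }

  out <- hmm
  out$transitions <- tr
  out$emissions <- em
  out
}
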