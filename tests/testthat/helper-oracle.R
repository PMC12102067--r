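# Exhaustive path-enumeration oracle: sums / maximizes over every state path
# that can emit the sequence. Independent of the dynamic-programming engine;
# only usable for small models and short sequences.

oracle_paths <- function(hmm, seq) {
  obs <- match(strsplit(seq, "", fixed = TRUE)[[1L]], fibrilHMM::AA_ALPHABET)
  stopifnot(!anyNA(obs))
  n <- length(hmm$id)
  si <- match(hmm$start_state, hmm$id)
  ei <- match(hmm$end_state, hmm$id)
  emitting <- setdiff(seq_len(n), c(si, ei))
  Tn <- length(obs)
  prio <- c(MATCH = 0, DELETE_EMIT = 1, INSERT = 2, FLANK = 3,
            START = 4, END = 4)[hmm$kind]

  total <- 0
  best <- -Inf
  best_path <- NULL
  rec <- function(prev, t, logp, path) {
    if (t > Tn) {
      p_end <- hmm$transitions[prev, ei]
      if (p_end > 0) {
        lp <- logp + log(p_end)
        total <<- total + exp(lp)
        if (lp > best) { best <<- lp; best_path <<- path }
      }
      return(invisible(NULL))
    }
    succ <- emitting[hmm$transitions[prev, emitting] > 0]
    succ <- succ[order(prio[succ], succ)]
    for (j in succ) {
      e <- hmm$emissions[j, obs[t]]
      if (e > 0)
        rec(j, t + 1L, logp + log(hmm$transitions[prev, j]) + log(e),
            c(path, j))
    }
  }
  rec(si, 1L, 0, integer(0))
  list(loglik = if (total > 0) log(total) else -Inf,
       best_logprob = best,
       best_path = if (is.null(best_path)) character(0) else hmm$id[best_path])
}

# log probability of one explicit state path emitting the sequence
path_logprob <- function(hmm, path_ids, seq) {
  obs <- match(strsplit(seq, "", fixed = TRUE)[[1L]], fibrilHMM::AA_ALPHABET)
  idx <- match(path_ids, hmm$id)
  si <- match(hmm$start_state, hmm$id)
  ei <- match(hmm$end_state, hmm$id)
  stopifnot(length(idx) == length(obs))
  lp <- log(hmm$transitions[si, idx[1L]]) + log(hmm$emissions[idx[1L], obs[1L]])
  if (length(idx) > 1L) {
    for (t in 2:length(idx))
      lp <- lp + log(hmm$transitions[idx[t - 1L], idx[t]]) +
        log(hmm$emissions[idx[t], obs[t]])
  }
  lp + log(hmm$transitions[idx[length(idx)], ei])
}
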