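# Hand-built toy models and random-model generators used across the suite.

# START -> M1 -> END, M1 emits 'A' with probability 1
one_match_hmm <- function() {
  em <- matrix(0, 3, 20)
  em[2L, match("A", AA_ALPHABET)] <- 1
  tr <- matrix(0, 3, 3)
  tr[1L, 2L] <- 1
  tr[2L, 3L] <- 1
  hmm_spec(c("START", "M1", "END"), c("START", "MATCH", "END"),
           em, tr, "START", "END", c(NA, 1L, NA))
}

# Three emitting states with mixed emissions; small enough to enumerate.
toy3_hmm <- function() {
  em <- matrix(0, 5, 20)
  aa <- function(...) match(c(...), AA_ALPHABET)
  em[2L, aa("A", "C")] <- c(0.7, 0.3)            # M1
  em[3L, aa("A", "C", "D")] <- c(0.2, 0.5, 0.3)  # D1 (emitting skip)
  em[4L, aa("C", "D")] <- c(0.6, 0.4)            # M2
  tr <- matrix(0, 5, 5)
  tr[1L, 2L] <- 1                                 # START -> M1
  tr[2L, c(2L, 3L, 4L)] <- c(0.2, 0.3, 0.5)       # M1 self/skip/next
  tr[3L, c(3L, 4L)] <- c(0.4, 0.6)
  tr[4L, c(4L, 5L)] <- c(0.3, 0.7)                # M2 self/END
  hmm_spec(c("START", "M1", "D1", "M2", "END"),
           c("START", "MATCH", "DELETE_EMIT", "MATCH", "END"),
           em, tr, "START", "END", c(NA, 1L, NA, 2L, NA))
}

# Random dense-ish HMM over a restricted alphabet; every emitting state can
# reach END so random sequences usually have finite likelihood.
random_small_hmm <- function(n_emit = 4L, n_letters = 5L, zero_frac = 0.25) {
  n <- n_emit + 2L
  kinds <- c("START",
             sample(c("MATCH", "DELETE_EMIT", "INSERT", "FLANK"), n_emit,
                    replace = TRUE),
             "END")
  # MATCH states need unique template positions
  tpos <- rep(NA_integer_, n)
  m <- which(kinds == "MATCH")
  tpos[m] <- seq_along(m)
  em <- matrix(0, n, 20)
  letters_idx <- seq_len(n_letters)
  for (i in 2:(n - 1L)) {
    w <- stats::runif(n_letters)
    w[stats::runif(n_letters) < zero_frac] <- 0
    if (all(w == 0)) w[sample.int(n_letters, 1L)] <- 1
    em[i, letters_idx] <- w / sum(w)
  }
  tr <- matrix(0, n, n)
  w <- stats::runif(n_emit); tr[1L, 2:(n - 1L)] <- w / sum(w)
  for (i in 2:(n - 1L)) {
    w <- stats::runif(n_emit + 1L)                 # emitting states + END
    w[stats::runif(n_emit + 1L) < zero_frac] <- 0
    w[n_emit + 1L] <- max(w[n_emit + 1L], 0.05)   # keep END reachable
    tr[i, c(2:(n - 1L), n)] <- w / sum(w)
  }
  ids <- c("START", paste0("S", seq_len(n_emit)), "END")
  validate_hmm(hmm_spec(ids, kinds, em, tr, "START", "END", tpos))
}

random_obs_seq <- function(len, n_letters = 5L) {
  paste(sample(AA_ALPHABET[seq_len(n_letters)], len, replace = TRUE),
        collapse = "")
}

# A small CDR-free template plus its initial model.
basic_template <- function(L = 30L, seed = 11L, cdr = NULL, missing = NULL) {
  withr::with_seed(seed, {
    cons <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    if (is.null(missing)) {
      segments <- data.frame(start = 1L, end = L)
      miss <- data.frame(after = integer(0), length = integer(0))
    } else {
      miss <- missing
      bounds <- sort(c(0L, miss$after, L))
      segments <- data.frame(start = integer(0), end = integer(0))
      r <- 0L
      for (s in seq_len(length(bounds) - 1L)) {
        lo <- bounds[s] + 1L; hi <- bounds[s + 1L]
        segments <- rbind(segments,
                          data.frame(start = r + 1L, end = r + (hi - lo + 1L)))
        r <- r + (hi - lo + 1L)
        if (s <= nrow(miss)) r <- r + miss$length[s]
      }
    }
    template_definition("TPL", cons, segments, miss,
                        if (is.null(cdr)) data.frame(start = integer(0), end = integer(0))
                        else cdr)
  })
}
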