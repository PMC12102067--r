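#' Training configuration
#'
#' Settings for the iterative retraining schedule: the corpus is scored with
#' the current model, the top fraction retained, and Baum-Welch (with
#' inertia) run on the retained sequences; this repeats once per fraction and
#' the calibrator is fitted on the final full-corpus scores. Defaults follow
#' the adopted schedule: fractions 30%, 20%, 10%, inertia 0.9, stop
#' threshold 50, 100 shuffles.
#'
#' @param fractions Strictly decreasing corpus fractions in `(0, 1]`.
#' @param inertia Baum-Welch inertia in `[0, 1]`.
#' @param stop_threshold Absolute corpus log-likelihood improvement below
#'   which a Baum-Welch run stops.
#' @param n_shuffles Shuffles per raw score.
#' @param rng_seed Master integer seed; all scoring randomness derives from
#'   it deterministically.
#' @param max_iterations Baum-Welch iteration cap per round.
#' @return An object of class `training_config`.
#' @export
training_config <- function(fractions = c(0.30, 0.20, 0.10), inertia = 0.9,
                            stop_threshold = 50, n_shuffles = 100L,
                            rng_seed = 1L, max_iterations = 500L) {
  stopifnot(length(fractions) >= 1L, all(fractions > 0), all(fractions <= 1))
  if (length(fractions) > 1L && any(diff(fractions) >= 0))
    stop("fractions must be strictly decreasing")
  structure(list(fractions = fractions, inertia = inertia,
                 stop_threshold = stop_threshold,
                 n_shuffles = as.integer(n_shuffles),
                 rng_seed = as.integer(rng_seed),
                 max_iterations = as.integer(max_iterations)),
            class = "training_config")
}

#' Keep only full-length light chains
#'
#' Full-length light chains comprise the variable and constant domains;
#' fragments are excluded by requiring at least `min_length` residues
#' (default 211).
#'
#' @param seqs Character vector of sequences (names preserved).
#' @param min_length Inclusive length threshold.
#' @return The retained sequences.
#' @export
filter_full_length <- function(seqs, min_length = 211L) {
  seqs[nchar(seqs) >= min_length]
}

# deterministic per-(round, sequence) scoring seed
derive_seed <- function(master, round, i) {
  as.integer((as.numeric(master) + 1000003 * round + 7919 * i) %% 2147483647)
}

score_corpus <- function(hmm, seqs, n_shuffles, master_seed, round) {
  vapply(seq_along(seqs), function(i)
    raw_score(hmm, seqs[[i]], n_shuffles,
              derive_seed(master_seed, round, i))$raw_score,
    numeric(1))
}

#' Iterative top-fraction retraining and final calibration
#'
#' For each fraction `f` in `cfg$fractions`: score the full corpus with the
#' current model (shuffle-normalized raw scores), select the
#' `ceiling(f * N)` top-scoring sequences (ties broken by input order;
#' degenerate sequences are never selected), and run Baum-Welch on the
#' selection. After the last round the full corpus is scored with the final
#' model and the quantile calibrator fitted on those scores (degenerate
#' sequences excluded from the fit but recorded in the log).
#'
#' @param initial The untrained [hmm_spec()] (see [build_initial_hmm()]).
#' @param corpus Named character vector of training sequences.
#' @param cfg A [training_config()].
#' @return A list with elements `model` (trained [hmm_spec()]), `calibrator`
#'   (a [fit_calibrator()] result), and `log` (data frame with columns
#'   `round`, `id`, `raw_score`, `selected`; the final scoring pass has
#'   round `"final"`).
#' @export
iterative_retrain <- function(initial, corpus, cfg = training_config()) {
  stopifnot(inherits(cfg, "training_config"), length(corpus) >= 1L)
  if (is.null(names(corpus)))
    names(corpus) <- sprintf("seq%04d", seq_along(corpus))
  N <- length(corpus)
  model <- initial
  log_rows <- list()
  for (r in seq_along(cfg$fractions)) {
    raw <- score_corpus(model, corpus, cfg$n_shuffles, cfg$rng_seed, r)
    k <- ceiling(cfg$fractions[r] * N)
    eligible <- which(is.finite(raw))
    if (!length(eligible))
      stop("round ", r, ": every corpus sequence is degenerate under the model")
    ord <- eligible[order(-raw[eligible])]     # stable: ties keep input order
    sel <- ord[seq_len(min(k, length(ord)))]
    if (!length(sel)) stop("round ", r, " selected zero sequences")
    log_rows[[r]] <- data.frame(round = as.character(r), id = names(corpus),
                                raw_score = raw,
                                selected = seq_len(N) %in% sel)
    model <- hmm_baum_welch(model, corpus[sel], inertia = cfg$inertia,
                            stop_threshold = cfg$stop_threshold,
                            max_iterations = cfg$max_iterations)
  }
  final_round <- length(cfg$fractions) + 1L
  raw <- score_corpus(model, corpus, cfg$n_shuffles, cfg$rng_seed, final_round)
  calibrator <- fit_calibrator(raw)
  log_rows[[final_round]] <- data.frame(round = "final", id = names(corpus),
                                        raw_score = raw, selected = FALSE)
  list(model = model, calibrator = calibrator,
       log = do.call(rbind, log_rows))
}

#' Write a training log as TSV
#' @param log The `log` element of an [iterative_retrain()] result.
#' @param path Output path.
#' @export
write_training_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
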