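#' Uniform random shuffle of a sequence
#'
#' Permutes the residues of a sequence uniformly at random, preserving the
#' residue multiset; reproducible under a fixed seed. The global RNG state is
#' left untouched.
#'
#' @param seq Non-empty amino-acid string.
#' @param rng_seed Integer seed.
#' @return A shuffled string.
#' @export
shuffle_sequence <- function(seq, rng_seed) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- split_seq(seq)
  if (length(chars) == 1L) return(seq)
  withr::with_seed(as.integer(rng_seed),
                   paste(chars[sample.int(length(chars))], collapse = ""))
}

#' Score report constructor
#'
#' @param template_id Template identifier (may be `NA`).
#' @param raw_score Log-ratio score (`-Inf` sentinel when degenerate).
#' @param calibrated_score Calibrated score in `[0, 1]`, or `NA` before
#'   calibration.
#' @param degenerate Logical: `TRUE` when the sequence has zero likelihood
#'   under the model.
#' @return An object of class `score_report`.
#' @export
score_report <- function(template_id, raw_score, calibrated_score = NA_real_,
                         degenerate = is.infinite(raw_score) && raw_score < 0) {
  if (!is.na(calibrated_score) &&
      (calibrated_score < 0 || calibrated_score > 1))
    stop("calibrated_score must lie in [0, 1]")
  structure(list(template_id = template_id, raw_score = raw_score,
                 calibrated_score = calibrated_score, degenerate = degenerate),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> template %s: raw %.4f, calibrated %s%s\n",
              x$template_id %||% "?", x$raw_score,
              ifelse(is.na(x$calibrated_score), "<unset>",
                     sprintf("%.4f", x$calibrated_score)),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shuffle-normalized raw score
#'
#' The raw score of a sequence against a template model is the log of the
#' ratio between the backward probability of the sequence and the average
#' backward probability of `n_shuffles` random shuffles of it, the average
#' taken in probability space (log-sum-exp minus `log n_shuffles`). The
#' shuffle null normalizes for sequence length and amino-acid composition. A
#' zero-likelihood sequence yields the `-Inf` sentinel and a `degenerate`
#' flag.
#'
#' @param hmm An [hmm_spec()].
#' @param seq Amino-acid string.
#' @param n_shuffles Number of random shuffles (default 100).
#' @param rng_seed Master seed; per-shuffle seeds are derived from it
#'   deterministically.
#' @param average One of `"probability"` (default: arithmetic mean of shuffle
#'   likelihoods in probability space) or `"log"` (mean of shuffle
#'   log-likelihoods).
#' @return A [score_report()] with `calibrated_score` unset.
#' @export
raw_score <- function(hmm, seq, n_shuffles = 100L, rng_seed = 1L,
                      average = c("probability", "log")) {
  average <- match.arg(average)
  stopifnot(n_shuffles >= 1L)
  cm <- hmm_compile(hmm)
  bwd <- function(s) {
    obs <- encode_seq(s) - 1L
    hmm_backward_cpp(cm$logemit, obs, cm$eto, cm$elogp, cm$fidx, cm$fptr,
                     cm$startlogp, cm$endlogp, FALSE)$loglik
  }
  ll <- bwd(seq)
  if (is.infinite(ll) && ll < 0)
    return(score_report(hmm$template_id, -Inf, degenerate = TRUE))
  seeds <- (as.numeric(rng_seed) + seq_len(n_shuffles)) %% 2147483647
  ll_sh <- vapply(seeds, function(s) bwd(shuffle_sequence(seq, s)), numeric(1))
  null_ll <- if (average == "probability") {
    fin <- ll_sh[is.finite(ll_sh)]
    if (!length(fin)) -Inf
    else {
      m <- max(fin)
      m + log(sum(exp(fin - m))) - log(n_shuffles)
    }
  } else mean(ll_sh)
  score_report(hmm$template_id, ll - null_ll, degenerate = FALSE)
}

#' Fit a quantile calibrator
#'
#' Maps raw scores to their empirical quantiles in `[0, 1]` over a reference
#' corpus: the sorted reference scores are assigned quantiles 0..1, queries
#' are linearly interpolated between reference points and clamped at the
#' extremes, so the reference minimum maps to 0 and the maximum to 1.
#' Non-finite entries (degenerate `-Inf` scores) are excluded before
#' fitting.
#'
#' @param raw_scores Numeric vector with at least two finite values.
#' @return An object of class `quantile_calibrator`.
#' @export
fit_calibrator <- function(raw_scores) {
  ref <- sort(raw_scores[is.finite(raw_scores)])
  if (length(ref) < 2L)
    stop("need at least two finite raw scores to fit a calibrator",
         if (length(ref) == 0L) " (all inputs are degenerate)" else "")
  q <- seq(0, 1, length.out = length(ref))
  # collapse duplicated reference scores to their mean quantile
  refu <- unique(ref)
  qm <- vapply(split(q, match(ref, refu)), mean, numeric(1))
  structure(list(ref = refu, q = unname(qm),
                 n_ref = length(ref), version = "1.0"),
            class = "quantile_calibrator")
}

#' Apply a quantile calibrator to raw scores
#'
#' @param calibrator A [fit_calibrator()] result.
#' @param x Numeric vector of raw scores (`-Inf` maps to 0, `Inf` to 1).
#' @return Calibrated scores in `[0, 1]`.
#' @export
calibrate <- function(calibrator, x) {
  stopifnot(inherits(calibrator, "quantile_calibrator"))
  out <- numeric(length(x))
  if (length(calibrator$ref) == 1L) {
    out[] <- as.numeric(x >= calibrator$ref)
  } else {
    out <- stats::approx(calibrator$ref, calibrator$q, xout = x,
                         rule = 2, ties = "ordered")$y
  }
  out[is.infinite(x) & x < 0] <- 0
  out[is.infinite(x) & x > 0] <- 1
  out
}

#' Calibrate a score report
#'
#' Fills `calibrated_score`; degenerate reports get calibrated score 0 and
#' keep their flag.
#'
#' @param calibrator A [fit_calibrator()] result.
#' @param report A [score_report()].
#' @return The report with `calibrated_score` set.
#' @export
calibrated_score <- function(calibrator, report) {
  stopifnot(inherits(report, "score_report"))
  report$calibrated_score <-
    if (isTRUE(report$degenerate)) 0 else calibrate(calibrator, report$raw_score)
  report
}

#' Serialize a calibrator to JSON
#' @param calibrator A [fit_calibrator()] result.
#' @param path Output path.
#' @export
write_calibrator_json <- function(calibrator, path) {
  jsonlite::write_json(
    list(format = "fibrilHMM-calibrator", version = calibrator$version,
         n_ref = calibrator$n_ref, ref = calibrator$ref, q = calibrator$q),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a calibrator from JSON
#' @param path Path written by [write_calibrator_json()].
#' @export
read_calibrator_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "fibrilHMM-calibrator"))
    stop("not a calibrator file: ", path)
  if (major_version(x$version) != 1L)
    stop("unsupported calibrator version ", x$version)
  structure(list(ref = x$ref, q = x$q, n_ref = x$n_ref, version = x$version),
            class = "quantile_calibrator")
}

major_version <- function(v) as.integer(strsplit(v, ".", fixed = TRUE)[[1L]][1L])
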