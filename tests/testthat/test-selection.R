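# calibrator placing raw score r exactly at quantile q (two-point reference)
cal_at <- function(r, q) fit_calibrator(c(r - q, r + (1 - q)))

test_that("the consensus query of a CDR-free template gets full gapless coverage", {
  tmpl <- basic_template(L = 40L, seed = 21L)
  h <- build_initial_hmm(tmpl)
  res <- align_to_template(h, NULL, tmpl, tmpl$consensus, n_shuffles = 3L)
  aln <- res$alignment
  expect_equal(aln$coverage, 1.0)
  expect_equal(nrow(aln$cdr_indels), 0L)
  expect_equal(unname(aln$flank_lengths), c(0L, 0L))
  expect_equal(aln$pairs$template_position, 1:40)
  expect_equal(aln$pairs$sequence_position, 1:40)
})

test_that("unalignable N-terminal residues are absorbed by the flank, costing coverage", {
  tmpl <- basic_template(L = 100L, seed = 23L)
  h <- build_initial_hmm(tmpl)
  junk <- withr::with_seed(24L, paste(sample(AA_ALPHABET, 20, TRUE), collapse = ""))
  q <- paste0(junk, substr(tmpl$consensus, 21, 100))
  aln <- align_to_template(h, NULL, tmpl, q, n_shuffles = 3L)$alignment
  expect_equal(aln$coverage, 0.8)
  expect_equal(unname(aln$flank_lengths[["n"]]), 20L)
  expect_equal(aln$pairs$template_position, 21:100)
  # the sequence-length denominator convention is available as a switch
  aln2 <- align_to_template(h, NULL, tmpl, q, n_shuffles = 3L,
                            coverage_denominator = "sequence")$alignment
  expect_equal(aln2$coverage, 80 / nchar(q))
})

test_that("appending unalignable residues to the termini never raises coverage", {
  tmpl <- basic_template(L = 50L, seed = 29L)
  h <- build_initial_hmm(tmpl)
  base_cov <- align_to_template(h, NULL, tmpl, tmpl$consensus,
                                n_shuffles = 3L)$alignment$coverage
  withr::with_seed(30L, {
    for (k in c(5L, 15L)) {
      pad <- paste(sample(AA_ALPHABET, k, TRUE), collapse = "")
      cov <- align_to_template(h, NULL, tmpl, paste0(pad, tmpl$consensus, pad),
                               n_shuffles = 3L)$alignment$coverage
      expect_lte(cov, base_cov)
    }
  })
})

test_that("an insertion inside a declared CDR is recorded without disturbing constant pairs", {
  tmpl <- basic_template(L = 40L, seed = 25L,
                         cdr = data.frame(start = 15L, end = 24L))
  h <- build_initial_hmm(tmpl)
  cons <- tmpl$consensus
  q <- paste0(substr(cons, 1, 18), "WWW", substr(cons, 19, 40))
  aln <- align_to_template(h, NULL, tmpl, q, n_shuffles = 3L)$alignment
  ins <- aln$cdr_indels[aln$cdr_indels$type == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$length, 3L)
  expect_true(ins$template_after >= 15L && ins$template_after < 24L)
  # constant-region pairs unaffected: identity before the CDR, +3 after it
  before <- aln$pairs[aln$pairs$template_position < 15L, ]
  after <- aln$pairs[aln$pairs$template_position > 24L, ]
  expect_equal(before$sequence_position, before$template_position)
  expect_equal(after$sequence_position, after$template_position + 3L)
})

test_that("a degenerate query yields an empty alignment with coverage zero", {
  h <- one_match_hmm()
  tmpl <- template_definition("T1", "A", data.frame(start = 1, end = 1))
  res <- align_to_template(h, NULL, tmpl, "C", n_shuffles = 2L)
  expect_equal(nrow(res$alignment$pairs), 0L)
  expect_equal(res$alignment$coverage, 0)
  expect_true(res$report$degenerate)
})

test_that("the modelability rule is strict on score and non-strict on coverage", {
  tmpl <- basic_template(L = 100L, seed = 23L)
  h <- build_initial_hmm(tmpl)
  junk20 <- withr::with_seed(24L, paste(sample(AA_ALPHABET, 20, TRUE), collapse = ""))
  q_cov80 <- paste0(junk20, substr(tmpl$consensus, 21, 100))   # coverage 0.80
  junk21 <- withr::with_seed(26L, paste(sample(AA_ALPHABET, 21, TRUE), collapse = ""))
  q_cov79 <- paste0(junk21, substr(tmpl$consensus, 22, 100))   # coverage 0.79
  r80 <- raw_score(h, q_cov80, 5L, 1L)$raw_score
  r79 <- raw_score(h, q_cov79, 5L, 1L)$raw_score

  verdict <- function(q, target_q) {
    r <- raw_score(h, q, 5L, 1L)$raw_score
    reg <- list(template_model(h, cal_at(r, target_q), tmpl))
    select_template(reg, q, n_shuffles = 5L, rng_seed = 1L)
  }
  s <- verdict(q_cov80, 0.51)                  # score 0.51, coverage 0.80
  expect_true(s$modelable)
  s <- verdict(q_cov79, 0.51)                  # score 0.51, coverage 0.79
  expect_false(s$modelable)
  expect_false(s$reasons[["coverage"]])
  expect_true(s$reasons[["score"]])
  s <- verdict(q_cov80, 0.50)                  # score exactly 0.5: strict
  expect_false(s$modelable)
  expect_false(s$reasons[["score"]])
  s <- verdict(q_cov80, 0.14)                  # far below the threshold
  expect_false(s$modelable)
})

test_that("ties between templates resolve to the lexicographically first id", {
  tmplA <- basic_template(L = 20L, seed = 31L)
  tmplB <- basic_template(L = 20L, seed = 31L)
  tmplA$template_id <- "AAA"; tmplB$template_id <- "BBB"
  hA <- build_initial_hmm(tmplA); hB <- build_initial_hmm(tmplB)
  q <- tmplA$consensus
  r <- raw_score(hA, q, 3L, 1L)$raw_score
  reg <- list(template_model(hB, cal_at(r, 0.7), tmplB),
              template_model(hA, cal_at(r, 0.7), tmplA))
  sel <- select_template(reg, q, n_shuffles = 3L, rng_seed = 1L)
  expect_identical(sel$best_template, "AAA")
})

test_that("the score matrix has one row per query and flags degenerate queries", {
  tmpl1 <- basic_template(L = 15L, seed = 41L); tmpl1$template_id <- "T1"
  tmpl2 <- basic_template(L = 15L, seed = 43L); tmpl2$template_id <- "T2"
  h1 <- build_initial_hmm(tmpl1); h2 <- build_initial_hmm(tmpl2)
  # make T2 emit only 'A' everywhere so non-A queries are degenerate on it
  emitting <- !(h2$kind %in% c("START", "END"))
  h2$emissions[emitting, ] <- 0
  h2$emissions[emitting, match("A", AA_ALPHABET)] <- 1
  cal <- fit_calibrator(c(-1, 0, 1))
  reg <- list(template_model(h1, cal, tmpl1), template_model(h2, cal, tmpl2))
  seqs <- c(q1 = tmpl1$consensus, q2 = strrep("A", 15L), q3 = tmpl1$consensus)
  mat <- export_score_matrix(reg, seqs, n_shuffles = 3L, rng_seed = 1L)
  expect_equal(nrow(mat), 3L)
  expect_true(all(c("score_T1", "score_T2", "degenerate_T1", "degenerate_T2",
                    "best_template", "modelable", "excluded") %in% names(mat)))
  sc <- unlist(mat[, c("score_T1", "score_T2")])
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(mat$excluded[mat$query_id == "q1"])     # degenerate on T2
  expect_false(mat$excluded[mat$query_id == "q2"])    # poly-A fine on both
})
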