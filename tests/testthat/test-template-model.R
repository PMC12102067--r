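make_pdb <- function(resno, path, chain = "A", seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", length(resno))
  fibrilHMM:::write_synthetic_pdb(seq, resno, 1L, path)
  path
}

test_that("contiguous numbering yields one segment and no missing segments", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_pdb(1:10, path)
  tmpl <- parse_template_structure(path, "A")
  expect_equal(tmpl$segments, data.frame(start = 1L, end = 10L))
  expect_equal(nrow(tmpl$missing_segments), 0L)
  expect_equal(nchar(tmpl$consensus), 10L)
})

test_that("a numbering jump opens a missing segment of the gap length", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_pdb(c(1:10, 16:20), path)
  tmpl <- parse_template_structure(path, "A")
  expect_equal(tmpl$segments, data.frame(start = c(1L, 16L), end = c(10L, 20L)))
  expect_equal(tmpl$missing_segments, data.frame(after = 10L, length = 5L))
})

test_that("selecting an absent chain fails with an explicit error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_pdb(1:10, path, chain = "A")
  expect_error(parse_template_structure(path, "Z"), "chain 'Z' not found")
})

test_that("template invariants are enforced", {
  expect_error(template_definition("T", "ACDE", data.frame(start = 1, end = 3)),
               "concatenate")
  expect_error(template_definition("T", "ACDE", data.frame(start = 1, end = 4),
                                   cdr_intervals = data.frame(start = 2, end = 9)),
               "within the consensus")
  expect_error(template_definition("T", "ACDE", data.frame(start = 1, end = 4),
                                   cdr_intervals = data.frame(start = c(1, 2), end = c(3, 4))),
               "overlap")
})

test_that("built model carries the untrained parameterization everywhere it should", {
  tmpl <- basic_template(L = 20L, seed = 3L, cdr = data.frame(start = 8L, end = 12L))
  h <- build_initial_hmm(tmpl)
  expect_silent(validate_hmm(h))
  cons <- strsplit(tmpl$consensus, "")[[1L]]
  for (k in c(1L, 5L, 20L)) {                # constant-region matches
    row <- h$emissions[paste0("M", k), ]
    expect_equal(unname(row[cons[k]]), 0.8)
    expect_equal(unname(row[setdiff(AA_ALPHABET, cons[k])]),
                 rep(0.2 / 19, 19))
  }
  expect_equal(unname(h$emissions["I8", ]), rep(0.05, 20))
  expect_equal(unname(h$emissions["D9", ]), rep(0.05, 20))
  expect_equal(unname(h$emissions["NFLANK", ]), rep(0.05, 20))
  # CDR gap-open split and extensions
  expect_equal(h$transitions["M8", "D9"], 0.05)
  expect_equal(h$transitions["M8", "I8"], 0.05)
  expect_equal(h$transitions["I8", "I8"], 0.9)
  expect_equal(h$transitions["D9", "D10"], 0.9)
})

test_that("a CDR-free, gap-free template reduces to a pure match chain", {
  tmpl <- basic_template(L = 15L, seed = 5L)
  h <- build_initial_hmm(tmpl)
  expect_false(any(h$kind %in% c("INSERT", "DELETE_EMIT")))
  for (k in 1:14) {
    row <- h$transitions[paste0("M", k), ]
    succ_m <- row[startsWith(names(row), "M") & row > 0]
    # exactly one successor match, absorbing all non-terminal mass
    expect_identical(names(succ_m), paste0("M", k + 1L))
    terminal <- row["CFLANK"] + row["END"]
    expect_equal(unname(succ_m + terminal), 1)
  }
})

test_that("inter-segment skip states carry the 0.9 extend / 0.1 terminate wiring", {
  tmpl <- basic_template(L = 20L, seed = 9L,
                         missing = data.frame(after = 12L, length = 6L))
  h <- build_initial_hmm(tmpl)
  expect_true("DSEG12" %in% h$id)
  expect_equal(h$transitions["DSEG12", "DSEG12"], 0.9)
  expect_equal(h$transitions["DSEG12", "M13"], 0.1)
  expect_equal(h$transitions["M12", "DSEG12"],
               1 - hmm_build_params()$exit_open)
})

test_that("structural constraints hold in the state graph for random templates", {
  withr::with_seed(77L, {
    for (case in 1:10) {
      L <- sample(30:60, 1L)
      a <- sample(8:(L - 15L), 1L); b <- a + sample(4:10, 1L)
      tmpl <- basic_template(L = L, seed = sample.int(1e6, 1L),
                             cdr = data.frame(start = a, end = b))
      h <- build_initial_hmm(tmpl)
      expect_silent(validate_hmm(h))
      in_cdr <- seq_len(L) %in% a:b
      for (i in which(h$kind == "INSERT")) {
        nb <- unique(c(names(which(h$transitions[i, ] > 0)),
                       names(which(h$transitions[, i] > 0))))
        nb_match <- nb[startsWith(nb, "M") & !startsWith(nb, "MI")]
        pos <- as.integer(sub("^M", "", nb_match))
        expect_true(all(in_cdr[pos]))   # inserts touch only CDR matches
      }
      for (i in which(h$kind == "DELETE_EMIT")) {
        id <- h$id[i]
        expect_true(startsWith(id, "DSEG") ||
                      in_cdr[as.integer(sub("^D", "", id))])
      }
      # round-trip: consensus reconstructed from MATCH states
      m <- which(h$kind == "MATCH")
      m <- m[order(h$template_position[m])]
      rebuilt <- vapply(m, function(i) AA_ALPHABET[which.max(h$emissions[i, ])],
                        character(1))
      expect_identical(paste(rebuilt, collapse = ""), tmpl$consensus)
    }
  })
})

test_that("a CDR overlapping a missing-segment boundary is rejected", {
  tmpl <- basic_template(L = 20L, seed = 13L,
                         missing = data.frame(after = 10L, length = 4L))
  tmpl$cdr_intervals <- data.frame(start = 8L, end = 13L)
  expect_error(build_initial_hmm(tmpl), "ambiguous")
})
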