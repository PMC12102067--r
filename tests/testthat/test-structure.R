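# Two-chain synthetic fibril fixture with a CDR-free template and its model.
structure_fixture <- function(L = 20L, seed = 51L) {
  fx <- generate_fixture(fixture_spec(template_length = L,
                                      cdr_intervals = list(),
                                      mutation_rate = 0, cdr_indel_rate = 0,
                                      corpus_size = 1L, rng_seed = seed,
                                      n_chains = 2L, flank_prob = 0),
                         dir = withr::local_tempdir(.local_envir = parent.frame()))
  fx$model <- build_initial_hmm(fx$template)
  fx
}

self_alignment <- function(fx) {
  align_to_template(fx$model, NULL, fx$template, fx$template$consensus,
                    n_shuffles = 2L)$alignment
}

test_that("full-coverage self-alignment preserves the backbone byte for byte", {
  fx <- structure_fixture()
  aln <- self_alignment(fx)
  expect_equal(aln$coverage, 1.0)
  pruned <- prune_backbone(fx$structure_path, aln, fx$template)
  orig <- readLines(fx$structure_path)
  atom_lines <- function(x) x[startsWith(x, "ATOM")]
  expect_identical(atom_lines(pruned$lines), atom_lines(orig))
  expect_equal(unname(pruned$removed_per_chain), c(0L, 0L))
})

test_that("self-modeling emits an empty mutation list that round-trips", {
  fx <- structure_fixture()
  aln <- self_alignment(fx)
  pruned <- prune_backbone(fx$structure_path, aln, fx$template)
  prefix <- file.path(withr::local_tempdir(), "job")
  job <- emit_sidechain_job(pruned, aln, fx$template$consensus, prefix)
  expect_equal(nrow(job$mutations), 0L)
  expect_equal(nrow(read_mutation_list(job$files[["mutant_file"]])), 0L)
  expect_true(file.exists(job$files[["pdb"]]))
  manifest <- jsonlite::read_json(job$files[["manifest"]])
  expect_identical(manifest$job_type, "BuildModel")
})

test_that("dropping k consensus positions removes exactly k residues per chain", {
  fx <- structure_fixture()
  aln <- self_alignment(fx)
  drop <- c(3L, 7L, 11L, 15L, 19L)
  aln$pairs <- aln$pairs[!(aln$pairs$template_position %in% drop), ]
  pruned <- prune_backbone(fx$structure_path, aln, fx$template)
  expect_equal(unname(pruned$removed_per_chain), c(5L, 5L))
  # atom-level count: 4 backbone atoms per residue, 2 chains, 5 residues each
  n_atoms <- function(lines) sum(startsWith(lines, "ATOM"))
  expect_equal(n_atoms(readLines(fx$structure_path)) - n_atoms(pruned$lines),
               4L * 2L * 5L)
})

test_that("a substitution on the query yields one mutation token per chain", {
  fx <- structure_fixture()
  aln <- self_alignment(fx)
  cons <- strsplit(fx$template$consensus, "")[[1L]]
  k <- 8L
  mutant <- setdiff(AA_ALPHABET, cons[k])[1L]
  q <- paste(replace(cons, k, mutant), collapse = "")
  pruned <- prune_backbone(fx$structure_path, aln, fx$template)
  prefix <- file.path(withr::local_tempdir(), "job")
  job <- emit_sidechain_job(pruned, aln, q, prefix)
  expect_equal(nrow(job$mutations), 2L)
  expect_setequal(job$mutations$chain, c("A", "B"))
  expect_true(all(job$mutations$wt == cons[k] & job$mutations$mut == mutant))
  back <- read_mutation_list(job$files[["mutant_file"]])
  expect_equal(back[order(back$chain), ],
               job$mutations[order(job$mutations$chain), ],
               ignore_attr = TRUE)
  # token format on disk
  line <- readLines(job$files[["mutant_file"]])[1L]
  expect_match(line, sprintf("^%sA%d%s;%sB%d%s;$", cons[k], k, mutant,
                             cons[k], k, mutant))
})

test_that("degenerate alignments and non-canonical queries are rejected", {
  fx <- structure_fixture()
  empty <- structure(list(template_id = "SYNTH1",
                          pairs = data.frame(template_position = integer(0),
                                             sequence_position = integer(0)),
                          coverage = 0),
                     class = "alignment_result")
  expect_error(prune_backbone(fx$structure_path, empty, fx$template),
               "degenerate")
  aln <- self_alignment(fx)
  pruned <- prune_backbone(fx$structure_path, aln, fx$template)
  prefix <- file.path(withr::local_tempdir(), "job")
  expect_error(emit_sidechain_job(pruned, aln, gsub("^.", "B", fx$template$consensus),
                                  prefix),
               "non-canonical")
})

test_that("pruning respects author numbering across a missing segment", {
  dirp <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(template_length = 16L,
                                      cdr_intervals = list(),
                                      missing_segments = list(c(8L, 4L)),
                                      mutation_rate = 0, cdr_indel_rate = 0,
                                      corpus_size = 1L, rng_seed = 53L,
                                      n_chains = 1L, flank_prob = 0),
                         dir = dirp)
  model <- build_initial_hmm(fx$template)
  q <- fx$corpus[[1L]]     # includes the unresolved-segment residues
  aln <- align_to_template(model, NULL, fx$template, q, n_shuffles = 2L)$alignment
  expect_equal(aln$coverage, 1.0)
  pruned <- prune_backbone(fx$structure_path, aln, fx$template)
  # consensus position 9 sits at author residue 13 after the 4-residue gap
  expect_equal(consensus_to_resno(fx$template)[9L], 13L)
  expect_equal(sort(unique(pruned$mapping$resno)), consensus_to_resno(fx$template))
})
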